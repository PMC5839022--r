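#' Read case-parent trios from a PED file
#'
#' Standard 6-column whitespace-delimited pedigree
#' (`family id father mother sex phenotype`). One trio is returned for every
#' affected child (phenotype 2) whose father and mother both appear as rows.
#'
#' @param path PED file path.
#' @return Tibble with columns `family_id`, `child_id`, `father_id`,
#'   `mother_id`, `child_affected`, `child_sex`.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(ped) < 6) stop("pedigree file must have at least 6 columns")
  ped <- ped[, 1:6]
  names(ped) <- c("family_id", "id", "father_id", "mother_id", "sex",
                  "phenotype")
  dup <- ped$id[duplicated(ped$id)]
  if (length(dup)) stop("duplicate sample id in pedigree: ",
                        paste(unique(dup), collapse = ", "))
  kids <- ped[ped$father_id != "0" & ped$mother_id != "0" &
                ped$phenotype == "2", , drop = FALSE]
  for (i in seq_len(nrow(kids))) {
    for (p in c(kids$father_id[i], kids$mother_id[i])) {
      if (!p %in% ped$id) {
        stop("child ", kids$id[i], " references absent parent ", p)
      }
    }
  }
  sex <- unname(c("1" = "male", "2" = "female")[kids$sex])
  sex[is.na(sex)] <- "unknown"
  tibble(
    family_id = kids$family_id,
    child_id = kids$id,
    father_id = kids$father_id,
    mother_id = kids$mother_id,
    child_affected = TRUE,
    child_sex = sex
  )
}

#' Write a trio table as a PED file
#'
#' @param trios Trio tibble as returned by [read_pedigree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(trios, path) {
  sex_code <- c(male = "1", female = "2", unknown = "0")
  lines <- character(0)
  for (i in seq_len(nrow(trios))) {
    lines <- c(
      lines,
      paste(trios$family_id[i], trios$father_id[i], "0", "0", "1", "1"),
      paste(trios$family_id[i], trios$mother_id[i], "0", "0", "2", "1"),
      paste(trios$family_id[i], trios$child_id[i], trios$father_id[i],
            trios$mother_id[i], sex_code[[trios$child_sex[i]]], "2")
    )
  }
  writeLines(lines, path)
  invisible(path)
}
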