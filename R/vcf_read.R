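#' Construct a trio dataset container
#'
#' The pipeline's in-memory data model: one tidy table per aspect of a
#' multi-sample, biallelic-normalized VCF, keyed by `chrom:pos:ref:alt`.
#'
#' @param variants Tibble: `key`, `chrom`, `pos`, `ref`, `alt`, `qual`.
#' @param genotypes Long tibble: `key`, `sample`, `n_alt` (0/1/2 alternate
#'   allele count, `NA` when uncalled), `ad_ref`, `ad_alt`, `dp`, `gq`,
#'   `pl0`, `pl1`, `pl2`.
#' @param annotations Tibble: `key` plus [parse_annotations()] columns.
#' @param scores Tibble: `key`, `sift`, `polyphen`, `cadd_phred`,
#'   `sift_rank`, `polyphen_rank`, `cadd_rank`, `maf`.
#' @param trios Trio tibble as from [read_pedigree()].
#' @return An object of class `trio_dataset`.
#' @export
trio_dataset <- function(variants, genotypes, annotations, scores, trios) {
  structure(list(variants = variants, genotypes = genotypes,
                 annotations = annotations, scores = scores, trios = trios),
            class = "trio_dataset")
}

#' @export
print.trio_dataset <- function(x, ...) {
  cat("trio_dataset:", nrow(x$variants), "biallelic records,",
      nrow(x$trios), "trios,", length(unique(x$genotypes$sample)),
      "samples\n")
  invisible(x)
}

empty_scores <- function() {
  tibble(key = character(), sift = numeric(), polyphen = numeric(),
         cadd_phred = numeric(), sift_rank = numeric(),
         polyphen_rank = numeric(), cadd_rank = numeric(), maf = numeric())
}

#' Read a per-variant score/MAF table
#'
#' Tab-delimited with header columns `chrom`, `pos`, `ref`, `alt` and any of
#' `sift`, `polyphen`, `cadd_phred`, `sift_rank`, `polyphen_rank`,
#' `cadd_rank`, `maf`. Missing score columns are filled with `NA`.
#'
#' @param path File path.
#' @return Score tibble keyed by `chrom:pos:ref:alt`.
#' @export
read_score_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(chrom = "c", pos = "i",
                                               ref = "c", alt = "c",
                                               .default = "d"))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(x))) {
    stop("score table must have columns chrom, pos, ref, alt")
  }
  for (col in c("sift", "polyphen", "cadd_phred", "sift_rank",
                "polyphen_rank", "cadd_rank", "maf")) {
    if (!col %in% names(x)) x[[col]] <- NA_real_
  }
  x %>%
    mutate(key = vkey(.data$chrom, .data$pos, .data$ref, .data$alt)) %>%
    select("key", "sift", "polyphen", "cadd_phred", "sift_rank",
           "polyphen_rank", "cadd_rank", "maf")
}

# PL indices (0-based) of the (0/0, 0/alt_k, alt_k/alt_k) likelihoods for
# alternate allele k under the VCF genotype ordering.
pl_subset_idx <- function(k) {
  c(0L, as.integer(k * (k + 1) / 2), as.integer(k * (k + 1) / 2 + k)) + 1L
}

#' Read a multi-sample VCF into the trio data model
#'
#' Multi-allelic sites are split into biallelic records: per alternate
#' allele, allele depths and the PL triple are subset; genotype calls that
#' involve a different alternate allele are treated as missing for that
#' split record. Positions are kept 1-based exactly as in the VCF. Records
#' are emitted in file order. A sample column missing for any trio member is
#' a hard error; a missing FORMAT field leaves the corresponding columns
#' `NA` with a warning.
#'
#' Per-variant scores are taken from INFO keys (`score_info_keys`) when
#' present and overridden by `score_table` entries on conflict.
#'
#' @param path VCF path (plain or bgzip).
#' @param trios Trio tibble from [read_pedigree()].
#' @param score_table Optional score tibble from [read_score_table()].
#' @param dialect Annotation dialect `"ANN"` or `"CSQ"`; auto-detected when
#'   `NULL`.
#' @param score_info_keys Named character vector mapping score columns to
#'   INFO keys.
#' @return A [trio_dataset()].
#' @export
read_trio_vcf <- function(path, trios, score_table = NULL, dialect = NULL,
                          score_info_keys = c(sift = "SIFT",
                                              polyphen = "POLYPHEN",
                                              cadd_phred = "CADD_PHRED",
                                              sift_rank = "SIFT_RANK",
                                              polyphen_rank = "POLYPHEN_RANK",
                                              cadd_rank = "CADD_RANK",
                                              maf = "MAF")) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcf@gt
  samples <- colnames(gt)[-1]
  need <- unique(c(trios$child_id, trios$father_id, trios$mother_id))
  miss <- setdiff(need, samples)
  if (length(miss)) {
    stop("VCF lacks sample column(s): ", paste(miss, collapse = ", "))
  }
  n <- nrow(fix)
  if (is.null(n) || n == 0) {
    return(trio_dataset(
      tibble(key = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), qual = numeric()),
      tibble(key = character(), sample = character(), n_alt = integer(),
             ad_ref = numeric(), ad_alt = numeric(), dp = integer(),
             gq = numeric(), pl0 = numeric(), pl1 = numeric(),
             pl2 = numeric()),
      mutate(empty_annotations(), key = character(0), .before = 1),
      empty_scores(), trios))
  }
  info <- fix[, "INFO"]
  if (is.null(dialect)) {
    if (any(grepl("(^|;)ANN=", info))) dialect <- "ANN"
    else if (any(grepl("(^|;)CSQ=", info))) dialect <- "CSQ"
  }

  fmt_keys <- strsplit(gt[, 1], ":", fixed = TRUE)
  warned <- new.env()
  warn_once <- function(fieldname) {
    if (!isTRUE(warned[[fieldname]])) {
      warned[[fieldname]] <- TRUE
      warning("FORMAT field ", fieldname,
              " missing for some records; fields left NA", call. = FALSE)
    }
  }

  var_rows <- vector("list", n)
  gt_rows <- vector("list", n)
  ann_rows <- vector("list", n)
  sc_rows <- vector("list", n)

  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    keys_i <- fmt_keys[[i]]
    svals <- strsplit(unname(gt[i, -1]), ":", fixed = TRUE)
    getf <- function(s, name) {
      j <- match(name, keys_i)
      if (is.na(j) || j > length(s)) NA_character_ else s[[j]]
    }
    ann <- if (!is.null(dialect)) parse_annotations(info[i], dialect) else
      empty_annotations()
    qual <- as_num(fix[i, "QUAL"])
    chrom <- fix[i, "CHROM"]
    pos <- as_int(fix[i, "POS"])
    ref <- fix[i, "REF"]

    vr <- list(); gr <- list(); ar <- list(); sr <- list()
    for (k in seq_along(alts)) {
      key <- vkey(chrom, pos, ref, alts[k])
      vr[[k]] <- tibble(key = key, chrom = chrom, pos = pos, ref = ref,
                        alt = alts[k], qual = qual)
      # per-allele annotation match; keep all entries when no allele matches
      a <- ann
      if (nrow(a) > 0 && length(alts) > 1) {
        hit <- a$allele == alts[k]
        if (any(hit)) a <- a[hit, , drop = FALSE]
      }
      if (nrow(a) > 0) ar[[k]] <- mutate(a, key = key, .before = 1)

      # INFO-derived scores (per-site; applied to each split record)
      sv <- vapply(score_info_keys, function(ik) {
        as_num(info_field(info[i], ik))
      }, 0.0)
      if (any(!is.na(sv))) {
        sr[[k]] <- tibble(key = key, sift = sv[["sift"]],
                          polyphen = sv[["polyphen"]],
                          cadd_phred = sv[["cadd_phred"]],
                          sift_rank = sv[["sift_rank"]],
                          polyphen_rank = sv[["polyphen_rank"]],
                          cadd_rank = sv[["cadd_rank"]], maf = sv[["maf"]])
      }

      n_alt <- integer(length(samples))
      ad_ref <- ad_alt <- gq <- pl0 <- pl1 <- pl2 <- rep(NA_real_,
                                                         length(samples))
      dp <- rep(NA_integer_, length(samples))
      for (s in seq_along(samples)) {
        sv_s <- svals[[s]]
        gts <- getf(sv_s, "GT")
        if (is.na(match("GT", keys_i))) warn_once("GT")
        na_gt <- TRUE
        if (!is.na(gts) && !grepl("\\.", gts)) {
          al <- as_int(strsplit(gts, "[/|]")[[1]])
          if (length(al) == 2 && !anyNA(al) && all(al %in% c(0L, k))) {
            n_alt[s] <- sum(al == k)
            na_gt <- FALSE
          }
        }
        if (na_gt) n_alt[s] <- NA_integer_

        adf <- getf(sv_s, "AD")
        if (is.na(match("AD", keys_i))) warn_once("AD")
        if (!is.na(adf)) {
          adv <- as_num(strsplit(adf, ",", fixed = TRUE)[[1]])
          if (length(adv) >= k + 1) {
            ad_ref[s] <- adv[1]
            ad_alt[s] <- adv[k + 1]
          }
        }
        dpf <- getf(sv_s, "DP")
        if (is.na(match("DP", keys_i))) warn_once("DP")
        dp[s] <- as_int(dpf)
        if (is.na(dp[s]) && !is.na(ad_ref[s])) {
          dp[s] <- as_int(ad_ref[s] + ad_alt[s])
        }
        gqf <- getf(sv_s, "GQ")
        if (is.na(match("GQ", keys_i))) warn_once("GQ")
        gq[s] <- as_num(gqf)
        plf <- getf(sv_s, "PL")
        if (is.na(match("PL", keys_i))) warn_once("PL")
        if (!is.na(plf)) {
          plv <- as_num(strsplit(plf, ",", fixed = TRUE)[[1]])
          idx <- pl_subset_idx(k)
          if (length(plv) >= max(idx) && !anyNA(plv[idx])) {
            p3 <- plv[idx] - min(plv[idx])
            pl0[s] <- p3[1]; pl1[s] <- p3[2]; pl2[s] <- p3[3]
          }
        }
      }
      gr[[k]] <- tibble(key = key, sample = samples, n_alt = n_alt,
                        ad_ref = ad_ref, ad_alt = ad_alt, dp = dp, gq = gq,
                        pl0 = pl0, pl1 = pl1, pl2 = pl2)
    }
    var_rows[[i]] <- bind_rows(vr)
    gt_rows[[i]] <- bind_rows(gr)
    if (length(ar)) ann_rows[[i]] <- bind_rows(ar)
    if (length(sr)) sc_rows[[i]] <- bind_rows(sr)
  }

  variants <- bind_rows(var_rows)
  genotypes <- bind_rows(gt_rows)
  annotations <- bind_rows(ann_rows)
  if (nrow(annotations) == 0) {
    annotations <- mutate(empty_annotations(), key = character(0),
                          .before = 1)
  }
  scores <- bind_rows(sc_rows)
  if (nrow(scores) == 0) scores <- empty_scores()

  # side table wins over INFO-derived values
  if (!is.null(score_table) && nrow(score_table) > 0) {
    scores <- scores %>%
      filter(!.data$key %in% score_table$key) %>%
      bind_rows(score_table %>% filter(.data$key %in% variants$key))
  }
  trio_dataset(variants, genotypes, annotations, scores, trios)
}
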