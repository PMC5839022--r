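#' Closed consequence vocabulary
#'
#' Functional consequence categories used by the pipeline, ordered from most
#' to least severe. Severity decides which annotation names a variant's gene
#' and under which category a multi-annotated variant is tallied.
#'
#' @return Character vector of consequence levels, most severe first.
#' @export
consequence_levels <- function() {
  c("stop_gained", "frameshift", "splice_site", "start_lost", "stop_lost",
    "missense", "inframe_insertion", "inframe_deletion", "synonymous",
    "other")
}

# Sequence-Ontology-style effect terms -> closed vocabulary.
.so_map <- c(
  missense_variant                 = "missense",
  stop_gained                      = "stop_gained",
  frameshift_variant               = "frameshift",
  inframe_insertion                = "inframe_insertion",
  conservative_inframe_insertion   = "inframe_insertion",
  disruptive_inframe_insertion     = "inframe_insertion",
  inframe_deletion                 = "inframe_deletion",
  conservative_inframe_deletion    = "inframe_deletion",
  disruptive_inframe_deletion      = "inframe_deletion",
  splice_acceptor_variant          = "splice_site",
  splice_donor_variant             = "splice_site",
  splice_region_variant            = "splice_site",
  start_lost                       = "start_lost",
  initiator_codon_variant          = "start_lost",
  stop_lost                        = "stop_lost",
  synonymous_variant               = "synonymous",
  stop_retained_variant            = "synonymous"
)

# Closed vocabulary -> representative SO term, used when writing VCFs.
.so_rev <- c(
  missense          = "missense_variant",
  stop_gained       = "stop_gained",
  frameshift        = "frameshift_variant",
  inframe_insertion = "inframe_insertion",
  inframe_deletion  = "inframe_deletion",
  splice_site       = "splice_donor_variant",
  start_lost        = "start_lost",
  stop_lost         = "stop_lost",
  synonymous        = "synonymous_variant",
  other             = "intergenic_region"
)

map_effect <- function(effect) {
  # effect strings may join several SO terms with '&'; keep the most severe
  vapply(strsplit(effect, "&", fixed = TRUE), function(terms) {
    mapped <- .so_map[terms]
    mapped <- mapped[!is.na(mapped)]
    if (length(mapped) == 0) return("other")
    mapped[which.min(match(mapped, consequence_levels()))]
  }, "")
}

empty_annotations <- function() {
  tibble(gene_symbol = character(), transcript_id = character(),
         consequence = character(), hgvs_c = character(),
         hgvs_p = character(), allele = character())
}

#' Parse functional annotations from a VCF INFO string
#'
#' Understands SnpEff `ANN=` and VEP `CSQ=` pipe-delimited entries. Effect
#' terms are mapped into the closed vocabulary of [consequence_levels()];
#' unknown terms become `"other"`. Malformed entries are skipped with a
#' warning, never an error.
#'
#' @param info_text A full INFO string (the `ANN=`/`CSQ=` value is located
#'   inside it) or the bare annotation value.
#' @param dialect `"ANN"` (SnpEff) or `"CSQ"` (VEP-style
#'   `Allele|Consequence|SYMBOL|Gene|Feature|HGVSc|HGVSp`).
#' @return Tibble with columns `gene_symbol`, `transcript_id`,
#'   `consequence`, `hgvs_c`, `hgvs_p`, `allele`.
#' @export
parse_annotations <- function(info_text, dialect = c("ANN", "CSQ")) {
  dialect <- match.arg(dialect)
  stopifnot(length(info_text) == 1)
  val <- info_text
  if (grepl(paste0("(^|;)", dialect, "="), info_text)) {
    val <- info_field(info_text, dialect)
  }
  if (is.na(val) || !nzchar(val)) return(empty_annotations())
  entries <- strsplit(val, ",", fixed = TRUE)[[1]]
  rows <- lapply(entries, function(e) {
    f <- strsplit(e, "|", fixed = TRUE)[[1]]
    if (dialect == "ANN") {
      if (length(f) < 4) {
        warning("skipping malformed ANN entry: ", e, call. = FALSE)
        return(NULL)
      }
      tibble(gene_symbol = f[4], transcript_id = if (length(f) >= 7) f[7] else "",
             consequence = map_effect(f[2]),
             hgvs_c = if (length(f) >= 10) f[10] else "",
             hgvs_p = if (length(f) >= 11) f[11] else "",
             allele = f[1])
    } else {
      if (length(f) < 3) {
        warning("skipping malformed CSQ entry: ", e, call. = FALSE)
        return(NULL)
      }
      tibble(gene_symbol = f[3], transcript_id = if (length(f) >= 5) f[5] else "",
             consequence = map_effect(f[2]),
             hgvs_c = if (length(f) >= 6) f[6] else "",
             hgvs_p = if (length(f) >= 7) f[7] else "",
             allele = f[1])
    }
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(empty_annotations())
  bind_rows(rows)
}

#' Most severe annotation per variant
#'
#' Collapses a multi-transcript annotation table to one row per variant key:
#' the most severe consequence, with ties on severity broken by lexicographic
#' gene symbol.
#'
#' @param annotations Tibble with columns `key`, `gene_symbol`,
#'   `consequence`.
#' @return Tibble with columns `key`, `gene`, `consequence`.
#' @export
most_severe_annotation <- function(annotations) {
  if (nrow(annotations) == 0) {
    return(tibble(key = character(), gene = character(),
                  consequence = character()))
  }
  annotations %>%
    mutate(.sev = match(.data$consequence, consequence_levels())) %>%
    arrange(.data$key, .data$.sev, .data$gene_symbol) %>%
    group_by(.data$key) %>%
    slice(1) %>%
    ungroup() %>%
    transmute(key = .data$key, gene = .data$gene_symbol,
              consequence = .data$consequence)
}
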