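#' Genotype-level filter thresholds
#'
#' Defaults follow the familial filtering rule used for trio exomes:
#' heterozygous calls must have balanced allele depths (alternate fraction
#' within `[0.35, 0.65]`, bounds inclusive) and every member must have a
#' genotype quality strictly greater than 20.
#'
#' @param ab_min,ab_max Inclusive allele-balance bounds for heterozygous
#'   calls.
#' @param gq_min Phred genotype-quality threshold (strict `>`).
#' @param min_depth Minimum read depth (0 disables).
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(ab_min = 0.35, ab_max = 0.65, gq_min = 20,
                              min_depth = 0) {
  stopifnot(ab_min >= 0, ab_min <= 0.5, ab_max >= 0.5, ab_max <= 1,
            gq_min >= 0, min_depth >= 0)
  structure(list(ab_min = ab_min, ab_max = ab_max, gq_min = gq_min,
                 min_depth = min_depth), class = "filter_thresholds")
}

#' Allele balance of a heterozygous call
#'
#' Fraction of reads supporting the alternate allele,
#' `ad_alt / (ad_ref + ad_alt)`. Defined only for heterozygous calls with
#' reads at the two alleles; `NA` otherwise (homozygous calls are
#' allele-balance-exempt).
#'
#' @param ad_ref,ad_alt Reference/alternate allele depths.
#' @param n_alt Alternate allele count of the call (0/1/2 or `NA`).
#' @return Numeric vector.
#' @export
allele_balance <- function(ad_ref, ad_alt, n_alt = 1L) {
  tot <- ad_ref + ad_alt
  ab <- ifelse(!is.na(tot) & tot > 0, ad_alt / tot, NA_real_)
  ifelse(!is.na(n_alt) & n_alt == 1L, ab, NA_real_)
}

member_pass <- function(n_alt, ad_ref, ad_alt, dp, gq, thresholds,
                        apply_ab = TRUE) {
  th <- thresholds
  called <- !is.na(n_alt)
  gq_ok <- !is.na(gq) & gq > th$gq_min
  dp_ok <- if (th$min_depth == 0) TRUE else (!is.na(dp) & dp >= th$min_depth)
  ab <- allele_balance(ad_ref, ad_alt, n_alt)
  het <- !is.na(n_alt) & n_alt == 1L
  ab_ok <- ifelse(het & apply_ab,
                  !is.na(ab) & ab >= th$ab_min & ab <= th$ab_max, TRUE)
  called & gq_ok & dp_ok & ab_ok
}

#' Per-member and record-level genotype filter flags for one trio
#'
#' A member passes when its genotype is called, its GQ is present and
#' strictly above `gq_min`, depth meets `min_depth`, and — for heterozygous
#' calls — the allele balance lies inside the inclusive `[ab_min, ab_max]`
#' band. A record passes when all three members pass.
#'
#' @param ds A [trio_dataset()].
#' @param trio One row of `ds$trios`.
#' @param thresholds A [filter_thresholds()] object.
#' @param ab_parents Apply the allele-balance band to parents as well as the
#'   child (default `TRUE`).
#' @return Tibble with `key`, `child_pass`, `father_pass`, `mother_pass`,
#'   `record_pass`.
#' @export
passes_genotype_filters <- function(ds, trio,
                                    thresholds = filter_thresholds(),
                                    ab_parents = TRUE) {
  g <- trio_genotype_wide(ds, trio)
  tibble(
    key = g$key,
    child_pass = member_pass(g$n_alt_c, g$ad_ref_c, g$ad_alt_c, g$dp_c,
                             g$gq_c, thresholds, apply_ab = TRUE),
    father_pass = member_pass(g$n_alt_f, g$ad_ref_f, g$ad_alt_f, g$dp_f,
                              g$gq_f, thresholds, apply_ab = ab_parents),
    mother_pass = member_pass(g$n_alt_m, g$ad_ref_m, g$ad_alt_m, g$dp_m,
                              g$gq_m, thresholds, apply_ab = ab_parents)
  ) %>%
    mutate(record_pass = .data$child_pass & .data$father_pass &
             .data$mother_pass)
}

# One row per variant with child/father/mother genotype evidence
# side-by-side, aligned to ds$variants order.
trio_genotype_wide <- function(ds, trio) {
  pick <- function(sample_id, suffix) {
    ds$genotypes %>%
      filter(.data$sample == sample_id) %>%
      select("key", "n_alt", "ad_ref", "ad_alt", "dp", "gq", "pl0", "pl1",
             "pl2") %>%
      rename_with(~ paste0(.x, "_", suffix), -"key")
  }
  ds$variants %>%
    select("key", "chrom", "pos", "ref", "alt") %>%
    left_join(pick(trio$child_id, "c"), by = "key") %>%
    left_join(pick(trio$father_id, "f"), by = "key") %>%
    left_join(pick(trio$mother_id, "m"), by = "key")
}
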