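#' Chance-observation probability from a site QUAL
#'
#' Converts a VCF site quality into the probability that the variant
#' observation is due to chance under the reciprocal convention
#' `p = 1/QUAL`.
#'
#' @param qual Positive site quality value(s).
#' @return Numeric vector of probabilities.
#' @export
qual_to_chance_prob <- function(qual) {
  if (any(is.na(qual)) || any(qual <= 0)) {
    stop("qual must be > 0")
  }
  1 / qual
}

variant_table_cols <- function() {
  readr::cols(gene = "c", trio_id = "c", chrom = "c", pos = "i", ref = "c",
              alt = "c", qual = "d", depth = "i", consequence = "c",
              sift = "d", polyphen = "d", maf = "d", class = "c")
}

#' Write segregation calls as a tab-delimited variant table
#'
#' One row per (trio, variant) call with the gene, coordinates, site
#' quality, child depth, most severe consequence, scores, MAF and
#' segregation class. Rows are ordered deterministically by (chrom, pos,
#' trio) so rewriting a read table is byte-identical.
#'
#' @param ds A [trio_dataset()].
#' @param calls Calls tibble from [segregate_all()].
#' @param path Output path.
#' @return The written tibble, invisibly.
#' @export
write_variant_table <- function(ds, calls, path) {
  stopifnot(all(calls$key %in% ds$variants$key))
  child_dp <- ds$genotypes %>%
    inner_join(ds$trios %>% select(trio_id = "family_id",
                                   sample = "child_id"),
               by = "sample") %>%
    select("key", "trio_id", depth = "dp")
  sev <- most_severe_annotation(ds$annotations)
  out <- calls %>%
    left_join(ds$variants %>% select("key", "qual"), by = "key") %>%
    left_join(child_dp, by = c("key", "trio_id")) %>%
    left_join(sev %>% select("key", "consequence"), by = "key") %>%
    left_join(ds$scores %>% select("key", "sift", "polyphen", "maf"),
              by = "key") %>%
    transmute(.data$gene, .data$trio_id, .data$chrom, .data$pos, .data$ref,
              .data$alt, .data$qual, .data$depth, .data$consequence,
              .data$sift, .data$polyphen, .data$maf, .data$class) %>%
    arrange(chrom_rank(.data$chrom), .data$chrom, .data$pos, .data$trio_id)
  readr::write_tsv(out, path, na = "NA")
  invisible(out)
}

#' Read a variant table written by [write_variant_table()]
#'
#' @param path File path.
#' @return Tibble with the variant-table columns.
#' @export
read_variant_table <- function(path) {
  readr::read_tsv(path, col_types = variant_table_cols())
}
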