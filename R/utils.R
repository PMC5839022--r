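#' Variant key
#'
#' Canonical `chrom:pos:ref:alt` identifier used throughout the pipeline.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position (as printed in VCF).
#' @param ref,alt Reference and alternate allele strings.
#' @return Character vector of keys.
#' @export
vkey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Numeric rank for chromosome names so output ordering is genomic, not
# lexicographic; unknown contigs sort after the standard set.
chrom_rank <- function(chrom) {
  std <- c(as.character(1:22), "X", "Y", "MT", "M")
  r <- match(sub("^chr", "", as.character(chrom)), std)
  r[is.na(r)] <- length(std) + 1L
  r
}

# Extract `KEY=value` from a semicolon-separated VCF INFO string.
info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

as_num <- function(x) suppressWarnings(as.numeric(x))
as_int <- function(x) suppressWarnings(as.integer(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
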