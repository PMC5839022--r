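# Shared in-code builders for small datasets.

test_trios <- function(n = 1) trioseg:::default_trios(n)

# A tiny single-trio dataset built directly from genotype triples.
# triples: list of c(child, father, mother) allele counts; gq/dp per call.
tiny_dataset <- function(triples, gq = 99, dp = 100, maf = NULL,
                         gene = NULL, consequence = "missense") {
  n <- length(triples)
  trios <- test_trios(1)
  chrom <- rep("1", n)
  pos <- 1000L + seq_len(n)
  ref <- rep("A", n)
  alt <- rep("G", n)
  key <- vkey(chrom, pos, ref, alt)
  gq <- rep_len(gq, n)
  dp <- rep_len(dp, n)
  gene <- if (is.null(gene)) sprintf("GENE%03d", seq_len(n)) else
    rep_len(gene, n)
  consequence <- rep_len(consequence, n)
  rows <- list()
  for (i in seq_len(n)) {
    ids <- c(trios$child_id, trios$father_id, trios$mother_id)
    for (m in 1:3) {
      na <- triples[[i]][m]
      e <- trioseg:::geno_fields(ifelse(is.na(na), 0L, na), dp[i],
                                 allele_noise = FALSE, base_error = 1e-3)
      rows[[length(rows) + 1]] <- tibble::tibble(
        key = key[i], sample = ids[m], n_alt = na, ad_ref = e$ad_ref,
        ad_alt = e$ad_alt, dp = dp[i], gq = gq[i], pl0 = e$pl[1],
        pl1 = e$pl[2], pl2 = e$pl[3])
    }
  }
  trio_dataset(
    variants = tibble::tibble(key = key, chrom = chrom, pos = pos,
                              ref = ref, alt = alt, qual = 1000),
    genotypes = dplyr::bind_rows(rows),
    annotations = tibble::tibble(key = key, gene_symbol = gene,
                                 transcript_id = paste0(gene, ".t1"),
                                 consequence = consequence, hgvs_c = "",
                                 hgvs_p = "", allele = alt),
    scores = tibble::tibble(key = key, sift = NA_real_,
                            polyphen = NA_real_, cadd_phred = NA_real_,
                            sift_rank = NA_real_, polyphen_rank = NA_real_,
                            cadd_rank = NA_real_,
                            maf = if (is.null(maf)) NA_real_ else
                              rep_len(maf, n)),
    trios = trios)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Minimal hand-written 9-sample-free VCF for the I/O tests (one trio).
tiny_vcf_lines <- function(body_lines, samples = c("T1c", "T1p", "T1m")) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"ann\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"gq\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"pl\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    body_lines)
}

ped_lines_one_trio <- c(
  "FAM1 T1c T1p T1m 2 2",
  "FAM1 T1p 0 0 1 1",
  "FAM1 T1m 0 0 2 1")
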