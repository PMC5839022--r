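#' Cross-family recurrence of recessive and compound-heterozygous variants
#'
#' Intersects per-trio segregation calls into three recurrence categories:
#'
#' * **A** — variants homozygous recessive at the identical
#'   (chrom, pos, ref, alt) in at least two trios;
#' * **B** — genes with homozygous recessive variants in at least two trios
#'   at non-identical positions (genes already in A are excluded);
#' * **C** — genes with transmission-phased compound heterozygotes in at
#'   least two trios (may overlap B).
#'
#' @param calls Calls tibble from [segregate_all()].
#' @param comp_hets Compound-het tibble from [find_compound_hets()].
#' @return List of class `recurrence_report` with `category_A`,
#'   `category_B`, `category_C` tibbles and a `totals` list. Ordering is
#'   deterministic (gene, then chrom:pos).
#' @export
cross_trio_recurrence <- function(calls, comp_hets) {
  empty <- function() {
    structure(list(
      category_A = tibble(key = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), gene = character(),
                          trios = character(), n_trios = integer()),
      category_B = tibble(gene = character(), trio_id = character(),
                          key = character(), chrom = character(),
                          pos = integer()),
      category_C = tibble(gene = character(), trio_id = character(),
                          key = character(), side = character()),
      totals = list(a_variants = 0L, a_genes = 0L, b_genes = 0L,
                    b_variants = 0L, c_genes = 0L, c_variants = 0L,
                    total_variants = 0L)), class = "recurrence_report")
  }
  if (length(unique(calls$trio_id)) < 2) {
    warning("fewer than 2 trios: recurrence report is empty")
    return(empty())
  }
  rec <- calls %>% filter(.data$pass, .data$class == "recessive_hom")

  by_var <- rec %>%
    group_by(.data$key, .data$chrom, .data$pos, .data$ref, .data$alt,
             .data$gene) %>%
    summarise(trios = paste(sort(unique(.data$trio_id)), collapse = "+"),
              n_trios = n_distinct(.data$trio_id), .groups = "drop")
  cat_a <- by_var %>%
    filter(.data$n_trios >= 2) %>%
    arrange(.data$gene, chrom_rank(.data$chrom), .data$pos)
  a_genes <- unique(cat_a$gene)

  b_candidates <- rec %>%
    filter(!.data$gene %in% a_genes, !is.na(.data$gene))
  b_genes <- b_candidates %>%
    group_by(.data$gene) %>%
    summarise(n_trios = n_distinct(.data$trio_id), .groups = "drop") %>%
    filter(.data$n_trios >= 2) %>%
    pull(.data$gene)
  cat_b <- b_candidates %>%
    filter(.data$gene %in% b_genes) %>%
    distinct(.data$gene, .data$trio_id, .data$key, .data$chrom,
             .data$pos) %>%
    arrange(.data$gene, chrom_rank(.data$chrom), .data$pos, .data$trio_id)

  c_gene_tbl <- comp_hets %>%
    group_by(.data$gene) %>%
    summarise(n_trios = n_distinct(.data$trio_id), .groups = "drop") %>%
    filter(.data$n_trios >= 2)
  cat_c <- comp_hets %>%
    filter(.data$gene %in% c_gene_tbl$gene)
  if (nrow(cat_c) > 0) {
    cat_c <- bind_rows(
      cat_c %>%
        select("gene", "trio_id", key = "paternal_variants") %>%
        tidyr::unnest("key") %>% mutate(side = "paternal"),
      cat_c %>%
        select("gene", "trio_id", key = "maternal_variants") %>%
        tidyr::unnest("key") %>% mutate(side = "maternal")
    ) %>%
      distinct() %>%
      arrange(.data$gene, .data$trio_id, .data$key)
  } else {
    cat_c <- tibble(gene = character(), trio_id = character(),
                    key = character(), side = character())
  }

  totals <- list(
    a_variants = nrow(cat_a),
    a_genes = length(a_genes),
    b_genes = length(unique(cat_b$gene)),
    b_variants = length(unique(cat_b$key)),
    c_genes = length(unique(cat_c$gene)),
    c_variants = length(unique(cat_c$key))
  )
  totals$total_variants <- totals$a_variants + totals$b_variants +
    totals$c_variants
  structure(list(category_A = cat_a, category_B = cat_b,
                 category_C = cat_c, totals = totals),
            class = "recurrence_report")
}

#' @export
print.recurrence_report <- function(x, ...) {
  t <- x$totals
  cat("recurrence_report: A =", t$a_variants, "variants /", t$a_genes,
      "genes; B =", t$b_variants, "variants /", t$b_genes,
      "genes; C =", t$c_variants, "variants /", t$c_genes,
      "genes; total", t$total_variants, "variants\n")
  invisible(x)
}

#' Rare homozygous recessive variants private to one trio
#'
#' Keeps homozygous recessive calls whose variant occurs (as recessive) in
#' exactly one trio and whose minor allele frequency is below the threshold;
#' variants without a MAF annotation are treated as rare by default.
#'
#' @param calls Calls tibble from [segregate_all()].
#' @param scores Score tibble (`key`, `maf`).
#' @param maf_threshold MAF cutoff (strict `<`), default 0.01.
#' @param missing_rare Treat missing MAF as rare.
#' @return Tibble of retained calls with a `maf` column.
#' @export
single_trio_rare_recessive <- function(calls, scores, maf_threshold = 0.01,
                                       missing_rare = TRUE) {
  rec <- calls %>% filter(.data$pass, .data$class == "recessive_hom")
  single <- rec %>%
    group_by(.data$key) %>%
    filter(n_distinct(.data$trio_id) == 1) %>%
    ungroup()
  single %>%
    left_join(scores %>% select("key", "maf"), by = "key") %>%
    filter((is.na(.data$maf) & missing_rare) |
             (!is.na(.data$maf) & .data$maf < maf_threshold)) %>%
    arrange(chrom_rank(.data$chrom), .data$pos, .data$trio_id)
}
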