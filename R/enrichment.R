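#' Read a GMT gene-set file
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return Named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 60))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, "", USE.NAMES = FALSE)
  sets
}

#' Gene-set over-representation analysis
#'
#' Hypergeometric upper-tail test of each set's overlap with a query gene
#' list against a gene universe (`P(X >= overlap)` with population the
#' universe, successes the set intersected with the universe, draws the
#' query), followed by Benjamini-Hochberg FDR across all tested sets.
#'
#' @param query_genes Character vector of genes of interest (subset of the
#'   universe).
#' @param gene_sets Named list of gene vectors (e.g. from [read_gmt()]).
#' @param universe_genes Background gene universe.
#' @return Tibble with `set_name`, `overlap_count`, `set_size`,
#'   `query_size`, `universe_size`, `p_hypergeometric`, `fdr_bh`, ordered
#'   by p-value.
#' @export
ora_enrichment <- function(query_genes, gene_sets, universe_genes) {
  query <- unique(query_genes)
  universe <- unique(universe_genes)
  if (length(query) == 0 || length(universe) == 0) {
    stop("query and universe must be non-empty")
  }
  if (!all(query %in% universe)) {
    stop("query genes must be a subset of the universe")
  }
  nn <- length(universe)
  nq <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(set, query))
    p <- phyper(k - 1, length(set), nn - length(set), nq,
                lower.tail = FALSE)
    tibble(set_name = nm, overlap_count = k, set_size = length(set),
           query_size = nq, universe_size = nn, p_hypergeometric = p)
  })
  out <- bind_rows(rows)
  out$fdr_bh <- p.adjust(out$p_hypergeometric, method = "BH")
  arrange(out, .data$p_hypergeometric, .data$set_name)
}
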