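#' Assemble a pipeline configuration
#'
#' @param vcf,ped Input VCF and PED paths (required).
#' @param scores Optional score-table path.
#' @param panel Optional marker-panel path for inbreeding estimation.
#' @param gmt Optional GMT gene-set path for over-representation analysis.
#' @param outdir Output directory.
#' @param ab_min,ab_max,gq_min,min_depth Filter thresholds (see
#'   [filter_thresholds()]).
#' @param denovo_mu Per-allele de novo prior (see [denovo_prior()]).
#' @param sift_max,polyphen_min Pathogenicity rule thresholds (see
#'   [pathogenicity_rule()]).
#' @param maf_threshold Rarity cutoff for the single-trio recessive list.
#' @param use_posterior,ab_parents Segregation options (see
#'   [segregate_all()]).
#' @param rank_mode Compare rank scores `"per_variant"` (default) or
#'   averaged `"per_gene"`.
#' @param inbreeding_subsamples,inbreeding_size Subsampling protocol for
#'   the inbreeding estimate.
#' @param seed Top-level seed; all stage randomness derives from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, ped, scores = NULL, panel = NULL,
                            gmt = NULL, outdir = tempfile("trioseg_out"),
                            ab_min = 0.35, ab_max = 0.65, gq_min = 20,
                            min_depth = 0, denovo_mu = 1e-6,
                            sift_max = 0.05, polyphen_min = 0.446,
                            maf_threshold = 0.01, use_posterior = TRUE,
                            ab_parents = TRUE,
                            rank_mode = c("per_variant", "per_gene"),
                            inbreeding_subsamples = 100,
                            inbreeding_size = 3900, seed = 1) {
  cfg <- list(vcf = vcf, ped = ped, scores = scores, panel = panel,
              gmt = gmt, outdir = outdir, ab_min = ab_min, ab_max = ab_max,
              gq_min = gq_min, min_depth = min_depth,
              denovo_mu = denovo_mu, sift_max = sift_max,
              polyphen_min = polyphen_min, maf_threshold = maf_threshold,
              use_posterior = use_posterior, ab_parents = ab_parents,
              rank_mode = match.arg(rank_mode),
              inbreeding_subsamples = inbreeding_subsamples,
              inbreeding_size = inbreeding_size, seed = seed)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return List of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full trio segregation pipeline
#'
#' Chains filtering, posterior reassignment, segregation classification,
#' compound-het detection, cross-trio recurrence, the rare single-trio
#' recessive list, pathogenicity flagging of recurrent variants, the
#' rank-score comparison of prioritized versus other variants, optional
#' gene-set over-representation and optional inbreeding estimation, writing
#' deterministic TSV outputs and a JSON summary to `config$outdir`.
#'
#' @param config A [pipeline_config()] (or a YAML path accepted by
#'   [read_pipeline_config()]).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  for (f in c("vcf", "ped", "scores", "panel", "gmt")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop("configured ", f, " path does not exist: ", config[[f]])
    }
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  trios <- read_pedigree(config$ped)
  score_tbl <- if (!is.null(config$scores)) read_score_table(config$scores)
  ds <- read_trio_vcf(config$vcf, trios, score_table = score_tbl)

  th <- filter_thresholds(config$ab_min, config$ab_max, config$gq_min,
                          config$min_depth)
  seg <- segregate_all(ds, thresholds = th,
                       prior = denovo_prior(config$denovo_mu),
                       use_posterior = config$use_posterior,
                       ab_parents = config$ab_parents)
  rec <- cross_trio_recurrence(seg$calls, seg$comp_hets)
  rare <- single_trio_rare_recessive(seg$calls, ds$scores,
                                     maf_threshold = config$maf_threshold)

  # pathogenicity of the recurrent variant set
  rule <- pathogenicity_rule(config$sift_max, config$polyphen_min)
  rec_keys <- unique(c(rec$category_A$key, rec$category_B$key,
                       rec$category_C$key))
  sev <- most_severe_annotation(ds$annotations)
  flags <- tibble(key = rec_keys) %>%
    left_join(ds$scores %>% select("key", "sift", "polyphen"),
              by = "key") %>%
    left_join(sev, by = "key")
  if (nrow(flags) > 0) {
    fl <- pathogenicity_flag(flags$sift, flags$polyphen,
                             flags$consequence, rule)
    flags <- bind_cols(flags, fl)
  } else {
    flags$flag <- logical(0)
    flags$reason <- character(0)
  }
  n_flagged <- sum(flags$flag)
  pct_flagged <- if (nrow(flags)) round(100 * n_flagged / nrow(flags), 1)
    else NA_real_

  # rank-score comparison: prioritized (recurrent + rare single-trio +
  # de novo) vs other variants in the same genes
  prio_keys <- unique(c(rec_keys, rare$key,
                        seg$calls$key[seg$calls$class == "de_novo" &
                                        seg$calls$pass]))
  rank_res <- NULL
  prio_genes <- sev$gene[sev$key %in% prio_keys]
  rank_tbl <- ds$scores %>%
    inner_join(sev, by = "key") %>%
    filter(.data$gene %in% prio_genes) %>%
    mutate(score = coalesce(.data$cadd_rank, .data$sift_rank,
                            .data$polyphen_rank),
           prioritized = .data$key %in% prio_keys)
  if (config$rank_mode == "per_gene") {
    rank_tbl <- rank_tbl %>%
      group_by(.data$gene, .data$prioritized) %>%
      summarise(score = mean(.data$score, na.rm = TRUE),
                .groups = "drop")
  }
  g1 <- rank_tbl$score[rank_tbl$prioritized & !is.na(rank_tbl$score)]
  g2 <- rank_tbl$score[!rank_tbl$prioritized & !is.na(rank_tbl$score)]
  if (length(g1) > 0 && length(g2) > 0) {
    rank_res <- rank_sum_test(g1, g2)
  }

  enrich <- NULL
  if (!is.null(config$gmt) && nrow(flags) > 0 && n_flagged > 0) {
    universe <- unique(sev$gene)
    query <- unique(flags$gene[flags$flag & !is.na(flags$gene)])
    if (length(query) > 0) {
      enrich <- ora_enrichment(query, read_gmt(config$gmt), universe)
    }
  }

  inbreeding <- NULL
  if (!is.null(config$panel)) {
    panel <- read_marker_panel(config$panel)
    inbreeding <- lapply(seq_len(nrow(trios)), function(t) {
      gt <- ds$genotypes %>%
        filter(.data$sample == trios$child_id[t]) %>%
        inner_join(ds$variants %>% select("key", "chrom", "pos"),
                   by = "key")
      gv <- gt$n_alt[match(paste(panel$chrom, panel$pos),
                           paste(gt$chrom, gt$pos))]
      if (sum(!is.na(gv)) < 100) {
        warning("child ", trios$child_id[t], ": fewer than 100 panel ",
                "markers genotyped; inbreeding not estimated",
                call. = FALSE)
        return(list(child = trios$child_id[t], f_median = NA_real_,
                    f_hat = NA_real_, p_value = NA_real_))
      }
      res <- subsample_median_estimate(
        gv, panel, n_subsamples = config$inbreeding_subsamples,
        subsample_size = config$inbreeding_size,
        seed = config$seed + t)
      list(child = trios$child_id[t], f_median = res$f_median,
           f_hat = res$f_hat, p_value = res$p_value)
    })
  }

  # ---- outputs -----------------------------------------------------------
  out <- function(...) file.path(config$outdir, ...)
  write_variant_table(ds, seg$calls, out("calls.tsv"))
  ch_out <- seg$comp_hets %>%
    mutate(paternal_variants = vapply(.data$paternal_variants, paste,
                                      "", collapse = ";"),
           maternal_variants = vapply(.data$maternal_variants, paste,
                                      "", collapse = ";"))
  readr::write_tsv(ch_out, out("comp_hets.tsv"), na = "NA")
  readr::write_tsv(rec$category_A, out("recurrence_A.tsv"), na = "NA")
  readr::write_tsv(rec$category_B, out("recurrence_B.tsv"), na = "NA")
  readr::write_tsv(rec$category_C, out("recurrence_C.tsv"), na = "NA")
  readr::write_tsv(rare %>% select(-any_of(c("x_flag"))),
                   out("rare_single_trio.tsv"), na = "NA")
  if (!is.null(enrich)) {
    readr::write_tsv(enrich, out("enrichment.tsv"), na = "NA")
  }

  class_counts <- seg$summary %>%
    tidyr::pivot_wider(names_from = "class", values_from = "n")
  summary <- list(
    n_records = nrow(ds$variants),
    n_trios = nrow(trios),
    class_counts = class_counts,
    de_novo_total = sum(seg$summary$n[seg$summary$class == "de_novo"]),
    recurrence = rec$totals,
    rare_single_trio = nrow(rare),
    flagged = list(n = n_flagged, of = nrow(flags),
                   percent = pct_flagged),
    rank_test = if (!is.null(rank_res)) {
      list(u = rank_res$u_statistic, z = rank_res$z_value,
           p = rank_res$p_two_sided, method = rank_res$method)
    },
    enrichment_top = if (!is.null(enrich)) head(enrich, 5),
    inbreeding = inbreeding,
    settings = list(ab_min = config$ab_min, ab_max = config$ab_max,
                    gq_min = config$gq_min, denovo_mu = config$denovo_mu,
                    maf_threshold = config$maf_threshold,
                    seed = config$seed)
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(summary)
}
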