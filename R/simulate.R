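#' Simulation configuration for synthetic trio exomes
#'
#' Defaults emulate a three-trio exome study: parents drawn under
#' Hardy-Weinberg equilibrium at each variant's alternate allele frequency
#' (Beta(0.5, 5) truncated to (0.001, 0.5)), children by Mendelian
#' transmission, two injected de novo variants per child, read depths
#' around 100x with binomial allele-depth noise, and PL/GQ derived from
#' binomial genotype likelihoods.
#'
#' @param n_trios Number of trios.
#' @param n_variants Total variant count (background + injected).
#' @param n_denovo Injected de novo variants per child.
#' @param recessive Optional tibble (`trio`, `gene`, `consequence`) of
#'   homozygous-recessive injections (one variant per row); `trio` is the
#'   1-based trio index.
#' @param comphet Optional tibble (`trio`, `gene`) of compound-heterozygote
#'   injections (two variants per row, one per parental side).
#' @param shared_recessive Optional tibble (`gene`, `trios` list-column of
#'   trio-index vectors) of variants forced recessive in several trios at
#'   the identical site.
#' @param alt_freq_shape Beta shape parameters of the alternate allele
#'   frequency distribution.
#' @param alt_freq_range Truncation interval for allele frequencies.
#' @param mean_depth Mean sequencing depth (Poisson).
#' @param allele_noise Draw allele depths binomially around the expected
#'   allele fraction (`TRUE`) or deterministically (`FALSE`).
#' @param base_error Sequencing error rate used in the PL likelihood model.
#' @param variants_per_gene Average variants per background gene.
#' @param forbid_background Segregation classes background (non-injected)
#'   genotype triples are resampled away from, e.g. `"recessive_hom"` for
#'   exact-count validation scenarios.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_trios = 3, n_variants = 2000, n_denovo = 2,
                       recessive = NULL, comphet = NULL,
                       shared_recessive = NULL,
                       alt_freq_shape = c(0.5, 5),
                       alt_freq_range = c(0.001, 0.5), mean_depth = 100,
                       allele_noise = TRUE, base_error = 1e-3,
                       variants_per_gene = 2,
                       forbid_background = character(), seed = 1) {
  n_inject <- n_trios * n_denovo +
    (if (is.null(recessive)) 0 else nrow(recessive)) +
    (if (is.null(comphet)) 0 else 2 * nrow(comphet)) +
    (if (is.null(shared_recessive)) 0 else nrow(shared_recessive))
  if (n_inject > n_variants) {
    stop("injected variant count (", n_inject, ") exceeds n_variants")
  }
  structure(list(n_trios = n_trios, n_variants = n_variants,
                 n_denovo = n_denovo, recessive = recessive,
                 comphet = comphet, shared_recessive = shared_recessive,
                 alt_freq_shape = alt_freq_shape,
                 alt_freq_range = alt_freq_range, mean_depth = mean_depth,
                 allele_noise = allele_noise, base_error = base_error,
                 variants_per_gene = variants_per_gene,
                 forbid_background = forbid_background, seed = seed),
            class = "sim_config")
}

default_trios <- function(n_trios) {
  tibble(
    family_id = paste0("FAM", seq_len(n_trios)),
    child_id = paste0("T", seq_len(n_trios), "c"),
    father_id = paste0("T", seq_len(n_trios), "p"),
    mother_id = paste0("T", seq_len(n_trios), "m"),
    child_affected = TRUE,
    child_sex = rep(c("female", "male"), length.out = n_trios)
  )
}

# Genotype likelihood model shared by simulator and fixtures: binomial
# likelihood of the alt read count under alt fractions (err, 1/2, 1-err).
pl_from_ad <- function(ad_alt, dp, base_error = 1e-3) {
  p <- c(base_error, 0.5, 1 - base_error)
  ll <- vapply(p, function(pg) dbinom(ad_alt, dp, pg, log = TRUE), 0.0)
  pl <- round(-10 / log(10) * (ll - max(ll)))
  pmin(pl, 9999)
}

geno_fields <- function(n_alt, dp, allele_noise, base_error) {
  frac <- c(0, 0.5, 1)[n_alt + 1L]
  ad_alt <- if (allele_noise) rbinom(1, dp, frac) else round(dp * frac)
  ad_ref <- dp - ad_alt
  pl <- pl_from_ad(ad_alt, dp, base_error)
  gq <- min(99, sort(pl)[2] - min(pl))
  list(ad_ref = ad_ref, ad_alt = ad_alt, dp = dp, gq = gq, pl = pl)
}

#' Simulate an annotated multi-trio exome dataset with ground truth
#'
#' Generates genotypes for `n_trios` case-parent trios at `n_variants`
#' biallelic sites, overrides the configured injections (de novo,
#' homozygous recessive, compound heterozygote, shared recessive), then
#' derives allele depths, PLs and GQs from the genotype likelihood model.
#' Ground-truth segregation classes are computed from the pre-noise
#' genotypes, with compound-heterozygote membership marked by transmission
#' phasing within genes.
#'
#' @param config A [sim_config()].
#' @return List of class `trio_simulation`: `dataset` (a [trio_dataset()]),
#'   `truth` (tibble `trio_id`, `key`, `true_class`), `config`.
#' @export
simulate_trio_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nv <- config$n_variants
  nt <- config$n_trios
  trios <- default_trios(nt)

  # sites: spread across 22 autosomes with increasing positions
  chrom <- sort(rep_len(as.character(1:22), nv))
  chrom <- chrom[order(chrom_rank(chrom))]
  pos <- unlist(lapply(split(seq_len(nv), chrom_rank(chrom)), function(i) {
    sort(sample.int(5e7, length(i)))
  }), use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "",
                USE.NAMES = FALSE)

  # truncated Beta alternate allele frequencies
  q <- numeric(nv)
  need <- seq_len(nv)
  while (length(need)) {
    draw <- rbeta(length(need), config$alt_freq_shape[1],
                  config$alt_freq_shape[2])
    ok <- draw >= config$alt_freq_range[1] & draw <= config$alt_freq_range[2]
    q[need[ok]] <- draw[ok]
    need <- need[!ok]
  }

  n_genes <- max(1, ceiling(nv / config$variants_per_gene))
  gene <- paste0("G", formatC(rep(seq_len(n_genes),
                                  each = config$variants_per_gene,
                                  length.out = nv), width = 5, flag = "0"))
  consequence <- sample(c("missense", "synonymous", "other"), nv,
                        replace = TRUE, prob = c(0.6, 0.3, 0.1))

  # true genotypes [variant, trio, member]; members c/f/m
  gt_c <- gt_f <- gt_m <- matrix(0L, nv, nt)
  for (t in seq_len(nt)) {
    gt_f[, t] <- rbinom(nv, 2, q)
    gt_m[, t] <- rbinom(nv, 2, q)
    gt_c[, t] <- rbinom(nv, 1, gt_f[, t] / 2) + rbinom(nv, 1, gt_m[, t] / 2)
  }

  # --- injections occupy the first slots ---------------------------------
  slot <- 0L
  injected <- integer(0)
  take_slot <- function() {
    slot <<- slot + 1L
    injected <<- c(injected, slot)
    slot
  }
  set_triple <- function(i, t, triple) {
    gt_c[i, t] <<- triple[1]; gt_f[i, t] <<- triple[2]
    gt_m[i, t] <<- triple[3]
  }
  clear_others <- function(i, ts) {
    for (t in setdiff(seq_len(nt), ts)) set_triple(i, t, c(0L, 0L, 0L))
  }
  denovo_slots <- integer(0)
  if (config$n_denovo > 0) {
    for (t in seq_len(nt)) {
      for (j in seq_len(config$n_denovo)) {
        i <- take_slot()
        denovo_slots <- c(denovo_slots, i)
        set_triple(i, t, c(1L, 0L, 0L))
        clear_others(i, t)
      }
    }
  }
  if (!is.null(config$recessive)) {
    for (r in seq_len(nrow(config$recessive))) {
      i <- take_slot()
      t <- config$recessive$trio[r]
      set_triple(i, t, c(2L, 1L, 1L))
      clear_others(i, t)
      gene[i] <- config$recessive$gene[r]
      if ("consequence" %in% names(config$recessive)) {
        consequence[i] <- config$recessive$consequence[r]
      }
    }
  }
  if (!is.null(config$comphet)) {
    for (r in seq_len(nrow(config$comphet))) {
      t <- config$comphet$trio[r]
      i1 <- take_slot(); i2 <- take_slot()
      set_triple(i1, t, c(1L, 1L, 0L))
      set_triple(i2, t, c(1L, 0L, 1L))
      clear_others(i1, t); clear_others(i2, t)
      gene[c(i1, i2)] <- config$comphet$gene[r]
      consequence[c(i1, i2)] <- "missense"
    }
  }
  if (!is.null(config$shared_recessive)) {
    for (r in seq_len(nrow(config$shared_recessive))) {
      i <- take_slot()
      ts <- config$shared_recessive$trios[[r]]
      for (t in ts) set_triple(i, t, c(2L, 1L, 1L))
      clear_others(i, ts)
      gene[i] <- config$shared_recessive$gene[r]
      consequence[i] <- "missense"
    }
  }

  # resample forbidden background configurations (Mendelian redraw)
  if (length(config$forbid_background)) {
    bg <- setdiff(seq_len(nv), injected)
    for (t in seq_len(nt)) {
      repeat {
        cls <- classify_trio_genotype(gt_c[bg, t], gt_f[bg, t], gt_m[bg, t])
        bad <- bg[cls %in% config$forbid_background]
        if (!length(bad)) break
        gt_f[bad, t] <- rbinom(length(bad), 2, q[bad])
        gt_m[bad, t] <- rbinom(length(bad), 2, q[bad])
        gt_c[bad, t] <- rbinom(length(bad), 1, gt_f[bad, t] / 2) +
          rbinom(length(bad), 1, gt_m[bad, t] / 2)
      }
    }
  }

  key <- vkey(chrom, pos, ref, alt)
  variants <- tibble(key = key, chrom = chrom, pos = pos, ref = ref,
                     alt = alt,
                     qual = round(pmin(pmax(rlnorm(nv, log(2e4), 1.2),
                                            299), 183916)))

  # observed evidence per sample
  members <- list(c = gt_c, f = gt_f, m = gt_m)
  gt_rows <- vector("list", nt * 3)
  idx <- 0
  for (t in seq_len(nt)) {
    for (mb in names(members)) {
      sample_id <- switch(mb, c = trios$child_id[t],
                          f = trios$father_id[t], m = trios$mother_id[t])
      n_alt <- members[[mb]][, t]
      dp <- pmax(1L, rpois(nv, config$mean_depth))
      fields <- lapply(seq_len(nv), function(i) {
        geno_fields(n_alt[i], dp[i], config$allele_noise,
                    config$base_error)
      })
      idx <- idx + 1
      gt_rows[[idx]] <- tibble(
        key = key, sample = sample_id, n_alt = n_alt,
        ad_ref = vapply(fields, `[[`, 0.0, "ad_ref"),
        ad_alt = vapply(fields, `[[`, 0.0, "ad_alt"),
        dp = dp,
        gq = vapply(fields, `[[`, 0.0, "gq"),
        pl0 = vapply(fields, function(x) x$pl[1], 0.0),
        pl1 = vapply(fields, function(x) x$pl[2], 0.0),
        pl2 = vapply(fields, function(x) x$pl[3], 0.0)
      )
    }
  }
  genotypes <- bind_rows(gt_rows)

  annotations <- tibble(key = key, gene_symbol = gene,
                        transcript_id = paste0(gene, ".t1"),
                        consequence = consequence, hgvs_c = "",
                        hgvs_p = "", allele = alt)
  scores <- tibble(key = key, sift = round(runif(nv), 3),
                   polyphen = round(runif(nv), 3),
                   cadd_phred = round(runif(nv, 0, 50), 2),
                   sift_rank = round(runif(nv), 4),
                   polyphen_rank = round(runif(nv), 4),
                   cadd_rank = round(runif(nv), 4), maf = round(q, 5))
  scores$maf[denovo_slots] <- NA_real_  # de novo injections unseen in ExAC

  ds <- trio_dataset(variants, genotypes, annotations, scores, trios)

  # ground truth from the pre-noise genotypes
  truth_rows <- vector("list", nt)
  for (t in seq_len(nt)) {
    cls <- classify_trio_genotype(gt_c[, t], gt_f[, t], gt_m[, t])
    truth_rows[[t]] <- tibble(trio_id = trios$family_id[t], key = key,
                              chrom = chrom, pos = pos, gene = gene,
                              class = cls)
  }
  truth_calls <- bind_rows(truth_rows)
  truth_ch <- find_compound_hets(truth_calls)
  ch_members <- if (nrow(truth_ch)) {
    bind_rows(
      truth_ch %>% select("trio_id", key = "paternal_variants") %>%
        tidyr::unnest("key"),
      truth_ch %>% select("trio_id", key = "maternal_variants") %>%
        tidyr::unnest("key"))
  } else tibble(trio_id = character(), key = character())
  truth <- truth_calls %>%
    mutate(true_class = case_when(
      paste(.data$trio_id, .data$key) %in%
        paste(ch_members$trio_id, ch_members$key) ~ "comp_het_member",
      .data$class == "de_novo" ~ "de_novo",
      .data$class == "recessive_hom" ~ "recessive_hom",
      TRUE ~ "inherited_other")) %>%
    select("trio_id", "key", "gene", "true_class")

  structure(list(dataset = ds, truth = truth, config = config),
            class = "trio_simulation")
}

#' Simulate genotypes of a (possibly inbred) individual along a panel
#'
#' Hidden IBD states follow the two-state Markov chain of the autozygosity
#' HMM (stationary start `(f, 1-f)` per chromosome); genotypes are drawn
#' from the state-conditional emissions with no genotyping error.
#'
#' @param panel Marker panel tibble (`chrom`, `pos`, `q`, `cm`).
#' @param f True inbreeding coefficient in `[0, 1)`.
#' @param a True exchange rate per Morgan, `> 0`.
#' @param seed Integer seed (`NULL` leaves RNG state alone).
#' @return List with `genotypes` (0/1/2) and logical `ibd` state mask.
#' @export
simulate_inbred_genotypes <- function(panel, f, a, seed = NULL) {
  stopifnot(f >= 0, f < 1, a > 0)
  if (!is.null(seed)) set.seed(seed)
  ch <- panel_chains(panel, warn_ld = FALSE)
  n <- nrow(panel)
  ibd <- logical(n)
  u <- runif(n)
  for (i in seq_len(n)) {
    if (ch$new_chain[i]) {
      ibd[i] <- u[i] < f
    } else {
      r <- exp(-a * ch$d[i])
      p_ibd <- if (ibd[i - 1]) r + (1 - r) * f else (1 - r) * f
      ibd[i] <- u[i] < p_ibd
    }
  }
  q <- panel$q
  gt <- integer(n)
  hom_alt <- runif(n)
  het <- runif(n)
  for (i in seq_len(n)) {
    if (ibd[i]) {
      gt[i] <- if (hom_alt[i] < q[i]) 2L else 0L
    } else {
      gt[i] <- if (het[i] < 2 * q[i] * (1 - q[i])) 1L
      else if (hom_alt[i] < q[i]^2 / (1 - 2 * q[i] * (1 - q[i]))) 2L
      else 0L
    }
  }
  list(genotypes = gt, ibd = ibd)
}

#' Simulate a marker panel of common polymorphisms
#'
#' Markers spread uniformly over `n_chrom` chromosomes of `morgans_each`
#' genetic length, with common alternate allele frequencies drawn uniformly
#' from `q_range`.
#'
#' @param n_markers Total marker count.
#' @param n_chrom Number of chromosomes.
#' @param morgans_each Genetic length per chromosome (Morgans).
#' @param q_range Allele-frequency range.
#' @param seed Integer seed.
#' @return Panel tibble (`chrom`, `pos`, `q`, `cm`).
#' @export
simulate_marker_panel <- function(n_markers = 3900, n_chrom = 22,
                                  morgans_each = 1.6,
                                  q_range = c(0.05, 0.5), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  per <- rep(n_markers %/% n_chrom, n_chrom)
  extra <- n_markers - sum(per)
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  rows <- lapply(seq_len(n_chrom), function(cc) {
    cm <- sort(runif(per[cc], 0, morgans_each * 100))
    tibble(chrom = as.character(cc), pos = as.integer(round(cm * 1e6)),
           q = round(runif(per[cc], q_range[1], q_range[2]), 4), cm = cm)
  })
  panel <- bind_rows(rows)
  # ensure strictly increasing positions within chromosome
  panel %>%
    group_by(.data$chrom) %>%
    mutate(pos = .data$pos + seq_len(n()) - 1L) %>%
    ungroup() %>%
    arrange(chrom_rank(.data$chrom), .data$pos)
}

#' Write a trio dataset as a VCF with SnpEff-style ANN annotations
#'
#' Emits a VCF 4.2 file with GT:AD:DP:GQ:PL sample fields that round-trips
#' through [read_trio_vcf()].
#'
#' @param ds A [trio_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(ds, path) {
  samples <- unique(ds$genotypes$sample)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele | Annotation | Annotation_Impact | Gene_Name | Gene_ID | Feature_Type | Feature_ID | Transcript_BioType | Rank | HGVS.c | HGVS.p'\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  ord <- order(chrom_rank(ds$variants$chrom), ds$variants$pos,
               ds$variants$alt)
  v <- ds$variants[ord, ]
  ann_by_key <- split(ds$annotations, ds$annotations$key)
  gt <- ds$genotypes
  gt_str <- ifelse(is.na(gt$n_alt), "./.",
                   c("0/0", "0/1", "1/1")[gt$n_alt + 1L])
  fld <- paste0(
    gt_str, ":",
    ifelse(is.na(gt$ad_ref), ".", paste0(gt$ad_ref, ",", gt$ad_alt)), ":",
    ifelse(is.na(gt$dp), ".", gt$dp), ":",
    ifelse(is.na(gt$gq), ".", gt$gq), ":",
    ifelse(is.na(gt$pl0), ".",
           paste0(gt$pl0, ",", gt$pl1, ",", gt$pl2)))
  fld_mat <- matrix(fld[order(match(gt$key, v$key),
                              match(gt$sample, samples))],
                    nrow = nrow(v), byrow = TRUE)
  lines <- vapply(seq_len(nrow(v)), function(i) {
    a <- ann_by_key[[v$key[i]]]
    info <- if (is.null(a) || nrow(a) == 0) "." else {
      paste0("ANN=", paste(
        paste(a$allele, .so_rev[a$consequence], "MODIFIER", a$gene_symbol,
              a$gene_symbol, "transcript", a$transcript_id,
              "protein_coding", "1", a$hgvs_c, a$hgvs_p, sep = "|"),
        collapse = ","))
    }
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i],
            format(v$qual[i], scientific = FALSE), "PASS", info,
            "GT:AD:DP:GQ:PL", fld_mat[i, ]), collapse = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write a score table next to a dataset's VCF
#'
#' @param ds A [trio_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(ds, path) {
  out <- ds$variants %>%
    select("key", "chrom", "pos", "ref", "alt") %>%
    left_join(ds$scores, by = "key") %>%
    select("chrom", "pos", "ref", "alt", "sift", "polyphen", "cadd_phred",
           "sift_rank", "polyphen_rank", "cadd_rank", "maf")
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' Write a simulation to disk (VCF + PED + scores + truth)
#'
#' @param sim A `trio_simulation` from [simulate_trio_dataset()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named list of file paths.
#' @export
write_simulated_dataset <- function(sim, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(dir, paste0(prefix, ".vcf")),
    ped = file.path(dir, paste0(prefix, ".ped")),
    scores = file.path(dir, paste0(prefix, "_scores.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv"))
  )
  write_trio_vcf(sim$dataset, paths$vcf)
  write_pedigree(sim$dataset$trios, paths$ped)
  write_score_table(sim$dataset, paths$scores)
  readr::write_tsv(sim$truth, paths$truth, na = "NA")
  paths
}
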