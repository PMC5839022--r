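#' Segregation classes
#'
#' Closed, mutually exclusive vocabulary for a variant's inheritance pattern
#' within one trio.
#'
#' @return Character vector of class names.
#' @export
segregation_classes <- function() {
  c("de_novo", "recessive_hom", "het_paternal", "het_maternal",
    "het_biparental", "inherited_other", "mendelian_error", "uncalled")
}

# Alleles a parent genotype can transmit (genotypes coded 0/1/2).
.transmissible <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)

#' Mendelian consistency of a genotype triple
#'
#' `TRUE` when the child genotype can be formed from one allele transmitted
#' by each parent without mutation.
#'
#' @param child,father,mother Alternate allele counts (0/1/2), vectorized;
#'   `NA` propagates.
#' @return Logical vector.
#' @export
mendelian_consistent <- function(child, father, mother) {
  ok <- function(c1, f1, m1) {
    tf <- .transmissible[[as.character(f1)]]
    tm <- .transmissible[[as.character(m1)]]
    any(outer(tf, tm, `+`) == c1)
  }
  mapply(function(c1, f1, m1) {
    if (is.na(c1) || is.na(f1) || is.na(m1)) return(NA)
    ok(c1, f1, m1)
  }, child, father, mother, USE.NAMES = FALSE)
}

# 3x3x3 lookup of classes, built once at load time.
.class_lookup <- local({
  arr <- array("", c(3, 3, 3))
  for (c1 in 0:2) {
    for (f1 in 0:2) {
      for (m1 in 0:2) {
        cls <- if (c1 == 1 && f1 == 0 && m1 == 0) {
          "de_novo"
        } else if (!any(outer(.transmissible[[as.character(f1)]],
                              .transmissible[[as.character(m1)]],
                              `+`) == c1)) {
          "mendelian_error"
        } else if (c1 == 1) {
          fc <- f1 > 0
          mc <- m1 > 0
          if (fc && mc) "het_biparental"
          else if (fc) "het_paternal"
          else "het_maternal"
        } else if (c1 == 2 && f1 == 1 && m1 == 1) {
          "recessive_hom"
        } else {
          "inherited_other"
        }
        arr[c1 + 1, f1 + 1, m1 + 1] <- cls
      }
    }
  }
  arr
})

#' Classify the inheritance pattern of a trio genotype
#'
#' - child 0/1, both parents 0/0: `de_novo`
#' - child 1/1, both parents 0/1: `recessive_hom`
#' - child 0/1 with exactly one parent carrying the alternate:
#'   `het_paternal` / `het_maternal`
#' - child 0/1 with both parents carrying: `het_biparental`
#' - any other configuration impossible without mutation:
#'   `mendelian_error`
#' - any member uncalled: `uncalled`; everything else `inherited_other`
#'
#' Child 1/1 with a homozygous-alternate parent is `inherited_other`: the
#' recessive class requires both unaffected parents to be strict carriers.
#'
#' @param child,father,mother Alternate allele counts (0/1/2 or `NA`),
#'   vectorized.
#' @return Character vector of [segregation_classes()].
#' @export
classify_trio_genotype <- function(child, father, mother) {
  out <- rep("uncalled", length(child))
  called <- !is.na(child) & !is.na(father) & !is.na(mother)
  idx <- which(called)
  if (length(idx)) {
    out[idx] <- .class_lookup[cbind(child[idx] + 1L, father[idx] + 1L,
                                    mother[idx] + 1L)]
  }
  out
}

#' Detect compound heterozygotes by transmission phasing
#'
#' For each (trio, gene) combining at least one paternally and one
#' maternally inherited heterozygous variant, emits one pair record listing
#' all such variants. Biparentally carried heterozygotes cannot be phased by
#' transmission and are excluded.
#'
#' @param calls Calls tibble (needs `trio_id`, `key`, `gene`, `class`,
#'   `chrom`, `pos`, and optionally `pass`).
#' @return Tibble with `trio_id`, `gene`, list-columns `paternal_variants`
#'   and `maternal_variants`, and their counts.
#' @export
find_compound_hets <- function(calls) {
  h <- calls
  if ("pass" %in% names(h)) h <- filter(h, .data$pass)
  h <- h %>%
    filter(.data$class %in% c("het_paternal", "het_maternal"),
           !is.na(.data$gene)) %>%
    arrange(chrom_rank(.data$chrom), .data$pos)
  if (nrow(h) == 0) {
    return(tibble(trio_id = character(), gene = character(),
                  paternal_variants = list(), maternal_variants = list(),
                  n_paternal = integer(), n_maternal = integer()))
  }
  h %>%
    group_by(.data$trio_id, .data$gene) %>%
    summarise(
      paternal_variants = list(.data$key[.data$class == "het_paternal"]),
      maternal_variants = list(.data$key[.data$class == "het_maternal"]),
      .groups = "drop"
    ) %>%
    mutate(n_paternal = lengths(.data$paternal_variants),
           n_maternal = lengths(.data$maternal_variants)) %>%
    filter(.data$n_paternal >= 1, .data$n_maternal >= 1) %>%
    arrange(.data$trio_id, .data$gene)
}

#' Filter, reassign and classify every variant in every trio
#'
#' For each trio: hard genotype filters are evaluated first; where all three
#' members carry complete PL triples the pedigree-informed posterior then
#' reassigns the child genotype and quality, and the reassigned quality is
#' re-checked against `gq_min`. Each record receives exactly one
#' segregation class per trio; records failing filters are retained with
#' `pass = FALSE`.
#'
#' @param ds A [trio_dataset()].
#' @param thresholds A [filter_thresholds()].
#' @param prior A [denovo_prior()].
#' @param use_posterior Apply posterior reassignment where PLs permit.
#' @param ab_parents Apply the allele-balance band to parents.
#' @param pop_alt_freq Fallback population frequency for the HWE parental
#'   prior when a variant has no MAF annotation.
#' @return List of class `segregation_result`: `calls` (one row per trio x
#'   record), `comp_hets` (from [find_compound_hets()] on passing calls)
#'   and `summary` (per-trio class counts over passing records).
#' @export
segregate_all <- function(ds, thresholds = filter_thresholds(),
                          prior = denovo_prior(), use_posterior = TRUE,
                          ab_parents = TRUE, pop_alt_freq = 0.01) {
  sev <- most_severe_annotation(ds$annotations)
  mafs <- ds$scores %>% select("key", "maf")
  all_calls <- vector("list", nrow(ds$trios))
  for (t in seq_len(nrow(ds$trios))) {
    trio <- ds$trios[t, ]
    g <- trio_genotype_wide(ds, trio)
    pf <- passes_genotype_filters(ds, trio, thresholds, ab_parents)
    stopifnot(identical(g$key, pf$key))
    child_gt <- g$n_alt_c
    pass <- pf$record_pass
    if (use_posterior && nrow(g) > 0) {
      maf_vec <- mafs$maf[match(g$key, mafs$key)]
      has_pl <- !is.na(g$pl0_c) & !is.na(g$pl1_c) & !is.na(g$pl2_c) &
        !is.na(g$pl0_f) & !is.na(g$pl1_f) & !is.na(g$pl2_f) &
        !is.na(g$pl0_m) & !is.na(g$pl1_m) & !is.na(g$pl2_m)
      for (i in which(has_pl & pass)) {
        q <- maf_vec[i]
        if (is.na(q) || q <= 0 || q >= 1) q <- pop_alt_freq
        post <- trio_genotype_posterior(
          c(g$pl0_c[i], g$pl1_c[i], g$pl2_c[i]),
          c(g$pl0_f[i], g$pl1_f[i], g$pl2_f[i]),
          c(g$pl0_m[i], g$pl1_m[i], g$pl2_m[i]),
          prior = prior, pop_alt_freq = q)
        child_gt[i] <- post$reassigned_child_gt
        if (post$reassigned_child_gq <= thresholds$gq_min) pass[i] <- FALSE
      }
    }
    cls <- classify_trio_genotype(child_gt, g$n_alt_f, g$n_alt_m)
    all_calls[[t]] <- tibble(
      trio_id = trio$family_id, key = g$key, chrom = g$chrom, pos = g$pos,
      ref = g$ref, alt = g$alt,
      gene = sev$gene[match(g$key, sev$key)],
      child_gt = child_gt, father_gt = g$n_alt_f, mother_gt = g$n_alt_m,
      class = cls, pass = pass,
      x_flag = chrom_rank(g$chrom) > 22L
    )
  }
  calls <- bind_rows(all_calls)
  comp_hets <- find_compound_hets(calls)
  summary <- calls %>%
    filter(.data$pass) %>%
    mutate(class = factor(.data$class, levels = segregation_classes())) %>%
    count(.data$trio_id, .data$class, .drop = FALSE, name = "n") %>%
    mutate(class = as.character(.data$class))
  structure(list(calls = calls, comp_hets = comp_hets, summary = summary),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat("segregation_result:", nrow(x$calls), "calls across",
      length(unique(x$calls$trio_id)), "trios;",
      nrow(x$comp_hets), "compound-het gene pairs\n")
  invisible(x)
}
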