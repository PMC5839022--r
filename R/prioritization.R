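#' In-silico pathogenicity rule
#'
#' A variant is flagged putatively pathogenic when its SIFT score is at or
#' below `sift_max` (SIFT's standard "deleterious" cutoff), its PolyPhen-2
#' probability is at or above `polyphen_min` (the "possibly damaging" lower
#' bound), or its consequence is loss-of-function.
#'
#' @param sift_max SIFT threshold (flag when `sift <= sift_max`).
#' @param polyphen_min PolyPhen-2 threshold (flag when
#'   `polyphen >= polyphen_min`).
#' @param lof_consequences Consequences flagged regardless of scores.
#' @return An object of class `pathogenicity_rule`.
#' @export
pathogenicity_rule <- function(sift_max = 0.05, polyphen_min = 0.446,
                               lof_consequences = c("stop_gained",
                                                    "frameshift",
                                                    "splice_site",
                                                    "start_lost",
                                                    "stop_lost")) {
  stopifnot(sift_max >= 0, sift_max <= 1, polyphen_min >= 0,
            polyphen_min <= 1)
  structure(list(sift_max = sift_max, polyphen_min = polyphen_min,
                 lof_consequences = lof_consequences),
            class = "pathogenicity_rule")
}

#' Flag putatively pathogenic variants
#'
#' @param sift,polyphen Numeric score vectors (`NA` allowed).
#' @param consequence Consequence per variant (closed vocabulary).
#' @param rule A [pathogenicity_rule()].
#' @return Tibble with logical `flag` and a `reason` string listing the
#'   triggering criteria (`"unscored"` when nothing was available).
#' @export
pathogenicity_flag <- function(sift, polyphen, consequence,
                               rule = pathogenicity_rule()) {
  n <- max(length(sift), length(polyphen), length(consequence))
  sift <- rep_len(sift, n)
  polyphen <- rep_len(polyphen, n)
  consequence <- rep_len(consequence, n)
  by_sift <- !is.na(sift) & sift <= rule$sift_max
  by_pp <- !is.na(polyphen) & polyphen >= rule$polyphen_min
  by_lof <- !is.na(consequence) & consequence %in% rule$lof_consequences
  unscored <- is.na(sift) & is.na(polyphen) & is.na(consequence)
  reason <- mapply(function(s, p, l, u) {
    if (u) return("unscored")
    r <- c(if (s) "sift", if (p) "polyphen", if (l) "lof")
    if (length(r) == 0) "benign" else paste(r, collapse = ";")
  }, by_sift, by_pp, by_lof, unscored, USE.NAMES = FALSE)
  tibble(flag = (by_sift | by_pp | by_lof) & !unscored, reason = reason)
}

#' Tally variants by most severe consequence
#'
#' Each (trio, variant) call is counted once under its most severe
#' consequence; variants without annotation count under `"other"`, so the
#' per-trio totals equal the input call counts.
#'
#' @param calls Calls tibble (`trio_id`, `key`).
#' @param annotations Annotation tibble (`key`, `gene_symbol`,
#'   `consequence`).
#' @return Tibble `trio_id` x [consequence_levels()] with count `n`
#'   (all categories present, zero-filled).
#' @export
consequence_tally <- function(calls, annotations) {
  sev <- most_severe_annotation(annotations)
  lv <- consequence_levels()
  if (nrow(calls) == 0) {
    return(tibble(trio_id = character(), consequence = character(),
                  n = integer()))
  }
  calls %>%
    distinct(.data$trio_id, .data$key) %>%
    left_join(sev %>% select("key", "consequence"), by = "key") %>%
    mutate(consequence = factor(ifelse(is.na(.data$consequence), "other",
                                       .data$consequence), levels = lv)) %>%
    count(.data$trio_id, .data$consequence, .drop = FALSE, name = "n") %>%
    mutate(consequence = as.character(.data$consequence))
}

#' Mann-Whitney/Wilcoxon rank-sum test
#'
#' U is computed with midranks, so ties are handled. The two-sided p-value
#' is exact (from the null U distribution) when both groups have at most 12
#' observations and there are no ties, otherwise a tie-corrected normal
#' approximation with continuity correction is used. The normal z-value is
#' reported in both cases.
#'
#' @param x,y Numeric score vectors for the two groups (non-empty).
#' @param exact Force exact (`TRUE`) or normal (`FALSE`); default decides by
#'   the rule above.
#' @return List of class `rank_test_result` with `u_statistic` (for `x`),
#'   `z_value`, `p_two_sided`, `method`.
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups must be non-empty")
  }
  n1 <- length(x)
  n2 <- length(y)
  nn <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (is.null(exact)) exact <- n1 <= 12 && n2 <= 12 && !has_ties

  mu <- n1 * n2 / 2
  tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((nn + 1) - tie_term))
  cc <- if (u == mu) 0 else sign(u - mu) * 0.5
  z <- if (sigma > 0) (u - mu - cc) / sigma else 0

  if (exact && !has_ties) {
    p <- if (u == mu) 1 else {
      2 * min(pwilcox(u, n1, n2),
              pwilcox(u - 1, n1, n2, lower.tail = FALSE))
    }
    method <- "exact"
  } else {
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  structure(list(u_statistic = u, z_value = z, p_two_sided = min(1, p),
                 method = method), class = "rank_test_result")
}
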