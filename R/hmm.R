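#' Read a marker panel for inbreeding estimation
#'
#' Tab-delimited with header columns `chrom`, `pos`, `q` (alternate allele
#' frequency in `(0,1)`) and `cm` (cumulative genetic position on the
#' chromosome, centimorgans). Markers must be sorted by position within
#' chromosome.
#'
#' @param path File path.
#' @return Panel tibble.
#' @export
read_marker_panel <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(chrom = "c", pos = "i",
                                               q = "d", cm = "d"))
  validate_panel(x)
  x
}

validate_panel <- function(panel) {
  stopifnot(all(c("chrom", "pos", "q", "cm") %in% names(panel)))
  if (any(panel$q <= 0 | panel$q >= 1)) {
    stop("marker allele frequencies must lie strictly in (0, 1)")
  }
  ord <- order(chrom_rank(panel$chrom), panel$chrom, panel$pos)
  if (!identical(ord, seq_len(nrow(panel)))) {
    stop("panel markers must be sorted by (chrom, pos)")
  }
  invisible(panel)
}

# Per-marker genetic gap (Morgans) to the previous marker, with chain
# restarts at chromosome boundaries. Zero gaps between distinct markers
# indicate unpruned LD and draw a warning.
panel_chains <- function(panel, warn_ld = TRUE) {
  new_chain <- c(TRUE, panel$chrom[-1] != panel$chrom[-nrow(panel)])
  d <- c(0, diff(panel$cm)) / 100
  d[new_chain] <- 0
  if (warn_ld && any(d[!new_chain] <= 0)) {
    warning("adjacent markers at zero genetic distance; ",
            "panel may not be LD-pruned", call. = FALSE)
  }
  list(d = pmax(d, 0), new_chain = new_chain)
}

#' Hidden-state transition matrix of the autozygosity HMM
#'
#' Two states, IBD (autozygous) and non-IBD, with stationary distribution
#' `(f, 1-f)` and exchange rate `a` per Morgan:
#' `P(IBD->IBD) = e^(-a d) + (1 - e^(-a d)) f`,
#' `P(non->IBD) = (1 - e^(-a d)) f`.
#'
#' @param f Inbreeding coefficient in `[0, 1)`.
#' @param a Rate per Morgan, `> 0`.
#' @param d Genetic distance in Morgans, `>= 0`.
#' @return 2x2 matrix, rows = from-state (IBD, non-IBD), rows sum to 1.
#' @export
transition_matrix <- function(f, a, d) {
  stopifnot(d >= 0, a > 0, f >= 0, f < 1)
  r <- exp(-a * d)
  matrix(c(r + (1 - r) * f, (1 - r) * (1 - f),
           (1 - r) * f, r + (1 - r) * (1 - f)),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("ibd", "non_ibd"), c("ibd", "non_ibd")))
}

#' Emission probabilities of observed genotypes under each hidden state
#'
#' Non-IBD markers emit Hardy-Weinberg genotype frequencies; IBD
#' (autozygous) markers emit the allele frequencies on homozygotes only,
#' mixed with HWE by a genotyping-error weight `eps`. Missing genotypes are
#' uninformative (probability 1 under both states).
#'
#' @param gt Genotypes coded 0 (hom-ref), 1 (het), 2 (hom-alt), `NA`
#'   missing; vectorized.
#' @param q Alternate allele frequency per marker, strictly in `(0,1)`.
#' @param eps Error mixing weight in `[0, 0.05]`.
#' @return Matrix with columns `ibd` and `non_ibd`.
#' @export
emission_probs <- function(gt, q, eps = 1e-3) {
  if (any(q <= 0 | q >= 1)) stop("q must lie strictly in (0, 1)")
  stopifnot(eps >= 0, eps <= 0.05)
  n <- max(length(gt), length(q))
  gt <- rep_len(gt, n)
  q <- rep_len(q, n)
  hwe <- cbind((1 - q)^2, 2 * q * (1 - q), q^2)
  ibd0 <- cbind(1 - q, 0, q)
  ibd <- (1 - eps) * ibd0 + eps * hwe
  idx <- cbind(seq_len(n), gt + 1L)
  e_ibd <- rep(1, n)
  e_non <- rep(1, n)
  ok <- !is.na(gt)
  e_ibd[ok] <- ibd[idx[ok, , drop = FALSE]]
  e_non[ok] <- hwe[idx[ok, , drop = FALSE]]
  cbind(ibd = e_ibd, non_ibd = e_non)
}

#' Forward log-likelihood of a genotype vector under the autozygosity HMM
#'
#' Scaled forward algorithm run independently per chromosome (initial
#' distribution `(f, 1-f)` at each chromosome start), summed over
#' chromosomes.
#'
#' @param gt Genotype vector aligned to `panel` markers (0/1/2/`NA`).
#' @param panel Marker panel tibble (`chrom`, `pos`, `q`, `cm`).
#' @param f,a HMM parameters (see [transition_matrix()]).
#' @param eps Genotyping-error weight (see [emission_probs()]).
#' @return Log-likelihood (scalar).
#' @export
forward_loglik <- function(gt, panel, f, a, eps = 1e-3) {
  if (length(gt) != nrow(panel)) {
    stop("genotype vector length must match panel size")
  }
  ch <- panel_chains(panel, warn_ld = FALSE)
  e <- emission_probs(gt, panel$q, eps)
  hmm_forward_cpp(e[, "ibd"], e[, "non_ibd"], ch$d, ch$new_chain, f, a)
}

#' Maximum-likelihood inbreeding coefficient from one marker panel
#'
#' Maximizes the forward likelihood jointly over `f` in `[0, 0.5]` and the
#' rate `a` in `[0.01, 10]` per Morgan by a coarse grid followed by bounded
#' local refinement. The likelihood-ratio statistic against `f = 0` uses
#' the boundary mixture `0.5*chisq(0) + 0.5*chisq(1)` for its p-value.
#'
#' @param gt Genotype vector aligned to `panel`.
#' @param panel Marker panel tibble.
#' @param eps Genotyping-error weight.
#' @return List of class `inbreeding_result`: `f_hat`, `a_hat`,
#'   `loglik_hat`, `loglik_f0`, `lrt_statistic`, `p_value`, `n_markers`,
#'   plus `subsample_estimates`/`f_median` when produced by
#'   [subsample_median_estimate()].
#' @export
estimate_f <- function(gt, panel, eps = 1e-3) {
  if (length(gt) != nrow(panel)) {
    stop("genotype vector length must match panel size")
  }
  n_inf <- sum(!is.na(gt))
  if (n_inf < 100) stop("need at least 100 informative markers, got ", n_inf)
  ch <- panel_chains(panel, warn_ld = FALSE)
  e <- emission_probs(gt, panel$q, eps)
  ll <- function(f, a) {
    hmm_forward_cpp(e[, "ibd"], e[, "non_ibd"], ch$d, ch$new_chain,
                    min(max(f, 0), 0.5), min(max(a, 0.01), 10))
  }
  f_grid <- c(0, 0.01, 0.03, 0.0625, 0.125, 0.25, 0.4, 0.5)
  a_grid <- c(0.05, 0.2, 1, 4, 9)
  grid <- expand.grid(f = f_grid, a = a_grid)
  grid$ll <- mapply(ll, grid$f, grid$a)
  best <- grid[which.max(grid$ll), ]
  opt <- optim(c(best$f, best$a), function(p) -ll(p[1], p[2]),
               method = "L-BFGS-B", lower = c(0, 0.01),
               upper = c(0.5, 10))
  if (opt$convergence != 0 && opt$convergence != 52) {
    stop("inbreeding optimizer failed to converge (code ",
         opt$convergence, "): ", opt$message)
  }
  ll_hat <- -opt$value
  f_hat <- opt$par[1]
  a_hat <- opt$par[2]
  ll0 <- ll(0, 1)
  if (ll0 > ll_hat) {  # boundary fit can only improve on f = 0
    ll_hat <- ll0
    f_hat <- 0
  }
  lrt <- max(0, 2 * (ll_hat - ll0))
  p <- if (lrt <= 0 || f_hat <= 0) 1 else
    0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(list(f_hat = f_hat, a_hat = a_hat, loglik_hat = ll_hat,
                 loglik_f0 = ll0, lrt_statistic = lrt, p_value = p,
                 n_markers = n_inf, subsample_estimates = NULL,
                 f_median = NA_real_),
            class = "inbreeding_result")
}

#' @export
print.inbreeding_result <- function(x, ...) {
  cat(sprintf("inbreeding_result: f_hat = %.4f (a = %.3f), LRT = %.3f, p = %.4g",
              x$f_hat, x$a_hat, x$lrt_statistic, x$p_value))
  if (!is.na(x$f_median)) {
    cat(sprintf("; median of %d subsamples = %.4f",
                length(x$subsample_estimates), x$f_median))
  }
  cat("\n")
  invisible(x)
}

#' Median-of-subsamples inbreeding estimate
#'
#' Draws `n_subsamples` random marker subsets of size `subsample_size`
#' (without replacement, genomic order preserved), estimates `f` on each,
#' and reports the median; the likelihood-ratio fields come from a fit on
#' the full panel. Fully reproducible given `seed`.
#'
#' @inheritParams estimate_f
#' @param n_subsamples Number of random subsets.
#' @param subsample_size Markers per subset.
#' @param seed Integer RNG seed (`NULL` leaves the RNG state alone).
#' @return An `inbreeding_result` with `subsample_estimates` and
#'   `f_median` filled.
#' @export
subsample_median_estimate <- function(gt, panel, n_subsamples = 100,
                                      subsample_size = 3900, seed = NULL,
                                      eps = 1e-3) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(panel)
  full <- estimate_f(gt, panel, eps)
  if (n < subsample_size) {
    warning("panel smaller than subsample_size; using the full panel once")
    full$subsample_estimates <- full$f_hat
    full$f_median <- full$f_hat
    return(full)
  }
  ests <- vapply(seq_len(n_subsamples), function(i) {
    idx <- sort(sample.int(n, subsample_size))
    estimate_f(gt[idx], panel[idx, , drop = FALSE], eps)$f_hat
  }, 0.0)
  full$subsample_estimates <- ests
  full$f_median <- median(ests)
  full
}
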