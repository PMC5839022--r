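test_that("transition matrix limits: zero distance, long distance, f = 0", {
  tm0 <- transition_matrix(0.1, 2, 0)
  expect_equal(unname(tm0), diag(2))
  tml <- transition_matrix(0.1, 2, 50)
  expect_equal(unname(tml[1, ]), c(0.1, 0.9), tolerance = 1e-10)
  expect_equal(unname(tml[2, ]), c(0.1, 0.9), tolerance = 1e-10)
  tmf0 <- transition_matrix(0, 2, 0.3)
  expect_equal(unname(tmf0[2, 1]), 0)
  expect_equal(unname(tmf0[1, 1]), exp(-2 * 0.3))
  for (d in c(0, 0.01, 0.5, 3)) {
    expect_equal(rowSums(transition_matrix(0.2, 1.5, d)),
                 c(ibd = 1, non_ibd = 1))
  }
})

test_that("emissions: autozygotes are homozygous, states normalize, closed forms hold", {
  e <- emission_probs(1L, 0.3, eps = 0)
  expect_equal(unname(e[1, "ibd"]), 0)
  expect_equal(unname(e[1, "non_ibd"]), 2 * 0.3 * 0.7)
  e2 <- emission_probs(2L, 0.5, eps = 0)
  expect_equal(unname(e2[1, "ibd"]), 0.5)
  expect_equal(unname(e2[1, "non_ibd"]), 0.25)
  for (q in c(0.05, 0.3, 0.49)) {
    for (eps in c(0, 1e-3, 0.02)) {
      e3 <- emission_probs(0:2, rep(q, 3), eps)
      expect_equal(sum(e3[, "ibd"]), 1, tolerance = 1e-12)
      expect_equal(sum(e3[, "non_ibd"]), 1, tolerance = 1e-12)
    }
  }
  em <- emission_probs(NA, 0.3)
  expect_equal(unname(em[1, ]), c(1, 1))
  expect_error(emission_probs(1L, 1.2), "strictly")
})

test_that("forward likelihood equals exhaustive hidden-path enumeration on short chains", {
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(5:12, 1)
    panel <- tibble::tibble(chrom = "1", pos = seq_len(n),
                            q = runif(n, 0.1, 0.5),
                            cm = cumsum(runif(n, 0.1, 3)))
    gt <- sample(c(0:2, NA), n, replace = TRUE,
                 prob = c(0.4, 0.3, 0.2, 0.1))
    f <- runif(1, 0, 0.4)
    a <- runif(1, 0.1, 8)
    eps <- sample(c(0, 1e-3, 0.01), 1)
    ll <- forward_loglik(gt, panel, f, a, eps)
    ch <- trioseg:::panel_chains(panel, warn_ld = FALSE)
    e <- emission_probs(gt, panel$q, eps)
    expect_equal(ll, log(enum_hmm_lik(e[, "ibd"], e[, "non_ibd"], ch$d,
                                      f, a)), tolerance = 1e-10)
  }
})

test_that("chromosome chains are independent and order-invariant", {
  set.seed(32)
  panel <- tibble::tibble(chrom = rep(c("1", "2"), each = 6),
                          pos = rep(1:6, 2), q = runif(12, 0.1, 0.5),
                          cm = rep(cumsum(runif(6, 0.5, 2)), 2))
  gt <- sample(0:2, 12, replace = TRUE)
  ll <- forward_loglik(gt, panel, 0.2, 3, 1e-3)
  # per-chromosome sums
  i1 <- panel$chrom == "1"
  ll_split <- forward_loglik(gt[i1], panel[i1, ], 0.2, 3, 1e-3) +
    forward_loglik(gt[!i1], panel[!i1, ], 0.2, 3, 1e-3)
  expect_equal(ll, ll_split, tolerance = 1e-12)
  # swapping chromosome blocks preserves the likelihood
  panel_sw <- dplyr::bind_rows(panel[!i1, ], panel[i1, ]) %>%
    dplyr::mutate(chrom = rep(c("1", "2"), each = 6))
  ll_sw <- forward_loglik(c(gt[!i1], gt[i1]), panel_sw, 0.2, 3, 1e-3)
  expect_equal(ll, ll_sw, tolerance = 1e-12)
})

test_that("the f = 0 likelihood is the Hardy-Weinberg closed form", {
  panel <- simulate_marker_panel(600, seed = 33)
  g <- simulate_inbred_genotypes(panel, 0, 5, seed = 34)
  ll <- forward_loglik(g$genotypes, panel, 0, 1, eps = 0)
  q <- panel$q
  p <- c((1 - q)^2, 2 * q * (1 - q), q^2)[
    seq_len(nrow(panel)) + nrow(panel) * g$genotypes]
  expect_equal(ll, sum(log(p)), tolerance = 1e-10)
})

test_that("heterozygotes forbid autozygosity: any f > 0 lowers the likelihood of an all-het sample", {
  panel <- simulate_marker_panel(300, seed = 35)
  gt <- rep(1L, 300)
  ll0 <- forward_loglik(gt, panel, 0, 1, eps = 0)
  for (f in c(0.01, 0.1, 0.3)) {
    expect_lt(forward_loglik(gt, panel, f, 1, eps = 0), ll0)
  }
})

test_that("estimate_f boundary identities and input contracts", {
  panel <- simulate_marker_panel(800, seed = 36)
  gt <- rep(1L, 800)   # hets force f_hat to the boundary
  res <- estimate_f(gt, panel, eps = 0)
  expect_equal(res$f_hat, 0)
  expect_equal(res$lrt_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_gte(res$lrt_statistic, 0)
  expect_error(estimate_f(rep(NA_integer_, 800), panel), "informative")
  expect_error(estimate_f(gt[1:10], panel), "length")
})

test_that("f is recovered without material bias on inbred and outbred samples", {
  panel <- simulate_marker_panel(3900, seed = 37)
  for (f_true in c(0, 0.25)) {
    ests <- vapply(1:15, function(i) {
      g <- simulate_inbred_genotypes(panel, f_true, 5, seed = 500 + i)
      estimate_f(g$genotypes, panel)$f_hat
    }, 0.0)
    expect_lt(abs(mean(ests) - f_true), 0.03)
  }
})

test_that("outbred samples rarely reject the f = 0 null", {
  panel <- simulate_marker_panel(1500, seed = 38)
  ps <- vapply(1:20, function(i) {
    g <- simulate_inbred_genotypes(panel, 0, 5, seed = 900 + i)
    estimate_f(g$genotypes, panel)$p_value
  }, 0.0)
  expect_gte(mean(ps > 0.05), 0.95)
})

test_that("subsampled median estimation is seed-reproducible", {
  panel <- simulate_marker_panel(1200, seed = 39)
  g <- simulate_inbred_genotypes(panel, 0.0625, 5, seed = 40)
  r1 <- subsample_median_estimate(g$genotypes, panel, n_subsamples = 8,
                                  subsample_size = 600, seed = 41)
  r2 <- subsample_median_estimate(g$genotypes, panel, n_subsamples = 8,
                                  subsample_size = 600, seed = 41)
  expect_identical(r1$subsample_estimates, r2$subsample_estimates)
  expect_equal(r1$f_median, median(r1$subsample_estimates))
  expect_length(r1$subsample_estimates, 8)
  # degenerate identical estimates -> median is that constant
  expect_equal(median(rep(r1$f_median, 5)), r1$f_median)
  # small panels fall back to a single full-panel fit with a warning
  expect_warning(
    r3 <- subsample_median_estimate(g$genotypes, panel,
                                    n_subsamples = 3,
                                    subsample_size = 5000, seed = 42),
    "full panel")
  expect_equal(r3$f_median, r3$f_hat)
})

test_that("marker panels read back from disk and reject malformed input", {
  panel <- simulate_marker_panel(200, seed = 43)
  f <- tempfile(fileext = ".tsv")
  readr::write_tsv(panel, f)
  p2 <- read_marker_panel(f)
  expect_equal(as.data.frame(p2), as.data.frame(panel))
  bad <- panel
  bad$q[5] <- 1.5
  readr::write_tsv(bad, f)
  expect_error(read_marker_panel(f), "strictly")
})
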