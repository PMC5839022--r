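test_that("the pathogenicity rule reproduces starred and unstarred score patterns", {
  fl <- pathogenicity_flag(
    sift = c(0, 0.14, 0.39, NA, NA),
    polyphen = c(0.999, 0.689, 0.063, NA, NA),
    consequence = c("missense", "missense", "missense", "stop_gained", NA))
  expect_equal(fl$flag, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(fl$reason[1], "sift;polyphen")
  expect_equal(fl$reason[2], "polyphen")
  expect_equal(fl$reason[3], "benign")
  expect_equal(fl$reason[4], "lof")
  expect_equal(fl$reason[5], "unscored")
})

test_that("rule thresholds are inclusive at the published boundary scores", {
  r <- pathogenicity_rule()
  expect_true(pathogenicity_flag(0.05, NA, "missense", r)$flag)   # starred 0.05
  expect_false(pathogenicity_flag(0.06, NA, "missense", r)$flag)  # unstarred 0.06
  expect_true(pathogenicity_flag(NA, 0.446, "missense", r)$flag)
  expect_false(pathogenicity_flag(NA, 0.274, "missense", r)$flag) # unstarred
})

test_that("consequence tallies count each variant once under its most severe consequence", {
  ds <- tiny_dataset(list(c(2L, 1L, 1L), c(2L, 1L, 1L), c(2L, 1L, 1L)))
  # give the first variant two transcripts: missense + stop_gained
  extra <- ds$annotations[1, ]
  extra$transcript_id <- "alt.t2"
  extra$consequence <- "stop_gained"
  ds$annotations <- dplyr::bind_rows(ds$annotations, extra)
  seg <- segregate_all(ds)
  tt <- consequence_tally(seg$calls, ds$annotations)
  expect_equal(sum(tt$n), nrow(seg$calls))        # conservation
  expect_equal(tt$n[tt$consequence == "stop_gained"], 1)
  expect_equal(tt$n[tt$consequence == "missense"], 2)
})

test_that("empty call sets tally to nothing", {
  expect_equal(nrow(consequence_tally(tibble::tibble(trio_id = character(),
                                                     key = character()),
                                      trioseg:::empty_annotations() %>%
                                        dplyr::mutate(key = character(0)))),
               0)
})

test_that("ranks without ties give the exact enumerated rank-sum p-value", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$method, "exact")
  expect_equal(r$p_two_sided, 0.1)
  expect_equal(r$p_two_sided, enum_ranksum_p(c(1, 2, 3), c(4, 5, 6)))
  # random no-tie cases against full enumeration and stats::wilcox.test
  set.seed(77)
  for (i in 1:8) {
    x <- sample(seq(0, 1, by = 0.001), sample(3:6, 1))
    y <- sample(seq(2, 3, by = 0.0007), sample(3:6, 1))
    r <- rank_sum_test(x, y)
    expect_equal(r$p_two_sided, enum_ranksum_p(x, y), tolerance = 1e-12)
    w <- wilcox.test(x, y, exact = TRUE, correct = TRUE)
    expect_equal(r$u_statistic, unname(w$statistic))
    expect_equal(r$p_two_sided, w$p.value, tolerance = 1e-12)
  }
})

test_that("the rank-sum test is symmetric under group swap", {
  set.seed(78)
  x <- runif(9)
  y <- runif(11)
  a <- rank_sum_test(x, y)
  b <- rank_sum_test(y, x)
  expect_equal(a$u_statistic, length(x) * length(y) - b$u_statistic)
  expect_equal(a$p_two_sided, b$p_two_sided, tolerance = 1e-12)
})

test_that("identical samples give a p-value of one", {
  x <- c(1.2, 3.4, 5.6, 7.8)
  r <- rank_sum_test(x, x)
  expect_equal(r$p_two_sided, 1)
})

test_that("tie-corrected normal approximation agrees with a permutation oracle", {
  set.seed(79)
  x <- round(rnorm(15, 0.0, 1), 1)
  y <- round(rnorm(15, 0.6, 1), 1)
  r <- rank_sum_test(x, y)
  expect_equal(r$method, "normal")
  # permutation with fixed combined midranks
  n1 <- length(x)
  rk <- rank(c(x, y))
  mu <- n1 * length(y) / 2
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- replicate(1e5, sum(sample(rk, n1)) - n1 * (n1 + 1) / 2)
  p_perm <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  expect_equal(r$p_two_sided, p_perm, tolerance = 0.01)
})

test_that("exact and normal p-values agree closely for moderate untied samples", {
  set.seed(80)
  x <- sample(seq(0, 10, by = 1e-4), 11)
  y <- sample(seq(0.5, 10.5, by = 1e-4 * 1.7), 12)
  pe <- rank_sum_test(x, y, exact = TRUE)$p_two_sided
  pn <- rank_sum_test(x, y, exact = FALSE)$p_two_sided
  expect_lt(abs(pe - pn), 0.02)
})

test_that("empty groups are rejected", {
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
  expect_error(rank_sum_test(1:3, NA_real_), "non-empty")
})

test_that("hypergeometric over-representation matches exact tail sums", {
  u <- paste0("g", 1:20)
  res <- ora_enrichment(u[1:5], list(s1 = u[c(1:3, 18, 19)]), u)
  expect_equal(res$p_hypergeometric, hyper_tail(3, 5, 20, 5),
               tolerance = 1e-12)
  expect_equal(res$overlap_count, 3)
  # overlap 0: upper tail at zero is one
  res0 <- ora_enrichment(u[1:5], list(s0 = u[10:14]), u)
  expect_equal(res0$p_hypergeometric, 1)
  # degenerate: query = set = universe forces p = 1
  resd <- ora_enrichment(u, list(all = u), u)
  expect_equal(resd$p_hypergeometric, 1)
  # random cases against the combinatorial oracle
  set.seed(81)
  for (i in 1:10) {
    nn <- sample(15:40, 1)
    uu <- paste0("x", seq_len(nn))
    set <- sample(uu, sample(3:10, 1))
    query <- sample(uu, sample(3:10, 1))
    r <- ora_enrichment(query, list(s = set), uu)
    expect_equal(r$p_hypergeometric,
                 hyper_tail(r$overlap_count, r$set_size, nn,
                            r$query_size), tolerance = 1e-12)
  }
})

test_that("BH adjustment is monotone and never below the raw p-value", {
  set.seed(82)
  u <- paste0("g", 1:50)
  sets <- lapply(1:12, function(i) sample(u, sample(5:15, 1)))
  names(sets) <- paste0("s", 1:12)
  res <- ora_enrichment(sample(u, 8), sets, u)
  expect_true(all(res$fdr_bh >= res$p_hypergeometric - 1e-12))
  expect_true(!is.unsorted(res$fdr_bh))   # results ordered by p
  expect_true(all(res$overlap_count <= pmin(res$set_size,
                                            res$query_size)))
})

test_that("enrichment input contracts are enforced", {
  u <- paste0("g", 1:10)
  expect_error(ora_enrichment(character(0), list(s = u[1:2]), u),
               "non-empty")
  expect_error(ora_enrichment(c("zz"), list(s = u[1:2]), u), "subset")
})

test_that("GMT files parse into named gene sets", {
  f <- write_lines_tmp(c("setA\tdesc\tg1\tg2\tg3",
                         "setB\tdesc\tg2\tg4"), ".gmt")
  sets <- read_gmt(f)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_error(read_gmt(write_lines_tmp("bad\tonly", ".gmt")),
               "malformed")
})
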