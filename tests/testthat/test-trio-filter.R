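test_that("allele balance is the alt-read fraction, defined for hets only", {
  expect_equal(allele_balance(10, 10, 1L), 0.5)
  expect_equal(allele_balance(65, 35, 1L), 0.35)
  expect_equal(allele_balance(90, 10, 1L), 0.10)
  expect_true(is.na(allele_balance(0, 0, 1L)))
  expect_true(is.na(allele_balance(2, 98, 2L)))   # hom calls exempt
  expect_true(is.na(allele_balance(50, 50, NA)))
})

test_that("genotype filters apply GQ strictly above threshold and the inclusive AB band", {
  mk <- function(ad_c, gq_c) {
    ds <- tiny_dataset(list(c(1L, 0L, 0L)), gq = 99, dp = 100)
    g <- ds$genotypes
    i <- g$sample == "T1c"
    g$ad_alt[i] <- ad_c
    g$ad_ref[i] <- 100 - ad_c
    g$gq[i] <- gq_c
    ds$genotypes <- g
    ds
  }
  th <- filter_thresholds()
  trio <- test_trios(1)[1, ]
  expect_true(passes_genotype_filters(mk(50, 21), trio, th)$record_pass)
  expect_false(passes_genotype_filters(mk(50, 20), trio, th)$child_pass)
  expect_false(passes_genotype_filters(mk(34, 99), trio, th)$child_pass)
  expect_true(passes_genotype_filters(mk(35, 99), trio, th)$child_pass)
  expect_true(passes_genotype_filters(mk(65, 99), trio, th)$child_pass)
  expect_false(passes_genotype_filters(mk(66, 99), trio, th)$child_pass)
  # missing GQ fails conservatively
  expect_false(passes_genotype_filters(mk(50, NA), trio, th)$child_pass)
})

test_that("hom-alt calls with extreme allele balance are not discarded", {
  ds <- tiny_dataset(list(c(2L, 1L, 1L)))
  g <- ds$genotypes
  i <- g$sample == "T1c"
  g$ad_alt[i] <- 98
  g$ad_ref[i] <- 2
  ds$genotypes <- g
  pf <- passes_genotype_filters(ds, test_trios(1)[1, ])
  expect_true(pf$child_pass)
})

test_that("parental AB filtering can be switched off", {
  ds <- tiny_dataset(list(c(0L, 1L, 0L)))
  g <- ds$genotypes
  i <- g$sample == "T1p"
  g$ad_alt[i] <- 10
  g$ad_ref[i] <- 90
  ds$genotypes <- g
  trio <- test_trios(1)[1, ]
  expect_false(passes_genotype_filters(ds, trio)$father_pass)
  expect_true(passes_genotype_filters(ds, trio,
                                      ab_parents = FALSE)$father_pass)
})

test_that("min_depth is enforced when set", {
  ds <- tiny_dataset(list(c(1L, 0L, 0L)), dp = 8)
  trio <- test_trios(1)[1, ]
  expect_true(passes_genotype_filters(ds, trio)$record_pass)
  th <- filter_thresholds(min_depth = 10)
  expect_false(passes_genotype_filters(ds, trio, th)$record_pass)
})

test_that("posterior boundary identities hold", {
  # mu = 0, certain hom-ref parents, uninformative child: only hom-ref
  # child states carry mass
  p <- trio_genotype_posterior(c(0, 0, 0), c(0, 255, 255), c(0, 255, 255),
                               denovo_prior(0), 0.01)
  expect_equal(p$child_marginal, c(1, 0, 0))
  # flat likelihoods everywhere: posterior equals the prior T * H * H
  p2 <- trio_genotype_posterior(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0),
                                denovo_prior(0), 0.3)
  tr <- trioseg:::transmission_array(0)
  h <- trioseg:::hwe_prior(0.3)
  prior <- tr * rep(1, 3)
  prior <- prior * rep(h, each = 3)
  prior <- prior * rep(h, each = 9)
  prior <- prior / sum(prior)
  expect_equal(p2$joint, prior, tolerance = 1e-12)
})

test_that("a weakly supported de novo is suppressed by the transmission prior", {
  p <- trio_genotype_posterior(c(30, 0, 30), c(0, 255, 255),
                               c(0, 255, 255), denovo_prior(1e-6), 0.01)
  expect_equal(p$child_marginal[2], 2e-6 / (2e-6 + 1e-3 + 1e-9),
               tolerance = 0.05)
  expect_equal(p$reassigned_child_gt, 0L)
  # brute-force agreement on the same case
  expect_equal(p$joint, brute_posterior(c(30, 0, 30), c(0, 255, 255),
                                        c(0, 255, 255), 1e-6, 0.01),
               tolerance = 1e-12)
})

test_that("posterior matches the literal 27-state enumeration and sums to one", {
  set.seed(401)
  for (i in 1:25) {
    pls <- lapply(1:3, function(j) {
      pl <- sample(0:120, 3, replace = TRUE)
      pl - min(pl)
    })
    mu <- sample(c(0, 1e-8, 1e-6, 1e-4), 1)
    q <- runif(1, 0.001, 0.5)
    p <- trio_genotype_posterior(pls[[1]], pls[[2]], pls[[3]],
                                 denovo_prior(mu), q)
    expect_equal(sum(p$joint), 1, tolerance = 1e-9)
    expect_equal(sum(p$child_marginal), 1, tolerance = 1e-9)
    expect_equal(p$child_marginal, apply(p$joint, 1, sum),
                 tolerance = 1e-12)
    b <- brute_posterior(pls[[1]], pls[[2]], pls[[3]], mu, q)
    expect_equal(p$joint, b, tolerance = 1e-12)
    expect_equal(p$reassigned_child_gt,
                 which.max(apply(b, 1, sum)) - 1L)
  }
})

test_that("mu = 0 posterior mass vanishes exactly on Mendelian-inconsistent triples", {
  set.seed(402)
  for (i in 1:10) {
    pls <- lapply(1:3, function(j) sample(0:60, 3))
    p <- trio_genotype_posterior(pls[[1]], pls[[2]], pls[[3]],
                                 denovo_prior(0), 0.2)
    for (ci in 0:2) for (fi in 0:2) for (mi in 0:2) {
      cons <- mendelian_consistent(ci, fi, mi)
      if (!cons) {
        expect_equal(p$joint[ci + 1, fi + 1, mi + 1], 0)
      }
    }
  }
})

test_that("weaker het evidence never increases the het posterior", {
  pl_par <- c(0, 90, 900)
  prev <- Inf
  for (pl_het in c(0, 10, 20, 40, 80)) {
    p <- trio_genotype_posterior(c(50, pl_het, 50), pl_par, pl_par,
                                 denovo_prior(1e-6), 0.05)
    expect_lte(p$child_marginal[2], prev + 1e-12)
    prev <- p$child_marginal[2]
  }
})

test_that("posterior requires complete PL triples", {
  expect_error(trio_genotype_posterior(c(0, NA, 10), c(0, 10, 20),
                                       c(0, 10, 20)), "PL")
  expect_error(trio_genotype_posterior(c(0, 1), c(0, 10, 20),
                                       c(0, 10, 20)), "PL")
})

test_that("reassigned genotype quality is phred of the residual and capped at 99", {
  p <- trio_genotype_posterior(c(2000, 0, 2000), c(2000, 0, 2000),
                               c(2000, 0, 2000), denovo_prior(1e-6), 0.3)
  expect_equal(p$reassigned_child_gq, 99)
  p2 <- trio_genotype_posterior(c(3, 0, 3), c(0, 0, 0), c(0, 0, 0),
                                denovo_prior(1e-6), 0.3)
  expect_equal(p2$reassigned_child_gq,
               min(99, round(-10 * log10(1 - max(p2$child_marginal)))))
})
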