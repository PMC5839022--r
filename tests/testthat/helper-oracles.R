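# Independent oracles used across the suite. Each is a deliberately naive
# implementation (literal loops, exhaustive enumeration, closed forms) kept
# separate from the package's own code paths.

# Literal triple-loop trio genotype posterior.
brute_posterior <- function(pl_c, pl_f, pl_m, mu, q) {
  lik <- function(pl) {
    l <- 10^(-pl / 10)
    l / sum(l)
  }
  p_alt <- function(g) (g / 2) * (1 - mu) + (1 - g / 2) * mu
  hwe <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  lc <- lik(pl_c); lf <- lik(pl_f); lm <- lik(pl_m)
  joint <- array(0, c(3, 3, 3))
  for (ci in 0:2) for (fi in 0:2) for (mi in 0:2) {
    pf <- p_alt(fi); pm <- p_alt(mi)
    tr <- switch(ci + 1,
                 (1 - pf) * (1 - pm),
                 pf * (1 - pm) + (1 - pf) * pm,
                 pf * pm)
    joint[ci + 1, fi + 1, mi + 1] <-
      lc[ci + 1] * lf[fi + 1] * lm[mi + 1] * tr * hwe[fi + 1] * hwe[mi + 1]
  }
  joint / sum(joint)
}

# Exhaustive hidden-path likelihood of the two-state autozygosity HMM on a
# single chain (no chromosome breaks inside; d[1] ignored).
enum_hmm_lik <- function(e_ibd, e_non, d, f, a) {
  n <- length(e_ibd)
  paths <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), n)))
  total <- 0
  for (p in seq_len(nrow(paths))) {
    st <- paths[p, ]
    pr <- if (st[1]) f else 1 - f
    pr <- pr * (if (st[1]) e_ibd[1] else e_non[1])
    for (i in 2:n) {
      r <- exp(-a * d[i])
      ptrans <- if (st[i - 1]) {
        if (st[i]) r + (1 - r) * f else (1 - r) * (1 - f)
      } else {
        if (st[i]) (1 - r) * f else r + (1 - r) * (1 - f)
      }
      pr <- pr * ptrans * (if (st[i]) e_ibd[i] else e_non[i])
    }
    total <- total + pr
  }
  total
}

# Exact two-sided rank-sum p-value by full enumeration of group-label
# assignments (no ties assumed).
enum_ranksum_p <- function(x, y) {
  n1 <- length(x)
  vals <- c(x, y)
  r <- rank(vals)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * length(y) / 2
  combos <- utils::combn(length(vals), n1)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Exact hypergeometric upper tail by explicit combinatorial sums.
hyper_tail <- function(k, set_size, universe, draws) {
  kk <- k:min(set_size, draws)
  sum(choose(set_size, kk) * choose(universe - set_size, draws - kk)) /
    choose(universe, draws)
}

# Mendelian transmission table: can the child triple arise without
# mutation?
oracle_consistent <- function(c1, f1, m1) {
  tf <- switch(f1 + 1, 0, c(0, 1), 1)
  tm <- switch(m1 + 1, 0, c(0, 1), 1)
  any(outer(tf, tm, `+`) == c1)
}

expect_tibble_equal <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
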