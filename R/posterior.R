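#' De novo transmission prior
#'
#' Per-allele mutation probability used by the pedigree-informed genotype
#' posterior: each transmitted allele mutates independently with probability
#' `mu`.
#'
#' @param mu Per-allele de novo probability, in `[0, 1e-3]`.
#' @return An object of class `denovo_prior`.
#' @export
denovo_prior <- function(mu = 1e-6) {
  stopifnot(mu >= 0, mu <= 1e-3)
  structure(list(mu = mu), class = "denovo_prior")
}

# P(child genotype | father, mother) with per-allele mutation rate mu;
# dimensions [child+1, father+1, mother+1], genotypes coded 0/1/2.
transmission_array <- function(mu) {
  p_alt <- function(g) (g / 2) * (1 - mu) + (1 - g / 2) * mu
  tr <- array(0, c(3, 3, 3))
  for (f in 0:2) {
    for (m in 0:2) {
      pf <- p_alt(f)
      pm <- p_alt(m)
      tr[1, f + 1, m + 1] <- (1 - pf) * (1 - pm)
      tr[2, f + 1, m + 1] <- pf * (1 - pm) + (1 - pf) * pm
      tr[3, f + 1, m + 1] <- pf * pm
    }
  }
  tr
}

hwe_prior <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

pl_to_lik <- function(pl) {
  l <- 10^(-pl / 10)
  l / sum(l)
}

#' Pedigree-informed joint genotype posterior for one trio at one site
#'
#' Combines the three members' PL-derived genotype likelihoods with
#' Hardy-Weinberg priors on the parents and a Mendelian transmission model
#' in which each transmitted allele mutates independently with probability
#' `mu`:
#' `joint(c,f,m) ∝ L_c(c) L_f(f) L_m(m) T(c|f,m; mu) H(f) H(m)`.
#' The child genotype is reassigned to the argmax of its marginal, with a
#' phred-scaled quality `-10 log10(1 - max marginal)` capped at 99.
#'
#' @param pl_child,pl_father,pl_mother Numeric PL triples
#'   (ref/ref, ref/alt, alt/alt).
#' @param prior A [denovo_prior()].
#' @param pop_alt_freq Population alternate-allele frequency for the HWE
#'   parental prior (use the variant's MAF when known).
#' @return List of class `trio_genotype_posterior` with `joint` (3x3x3
#'   array, child x father x mother), `child_marginal`,
#'   `reassigned_child_gt` (0/1/2) and `reassigned_child_gq`.
#' @export
trio_genotype_posterior <- function(pl_child, pl_father, pl_mother,
                                    prior = denovo_prior(),
                                    pop_alt_freq = 0.01) {
  pls <- list(pl_child, pl_father, pl_mother)
  if (any(vapply(pls, function(p) length(p) != 3 || anyNA(p), TRUE))) {
    stop("all three members need complete PL triples")
  }
  stopifnot(pop_alt_freq > 0, pop_alt_freq < 1)
  tr <- transmission_array(prior$mu)
  h <- hwe_prior(pop_alt_freq)
  lc <- pl_to_lik(pl_child)
  lf <- pl_to_lik(pl_father)
  lm <- pl_to_lik(pl_mother)
  # element (c,f,m); recycling runs the child index fastest
  joint <- tr * lc
  joint <- joint * rep(lf * h, each = 3)
  joint <- joint * rep(lm * h, each = 9)
  total <- sum(joint)
  if (total <= 0) stop("degenerate posterior: zero total mass")
  joint <- joint / total
  child_marginal <- apply(joint, 1, sum)
  gt <- which.max(child_marginal) - 1L
  gq <- -10 * log10(max(1 - max(child_marginal), 1e-10))
  structure(list(joint = joint, child_marginal = child_marginal,
                 reassigned_child_gt = gt,
                 reassigned_child_gq = min(99, round(gq))),
            class = "trio_genotype_posterior")
}
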