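#' Exact conditional test of Hardy-Weinberg equilibrium
#'
#' Exact test conditioning on the observed allele counts: the p-value is the
#' total probability, under random mating, of all heterozygote counts whose
#' conditional probability does not exceed that of the observed
#' configuration.  This is the standard exact test for biallelic markers and
#' is preferred over the chi-square approximation in small samples such as a
#' 42-subject unaffected stratum.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative integers)
#' @return p-value in (0, 1]; a monomorphic sample returns 1 by convention.
#' @export
#' @examples
#' hwe_exact(25, 50, 25)   # most probable configuration, p = 1
#' hwe_exact(5, 0, 5)      # heterozygote deficit, small p
hwe_exact <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  .stop_if(any(counts < 0) || any(counts != round(counts)),
           "genotype counts must be non-negative integers")
  n <- sum(counts)
  .stop_if(n < 1, "total genotype count must be >= 1")
  n_a <- n_Aa + 2L * n_aa           # minor-allele count (either allele works
  n_a <- min(n_a, 2L * n - n_a)     # by symmetry of the conditional law)
  if (n_a == 0) return(1)

  # heterozygote counts share the parity of the rarer allele count
  het <- seq(n_a %% 2L, n_a, by = 2L)
  # log conditional probability of each heterozygote count given (n, n_a)
  logp <- lgamma(n + 1) - lgamma((n_a - het) / 2 + 1) - lgamma(het + 1) -
    lgamma(n - (n_a + het) / 2 + 1) + het * log(2) +
    lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, het)]
  # tolerance guards ties against floating-point noise
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}
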