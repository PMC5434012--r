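#' Pairwise linkage disequilibrium via EM haplotype frequencies
#'
#' Estimates the four two-locus haplotype frequencies from unphased
#' genotypes by expectation-maximization: double heterozygotes are split
#' between the two phase configurations in proportion to the current
#' haplotype-frequency estimates at each iteration.  From the converged
#' frequencies it reports D' and r-squared; r-squared equal to one defines
#' complete LD for pruning.
#'
#' @param x a \code{\link{cohort}}
#' @param snp_a,snp_b SNP ids present in \code{x}
#' @param tol EM convergence tolerance on the frequency change
#'   (default 1e-10)
#' @param max_iter iteration cap (default 1000)
#' @return an object of class \code{ld_pair}: list with \code{snp_a},
#'   \code{snp_b}, \code{hap_freqs} (named AB, Ab, aB, ab), \code{d_prime},
#'   \code{r2}, \code{n} (doubly-called subjects), \code{loglik_trace}.
#' @export
ld_em <- function(x, snp_a, snp_b, tol = 1e-10, max_iter = 1000) {
  .stop_if(!all(c(snp_a, snp_b) %in% x$snp_ids),
           "both SNPs must be present in the cohort")
  ga <- x$genotypes[, snp_a]
  gb <- x$genotypes[, snp_b]
  ok <- !is.na(ga) & !is.na(gb)
  .stop_if(sum(ok) < 2, "need at least 2 doubly-called subjects")
  # minor-allele dosage 0/1/2
  da <- c(AA = 0, Aa = 1, aa = 2)[ga[ok]]
  db <- c(AA = 0, Aa = 1, aa = 2)[gb[ok]]
  n <- sum(ok)
  .stop_if(all(da == da[1]) || all(db == db[1]),
           "LD undefined: monomorphic locus among doubly-called subjects")

  # 3x3 genotype table; cell (i, j) = count with dosage i-1 at a, j-1 at b
  tab <- matrix(0, 3, 3)
  for (k in seq_len(n)) tab[da[k] + 1, db[k] + 1] <- tab[da[k] + 1, db[k] + 1] + 1

  # haplotypes: 1 = AB, 2 = Ab, 3 = aB, 4 = ab  (A/B = major alleles)
  f <- rep(0.25, 4)
  # known haplotype contributions from all cells except the double het
  known <- c(
    AB = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1],
    Ab = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
    aB = 2 * tab[3, 1] + tab[2, 1] + tab[3, 2],
    ab = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3])
  ndh <- tab[2, 2]
  loglik_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    # E: split double heterozygotes between AB/ab and Ab/aB phases
    w_cis <- f[1] * f[4]
    w_trans <- f[2] * f[3]
    denom <- w_cis + w_trans
    share_cis <- if (denom > 0) w_cis / denom else 0.5
    exp_counts <- known + ndh * c(share_cis, 1 - share_cis,
                                  1 - share_cis, share_cis)
    f_new <- exp_counts / (2 * n)
    ll <- .ld_loglik(tab, f_new)
    loglik_trace <- c(loglik_trace, ll)
    if (max(abs(f_new - f)) < tol) {
      f <- f_new
      break
    }
    f <- f_new
  }
  names(f) <- c("AB", "Ab", "aB", "ab")

  pA <- f[1] + f[2]; pB <- f[1] + f[3]
  d <- f[1] - pA * pB
  dmax <- if (d >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  d_prime <- if (dmax > 0) abs(d) / dmax else 0
  r2 <- d^2 / (pA * (1 - pA) * pB * (1 - pB))

  structure(list(snp_a = snp_a, snp_b = snp_b, hap_freqs = f,
                 d_prime = unname(min(1, d_prime)), r2 = unname(min(1, r2)),
                 n = n, loglik_trace = loglik_trace),
            class = "ld_pair")
}

# observed-genotype log-likelihood under haplotype frequencies f
.ld_loglik <- function(tab, f) {
  # probability of each genotype cell under random union of haplotypes
  p <- matrix(0, 3, 3)
  p[1, 1] <- f[1]^2;        p[1, 2] <- 2 * f[1] * f[2]; p[1, 3] <- f[2]^2
  p[2, 1] <- 2 * f[1] * f[3]
  p[2, 2] <- 2 * (f[1] * f[4] + f[2] * f[3])
  p[2, 3] <- 2 * f[2] * f[4]
  p[3, 1] <- f[3]^2;        p[3, 2] <- 2 * f[3] * f[4]; p[3, 3] <- f[4]^2
  sum(tab[tab > 0] * log(p[tab > 0]))
}

#' @export
print.ld_pair <- function(x, ...) {
  cat(sprintf("LD %s ~ %s (n = %d): D' = %.4f, r2 = %.4f\n",
              x$snp_a, x$snp_b, x$n, x$d_prime, x$r2))
  invisible(x)
}
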