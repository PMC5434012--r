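# Independent oracles used across the suite.  These are deliberately
# written with different primitives (dlogis/plogis, choose(), explicit
# set operations, subject-by-subject loops) than the implementation paths
# they check.

# brute-force mixture log-likelihood: per-subject loop over the density /
# survivor expressions via stats::dlogis / stats::plogis
oracle_loglik <- function(params, data, spec) {
  p1 <- 1 + length(spec$logistic)
  p2 <- 1 + length(spec$location)
  beta <- params[1:p1]
  gamma <- params[(p1 + 1):(p1 + p2)]
  alpha <- params[(p1 + p2 + 1):length(params)]
  total <- 0
  for (i in seq_len(nrow(data))) {
    zb <- c(1, as.numeric(data[i, spec$logistic, drop = FALSE]))
    zl <- c(1, as.numeric(data[i, spec$location, drop = FALSE]))
    zs <- c(1, as.numeric(data[i, spec$scale, drop = FALSE]))
    pi_i <- plogis(sum(beta * zb))
    mu <- sum(gamma * zl)
    sigma <- exp(sum(alpha * zs))
    w <- (log(data$age[i]) - mu) / sigma
    if (data$event[i] == 1) {
      # f_T(t) = f_logis(w) / (sigma * t)
      total <- total + log(pi_i) +
        dlogis(w, log = TRUE) - log(sigma) - log(data$age[i])
    } else {
      s <- 1 - plogis(w)
      total <- total + log(pi_i * s + (1 - pi_i))
    }
  }
  total
}

# full-enumeration exact HWE p-value via choose() arithmetic
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- n_Aa + 2 * n_aa
  na <- min(na, 2 * n - na)
  if (na == 0) return(1)
  hets <- seq(na %% 2, na, by = 2)
  probs <- vapply(hets, function(h) {
    naa <- (na - h) / 2
    nAA <- n - h - naa
    # multinomial count of genotype configurations / arrangements of alleles
    exp(lfactorial(n) - lfactorial(nAA) - lfactorial(h) - lfactorial(naa) +
          h * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
          lfactorial(2 * n))
  }, 0)
  probs <- probs / sum(probs)
  obs <- probs[hets == n_Aa]
  min(1, sum(probs[probs <= obs * (1 + 1e-9)]))
}

# Jaccard by explicit set operations on index sets
oracle_jaccard <- function(x, y) {
  ix <- which(x == 1)
  iy <- which(y == 1)
  un <- union(ix, iy)
  if (length(un) == 0) return(0)
  length(intersect(ix, iy)) / length(un)
}

# hand-rolled product-limit estimator (events before censorings at ties)
oracle_km <- function(ages, events) {
  ts <- sort(unique(ages[events == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (k in seq_along(ts)) {
    at_risk <- sum(ages >= ts[k])
    d <- sum(ages == ts[k] & events == 1)
    s <- s * (1 - d / at_risk)
    out[k] <- 1 - s
  }
  list(times = ts, event_prob = out)
}

# dense grid search for the intercept-only mixture MLE, driven by the
# brute-force likelihood above
oracle_grid_mle <- function(data, b0, g0, a0) {
  spec0 <- mixture_spec()
  best <- c(NA, NA, NA)
  best_ll <- -Inf
  for (b in b0) for (g in g0) for (a in a0) {
    ll <- oracle_loglik(c(b, g, a), data, spec0)
    if (is.finite(ll) && ll > best_ll) {
      best_ll <- ll
      best <- c(b, g, a)
    }
  }
  list(par = best, loglik = best_ll)
}

# small deterministic 10-subject mixed event/censoring fixture
ten_subject_fixture <- function() {
  data.frame(
    id = sprintf("P%02d", 1:10),
    age = c(18.2, 22.5, 25.1, 30.7, 33.3, 35.0, 41.8, 45.2, 52.9, 61.4),
    event = c(1L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 0L),
    x = c(0, 1, 1, 0, 0, 1, 1, 0, 1, 0),
    stringsAsFactors = FALSE)
}

# cohort writer shortcut for IO tests
write_toy_table <- function(df, path, sep = ",") {
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              na = "NA")
  path
}
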