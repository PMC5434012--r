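#' Susceptibility probability from the logistic submodel
#'
#' \eqn{\pi = \mathrm{expit}(\beta'Z)}: the probability of eventual disease
#' development (lifetime susceptibility) for covariate vector \code{z}.
#' The linear predictor is clipped at \eqn{\pm 700} before exponentiation.
#'
#' @param beta logistic coefficients (intercept first)
#' @param z covariate vector or matrix (rows = profiles), intercept included
#'   as leading 1; a vector of length \code{length(beta) - 1} is padded with
#'   the intercept automatically.
#' @return susceptibility probabilities in (0, 1)
#' @export
susceptibility <- function(beta, z) {
  z <- .profile_matrix(z, length(beta))
  .expit(drop(z %*% beta))
}

.profile_matrix <- function(z, p) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (ncol(z) == p - 1) z <- cbind(1, z)
  .stop_if(ncol(z) != p, "profile has wrong length for the coefficients")
  z
}

#' Conditional survival of susceptible subjects
#'
#' Log-logistic AFT survival among those who will develop the disease:
#' \eqn{\Pr(T > t \mid D = 1) = 1 / (1 + \exp((\ln t - \mu)/\sigma))} with
#' location \eqn{\mu} and scale \eqn{\sigma = \exp(\eta)}.  At
#' \eqn{t = e^\mu} the survival is exactly one half (the log-logistic
#' median).
#'
#' @param t age(s), strictly positive
#' @param mu location linear predictor \eqn{\gamma'Z^*}
#' @param log_sigma log-scale linear predictor \eqn{\eta = \alpha'Z^*}
#' @return survival probabilities
#' @export
conditional_survival <- function(t, mu, log_sigma = 0) {
  .stop_if(any(t <= 0), "domain error: t must be > 0")
  sigma <- exp(.clip_lp(log_sigma, 300))
  .logis_surv((log(t) - mu) / sigma)
}

#' Median onset age of susceptible subjects
#'
#' The log-logistic AFT median is \eqn{\exp(\mu)}, independent of the scale
#' part.
#'
#' @param mu location linear predictor(s)
#' @return median onset age(s) in years
#' @export
#' @examples
#' median_onset(3.62)  # about 37.3 years
median_onset <- function(mu) exp(mu)

#' Overall mixture survival
#'
#' \eqn{\Pr(T > t) = \pi S(t \mid D = 1) + (1 - \pi)}: susceptible subjects
#' survive per the conditional law, the risk-free fraction survives forever,
#' which produces the flat tail at \eqn{1 - \pi}.
#'
#' @param t age(s), strictly positive
#' @param pi susceptibility probability in [0, 1]
#' @param mu,log_sigma conditional location and log-scale
#' @return overall survival probabilities
#' @export
mixture_survival <- function(t, pi, mu, log_sigma = 0) {
  .stop_if(any(pi < 0 | pi > 1), "pi must be in [0, 1]")
  pi * conditional_survival(t, mu, log_sigma) + (1 - pi)
}

# ---------------------------------------------------------------------------

#' Wald tests and confidence intervals for a mixture fit
#'
#' Per-coefficient normal-theory inference from the observed-information
#' covariance: \eqn{z = \hat\theta/SE}, two-sided p, 95\% CI
#' \eqn{\hat\theta \pm 1.96\,SE}.  Logistic-part coefficients are also
#' reported on the odds-ratio scale with exponentiated CI bounds.  If the
#' fit sits at a susceptibility boundary, inference for the logistic part
#' is suppressed (\code{NA}) rather than trusted.
#'
#' @param fit a \code{\link{fit_mixture}} result
#' @param level confidence level (default 0.95)
#' @return data.frame with columns \code{part}, \code{term},
#'   \code{estimate}, \code{se}, \code{z}, \code{p}, \code{lower},
#'   \code{upper}, \code{or}, \code{or_lower}, \code{or_upper} (OR columns
#'   \code{NA} outside the logistic part)
#' @export
wald_tests <- function(fit, level = 0.95) {
  .stop_if(!inherits(fit, "mixture_fit"), "fit must be a mixture_fit")
  if (is.null(fit$vcov) || !fit$vcov_psd) {
    warning("covariance not positive definite; Wald inference unavailable",
            call. = FALSE)
  }
  est <- coef(fit)
  parts <- rep(c("logistic", "location", "scale"),
               times = lengths(fit$coefficients))
  terms <- unlist(lapply(fit$coefficients, names), use.names = FALSE)
  se <- if (!is.null(fit$vcov) && fit$vcov_psd) sqrt(pmax(diag(fit$vcov), 0))
        else rep(NA_real_, length(est))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  lower <- est - zq * se
  upper <- est + zq * se
  if (fit$boundary) {
    idx <- parts == "logistic"
    se[idx] <- z[idx] <- p[idx] <- lower[idx] <- upper[idx] <- NA_real_
  }
  out <- data.frame(part = parts, term = terms, estimate = unname(est),
                    se = unname(se), z = unname(z), p = unname(p),
                    lower = unname(lower), upper = unname(upper),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$or <- ifelse(out$part == "logistic", exp(out$estimate), NA_real_)
  out$or_lower <- ifelse(out$part == "logistic", exp(out$lower), NA_real_)
  out$or_upper <- ifelse(out$part == "logistic", exp(out$upper), NA_real_)
  out
}

#' Likelihood ratio test between nested mixture fits
#'
#' @param fit_full,fit_null converged fits on identical data, with the null
#'   spec's covariates nested in the full spec's, part by part
#' @return list with \code{chi2}, \code{df}, \code{p}
#' @export
lrt <- function(fit_full, fit_null) {
  .stop_if(!inherits(fit_full, "mixture_fit") ||
             !inherits(fit_null, "mixture_fit"),
           "both arguments must be mixture fits")
  for (part in c("logistic", "location", "scale")) {
    .stop_if(!all(fit_null$spec[[part]] %in% fit_full$spec[[part]]),
             "usage error: null spec not nested in full spec (", part, " part)")
  }
  .stop_if(fit_full$n != fit_null$n,
           "usage error: fits use different complete-case sets")
  chi2 <- 2 * (fit_full$loglik - fit_null$loglik)
  .stop_if(chi2 < -1e-6,
           "full fit has lower likelihood than null; refit with more starts")
  chi2 <- max(chi2, 0)
  df <- fit_full$df - fit_null$df
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Model-based overall and conditional event curves
#'
#' Evaluates, for each covariate profile, the overall cumulative event
#' probability \eqn{1 - [\pi S(t|D=1) + (1-\pi)]} and the conditional one
#' \eqn{1 - S(t|D=1)} on an age grid.  The overall curve plateaus at
#' \eqn{\pi} as age grows.
#'
#' @param fit a \code{mixture_fit}
#' @param profiles data.frame of covariate values, one row per profile,
#'   columns covering the union of the spec's covariates; a \code{label}
#'   column is carried through if present.
#' @param grid age grid (default 200 points spanning the data)
#' @return list of \code{event_curve} objects; each is a list with
#'   \code{kind}-annotated data.frame \code{curve} (age, overall,
#'   conditional), \code{pi}, \code{mu}, \code{log_sigma}, \code{profile}.
#' @export
predict_curves <- function(fit, profiles, grid = NULL) {
  .stop_if(!inherits(fit, "mixture_fit"), "fit must be a mixture_fit")
  if (is.null(grid)) {
    grid <- seq(max(min(fit$data$age) * 0.5, 1e-3), max(fit$data$age) * 1.1,
                length.out = 200)
  }
  need <- unique(c(fit$spec$logistic, fit$spec$location, fit$spec$scale))
  miss <- setdiff(need, names(profiles))
  .stop_if(length(miss) > 0, "profiles missing covariate(s): ",
           paste(miss, collapse = ", "))
  lapply(seq_len(nrow(profiles)), function(i) {
    row <- profiles[i, , drop = FALSE]
    grab <- function(v) if (length(v) == 0) numeric(0) else
      as.numeric(row[1, v])
    pi_hat <- susceptibility(fit$coefficients$beta,
                             grab(fit$spec$logistic))
    mu <- drop(c(1, grab(fit$spec$location)) %*% fit$coefficients$gamma)
    eta <- drop(c(1, grab(fit$spec$scale)) %*% fit$coefficients$alpha)
    curve <- data.frame(
      age = grid,
      overall = 1 - mixture_survival(grid, pi_hat, mu, eta),
      conditional = 1 - conditional_survival(grid, mu, eta))
    structure(list(curve = curve, pi = pi_hat, mu = mu, log_sigma = eta,
                   profile = row,
                   label = if ("label" %in% names(row)) row$label else
                     paste0("profile_", i)),
              class = "event_curve")
  })
}

#' Export event curves as a delimited table
#' @param curves list of \code{event_curve} objects from
#'   \code{\link{predict_curves}}
#' @param path output path (tab-separated: label, age, overall, conditional)
#' @return \code{path}, invisibly
#' @export
write_curves <- function(curves, path) {
  tab <- do.call(rbind, lapply(curves, function(cv) {
    cbind(label = cv$label, cv$curve)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a mixture fit (JSON + coefficient table)
#'
#' Writes a JSON file with coefficients, standard errors, CIs, p-values,
#' log-likelihood, AIC and convergence diagnostics, plus a tab-separated
#' coefficient table laid out by regression part (logistic | location |
#' scale), the layout used for single-SNP report tables.
#'
#' @param fit a \code{mixture_fit}
#' @param path base output path; writes \code{<path>.json} and
#'   \code{<path>.tsv}
#' @param lrt_result optional result of \code{\link{lrt}} to embed
#' @return \code{path}, invisibly
#' @export
write_fit <- function(fit, path, lrt_result = NULL) {
  wt <- wald_tests(fit)
  jsonlite::write_json(
    list(coefficients = wt, loglik = fit$loglik, aic = fit$aic,
         df = fit$df, n = fit$n, converged = fit$converged,
         boundary = fit$boundary, lrt = lrt_result),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.table(wt, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
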