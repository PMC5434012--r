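#' Covariate specification for the three-part mixture regression
#'
#' Names the covariates entering each regression part of the logistic-AFT
#' location-scale mixture model.  Every part always contains an intercept;
#' the vectors name the additional columns of the model data, and the three
#' parts may share covariates.
#'
#' @param logistic covariate names for the logistic (susceptibility) part
#' @param location covariate names for the AFT location part
#' @param scale covariate names for the AFT (log-)scale part
#' @return object of class \code{mixture_spec}
#' @export
mixture_spec <- function(logistic = character(0), location = character(0),
                         scale = character(0)) {
  structure(list(logistic = as.character(logistic),
                 location = as.character(location),
                 scale = as.character(scale),
                 error_family = "log-logistic"),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  fmt <- function(v) if (length(v) == 0) "1" else paste(c("1", v), collapse = " + ")
  cat("mixture spec (log-logistic AFT):\n",
      "  logistic: ~ ", fmt(x$logistic), "\n",
      "  location: ~ ", fmt(x$location), "\n",
      "  scale:    ~ ", fmt(x$scale), "\n", sep = "")
  invisible(x)
}

# number of free parameters (three intercepts plus covariates)
.n_par <- function(spec) 3L + length(spec$logistic) + length(spec$location) +
  length(spec$scale)

# design matrices (with leading 1 column) from a model data.frame
.design <- function(data, spec) {
  need <- unique(c(spec$logistic, spec$location, spec$scale))
  miss <- setdiff(need, names(data))
  .stop_if(length(miss) > 0, "missing covariate column(s): ",
           paste(miss, collapse = ", "))
  .stop_if(any(!stats::complete.cases(data[, c("age", "event", need),
                                           drop = FALSE])),
           "model data must be complete cases for the spec's covariates")
  one <- rep(1, nrow(data))
  mk <- function(v) {
    m <- cbind(`(Intercept)` = one)
    if (length(v) > 0) m <- cbind(m, as.matrix(data[, v, drop = FALSE]))
    m
  }
  list(zb = mk(spec$logistic), zl = mk(spec$location), zs = mk(spec$scale))
}

.split_params <- function(theta, des) {
  p1 <- ncol(des$zb); p2 <- ncol(des$zl); p3 <- ncol(des$zs)
  list(beta = theta[seq_len(p1)],
       gamma = theta[p1 + seq_len(p2)],
       alpha = theta[p1 + p2 + seq_len(p3)])
}

#' Mixture-model log-likelihood
#'
#' The observed-data log-likelihood of the logistic-AFT log-logistic
#' location-scale mixture: an observed onset at age \eqn{t} contributes
#' \eqn{\ln \pi + \ln f(t)} with \eqn{f} the log-logistic density under the
#' subject's location/scale linear predictors; a censored subject at age
#' \eqn{c} contributes \eqn{\ln[\pi S(c) + 1 - \pi]}, mixing the susceptible
#' survivors with the risk-free fraction.
#'
#' @param params numeric parameter vector, concatenating the logistic,
#'   location and scale coefficients (each with its intercept first)
#' @param data data.frame with columns \code{age}, \code{event} and the
#'   spec's covariates (complete cases)
#' @param spec a \code{\link{mixture_spec}}
#' @return scalar log-likelihood
#' @export
mixture_loglik <- function(params, data, spec) {
  des <- .design(data, spec)
  .mix_ll(params, des, data$age, data$event == 1L)
}

.mix_ll <- function(theta, des, t, ev) {
  pp <- .split_params(theta, des)
  zb <- .clip_lp(drop(des$zb %*% pp$beta))
  mu <- drop(des$zl %*% pp$gamma)
  eta <- .clip_lp(drop(des$zs %*% pp$alpha), 300)
  sigma <- exp(eta)
  w <- .clip_lp((log(t) - mu) / sigma)
  ew <- exp(w)
  log1pew <- log1p(ew)
  ll <- numeric(length(t))
  # events: log pi + log f(t); log pi = zb - log(1+e^zb)
  lp1 <- -log1p(exp(-zb))            # log pi
  lp0 <- -log1p(exp(zb))             # log (1 - pi)
  ll[ev] <- lp1[ev] + w[ev] - eta[ev] - log(t[ev]) - 2 * log1pew[ev]
  # censored: log( pi * S + 1 - pi ), S = 1/(1+e^w)
  if (any(!ev)) {
    cs <- !ev
    s <- 1 / (1 + ew[cs])
    pi_c <- .expit(zb[cs])
    ll[cs] <- log(pi_c * s + (1 - pi_c))
  }
  sum(ll)
}

# analytic gradient of .mix_ll in theta
.mix_grad <- function(theta, des, t, ev) {
  pp <- .split_params(theta, des)
  zb <- .clip_lp(drop(des$zb %*% pp$beta))
  mu <- drop(des$zl %*% pp$gamma)
  eta <- .clip_lp(drop(des$zs %*% pp$alpha), 300)
  sigma <- exp(eta)
  w <- .clip_lp((log(t) - mu) / sigma)
  Fw <- .expit(w)                 # logistic cdf of w
  pi_all <- .expit(zb)

  dzb <- numeric(length(t))
  dmu <- numeric(length(t))
  deta <- numeric(length(t))

  # events
  dzb[ev] <- 1 - pi_all[ev]
  dmu[ev] <- -(1 - 2 * Fw[ev]) / sigma[ev]
  deta[ev] <- -1 - (1 - 2 * Fw[ev]) * w[ev]
  # censored
  cs <- !ev
  if (any(cs)) {
    s <- 1 - Fw[cs]
    a <- pi_all[cs] * s + (1 - pi_all[cs])
    dzb[cs] <- pi_all[cs] * (1 - pi_all[cs]) * (s - 1) / a
    common <- pi_all[cs] * Fw[cs] * s / a
    dmu[cs] <- common / sigma[cs]
    deta[cs] <- common * w[cs]
  }
  c(drop(crossprod(des$zb, dzb)),
    drop(crossprod(des$zl, dmu)),
    drop(crossprod(des$zs, deta)))
}

# starting values: logistic part from a plain logistic fit of the event
# indicator, location/scale from an AFT fit to the events only, plus fixed
# deterministic jitters (no RNG, so fitting is reproducible by itself)
.mix_starts <- function(des, t, ev, n_starts) {
  p1 <- ncol(des$zb); p2 <- ncol(des$zl); p3 <- ncol(des$zs)
  beta0 <- tryCatch(
    stats::glm.fit(des$zb, as.numeric(ev),
                   family = stats::binomial())$coefficients,
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(beta0) || any(!is.finite(beta0))) {
    beta0 <- c(stats::qlogis(max(0.05, min(0.95, mean(ev)))), rep(0, p1 - 1))
  }
  gamma0 <- rep(0, p2); alpha0 <- rep(0, p3)
  fit_aft <- tryCatch(
    suppressWarnings(survival::survreg(
      survival::Surv(t[ev], rep(1, sum(ev))) ~ des$zl[ev, -1, drop = FALSE],
      dist = "loglogistic")),
    error = function(e) NULL)
  if (!is.null(fit_aft) && all(is.finite(stats::coef(fit_aft)))) {
    gamma0 <- unname(stats::coef(fit_aft))[seq_len(p2)]
    gamma0[is.na(gamma0)] <- 0
    alpha0[1] <- log(fit_aft$scale)
  } else {
    lt <- log(t[ev])
    gamma0[1] <- mean(lt)
    alpha0[1] <- log(max(stats::sd(lt) * sqrt(3) / pi, 0.05))
  }
  base <- c(beta0, gamma0, alpha0)
  starts <- list(base)
  if (n_starts > 1) {
    # deterministic jitter directions cycling over the parameters
    k <- length(base)
    for (j in seq_len(n_starts - 1)) {
      delta <- 0.3 * ((-1)^j) * (1 + (seq_len(k) + j) %% 3) / 3
      starts[[j + 1]] <- base + delta
    }
  }
  starts
}

#' Fit the logistic-AFT location-scale mixture model
#'
#' Maximum likelihood by multi-start quasi-Newton (BFGS) optimization with
#' the analytic gradient.  The first start combines an ordinary logistic fit
#' of the event indicator with an AFT log-logistic fit to the observed
#' events; the remaining starts apply fixed deterministic jitters.  The
#' covariance estimate is the inverse of the observed information (numeric
#' Hessian of the negative log-likelihood via central differences of the
#' analytic gradient).
#'
#' @param data data.frame with columns \code{age}, \code{event} and all
#'   covariates named in \code{spec}; must be complete cases.
#' @param spec a \code{\link{mixture_spec}}
#' @param n_starts number of optimizer starts (default 5)
#' @param grad_tol gradient-infinity-norm convergence criterion
#'   (default 1e-6)
#' @param max_iter BFGS iteration cap per start
#' @param fixed optional named numeric vector pinning parameters at fixed
#'   values instead of estimating them; names use the
#'   \code{part:term} convention, e.g.
#'   \code{c("logistic:(Intercept)" = 700)} forces \eqn{\pi \equiv 1}
#'   (no risk-free fraction).  Pinned parameters carry no standard error
#'   and do not count as free parameters in the AIC.
#' @return object of class \code{mixture_fit}: list with \code{coefficients}
#'   (named list \code{beta}, \code{gamma}, \code{alpha}), \code{vcov},
#'   \code{loglik}, \code{n}, \code{aic}, \code{df} (free parameters),
#'   \code{converged}, \code{boundary}, \code{spec}, \code{data},
#'   \code{starts} (per-start log-likelihoods).
#' @export
fit_mixture <- function(data, spec, n_starts = 5, grad_tol = 1e-6,
                        max_iter = 500, fixed = NULL) {
  .stop_if(!inherits(spec, "mixture_spec"), "spec must be a mixture_spec")
  .stop_if(sum(data$event) < 1, "need at least one observed event")
  des <- .design(data, spec)
  # identifiability: full column rank of each part's design
  for (nm in names(des)) {
    .stop_if(qr(des[[nm]])$rank < ncol(des[[nm]]),
             "rank error: non-identifiable design in the ",
             c(zb = "logistic", zl = "location", zs = "scale")[nm], " part")
  }
  t <- data$age; ev <- data$event == 1L

  pn <- c(paste0("logistic:", colnames(des$zb)),
          paste0("location:", colnames(des$zl)),
          paste0("scale:", colnames(des$zs)))
  fixed_idx <- integer(0)
  fixed_val <- numeric(0)
  if (!is.null(fixed)) {
    .stop_if(!all(names(fixed) %in% pn),
             "unknown fixed parameter(s): ",
             paste(setdiff(names(fixed), pn), collapse = ", "))
    fixed_idx <- match(names(fixed), pn)
    fixed_val <- unname(fixed)
  }
  free_idx <- setdiff(seq_along(pn), fixed_idx)
  embed <- function(th_free) {
    th <- numeric(length(pn))
    th[fixed_idx] <- fixed_val
    th[free_idx] <- th_free
    th
  }
  negll <- function(th) -.mix_ll(embed(th), des, t, ev)
  neggr <- function(th) -.mix_grad(embed(th), des, t, ev)[free_idx]

  starts <- lapply(.mix_starts(des, t, ev, n_starts), `[`, free_idx)
  best <- NULL
  start_lls <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    opt <- tryCatch(
      stats::optim(starts[[i]], negll, neggr, method = "BFGS",
                   control = list(maxit = max_iter, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    start_lls[i] <- -opt$value
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  .stop_if(is.null(best), "all optimizer starts failed")
  theta <- best$par
  value <- best$value
  # Newton polishing with step halving until the gradient criterion is met
  for (r in 1:25) {
    g <- neggr(theta)
    if (max(abs(g)) < grad_tol) break
    h <- .num_hessian(neggr, theta)
    step <- tryCatch(solve(h, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    improved <- FALSE
    lambda <- 1
    for (s in 1:20) {
      cand <- theta - lambda * step
      v <- negll(cand)
      if (is.finite(v) && v <= value + 1e-12) {
        # accept if not worse (near the optimum the value barely moves
        # while the gradient keeps shrinking)
        theta <- cand; value <- v; improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  converged <- max(abs(neggr(theta))) < grad_tol
  loglik <- -value

  theta_full <- embed(theta)
  pp <- .split_params(theta_full, des)
  names(pp$beta) <- colnames(des$zb)
  names(pp$gamma) <- colnames(des$zl)
  names(pp$alpha) <- colnames(des$zs)

  # boundary susceptibility: the whole cohort's fitted logit pushed past 10
  zb_hat <- drop(des$zb %*% pp$beta)
  boundary <- length(fixed_idx) == 0 &&
    (all(zb_hat > 10) || all(zb_hat < -10))

  hess <- .num_hessian(neggr, theta)
  vcov_free <- tryCatch(solve(hess), error = function(e) NULL)
  psd <- !is.null(vcov_free) && all(eigen(hess, symmetric = TRUE,
                                          only.values = TRUE)$values > 0)
  vcov <- NULL
  if (!is.null(vcov_free)) {
    vcov <- matrix(NA_real_, length(pn), length(pn), dimnames = list(pn, pn))
    vcov[free_idx, free_idx] <- vcov_free
  }
  k <- length(free_idx)
  structure(list(coefficients = pp, vcov = vcov, vcov_psd = psd,
                 loglik = loglik, n = nrow(data),
                 aic = -2 * loglik + 2 * k, df = k,
                 converged = converged, boundary = boundary,
                 fixed = fixed, spec = spec, data = data,
                 starts = start_lls),
            class = "mixture_fit")
}

# central-difference Hessian from an analytic gradient
.num_hessian <- function(gr, theta, eps = 1e-5) {
  k <- length(theta)
  h <- matrix(0, k, k)
  for (j in seq_len(k)) {
    step <- eps * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + step
    tm <- theta; tm[j] <- tm[j] - step
    h[, j] <- (gr(tp) - gr(tm)) / (2 * step)
  }
  (h + t(h)) / 2
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "logistic-AFT log-logistic mixture fit: n = %d, loglik = %.4f, AIC = %.4f%s%s\n",
    x$n, x$loglik, x$aic,
    if (!x$converged) " [not converged]" else "",
    if (x$boundary) " [boundary susceptibility]" else ""))
  for (part in c("beta", "gamma", "alpha")) {
    lab <- c(beta = "logistic", gamma = "location", alpha = "scale")[part]
    co <- x$coefficients[[part]]
    cat(sprintf("  %-8s %s\n", lab,
                paste(sprintf("%s = %.4f", names(co), co), collapse = ", ")))
  }
  invisible(x)
}

#' @export
logLik.mixture_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, class = "logLik")
}

#' @export
coef.mixture_fit <- function(object, ...) {
  unlist(object$coefficients)
}

#' @export
vcov.mixture_fit <- function(object, ...) object$vcov
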