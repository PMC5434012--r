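#' Nonparametric bootstrap validation of a mixture fit
#'
#' Subjects are resampled with replacement (unstratified by case status)
#' and the fixed, already-chosen model specification is refit on every
#' resample; model selection is not re-run unless \code{reselect} is set.
#' Percentile confidence intervals come from the empirical quantiles of the
#' resample estimates (type-7 linear interpolation, fixed because the tail
#' definition is visible at a few hundred resamples).  Fully reproducible
#' from the seed.
#'
#' @param fit a \code{mixture_fit} (the original fit; its data and spec are
#'   reused, and its estimates seed the per-resample optimizer)
#' @param n_resamples number of bootstrap resamples (default 400)
#' @param seed integer RNG seed (required)
#' @param resample_size subjects per resample (default the original n)
#' @param level confidence level (default 0.95)
#' @param reselect optional function(data) -> mixture_fit re-running a full
#'   selection inside each resample (methods-research mode)
#' @param n_starts optimizer starts per resample (default 2: the original
#'   estimate plus the standard data-driven start)
#' @return object of class \code{bootstrap_result}: list with
#'   \code{estimates} (resamples x parameters matrix), \code{percentile_ci},
#'   \code{boot_median}, \code{boot_mean}, \code{n_resamples},
#'   \code{resample_size}, \code{n_failed}, \code{seed}.  Errors if more
#'   than half the resamples fail to converge.
#' @export
bootstrap_mixture <- function(fit, n_resamples = 400, seed,
                              resample_size = NULL, level = 0.95,
                              reselect = NULL, n_starts = 2) {
  .stop_if(missing(seed), "a seed is required for reproducibility")
  .stop_if(!inherits(fit, "mixture_fit"), "fit must be a mixture_fit")
  data <- fit$data
  n <- nrow(data)
  resample_size <- resample_size %||% n
  set.seed(seed)
  idx <- matrix(sample.int(n, n_resamples * resample_size, replace = TRUE),
                nrow = n_resamples)

  theta_hat <- .flat_names(fit)
  est <- matrix(NA_real_, n_resamples, length(theta_hat),
                dimnames = list(NULL, names(theta_hat)))
  failed <- logical(n_resamples)
  for (b in seq_len(n_resamples)) {
    db <- data[idx[b, ], , drop = FALSE]
    fb <- tryCatch({
      if (is.null(reselect)) {
        .refit_from(db, fit$spec, theta_hat, n_starts = n_starts)
      } else {
        reselect(db)
      }
    }, error = function(e) NULL)
    if (is.null(fb) || !fb$converged) {
      failed[b] <- TRUE
    } else {
      est[b, ] <- coef(fb)
    }
  }
  n_failed <- sum(failed)
  .stop_if(n_failed > n_resamples / 2,
           "validation failed: ", n_failed, " of ", n_resamples,
           " resamples did not converge")
  ok <- est[!failed, , drop = FALSE]
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- t(apply(ok, 2, stats::quantile, probs = probs, type = 7))
  colnames(ci) <- c("lower", "upper")
  structure(list(estimates = est, percentile_ci = ci,
                 boot_median = apply(ok, 2, stats::median),
                 boot_mean = colMeans(ok),
                 original = theta_hat,
                 n_resamples = n_resamples, resample_size = resample_size,
                 n_failed = n_failed, seed = seed, level = level),
            class = "bootstrap_result")
}

#' Percentile bootstrap of an arbitrary subject-level statistic
#'
#' The same resampling engine as \code{\link{bootstrap_mixture}} for any
#' statistic of the subject rows: subjects are resampled with replacement
#' and the statistic recomputed on every resample.
#'
#' @param data data.frame of subject rows
#' @param statistic function(data) -> named (or unnamed) numeric vector
#' @param n_resamples number of resamples
#' @param seed integer RNG seed (required)
#' @param level confidence level
#' @return a \code{bootstrap_result} (with \code{n_failed} counting
#'   resamples where the statistic errored)
#' @export
bootstrap_statistic <- function(data, statistic, n_resamples = 400, seed,
                                level = 0.95) {
  .stop_if(missing(seed), "a seed is required for reproducibility")
  n <- nrow(data)
  set.seed(seed)
  idx <- matrix(sample.int(n, n_resamples * n, replace = TRUE),
                nrow = n_resamples)
  s0 <- statistic(data)
  est <- matrix(NA_real_, n_resamples, length(s0),
                dimnames = list(NULL, names(s0)))
  failed <- logical(n_resamples)
  for (b in seq_len(n_resamples)) {
    sb <- tryCatch(statistic(data[idx[b, ], , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(sb)) failed[b] <- TRUE else est[b, ] <- sb
  }
  n_failed <- sum(failed)
  .stop_if(n_failed > n_resamples / 2, "validation failed: ", n_failed,
           " of ", n_resamples, " resamples errored")
  ok <- est[!failed, , drop = FALSE]
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- t(apply(ok, 2, stats::quantile, probs = probs, type = 7))
  colnames(ci) <- c("lower", "upper")
  structure(list(estimates = est, percentile_ci = ci,
                 boot_median = apply(ok, 2, stats::median),
                 boot_mean = colMeans(ok), original = s0,
                 n_resamples = n_resamples, resample_size = n,
                 n_failed = n_failed, seed = seed, level = level),
            class = "bootstrap_result")
}

.flat_names <- function(fit) {
  stats::setNames(coef(fit),
                  unlist(lapply(names(fit$coefficients), function(p)
                    paste0(c(beta = "logistic", gamma = "location",
                             scale = "scale", alpha = "scale")[p], ":",
                           names(fit$coefficients[[p]])))))
}

# refit a fixed spec starting from the original estimates (fast path used
# inside the bootstrap loop)
.refit_from <- function(data, spec, theta_start, n_starts = 2) {
  .stop_if(sum(data$event) < 1, "no events in resample")
  des <- .design(data, spec)
  t <- data$age; ev <- data$event == 1L
  negll <- function(th) -.mix_ll(th, des, t, ev)
  neggr <- function(th) -.mix_grad(th, des, t, ev)
  starts <- c(list(unname(theta_start)),
              if (n_starts > 1) .mix_starts(des, t, ev, n_starts - 1))
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, negll, neggr, method = "BFGS",
                   control = list(maxit = 300, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("refit failed")
  theta <- best$par
  value <- best$value
  # a few Newton steps so single-start refits reach the gradient criterion
  for (r in 1:10) {
    g <- neggr(theta)
    if (max(abs(g)) < 1e-6) break
    h <- .num_hessian(neggr, theta)
    step <- tryCatch(solve(h, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lambda <- 1
    ok <- FALSE
    for (s in 1:15) {
      cand <- theta - lambda * step
      v <- negll(cand)
      if (is.finite(v) && v <= value + 1e-12) {
        theta <- cand; value <- v; ok <- TRUE; break
      }
      lambda <- lambda / 2
    }
    if (!ok) break
  }
  best$value <- value
  pp <- .split_params(theta, des)
  names(pp$beta) <- colnames(des$zb)
  names(pp$gamma) <- colnames(des$zl)
  names(pp$alpha) <- colnames(des$zs)
  structure(list(coefficients = pp, vcov = NULL, vcov_psd = FALSE,
                 loglik = -best$value, n = nrow(data),
                 aic = 2 * best$value + 2 * .n_par(spec), df = .n_par(spec),
                 converged = max(abs(neggr(theta))) < 1e-4,
                 boundary = FALSE, spec = spec, data = data),
            class = "mixture_fit")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "bootstrap validation: %d resamples of size %d (%d failed), seed %d\n",
    x$n_resamples, x$resample_size, x$n_failed, x$seed))
  tab <- bootstrap_table(x)
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Bootstrap report table
#'
#' Parameter, bootstrap estimate (median of resample estimates, with the
#' mean alongside) and percentile confidence interval — the layout of a
#' bootstrap-validation table accompanying an original fit.
#'
#' @param x a \code{bootstrap_result}
#' @return data.frame
#' @export
bootstrap_table <- function(x) {
  data.frame(parameter = colnames(x$estimates),
             original = unname(x$original),
             boot_median = unname(x$boot_median),
             boot_mean = unname(x$boot_mean),
             ci_lower = unname(x$percentile_ci[, "lower"]),
             ci_upper = unname(x$percentile_ci[, "upper"]),
             stringsAsFactors = FALSE)
}

#' Write a bootstrap report (delimited + JSON)
#' @param x a \code{bootstrap_result}
#' @param path output path; JSON goes to \code{<path>.json}
#' @return \code{path}, invisibly
#' @export
write_bootstrap_report <- function(x, path) {
  tab <- bootstrap_table(x)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(table = tab, n_resamples = x$n_resamples,
         resample_size = x$resample_size, n_failed = x$n_failed,
         seed = x$seed, level = x$level),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
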