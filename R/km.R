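#' Kaplan-Meier event curve
#'
#' Product-limit estimate of the cumulative event probability
#' \eqn{1 - \hat S(t)} under right censoring, computed via
#' \code{survival::survfit}.  Events precede censorings at tied ages (the
#' standard product-limit convention).  The terminal plateau estimates the
#' susceptible fraction when follow-up extends past the onset-age support.
#'
#' @param ages positive ages (onset age if the event was observed, censoring
#'   age otherwise)
#' @param events binary event indicators
#' @return object of class \code{km_curve}: list with \code{times} (distinct
#'   event ages), \code{event_prob}, \code{at_risk}, \code{n_events},
#'   \code{plateau}, \code{n}
#' @export
km_curve <- function(ages, events) {
  .stop_if(length(ages) == 0, "empty input")
  .stop_if(any(ages <= 0), "ages must be positive")
  events <- as.integer(events)
  .stop_if(!.is_binary01(events), "events must be 0/1")
  sf <- survival::survfit(survival::Surv(ages, events) ~ 1)
  keep <- sf$n.event > 0
  times <- sf$time[keep]
  surv <- sf$surv[keep]
  structure(list(times = times, event_prob = 1 - surv,
                 at_risk = sf$n.risk[keep], n_events = sf$n.event[keep],
                 plateau = if (length(times) > 0) max(1 - surv) else 0,
                 n = length(ages)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier event curve: n = %d, %d event times, plateau %.4f\n",
              x$n, length(x$times), x$plateau))
  invisible(x)
}

#' Evaluate a KM event curve at given ages
#'
#' The cumulative event probability is a right-continuous step function:
#' the value at an event age includes the jump at that age.
#'
#' @param curve a \code{km_curve}
#' @param ages ages at which to evaluate
#' @return event probabilities
#' @export
eval_km <- function(curve, ages) {
  if (length(curve$times) == 0) return(rep(0, length(ages)))
  f <- stats::stepfun(curve$times, c(0, curve$event_prob), right = FALSE)
  f(ages)
}

#' Stratified Kaplan-Meier curves
#'
#' One independent product-limit curve per stratum.  Strata can be given as
#' a factor/vector over subjects, a SNP id (stratifying by its genotype,
#' optionally merged through a \code{\link{genotype_coding}}), or
#' \code{"smoking"}.  Empty strata are omitted with a warning, and strata
#' with at most one event are flagged as sparse.
#'
#' @param x a \code{\link{cohort}}
#' @param strata stratum labels (length = subjects), a SNP id, or
#'   \code{"smoking"}
#' @param coding optional \code{genotype_coding} used to merge genotype
#'   strata (e.g. dominant: \code{AA} vs \code{Aa+aa})
#' @return named list of \code{km_curve}s; sparse strata carry attribute
#'   \code{sparse = TRUE}
#' @export
stratified_km <- function(x, strata, coding = NULL) {
  if (length(strata) == 1 && is.character(strata)) {
    if (strata %in% x$snp_ids) {
      g <- x$genotypes[, strata]
      if (!is.null(coding)) {
        # merge genotypes mapping to the same covariate code
        codes <- vapply(c("AA", "Aa", "aa"), function(gg)
          paste(encode_genotype(gg, coding), collapse = ","), "")
        merged <- vapply(c("AA", "Aa", "aa"), function(gg) {
          paste(c("AA", "Aa", "aa")[codes == codes[gg]], collapse = "+")
        }, "")
        names(merged) <- c("AA", "Aa", "aa")
        g <- unname(merged[g])
      }
      strata <- g
    } else if (strata == "smoking") {
      strata <- c("nonsmoker", "smoker")[x$subjects$smoking + 1L]
    } else {
      stop("unknown stratifier: ", strata, call. = FALSE)
    }
  }
  .stop_if(length(strata) != n_subjects(x),
           "strata must label every subject")
  out <- list()
  for (lv in sort(unique(strata[!is.na(strata)]))) {
    idx <- which(!is.na(strata) & strata == lv)
    if (length(idx) == 0) next
    cv <- km_curve(x$subjects$age[idx], x$subjects$event[idx])
    if (sum(x$subjects$event[idx]) <= 1) attr(cv, "sparse") <- TRUE
    out[[lv]] <- cv
  }
  dropped <- setdiff(unique(strata), c(names(out), NA))
  if (length(dropped) > 0) {
    warning("empty stratum(s) omitted: ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Model-adequacy comparison of a KM curve against a fitted overall curve
#'
#' Sup-distance over the observed event times between the nonparametric and
#' model-based overall cumulative event curves, plus the gap between the KM
#' plateau and the fitted susceptibility.
#'
#' @param km a \code{km_curve}
#' @param curve an \code{event_curve} from \code{\link{predict_curves}}, or
#'   a function age -> overall event probability
#' @return list with \code{sup_distance} and \code{plateau_gap}
#'   (\code{plateau_gap} is \code{NA} when \code{curve} is a bare function)
#' @export
km_adequacy <- function(km, curve) {
  if (inherits(curve, "event_curve")) {
    pi_hat <- curve$pi
    f <- function(a) 1 - mixture_survival(a, curve$pi, curve$mu,
                                          curve$log_sigma)
  } else {
    .stop_if(!is.function(curve), "curve must be an event_curve or function")
    pi_hat <- NA_real_
    f <- curve
  }
  sup <- if (length(km$times) == 0) NA_real_ else
    max(abs(eval_km(km, km$times) - f(km$times)))
  list(sup_distance = sup,
       plateau_gap = if (is.na(pi_hat)) NA_real_ else abs(km$plateau - pi_hat))
}

#' Export KM curves as delimited text
#' @param curves named list of \code{km_curve}s (as from
#'   \code{\link{stratified_km}}) or a single curve
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_km <- function(curves, path) {
  if (inherits(curves, "km_curve")) curves <- list(all = curves)
  tab <- do.call(rbind, lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    if (length(cv$times) == 0) return(NULL)
    data.frame(stratum = nm, time = cv$times, at_risk = cv$at_risk,
               events = cv$n_events, event_prob = cv$event_prob)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
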