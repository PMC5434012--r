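#' Build a model data.frame from a cohort
#'
#' Encodes the listed SNPs under their coding schemes, attaches phenotype
#' covariates, and restricts to complete cases — the per-model analysis set
#' of a single- or multi-SNP fit.
#'
#' @param x a \code{\link{cohort}}
#' @param codings named list: SNP id -> \code{\link{genotype_coding}}
#' @param covariates phenotype covariates to carry (e.g. \code{"smoking"})
#' @return data.frame with columns \code{id}, \code{age}, \code{event},
#'   encoded genotype columns named \code{<snp>_<label>}, and the phenotype
#'   covariates; complete cases only
#' @export
model_frame <- function(x, codings = list(), covariates = character(0)) {
  cc <- complete_cases(x, names(codings), covariates)
  out <- cc$subjects[, c("id", "age", "event")]
  for (s in names(codings)) {
    enc <- encode_genotype(cc$genotypes[, s], codings[[s]])
    if (is.null(dim(enc))) enc <- matrix(enc, ncol = 1)
    colnames(enc) <- paste0(s, "_", codings[[s]]$labels)
    out <- cbind(out, enc)
  }
  for (cv in covariates) out[[cv]] <- cc$subjects[[cv]]
  rownames(out) <- NULL
  out
}

# covariate column names a coding contributes for a SNP
.snp_terms <- function(snp_id, coding) paste0(snp_id, "_", coding$labels)

#' Sparse-event coding constraint for a SNP
#'
#' If any genotype class carries at most one observed event, the candidate
#' codings are restricted to two-group merged schemes (sparse classes cannot
#' support their own parameters); otherwise the full candidate set
#' (general, additive, dominant, recessive) is allowed.
#'
#' @param x a \code{\link{cohort}}
#' @param snp_id SNP id
#' @return list with \code{merged_only} (logical), \code{event_table}
#'   (events by genotype among called subjects), \code{n_genotypes}
#' @export
sparse_event_rule <- function(x, snp_id) {
  g <- x$genotypes[, snp_id]
  ok <- !is.na(g)
  genos <- c("AA", "Aa", "aa")
  present <- genos[genos %in% g[ok]]
  ev <- vapply(present, function(gg)
    sum(x$subjects$event[ok & g == gg]), 0L)
  list(merged_only = any(ev <= 1L) || length(present) < 3,
       event_table = ev, n_genotypes = length(present))
}

# choose the merged two-group scheme by merging the genotype pair whose
# KM event curves are closest in sup-distance (operationalizing the visual
# "merge the two genotypes whose event curves were closer")
.merged_scheme <- function(x, snp_id) {
  g <- x$genotypes[, snp_id]
  present <- c("AA", "Aa", "aa")[c("AA", "Aa", "aa") %in% g[!is.na(g)]]
  if (length(present) < 3) return("merged-dominant")
  km <- lapply(present, function(gg) {
    idx <- !is.na(g) & g == gg
    km_curve(x$subjects$age[idx], x$subjects$event[idx])
  })
  names(km) <- present
  supd <- function(a, b) {
    ts <- sort(unique(c(a$times, b$times)))
    if (length(ts) == 0) return(0)
    max(abs(eval_km(a, ts) - eval_km(b, ts)))
  }
  d_AaAa <- supd(km[["Aa"]], km[["aa"]])   # candidates for dominant merge
  d_AAAa <- supd(km[["AA"]], km[["Aa"]])   # candidates for recessive merge
  d_AAaa <- supd(km[["AA"]], km[["aa"]])
  dists <- c(`merged-dominant` = d_AaAa, `merged-recessive` = d_AAAa,
             `merged-dominant2` = d_AAaa)
  pick <- names(dists)[which.min(dists)]
  # a non-contiguous AA+aa merge has no standard coding; fall back to the
  # dominant merge (documented in the methods vignette)
  if (pick == "merged-dominant2") pick <- "merged-dominant"
  pick
}

#' Candidate model specifications for a single SNP
#'
#' Enumerates the cross of allowed coding schemes with placements of the
#' SNP covariate into the regression parts: none (the intercept-only null,
#' present exactly once), logistic only, location only, scale only, and all
#' two- and three-part combinations.  Extra covariates (e.g. smoking) can
#' be pinned into fixed parts via \code{extra}.
#'
#' @param snp_id SNP id
#' @param schemes character vector of allowed coding schemes
#' @param extra optional named list of extra covariates:
#'   name -> character vector of parts
#' @return list of candidates; each is a list with \code{coding} (a
#'   \code{genotype_coding} or NULL for the null model), \code{spec}
#'   (a \code{\link{mixture_spec}}), \code{placement}
#' @export
candidate_specs <- function(snp_id, schemes = c("general", "additive",
                                                "dominant", "recessive"),
                            extra = list()) {
  placements <- list(
    none = character(0), logistic = "logistic", location = "location",
    scale = "scale", `location+scale` = c("location", "scale"),
    `logistic+location` = c("logistic", "location"),
    `logistic+scale` = c("logistic", "scale"),
    `logistic+location+scale` = c("logistic", "location", "scale"))
  base <- list(logistic = character(0), location = character(0),
               scale = character(0))
  for (nm in names(extra)) {
    for (pt in extra[[nm]]) base[[pt]] <- c(base[[pt]], nm)
  }
  out <- list()
  seen_null <- FALSE
  for (sc in schemes) {
    coding <- genotype_coding(sc)
    terms <- .snp_terms(snp_id, coding)
    for (pl in names(placements)) {
      if (pl == "none") {
        if (seen_null) next
        seen_null <- TRUE
        out[[length(out) + 1]] <- list(
          coding = NULL, placement = "none",
          spec = mixture_spec(base$logistic, base$location, base$scale))
        next
      }
      parts <- base
      for (pt in placements[[pl]]) parts[[pt]] <- c(parts[[pt]], terms)
      out[[length(out) + 1]] <- list(
        coding = coding, placement = pl, scheme = sc,
        spec = mixture_spec(parts$logistic, parts$location, parts$scale))
    }
  }
  out
}

#' Classify a fitted model into the four association categories
#'
#' The four exhaustive, mutually exclusive categories of a SNP's effect
#' pattern: \describe{
#'   \item{a}{equal susceptibility, different conditional onset-age
#'     distribution (AFT part significant only);}
#'   \item{b}{unequal susceptibility, same conditional distribution
#'     (logistic part significant only);}
#'   \item{c}{both;}
#'   \item{d}{neither.}
#' }
#' A part is "significant" when any of its non-intercept Wald p-values for
#' the covariate of interest falls below \code{alpha}; a part that does not
#' carry the covariate is non-significant by construction.
#'
#' @param fit a \code{mixture_fit}
#' @param alpha significance threshold (default 0.05; the relaxed 0.10 mode
#'   reflects sparse-sample attenuation of mixture-model effects)
#' @param terms optional character vector restricting which covariate terms
#'   count (default: all non-intercept terms)
#' @return list with \code{category} (one of "a", "b", "c", "d"),
#'   \code{logistic_sig}, \code{aft_sig}, \code{alpha}
#' @export
classify_fit <- function(fit, alpha = 0.05, terms = NULL) {
  wt <- wald_tests(fit)
  wt <- wt[wt$term != "(Intercept)", , drop = FALSE]
  if (!is.null(terms)) wt <- wt[wt$term %in% terms, , drop = FALSE]
  sig <- function(part) {
    p <- wt$p[wt$part %in% part]
    any(!is.na(p) & p < alpha)
  }
  logistic_sig <- sig("logistic")
  aft_sig <- sig(c("location", "scale"))
  category <- if (logistic_sig && aft_sig) "c"
    else if (logistic_sig) "b"
    else if (aft_sig) "a"
    else "d"
  list(category = category, logistic_sig = logistic_sig,
       aft_sig = aft_sig, alpha = alpha)
}

#' Single-SNP model selection
#'
#' Fits every candidate coding/placement for a SNP on its complete cases,
#' selects the minimum-AIC model (ties broken toward fewer parameters, then
#' listing order), attaches the likelihood ratio test versus the
#' intercept-only null, and classifies the chosen model.
#'
#' @param x a \code{\link{cohort}}
#' @param snp_id SNP id (should have passed QC)
#' @param alpha significance threshold for classification
#' @param extra optional named list of extra covariates pinned into fixed
#'   parts (passed to \code{\link{candidate_specs}})
#' @param n_starts optimizer starts per candidate fit
#' @return object of class \code{selection_result}: list with
#'   \code{snp_id}, \code{chosen} (coding/placement/spec), \code{fit},
#'   \code{lrt}, \code{category}, \code{evidence}, \code{aic_table},
#'   \code{merged_forced}
#' @export
select_model <- function(x, snp_id, alpha = 0.05, extra = list(),
                         n_starts = 5) {
  rule <- sparse_event_rule(x, snp_id)
  schemes <- if (rule$merged_only) .merged_scheme(x, snp_id)
             else c("general", "additive", "dominant", "recessive")
  cands <- candidate_specs(snp_id, schemes, extra = extra)
  data <- model_frame(x, stats::setNames(list(genotype_coding("general")),
                                         snp_id),
                      covariates = names(extra))
  # encode under every needed coding once
  g <- complete_cases(x, snp_id, names(extra))$genotypes[, snp_id]
  for (sc in unique(schemes)) {
    coding <- genotype_coding(sc)
    enc <- encode_genotype(g, coding)
    if (is.null(dim(enc))) enc <- matrix(enc, ncol = 1)
    colnames(enc) <- .snp_terms(snp_id, coding)
    for (cn in colnames(enc)) data[[cn]] <- enc[, cn]
  }

  fits <- vector("list", length(cands))
  rows <- list()
  for (i in seq_along(cands)) {
    ft <- tryCatch(
      fit_mixture(data, cands[[i]]$spec, n_starts = n_starts),
      error = function(e) NULL)
    fits[[i]] <- ft
    rows[[i]] <- data.frame(
      scheme = cands[[i]]$scheme %||% "none",
      placement = cands[[i]]$placement,
      k = .n_par(cands[[i]]$spec),
      loglik = if (is.null(ft)) NA_real_ else ft$loglik,
      aic = if (is.null(ft)) NA_real_ else ft$aic,
      converged = !is.null(ft) && ft$converged,
      stringsAsFactors = FALSE)
  }
  aic_table <- do.call(rbind, rows)
  usable <- which(!is.na(aic_table$aic) & aic_table$converged)
  if (length(usable) == 0) {
    return(structure(list(snp_id = snp_id, chosen = NULL, fit = NULL,
                          failed = TRUE, aic_table = aic_table),
                     class = "selection_result"))
  }
  # minimum AIC; ties (< 1e-6) toward fewer parameters, then listing order
  best_aic <- min(aic_table$aic[usable])
  tied <- usable[aic_table$aic[usable] < best_aic + 1e-6]
  chosen_i <- tied[order(aic_table$k[tied])][1]

  null_i <- which(aic_table$placement == "none")
  chosen_fit <- fits[[chosen_i]]
  lrt_res <- if (chosen_i == null_i || is.null(fits[[null_i]])) {
    list(chi2 = 0, df = 0L, p = 1)
  } else lrt(chosen_fit, fits[[null_i]])

  snp_terms <- if (is.null(cands[[chosen_i]]$coding)) character(0) else
    .snp_terms(snp_id, cands[[chosen_i]]$coding)
  evidence <- classify_fit(chosen_fit, alpha = alpha, terms = snp_terms)

  structure(list(snp_id = snp_id, failed = FALSE,
                 chosen = cands[[chosen_i]], fit = chosen_fit,
                 lrt = lrt_res, category = evidence$category,
                 evidence = evidence, aic_table = aic_table,
                 merged_forced = rule$merged_only, n = chosen_fit$n),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  if (isTRUE(x$failed)) {
    cat(sprintf("%s: selection failed (no candidate converged)\n", x$snp_id))
    return(invisible(x))
  }
  cat(sprintf(
    "%s (n = %d): %s coding, SNP in %s part(s); category (%s); AIC %.2f; LRT chi2 %.2f (df %d, p %.4g)\n",
    x$snp_id, x$n, x$chosen$scheme %||% "none", x$chosen$placement,
    x$category, x$fit$aic, x$lrt$chi2, x$lrt$df, x$lrt$p))
  invisible(x)
}

#' Multi-covariate subset-model search
#'
#' Joint mixture model over several SNPs (each with its single-SNP chosen
#' coding and suggested part placement) and optional extra covariates.  For
#' every covariate the search considers keeping it in its suggested part(s)
#' or dropping it, fits all subset combinations on the common complete
#' cases, and selects the minimum-AIC model.
#'
#' @param x a \code{\link{cohort}}
#' @param snps named list: SNP id -> list(coding = genotype_coding,
#'   parts = character vector of parts), typically harvested from
#'   \code{\link{select_model}} results
#' @param extra named list: covariate -> suggested parts (e.g.
#'   \code{list(smoking = "location")})
#' @param alpha significance threshold for the per-part evidence flags
#' @param n_starts optimizer starts per fit
#' @return a \code{selection_result}-like object with the joint fit, its
#'   AIC table over subsets, and the LRT versus the intercept-only model
#' @export
multi_covariate_search <- function(x, snps = list(), extra = list(),
                                   alpha = 0.05, n_starts = 5) {
  codings <- lapply(snps, `[[`, "coding")
  data <- model_frame(x, codings, covariates = names(extra))
  k_max <- 3 + sum(vapply(snps, function(s)
    length(s$coding$labels) * length(s$parts), 0)) +
    sum(lengths(extra))
  .stop_if(nrow(data) < k_max + 5,
           "sample-size error: ", nrow(data), " complete cases for up to ",
           k_max, " parameters")

  effects <- c(
    lapply(stats::setNames(names(snps), names(snps)), function(s)
      list(terms = .snp_terms(s, snps[[s]]$coding), parts = snps[[s]]$parts)),
    lapply(stats::setNames(names(extra), names(extra)), function(nm)
      list(terms = nm, parts = extra[[nm]])))

  combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(effects)))
  names(combos) <- names(effects)
  fits <- vector("list", nrow(combos))
  rows <- list()
  specs <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    parts <- list(logistic = character(0), location = character(0),
                  scale = character(0))
    for (nm in names(effects)) {
      if (!combos[i, nm]) next
      for (pt in effects[[nm]]$parts) {
        parts[[pt]] <- c(parts[[pt]], effects[[nm]]$terms)
      }
    }
    specs[[i]] <- mixture_spec(parts$logistic, parts$location, parts$scale)
    ft <- tryCatch(fit_mixture(data, specs[[i]], n_starts = n_starts),
                   error = function(e) NULL)
    fits[[i]] <- ft
    rows[[i]] <- data.frame(
      included = paste(names(effects)[unlist(combos[i, ])], collapse = "+"),
      k = .n_par(specs[[i]]),
      loglik = if (is.null(ft)) NA_real_ else ft$loglik,
      aic = if (is.null(ft)) NA_real_ else ft$aic,
      converged = !is.null(ft) && ft$converged,
      stringsAsFactors = FALSE)
  }
  aic_table <- do.call(rbind, rows)
  usable <- which(!is.na(aic_table$aic) & aic_table$converged)
  .stop_if(length(usable) == 0, "no subset model converged")
  best_aic <- min(aic_table$aic[usable])
  tied <- usable[aic_table$aic[usable] < best_aic + 1e-6]
  chosen_i <- tied[order(aic_table$k[tied])][1]
  null_i <- which(!apply(combos, 1, any))
  chosen_fit <- fits[[chosen_i]]
  lrt_res <- if (chosen_i == null_i) list(chi2 = 0, df = 0L, p = 1) else
    lrt(chosen_fit, fits[[null_i]])
  evidence <- classify_fit(chosen_fit, alpha = alpha)
  structure(list(snp_id = paste(names(snps), collapse = "+"), failed = FALSE,
                 chosen = list(placement = aic_table$included[chosen_i],
                               spec = specs[[chosen_i]],
                               included = unlist(combos[chosen_i, ])),
                 fit = chosen_fit, lrt = lrt_res,
                 category = evidence$category, evidence = evidence,
                 aic_table = aic_table, n = chosen_fit$n),
            class = "selection_result")
}

#' Write a selection report (delimited + JSON)
#'
#' One row per SNP with the chosen coding, placement, category, sample
#' size, AIC and LRT; the JSON variant embeds the full per-candidate AIC
#' tables plus a supplementary Bonferroni-adjusted LRT p-value column
#' (no multiplicity adjustment is applied to the primary results).
#'
#' @param results list of \code{selection_result}s
#' @param path output path for the table; JSON goes to \code{<path>.json}
#' @return \code{path}, invisibly
#' @export
write_selection_report <- function(results, path) {
  rows <- lapply(results, function(r) {
    if (isTRUE(r$failed)) {
      return(data.frame(snp_id = r$snp_id, scheme = NA, placement = NA,
                        category = NA, n = NA, aic = NA, lrt_chi2 = NA,
                        lrt_df = NA, lrt_p = NA, stringsAsFactors = FALSE))
    }
    data.frame(snp_id = r$snp_id, scheme = r$chosen$scheme %||% "none",
               placement = r$chosen$placement, category = r$category,
               n = r$n, aic = r$fit$aic, lrt_chi2 = r$lrt$chi2,
               lrt_df = r$lrt$df, lrt_p = r$lrt$p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  m <- sum(!is.na(tab$lrt_p))
  tab$lrt_p_bonferroni <- pmin(1, tab$lrt_p * m)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(summary = tab,
         aic_tables = lapply(results, `[[`, "aic_table")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
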