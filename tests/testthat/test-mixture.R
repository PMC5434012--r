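test_that("susceptibility follows the logistic submodel", {
  expect_equal(susceptibility(c(0), numeric(0)), 0.5)
  # dominant coefficient log(3.44): odds ratio between carrier and referent
  beta <- c(-0.5, log(3.44))
  or <- (susceptibility(beta, 1) / (1 - susceptibility(beta, 1))) /
    (susceptibility(beta, 0) / (1 - susceptibility(beta, 0)))
  expect_equal(or, 3.44, tolerance = 1e-12)
  # saturation without overflow at extreme linear predictors
  expect_equal(susceptibility(c(-1e6), numeric(0)), 0)
  expect_equal(susceptibility(c(1e6), numeric(0)), 1)
})

test_that("conditional survival has the log-logistic form", {
  mu <- 3.1
  expect_equal(conditional_survival(exp(mu), mu, -0.7), 0.5)  # median identity
  expect_equal(conditional_survival(exp(1), 0, 0), 1 / (1 + exp(1)),
               tolerance = 1e-12)
  # degenerate scale: all mass at the median
  expect_equal(conditional_survival(exp(mu) * 0.99, mu, -40), 1)
  expect_equal(conditional_survival(exp(mu) * 1.01, mu, -40), 0)
  expect_error(conditional_survival(-1, mu), "domain")
})

test_that("median onset is exp(location), independent of scale", {
  expect_equal(signif(median_onset(3.62), 3), 37.3)
  expect_equal(signif(median_onset(2.97), 3), 19.5)
  expect_equal(median_onset(0), 1)
})

test_that("the mixture survival interpolates between 1 and the risk-free tail", {
  expect_equal(mixture_survival(1e-8, 0.4, 3, -1), 1, tolerance = 1e-6)
  expect_equal(mixture_survival(1e12, 0.4, 3, -1), 0.6, tolerance = 1e-6)
  expect_equal(mixture_survival(exp(3), 0.5, 3, -1), 0.75, tolerance = 1e-12)
})

test_that("the mixture log-likelihood matches closed forms and the oracle", {
  # single event at the conditional median: ln f = -ln t - ln 4
  d1 <- data.frame(id = "a", age = exp(2), event = 1L)
  ll <- mixture_loglik(c(700, 2, 0), d1, mixture_spec())
  expect_equal(ll, -2 - log(4), tolerance = 1e-9)

  # all-censored data: supremum 0 approached as susceptibility -> 0
  dc <- data.frame(id = c("a", "b"), age = c(40, 50), event = 0L)
  expect_gt(mixture_loglik(c(-30, 3, 0), dc, mixture_spec()), -1e-10)
  expect_lt(mixture_loglik(c(0, 3, 0), dc, mixture_spec()), 0)

  # 10-subject fixture vs the independent summation oracle
  data <- ten_subject_fixture()
  spec <- mixture_spec(logistic = "x", location = "x", scale = "x")
  for (params in list(c(-0.5, 0.8, 3.4, -0.3, -1.5, 0.4),
                      c(0.2, -0.1, 3.0, 0.2, -1.0, -0.2),
                      c(1.5, 0.0, 2.5, 0.5, -2.0, 0.0))) {
    expect_equal(mixture_loglik(params, data, spec),
                 oracle_loglik(params, data, spec), tolerance = 1e-10)
  }
})

test_that("the analytic gradient matches central finite differences", {
  data <- ten_subject_fixture()
  spec <- mixture_spec(logistic = "x", location = "x", scale = "x")
  des <- eventcure:::.design(data, spec)
  theta <- c(-0.4, 0.6, 3.2, -0.2, -1.2, 0.3)
  g <- eventcure:::.mix_grad(theta, des, data$age, data$event == 1L)
  eps <- 1e-6
  for (j in seq_along(theta)) {
    tp <- theta; tp[j] <- tp[j] + eps
    tm <- theta; tm[j] <- tm[j] - eps
    fd <- (mixture_loglik(tp, data, spec) -
             mixture_loglik(tm, data, spec)) / (2 * eps)
    expect_equal(unname(g[j]), fd, tolerance = 1e-5)
  }
})

test_that("the fitted maximum dominates the truth and all starts", {
  cfg <- table1_preset(seed = 21, n_subjects = 800)
  cht <- gen_cohort(cfg)
  data <- model_frame(cht, table1_codings())
  fit <- fit_mixture(data, table1_spec())
  truth <- c(qlogis(0.378), log(3.44), 3.5, -0.29, 0.52, -0.41, -1.5, -1.32)
  expect_true(fit$converged)
  expect_gte(fit$loglik, mixture_loglik(truth, data, fit$spec))
  expect_gte(fit$loglik, max(fit$starts, na.rm = TRUE) - 1e-8)
  # single-replicate recovery within 4 Wald SEs of the truth
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(coef(fit) - truth) < 4 * se))
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$df)
})

test_that("non-identifiable designs raise a rank error", {
  data <- ten_subject_fixture()
  data$x2 <- data$x  # duplicated covariate
  expect_error(fit_mixture(data, mixture_spec(location = c("x", "x2"))),
               "rank error")
})

test_that("boundary susceptibility is detected and logistic inference suppressed", {
  set.seed(8)
  n <- 120
  tt <- exp(3.2 + 0.25 * rlogis(n))
  d <- data.frame(id = as.character(1:n), age = tt, event = 1L)
  fit <- fit_mixture(d, mixture_spec(), grad_tol = 1e-3)
  expect_true(fit$boundary)
  wt <- wald_tests(fit)
  expect_true(is.na(wt$p[wt$part == "logistic"]))
  expect_false(is.na(wt$p[wt$part == "location"]))
})

test_that("Wald inference is internally consistent", {
  cfg <- table1_preset(seed = 31, n_subjects = 600)
  cht <- gen_cohort(cfg)
  data <- model_frame(cht, table1_codings()["snp_drd3"])
  fit <- fit_mixture(data, mixture_spec(logistic = "snp_drd3_dom"))
  wt <- wald_tests(fit)
  # odds-ratio CI is the exponentiated coefficient CI (monotone map)
  lg <- wt[wt$part == "logistic", ]
  expect_equal(lg$or, exp(lg$estimate))
  expect_equal(lg$or_lower, exp(lg$lower))
  expect_equal(lg$or_upper, exp(lg$upper))
  # a coefficient of exactly zero would have p = 1
  z0 <- 0 / lg$se[1]
  expect_equal(2 * pnorm(-abs(z0)), 1)
})

test_that("Wald test size is near nominal under the null", {
  set.seed(12)
  reps <- 150
  rej <- 0
  for (r in seq_len(reps)) {
    n <- 300
    x <- rbinom(n, 1, 0.5)
    pi_i <- plogis(-0.5)
    dd <- rbinom(n, 1, pi_i)
    tt <- exp(3.4 + 0.25 * rlogis(n))
    cc <- runif(n, 25, 70)
    ev <- as.integer(dd == 1 & tt <= cc)
    data <- data.frame(id = as.character(1:n),
                       age = ifelse(dd == 1, pmin(tt, cc), cc),
                       event = ev, x = x)
    fit <- tryCatch(
      fit_mixture(data, mixture_spec(location = "x"), n_starts = 2),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    wt <- wald_tests(fit)
    p <- wt$p[wt$part == "location" & wt$term == "x"]
    if (!is.na(p) && p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / reps, 0.01)
  expect_lte(rej / reps, 0.10)
})

test_that("likelihood ratio test bookkeeping is correct", {
  cfg <- table1_preset(seed = 41, n_subjects = 400)
  cht <- gen_cohort(cfg)
  data <- model_frame(cht, table1_codings()["snp_ntrk2"])
  null_fit <- fit_mixture(data, mixture_spec())
  full_fit <- fit_mixture(data, mixture_spec(location = "snp_ntrk2_dom",
                                             scale = "snp_ntrk2_dom"))
  out <- lrt(full_fit, null_fit)
  expect_equal(out$df, 2)          # one covariate added to two parts
  expect_gte(out$chi2, 0)
  same <- lrt(null_fit, null_fit)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  # non-nested specs are refused
  other <- fit_mixture(data, mixture_spec(logistic = "snp_ntrk2_dom"))
  expect_error(lrt(full_fit, other), "not nested")
})

test_that("predicted event curves satisfy the mixture identities", {
  cfg <- table1_preset(seed = 51, n_subjects = 500)
  cht <- gen_cohort(cfg)
  data <- model_frame(cht, table1_codings()["snp_drd2"])
  fit <- fit_mixture(data, mixture_spec(logistic = "snp_drd2_dom",
                                        scale = "snp_drd2_dom"))
  curves <- predict_curves(fit, data.frame(snp_drd2_dom = c(0, 1)))
  for (cv in curves) {
    # conditional curve crosses one half exactly at the fitted median
    expect_equal(1 - conditional_survival(exp(cv$mu), cv$mu, cv$log_sigma),
                 0.5, tolerance = 1e-12)
    # overall curve plateau equals the fitted susceptibility far out; at
    # 20 fitted scales past the median the conditional tail is below 1e-8
    far <- exp(cv$mu + 20 * exp(cv$log_sigma))
    expect_equal(1 - mixture_survival(far, cv$pi, cv$mu, cv$log_sigma),
                 cv$pi, tolerance = 1e-6)
    # monotone non-decreasing on the grid
    expect_true(all(diff(cv$curve$overall) >= -1e-12))
    expect_true(all(diff(cv$curve$conditional) >= -1e-12))
    # pointwise mixture decomposition
    ages <- cv$curve$age
    lhs <- mixture_survival(ages, cv$pi, cv$mu, cv$log_sigma) - (1 - cv$pi)
    rhs <- cv$pi * conditional_survival(ages, cv$mu, cv$log_sigma)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("a larger scale linear predictor widens the conditional IQR", {
  mu <- 3.3
  iqr <- function(eta) {
    s <- exp(eta)
    exp(mu + s * qlogis(0.75)) - exp(mu + s * qlogis(0.25))
  }
  etas <- seq(-2, 0.5, by = 0.25)
  widths <- vapply(etas, iqr, 0)
  expect_true(all(diff(widths) > 0))
})

test_that("serialized fits round-trip their headline numbers", {
  cfg <- table1_preset(seed = 61, n_subjects = 300)
  cht <- gen_cohort(cfg)
  data <- model_frame(cht, table1_codings()["snp_drd3"])
  fit <- fit_mixture(data, mixture_spec(logistic = "snp_drd3_dom"))
  base <- tempfile()
  write_fit(fit, base, lrt_result = list(chi2 = 1, df = 1, p = 0.3))
  js <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(js$loglik, fit$loglik, tolerance = 1e-12)
  expect_equal(js$aic, fit$aic, tolerance = 1e-12)
  tab <- read.delim(paste0(base, ".tsv"))
  expect_equal(nrow(tab), length(coef(fit)))
})
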