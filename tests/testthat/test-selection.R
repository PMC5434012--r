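test_that("the sparse-event rule restricts codings from the event table", {
  mk <- function(geno, event) {
    cohort(data.frame(id = as.character(seq_along(geno)), event = event,
                      age = seq(25, 55, length.out = length(geno))),
           matrix(geno, ncol = 1, dimnames = list(NULL, "s")))
  }
  # aa group with zero events -> merged coding forced
  g <- rep(c("AA", "Aa", "aa"), c(12, 9, 6))
  ev <- c(rep(1L, 6), rep(0L, 6), rep(1L, 4), rep(0L, 5), rep(0L, 6))
  expect_true(sparse_event_rule(mk(g, ev), "s")$merged_only)
  # aa group with exactly one event -> still forced
  ev1 <- ev; ev1[22] <- 1L
  expect_true(sparse_event_rule(mk(g, ev1), "s")$merged_only)
  # two or more events everywhere -> full candidate set
  ev2 <- ev1; ev2[23] <- 1L
  expect_false(sparse_event_rule(mk(g, ev2), "s")$merged_only)
  # pure function of the event x genotype table: permutation invariant
  set.seed(2)
  p <- sample(length(g))
  expect_equal(sparse_event_rule(mk(g[p], ev2[p]), "s")$event_table,
               sparse_event_rule(mk(g, ev2), "s")$event_table)
})

test_that("candidate enumeration covers codings and placements once each", {
  cands <- candidate_specs("s", c("general", "additive", "dominant",
                                  "recessive"))
  placements <- vapply(cands, `[[`, "", "placement")
  expect_equal(sum(placements == "none"), 1)      # null model exactly once
  expect_equal(length(cands), 1 + 4 * 7)
  # general coding contributes two-dummy designs with Aa as referent
  gen <- cands[[which(placements == "logistic+location+scale")[1]]]
  expect_equal(gen$coding$referent, "Aa")
  expect_length(gen$spec$logistic, 2)
  # merged-only constraint yields single-dummy designs
  m <- candidate_specs("s", "merged-dominant")
  expect_equal(length(m), 1 + 7)
  specs1 <- m[vapply(m, `[[`, "", "placement") == "location"][[1]]
  expect_length(specs1$spec$location, 1)
})

test_that("classification is exhaustive and mutually exclusive", {
  cfg <- table1_preset(seed = 83, n_subjects = 1200)
  cht <- gen_cohort(cfg)
  data <- model_frame(cht, table1_codings()[c("snp_drd3", "snp_grin2b")])
  fit <- fit_mixture(data, mixture_spec(logistic = "snp_drd3_dom",
                                        location = "snp_grin2b_add"),
                     n_starts = 2)
  for (alpha in c(0.01, 0.05, 0.10, 0.5)) {
    cl <- classify_fit(fit, alpha)
    expect_true(cl$category %in% c("a", "b", "c", "d"))
    expected <- if (cl$logistic_sig && cl$aft_sig) "c"
      else if (cl$logistic_sig) "b"
      else if (cl$aft_sig) "a" else "d"
    expect_equal(cl$category, expected)
  }
  # at n = 1200 both generating effects are detected jointly
  expect_equal(classify_fit(fit, 0.05)$category, "c")
  # restricting the terms to one SNP isolates its part
  expect_equal(classify_fit(fit, 0.05, terms = "snp_drd3_dom")$category, "b")
  expect_equal(classify_fit(fit, 0.05, terms = "snp_grin2b_add")$category, "a")
})

test_that("selection recovers the generating placement and category", {
  # susceptibility-only dominant effect (odds ratio 3.4)
  cfg_b <- generator_config(
    n_subjects = 1500,
    snp_specs = data.frame(snp_id = "s1", gene = "G", maf = 0.3, gcr = 1,
                           stringsAsFactors = FALSE),
    true_beta = c("(Intercept)" = qlogis(0.3), s1_dom = log(3.4)),
    seed = 91)
  sel_b <- select_model(gen_cohort(cfg_b), "s1", n_starts = 2)
  expect_false(sel_b$failed)
  expect_equal(sel_b$category, "b")
  expect_equal(sel_b$chosen$placement, "logistic")

  # onset-age-only additive location effect (-0.29 per allele)
  cfg_a <- generator_config(
    n_subjects = 1500,
    snp_specs = data.frame(snp_id = "s1", gene = "G", maf = 0.4, gcr = 1,
                           stringsAsFactors = FALSE),
    true_gamma = c("(Intercept)" = 3.5, s1_add = -0.29),
    seed = 92)
  sel_a <- select_model(gen_cohort(cfg_a), "s1", n_starts = 2)
  expect_equal(sel_a$category, "a")
  expect_true(grepl("location", sel_a$chosen$placement))
  expect_false(grepl("logistic", sel_a$chosen$placement))
  # AIC consistency: chosen model beats the null whenever the LRT rejects
  if (sel_a$lrt$p < 0.05) {
    null_aic <- sel_a$aic_table$aic[sel_a$aic_table$placement == "none"]
    expect_lte(sel_a$fit$aic, null_aic)
  }
})

test_that("the joint subset search recovers a three-part structure", {
  cfg <- table1_preset(seed = 93, n_subjects = 1500)
  cht <- gen_cohort(cfg)
  snps <- list(
    snp_drd3 = list(coding = genotype_coding("dominant"), parts = "logistic"),
    snp_grin2b = list(coding = genotype_coding("additive"),
                      parts = "location"),
    snp_drd2 = list(coding = genotype_coding("dominant"), parts = "scale"))
  joint <- multi_covariate_search(cht, snps, n_starts = 2)
  expect_false(joint$failed)
  expect_true(all(c("snp_drd3", "snp_grin2b", "snp_drd2") %in%
                    names(which(joint$chosen$included))))
  expect_equal(joint$category, "c")
  expect_lt(joint$lrt$p, 0.01)
})

test_that("a null extra covariate is usually left out of the joint model", {
  set.seed(44)
  kept_out <- 0
  reps <- 15
  for (r in seq_len(reps)) {
    cfg <- generator_config(
      n_subjects = 800,
      snp_specs = data.frame(snp_id = c("s1", "s0"), gene = c("G1", "G0"),
                             maf = c(0.3, 0.3), gcr = 1,
                             stringsAsFactors = FALSE),
      true_gamma = c("(Intercept)" = 3.5, s1_dom = 0.5),
      seed = sample.int(1e6, 1))
    cht <- gen_cohort(cfg)
    snps <- list(
      s1 = list(coding = genotype_coding("dominant"), parts = "location"),
      s0 = list(coding = genotype_coding("dominant"), parts = "location"))
    joint <- tryCatch(multi_covariate_search(cht, snps, n_starts = 1),
                      error = function(e) NULL)
    if (is.null(joint)) next
    if (!isTRUE(joint$chosen$included["s0"])) kept_out <- kept_out + 1
  }
  expect_gte(kept_out / reps, 0.65)
})

test_that("the joint search degenerates gracefully to a single factor", {
  cfg <- table1_preset(seed = 94, n_subjects = 400)
  cht <- gen_cohort(cfg)
  only_smoking <- multi_covariate_search(cht, snps = list(),
                                         extra = list(smoking = "location"),
                                         n_starts = 2)
  expect_false(only_smoking$failed)
  expect_true(nrow(only_smoking$aic_table) == 2)  # smoking in/out
  # refuses when complete cases cannot support the parameter count
  tiny <- cohort(cht$subjects[1:8, ], cht$genotypes[1:8, , drop = FALSE])
  expect_error(
    multi_covariate_search(tiny, snps = list(
      snp_drd3 = list(coding = genotype_coding("general"),
                      parts = c("logistic", "location", "scale"))),
      n_starts = 1),
    "sample-size")
})

test_that("selection reports serialize with a supplementary Bonferroni column", {
  cfg <- table1_preset(seed = 95, n_subjects = 300)
  cht <- gen_cohort(cfg)
  sels <- lapply(c("snp_drd3", "snp_ntrk2"), function(s)
    select_model(cht, s, n_starts = 1))
  p <- tempfile(fileext = ".tsv")
  write_selection_report(sels, p)
  tab <- read.delim(p)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$lrt_p_bonferroni >= tab$lrt_p, na.rm = TRUE))
  js <- jsonlite::read_json(paste0(p, ".json"))
  expect_length(js$aic_tables, 2)
})
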