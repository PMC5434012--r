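test_that("exact HWE test matches spot-checked enumeration values", {
  expect_equal(hwe_exact(25, 50, 25), oracle_hwe(25, 50, 25), tolerance = 1e-12)
  expect_equal(hwe_exact(0, 10, 0), oracle_hwe(0, 10, 0), tolerance = 1e-12)
  expect_equal(hwe_exact(5, 0, 5), oracle_hwe(5, 0, 5), tolerance = 1e-12)
  expect_lt(hwe_exact(5, 0, 5), 0.05)     # all-homozygote extreme
  expect_equal(hwe_exact(25, 50, 25), 1)  # most probable configuration
  expect_equal(hwe_exact(40, 0, 0), 1)    # monomorphic convention
})

test_that("exact HWE test is conservative under simulated equilibrium", {
  set.seed(71)
  n <- 65; maf <- 0.3; reps <- 2000
  rej <- 0
  probs <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  for (r in seq_len(reps)) {
    counts <- as.vector(rmultinom(1, n, probs))
    if (hwe_exact(counts[1], counts[2], counts[3]) < 0.05) rej <- rej + 1
  }
  expect_lte(rej / reps, 0.06)
})

test_that("per-SNP stats report MAF over called subjects and GCR over all", {
  cht <- qc_demo_cohort()
  st <- snp_stats(cht, "rs1421109")
  expect_equal(st$n_called, 48)
  expect_equal(st$gcr, 48 / 65, tolerance = 1e-12)
  expect_equal(st$maf, 3 / 96, tolerance = 1e-12)

  # all-AA SNP
  base <- data.frame(id = c("a", "b"), event = c(1, 0), age = c(20, 30))
  g <- matrix(c("AA", "AA", "AA", "Aa"), 2, 2,
              dimnames = list(NULL, c("s1", "s2")))
  c2 <- cohort(base, g)
  expect_equal(snp_stats(c2, "s1")$maf, 0)

  # symmetric counts give MAF exactly one half
  base3 <- data.frame(id = sprintf("i%02d", 1:64), event = 0L,
                      age = rep(30, 64))
  g3 <- matrix(rep(c("AA", "Aa", "aa"), c(16, 32, 16)), ncol = 1,
               dimnames = list(NULL, "s"))
  expect_equal(snp_stats(cohort(base3, g3), "s")$maf, 0.5)
})

test_that("EM linkage disequilibrium recovers haplotype structure", {
  # perfectly co-inherited loci -> complete LD
  base <- data.frame(id = sprintf("i%02d", 1:60), event = 0L, age = rep(30, 60))
  calls <- rep(c("AA", "Aa", "aa"), c(30, 24, 6))
  g <- cbind(a = calls, b = calls)
  ld <- ld_em(cohort(base, g), "a", "b")
  expect_equal(ld$r2, 1, tolerance = 1e-6)
  expect_equal(ld$d_prime, 1, tolerance = 1e-6)

  # no-double-heterozygote table: EM equals direct haplotype counting
  # haplotypes: 20 x (AB/AB), 10 x (AB/aB), 10 x (Ab/Ab)
  ga <- rep(c("AA", "Aa", "AA"), c(20, 10, 10))
  gb <- rep(c("AA", "AA", "aa"), c(20, 10, 10))
  ld2 <- ld_em(cohort(data.frame(id = sprintf("j%02d", 1:40), event = 0L,
                                 age = rep(30, 40)),
                      cbind(a = ga, b = gb)), "a", "b")
  counted <- c(AB = (40 + 10) / 80, Ab = 20 / 80, aB = 10 / 80, ab = 0)
  expect_equal(ld2$hap_freqs, counted, tolerance = 1e-8)

  # independent loci at n = 2000: mean r2 across reps is near zero
  set.seed(5)
  r2s <- replicate(10, {
    cfg <- generator_config(
      n_subjects = 2000,
      snp_specs = data.frame(snp_id = c("u", "v"), gene = c("G", "G"),
                             maf = c(0.3, 0.4), gcr = 1,
                             stringsAsFactors = FALSE),
      seed = sample.int(1e6, 1))
    cc <- gen_cohort(cfg)
    ld_em(cc, "u", "v")$r2
  })
  expect_lt(mean(r2s), 0.01)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  set.seed(9)
  for (r in 1:25) {
    n <- 40
    da <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.4, 0.1))
    db <- sample(0:2, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    if (length(unique(da)) == 1 || length(unique(db)) == 1) next
    g <- cbind(a = c("AA", "Aa", "aa")[da + 1], b = c("AA", "Aa", "aa")[db + 1])
    ld <- ld_em(cohort(data.frame(id = as.character(1:n), event = 0L,
                                  age = rep(30, n)), g), "a", "b")
    diffs <- diff(ld$loglik_trace)
    expect_true(all(diffs > -1e-9))
  }
})

test_that("the QC cascade reproduces the engineered panel outcome", {
  cht <- qc_demo_cohort()
  rep <- qc_cascade(cht, attr(cht, "snp_genes"))
  expect_equal(length(rep$kept), 22)
  expect_equal(length(unique(rep$decisions$gene[rep$decisions$verdict == "keep"])),
               12)
  expect_setequal(rep$excluded_genes, c("FYN", "GABRB1"))
  reasons <- setNames(rep$decisions$reasons, rep$decisions$snp_id)
  expect_equal(unname(reasons["rs1421109"]), "low-maf;low-gcr")
  expect_equal(unname(reasons["rs956412"]), "hwe-violation")
  expect_setequal(
    rep$decisions$snp_id[grepl("complete-ld", rep$decisions$reasons)],
    c("rs728293", "rs1079598", "rs1079596", "rs1386483", "rs985934"))
  expect_equal(unname(reasons[c("rs1409836", "rs910683")]),
               c("low-maf", "low-maf"))
})

test_that("the QC cascade passes clean panels through and handles empties", {
  cht <- qc_demo_cohort()
  keep <- c("rs63319", "rs348457", "rs2134655")
  sub <- cohort(cht$subjects, cht$genotypes[, keep])
  map <- attr(cht, "snp_genes")[keep]
  rep <- qc_cascade(sub, map)
  expect_equal(rep$kept, keep)
  expect_equal(length(rep$dropped), 0)

  empty <- cohort(cht$subjects)
  rep0 <- qc_cascade(empty, character(0))
  expect_equal(nrow(rep0$decisions), 0)
})

test_that("QC verdicts are invariant to SNP input order", {
  cht <- qc_demo_cohort()
  map <- attr(cht, "snp_genes")
  rep1 <- qc_cascade(cht, map)
  perm <- rev(cht$snp_ids)
  cht2 <- cohort(cht$subjects, cht$genotypes[, perm])
  rep2 <- qc_cascade(cht2, map)
  v1 <- setNames(rep1$decisions$verdict, rep1$decisions$snp_id)
  v2 <- setNames(rep2$decisions$verdict, rep2$decisions$snp_id)
  expect_equal(v1[sort(names(v1))], v2[sort(names(v2))])
})

test_that("gene-set arithmetic matches inclusion-exclusion", {
  a <- paste0("G", 1:15)
  b <- c(paste0("G", 1:10), paste0("H", 1:55))   # overlap 10, |B| = 65
  gs <- gene_set_summary(a, b)
  expect_equal(gs$intersection, 10)
  expect_equal(gs$union, 70)

  same <- gene_set_summary(a, tolower(a))        # case-insensitive
  expect_equal(same$intersection, 15)
  expect_equal(same$union, 15)

  disj <- gene_set_summary(a, paste0("Z", 1:7))
  expect_equal(disj$intersection, 0)
  expect_equal(disj$union, 22)

  set.seed(3)
  for (r in 1:20) {
    s1 <- sample(paste0("g", 1:40), sample(1:30, 1))
    s2 <- sample(paste0("g", 1:40), sample(1:30, 1))
    gs <- gene_set_summary(s1, s2)
    expect_equal(gs$union,
                 length(unique(toupper(s1))) + length(unique(toupper(s2))) -
                   gs$intersection)
  }
})
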