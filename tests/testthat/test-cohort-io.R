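test_that("a toy table round-trips through read and write", {
  tab <- data.frame(id = c("a", "b", "c"), event = c(1, 0, 1),
                    age = c(20.5, 44, 31), smoking = c(1, 0, NA),
                    rs1 = c("AA", "Aa", "aa"), stringsAsFactors = FALSE)
  p <- write_toy_table(tab, tempfile(fileext = ".csv"))
  cht <- read_cohort(p)
  expect_equal(n_subjects(cht), 3)
  expect_equal(length(cht$snp_ids), 1)
  expect_equal(unname(cht$genotypes[, "rs1"]), c("AA", "Aa", "aa"))

  p2 <- tempfile(fileext = ".tsv")
  write_cohort(cht, p2)
  cht2 <- read_cohort(p2)
  expect_equal(cht2$subjects$id, cht$subjects$id)
  expect_equal(cht2$subjects$age, cht$subjects$age)
  expect_equal(cht2$subjects$smoking, cht$subjects$smoking)
  expect_equal(cht2$genotypes, cht$genotypes)
  expect_true(file.exists(paste0(p2, ".json")))
})

test_that("missing and unparseable genotype tokens become missing calls", {
  tab <- data.frame(id = c("a", "b", "c"), event = c(1, 0, 0),
                    age = c(20, 30, 40),
                    rs1 = c("NA", "Aa", "XX"), stringsAsFactors = FALSE)
  p <- write_toy_table(tab, tempfile(fileext = ".csv"))
  expect_warning(cht <- read_cohort(p), "unparseable")
  expect_true(is.na(cht$genotypes["a", "rs1"]))   # missing token
  expect_true(is.na(cht$genotypes["c", "rs1"]))   # unparseable string
  expect_equal(n_subjects(cht), 3)                # subjects retained
})

test_that("dosage and VCF-style genotype strings are normalized per SNP", {
  # alt allele is the minor one here: 0/1/2 -> AA/Aa/aa
  tab <- data.frame(id = letters[1:5], event = c(1, 0, 0, 0, 0),
                    age = c(20, 30, 40, 50, 60),
                    rs1 = c("0", "1", "2", "0", "0"),
                    rs2 = c("0/0", "0/1", "1/1", "0|0", "0/0"),
                    stringsAsFactors = FALSE)
  p <- write_toy_table(tab, tempfile(fileext = ".csv"))
  cht <- read_cohort(p)
  expect_equal(unname(cht$genotypes[, "rs1"]), c("AA", "Aa", "aa", "AA", "AA"))
  expect_equal(unname(cht$genotypes[, "rs2"]), c("AA", "Aa", "aa", "AA", "AA"))

  # alt allele in the majority: dosage flipped so 2 = major homozygote
  tab2 <- data.frame(id = letters[1:4], event = c(1, 0, 0, 0),
                     age = c(20, 30, 40, 50),
                     rs3 = c("2", "2", "2", "1"), stringsAsFactors = FALSE)
  p2 <- write_toy_table(tab2, tempfile(fileext = ".csv"))
  cht2 <- read_cohort(p2)
  expect_equal(unname(cht2$genotypes[, "rs3"]), c("AA", "AA", "AA", "Aa"))
})

test_that("schema and validation errors are raised with context", {
  tab <- data.frame(id = "a", age = 20, stringsAsFactors = FALSE)
  p <- write_toy_table(tab, tempfile(fileext = ".csv"))
  expect_error(read_cohort(p), "schema error.*event")

  tab2 <- data.frame(id = c("a", "b"), event = c(1, 0), age = c(20, -3),
                     stringsAsFactors = FALSE)
  p2 <- write_toy_table(tab2, tempfile(fileext = ".csv"))
  expect_error(read_cohort(p2), "non-positive age.*2")
})

test_that("a study-sized table yields the expected event split", {
  cht <- qc_demo_cohort()
  p <- tempfile(fileext = ".tsv")
  write_cohort(cht, p)
  back <- read_cohort(p)
  expect_equal(n_subjects(back), 65)
  expect_equal(sum(back$subjects$event), 23)
  expect_equal(sum(1 - back$subjects$event), 42)
})

test_that("the optional onset-age outlier filter drops late-onset events only", {
  tab <- data.frame(id = c("a", "b", "c"), event = c(1, 1, 0),
                    age = c(35, 91, 95), stringsAsFactors = FALSE)
  p <- write_toy_table(tab, tempfile(fileext = ".csv"))
  expect_equal(n_subjects(read_cohort(p)), 3)
  filtered <- read_cohort(p, max_onset_age = 90)
  expect_equal(filtered$subjects$id, c("a", "c"))  # censored 95 is kept
})

test_that("genotype encodings follow the coding schemes", {
  expect_equal(encode_genotype("aa", genotype_coding("additive")), 2)
  expect_equal(encode_genotype("AA", genotype_coding("dominant")), 0)
  expect_equal(encode_genotype("Aa", genotype_coding("merged-dominant")), 1)
  expect_equal(encode_genotype("aa", genotype_coding("merged-dominant")), 1)
  expect_equal(encode_genotype("aa", genotype_coding("recessive")), 1)
  # general: two indicators, referent Aa maps to the zero vector
  gen <- genotype_coding("general")
  expect_equal(encode_genotype("Aa", gen), c(0, 0))
  expect_equal(sort(c(sum(encode_genotype("AA", gen)),
                      sum(encode_genotype("aa", gen)))), c(1, 1))
  # referent maps to zero for every scheme
  for (sc in c("general", "additive", "dominant", "recessive")) {
    cd <- genotype_coding(sc)
    expect_equal(sum(abs(encode_genotype(cd$referent, cd))), 0)
  }
  # missing call -> NA sentinel of the design width
  expect_true(all(is.na(encode_genotype(NA_character_, gen))))
  expect_length(encode_genotype(NA_character_, gen), 2)
})

test_that("encode is injective up to the scheme's merging", {
  genos <- c("AA", "Aa", "aa")
  for (sc in c("general", "additive")) {
    cd <- genotype_coding(sc)
    codes <- apply(encode_genotype(genos, cd), 1, paste, collapse = ",")
    expect_equal(length(unique(codes)), 3)
  }
  dom <- genotype_coding("dominant")
  expect_equal(encode_genotype("Aa", dom), encode_genotype("aa", dom))
  expect_false(encode_genotype("AA", dom) == encode_genotype("Aa", dom))
})

test_that("VCF genotypes attach to a cohort and multiallelic records are rejected", {
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "a", "b", "c", sep = "\t"),
    paste("1", "100", "rsA", "G", "T", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "rsB", "C", "A", ".", "PASS", ".", "GT",
          "0/1", "./.", "0/0", sep = "\t"))
  vp <- tempfile(fileext = ".vcf")
  writeLines(vcf_lines, vp)
  base <- data.frame(id = c("a", "b", "c"), event = c(1, 0, 0),
                     age = c(30, 40, 50), stringsAsFactors = FALSE)
  cht <- read_genotypes_vcf(cohort(base), vp)
  expect_equal(unname(cht$genotypes[, "rsA"]), c("AA", "Aa", "aa"))
  expect_equal(unname(cht$genotypes[, "rsB"]), c("Aa", NA, "AA"))

  multi <- c(vcf_lines[1:3],
             paste("1", "300", "rsM", "G", "T,C", ".", "PASS", ".", "GT",
                   "0/1", "0/2", "0/0", sep = "\t"))
  mp <- tempfile(fileext = ".vcf")
  writeLines(multi, mp)
  expect_error(read_genotypes_vcf(cohort(base), mp), "multiallelic")
})

test_that("complete_cases drops exactly the subjects with missing inputs", {
  base <- data.frame(id = sprintf("s%02d", 1:65),
                     event = rep(c(1L, 0L), c(23, 42)),
                     age = seq(20, 60, length.out = 65),
                     stringsAsFactors = FALSE)
  gx <- matrix("Aa", 65, 2, dimnames = list(NULL, c("snpX", "snpY")))
  gx[1:11, "snpX"] <- NA
  gx[1:8, "snpY"] <- NA
  cht <- cohort(base, gx)
  expect_equal(n_subjects(complete_cases(cht, "snpX")), 54)
  expect_equal(n_subjects(complete_cases(cht, "snpY")), 57)
  # identity when nothing is missing
  full <- complete_cases(cht, character(0))
  expect_equal(full$subjects, cht$subjects)
  # retained + dropped = input, fields untouched
  cc <- complete_cases(cht, "snpX")
  expect_equal(n_subjects(cc) + cc$metadata$n_dropped, 65)
  expect_equal(cc$subjects, cht$subjects[!is.na(gx[, "snpX"]), ],
               ignore_attr = TRUE)
  # all-missing SNP -> degenerate-input error
  gx2 <- matrix(NA_character_, 65, 1, dimnames = list(NULL, "snpZ"))
  expect_error(complete_cases(cohort(base, gx2), "snpZ"), "degenerate")
})
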