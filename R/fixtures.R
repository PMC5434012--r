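# Synthetic, fully deterministic demonstration fixtures.  These are
# constructed data sets (no RNG, no external files) that emulate the
# structure of a small male founder candidate-gene panel, so that the QC
# cascade and the clustering module can be exercised end to end.

# expand per-genotype counts into a call vector, rotated by `offset` within
# the group so different SNPs are decorrelated while keeping identical
# genotype counts (hence identical MAF/HWE within the group)
.expand_calls <- function(counts, offset = 0) {
  v <- rep(c("AA", "Aa", "aa"), times = counts)
  n <- length(v)
  if (n == 0) return(character(0))
  off <- offset %% n
  if (off > 0) v <- c(v[(off + 1):n], v[1:off])
  v
}

#' Synthetic candidate-gene QC demonstration cohort
#'
#' A deterministic 65-subject cohort (23 events, 42 censored) carrying a
#' 31-SNP panel on 14 genes engineered so that the QC cascade reproduces
#' one failure of every kind: two (near-)monomorphic SNPs (excluding their
#' gene entirely), one SNP with both low minor-allele frequency and low
#' call rate, five SNPs in complete LD with a same-gene partner of higher
#' call rate, and two SNPs violating exact Hardy-Weinberg equilibrium in
#' the unaffected stratum (one of which is also complete-LD-redundant).
#' Running \code{\link{qc_cascade}} with default thresholds retains 22
#' SNPs on 12 genes.
#'
#' All genotype vectors are built from fixed genotype counts (separately
#' for cases and unaffected subjects, so the unaffected-only HWE test is
#' controlled) and deterministic rotations; the data are synthetic and
#' carry no individual-level information.
#'
#' @return a \code{\link{cohort}}; \code{attr(, "snp_genes")} holds the
#'   SNP-to-gene map in map order
#' @export
qc_demo_cohort <- function() {
  n_case <- 23; n_ctrl <- 42; n <- n_case + n_ctrl
  # gene map in map-position order
  panel <- list(
    ALDH1A1 = c("rs63319", "rs348457"),
    CHRM2 = c("rs1378647", "rs1111418"),
    DRD2 = c("rs1079598", "rs1079597", "rs1079596"),
    DRD3 = "rs2134655",
    FYN = c("rs1409836", "rs910683"),
    GABRA1 = c("rs966137", "rs1157122"),
    GABRB1 = c("rs728293", "rs956412"),
    GABRB3 = "rs1365225",
    GABRG2 = c("rs411409", "rs387661", "rs2422106"),
    GRIN2B = c("rs172677", "rs1421109"),
    HTR2A = c("rs985934", "rs985933", "rs927544"),
    NTRK2 = c("rs1439047", "rs1838158"),
    RXRG = c("rs2134095", "rs157864"),
    TPH2 = c("rs1386493", "rs1386492", "rs1386485", "rs1386483"))
  snp_genes <- stats::setNames(rep(names(panel), lengths(panel)),
                               unlist(panel))
  snps <- names(snp_genes)

  # near-HWE genotype counts (cases then unaffected) for a well-behaved SNP
  case_counts <- c(11, 9, 3)    # 23 subjects, MAF ~ 0.33
  ctrl_counts <- c(21, 17, 4)   # 42 subjects, MAF ~ 0.30, HWE-consistent
  geno <- matrix(NA_character_, n, length(snps),
                 dimnames = list(NULL, snps))
  for (j in seq_along(snps)) {
    geno[, snps[j]] <- c(.expand_calls(case_counts, offset = 3 * j),
                         .expand_calls(ctrl_counts, offset = 5 * j))
  }

  # (near-)monomorphic pair: gene dropped entirely
  geno[, "rs1409836"] <- "AA"
  geno[, "rs910683"] <- c("Aa", rep("AA", n - 1))

  # low MAF (3/96) and low call rate (48/65)
  geno[, "rs1421109"] <- c(rep("Aa", 3), rep("AA", 45), rep(NA, 17))

  # HWE violation in the unaffected stratum: strong heterozygote deficit
  hwe_bad <- c(.expand_calls(c(15, 2, 6)),        # cases, unconstrained
               .expand_calls(c(30, 2, 10)))       # unaffected, exact p << 0.05
  geno[, "rs956412"] <- hwe_bad

  # complete-LD copies: identical calls, lower call rate than the source
  copy_with_gaps <- function(src, na_at) {
    v <- geno[, src]
    v[na_at] <- NA_character_
    v
  }
  geno[, "rs728293"] <- copy_with_gaps("rs956412", c(5, 29, 51))
  geno[, "rs1079598"] <- copy_with_gaps("rs1079597", c(2, 33))
  geno[, "rs1079596"] <- copy_with_gaps("rs1079597", c(7, 19, 40))
  geno[, "rs1386483"] <- copy_with_gaps("rs1386493", c(11, 44))
  geno[, "rs985934"] <- copy_with_gaps("rs985933", c(3, 26, 60))

  # phenotype: onset ages for the 23 cases, interview ages for the rest;
  # habitual smoking 19/23 in cases, 27/42 in unaffected
  onset_ages <- seq(16, 42, length.out = n_case)
  interview_ages <- seq(26, 68, length.out = n_ctrl)
  smoking <- c(rep(1L, 19), rep(0L, 4), rep(1L, 27), rep(0L, 15))
  subjects <- data.frame(
    id = sprintf("S%03d", seq_len(n)),
    event = c(rep(1L, n_case), rep(0L, n_ctrl)),
    age = c(onset_ages, interview_ages),
    smoking = smoking,
    stringsAsFactors = FALSE)
  out <- cohort(subjects, geno,
                metadata = list(description = "synthetic QC demonstration panel"))
  attr(out, "snp_genes") <- snp_genes
  out
}

#' Synthetic gene-by-pathway membership fixture
#'
#' A deterministic 5-gene by 23-pathway binary membership matrix encoding
#' the qualitative topology of an alcoholism candidate-gene pathway
#' analysis: two dopamine/glutamate genes sharing six pathways across
#' three categories, a neurotrophin-receptor gene sharing the alcoholism
#' pathway with them, a dopamine-receptor gene sharing the synaptic and
#' signalling pathways, and one aldehyde-dehydrogenase gene confined to
#' the metabolism category (and therefore unlinked to the rest).  Entries
#' beyond those stated relationships are synthetic filler and are flagged
#' as unconstrained in the \code{constrained} attribute.
#'
#' @return list with \code{values} (0/1 matrix genes x pathways),
#'   \code{categories} (pathway -> category), \code{constrained}
#'   (logical matrix marking topology-bearing entries)
#' @export
gene_pathway_fixture <- function() {
  genes <- c("ALDH1A1", "DRD2", "DRD3", "GRIN2B", "NTRK2")
  pathways <- c(
    "Glycolysis / Gluconeogenesis", "Fatty acid degradation",
    "Tryptophan metabolism", "Histidine metabolism",
    "beta-Alanine metabolism",
    "Alcoholism", "Cocaine addiction", "Amphetamine addiction",
    "Nicotine addiction", "Alzheimer disease", "Huntington disease",
    "Parkinson disease",
    "Dopaminergic synapse", "Glutamatergic synapse",
    "Long-term potentiation", "Prolactin signaling pathway",
    "Neuroactive ligand-receptor interaction", "cAMP signaling pathway",
    "Rap1 signaling pathway", "Calcium signaling pathway",
    "Neurotrophin signaling pathway", "MAPK signaling pathway",
    "Gap junction")
  categories <- c(rep("Metabolism", 5),
                  rep("Human Diseases", 7),
                  rep("Organismal Systems", 4),
                  rep("Environmental Information Processing", 6),
                  "Cellular Processes")
  names(categories) <- pathways
  members <- list(
    ALDH1A1 = pathways[1:5],
    DRD2 = c("Alcoholism", "Cocaine addiction", "Dopaminergic synapse",
             "Neuroactive ligand-receptor interaction",
             "cAMP signaling pathway", "Rap1 signaling pathway",
             "Parkinson disease", "Gap junction"),
    DRD3 = c("Dopaminergic synapse",
             "Neuroactive ligand-receptor interaction",
             "cAMP signaling pathway", "Rap1 signaling pathway",
             "Prolactin signaling pathway", "Calcium signaling pathway"),
    GRIN2B = c("Alcoholism", "Cocaine addiction", "Amphetamine addiction",
               "Nicotine addiction", "Alzheimer disease",
               "Huntington disease", "Dopaminergic synapse",
               "Glutamatergic synapse", "Long-term potentiation",
               "Neuroactive ligand-receptor interaction",
               "cAMP signaling pathway", "Rap1 signaling pathway"),
    NTRK2 = c("Alcoholism", "Neurotrophin signaling pathway",
              "MAPK signaling pathway"))
  vals <- matrix(0L, length(genes), length(pathways),
                 dimnames = list(genes, pathways))
  for (g in genes) vals[g, members[[g]]] <- 1L
  constrained <- matrix(FALSE, length(genes), length(pathways),
                        dimnames = dimnames(vals))
  constrained["ALDH1A1", ] <- TRUE     # metabolism-only is load-bearing
  constrained[c("DRD2", "GRIN2B"),
              c("Alcoholism", "Cocaine addiction", "Dopaminergic synapse",
                "Neuroactive ligand-receptor interaction",
                "cAMP signaling pathway", "Rap1 signaling pathway")] <- TRUE
  constrained["NTRK2", "Alcoholism"] <- TRUE
  constrained["DRD3", c("Dopaminergic synapse",
                        "Neuroactive ligand-receptor interaction",
                        "cAMP signaling pathway",
                        "Rap1 signaling pathway")] <- TRUE
  list(values = vals, categories = categories, constrained = constrained)
}
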