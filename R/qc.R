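#' Per-SNP quality metrics
#'
#' Minor allele frequency and call rate are computed over all subjects
#' (called genotypes only for the MAF); the exact Hardy-Weinberg p-value is
#' computed on the subjects selected by \code{hwe_on} (default the
#' unaffected group, where selection on the phenotype cannot distort
#' genotype frequencies).
#'
#' @param x a \code{\link{cohort}}
#' @param snp_id SNP id
#' @param hwe_on which subjects enter the HWE test: \code{"unaffected"}
#'   (default) or \code{"all"}
#' @return object of class \code{snp_stats}: list with \code{snp_id},
#'   \code{maf}, \code{gcr}, \code{genotype_counts} (n_AA, n_Aa, n_aa over
#'   all called subjects), \code{hwe_p}, \code{n_called}, \code{n_subjects}.
#' @export
snp_stats <- function(x, snp_id, hwe_on = c("unaffected", "all")) {
  hwe_on <- match.arg(hwe_on)
  .stop_if(!snp_id %in% x$snp_ids, "unknown SNP id: ", snp_id)
  g <- x$genotypes[, snp_id]
  called <- !is.na(g)
  .stop_if(!any(called), "undefined stats: zero called genotypes for ", snp_id)
  counts <- c(n_AA = sum(g == "AA", na.rm = TRUE),
              n_Aa = sum(g == "Aa", na.rm = TRUE),
              n_aa = sum(g == "aa", na.rm = TRUE))
  n_called <- sum(called)
  maf <- (counts["n_Aa"] + 2 * counts["n_aa"]) / (2 * n_called)
  maf <- unname(min(maf, 1 - maf))
  sub <- if (hwe_on == "unaffected") x$subjects$event == 0L else rep(TRUE, n_subjects(x))
  gh <- g[sub & called]
  hwe_p <- if (length(gh) == 0) NA_real_ else
    hwe_exact(sum(gh == "AA"), sum(gh == "Aa"), sum(gh == "aa"))
  structure(list(snp_id = snp_id, maf = maf, gcr = n_called / n_subjects(x),
                 genotype_counts = counts, hwe_p = hwe_p,
                 n_called = n_called, n_subjects = n_subjects(x)),
            class = "snp_stats")
}

#' @export
print.snp_stats <- function(x, ...) {
  cat(sprintf("%s: MAF %.4f, GCR %.3f, counts (%d/%d/%d), HWE p = %.4g\n",
              x$snp_id, x$maf, x$gcr, x$genotype_counts[1],
              x$genotype_counts[2], x$genotype_counts[3], x$hwe_p))
  invisible(x)
}

#' SNP elimination cascade
#'
#' Ordered quality-control cascade for a candidate-gene SNP panel:
#' \enumerate{
#'   \item drop SNPs with minor allele frequency below \code{maf_min} or
#'     genotyping call rate below \code{gcr_min} (computed on all subjects);
#'   \item among surviving within-gene pairs in complete LD
#'     (\eqn{r^2 = 1}), drop the member with the lower call rate (ties:
#'     the later map position, i.e. the SNP listed later for that gene);
#'   \item drop SNPs whose exact Hardy-Weinberg p-value, computed on the
#'     unaffected subjects only, falls below \code{hwe_alpha}.
#' }
#' Genes left with no surviving SNP are reported as excluded.
#'
#' @param x a \code{\link{cohort}}
#' @param snp_genes named character vector mapping SNP id -> gene symbol
#'   (order within a gene gives the map position)
#' @param maf_min,gcr_min,hwe_alpha thresholds (defaults 0.05, 0.85, 0.05)
#' @param r2_tol numerical tolerance for declaring \eqn{r^2 = 1}
#' @param hwe_on population for the HWE step (default unaffected only)
#' @return object of class \code{qc_report}: list with \code{decisions}
#'   (data.frame: snp_id, gene, maf, gcr, hwe_p, verdict, reasons),
#'   \code{kept}, \code{dropped}, \code{excluded_genes}, \code{thresholds}.
#' @export
qc_cascade <- function(x, snp_genes, maf_min = 0.05, gcr_min = 0.85,
                       hwe_alpha = 0.05, r2_tol = 1e-6,
                       hwe_on = c("unaffected", "all")) {
  hwe_on <- match.arg(hwe_on)
  snps <- x$snp_ids
  if (length(snps) == 0) {
    return(structure(list(decisions = data.frame(), kept = character(0),
                          dropped = character(0),
                          excluded_genes = character(0),
                          thresholds = list(maf_min = maf_min,
                                            gcr_min = gcr_min,
                                            hwe_alpha = hwe_alpha)),
                     class = "qc_report"))
  }
  .stop_if(!all(snps %in% names(snp_genes)),
           "configuration error: SNP(s) missing from the gene map: ",
           paste(setdiff(snps, names(snp_genes)), collapse = ", "))
  genes <- snp_genes[snps]

  stats <- lapply(snps, function(s) snp_stats(x, s, hwe_on = hwe_on))
  names(stats) <- snps
  maf <- vapply(stats, `[[`, 0, "maf")
  gcr <- vapply(stats, `[[`, 0, "gcr")
  hwe_p <- vapply(stats, `[[`, 0, "hwe_p")

  reasons <- stats::setNames(vector("list", length(snps)), snps)

  # step 1: frequency and call-rate thresholds
  for (s in snps) {
    if (maf[s] < maf_min) reasons[[s]] <- c(reasons[[s]], "low-maf")
    if (gcr[s] < gcr_min) reasons[[s]] <- c(reasons[[s]], "low-gcr")
  }
  alive <- snps[lengths(reasons) == 0]

  # step 2: within-gene complete-LD pruning among survivors.
  # Map position = listing order within the gene in snp_genes.
  map_pos <- stats::setNames(seq_along(snp_genes), names(snp_genes))
  for (g in unique(genes)) {
    members <- alive[genes[alive] == g]
    members <- members[order(map_pos[members])]
    repeat {
      if (length(members) < 2) break
      dropped_one <- FALSE
      pairs <- utils::combn(members, 2, simplify = FALSE)
      for (pr in pairs) {
        pair <- tryCatch(ld_em(x, pr[1], pr[2]), error = function(e) NULL)
        if (!is.null(pair) && pair$r2 >= 1 - r2_tol) {
          # drop the lower-GCR member; tie -> the later map position
          drop_s <- if (gcr[pr[1]] < gcr[pr[2]]) pr[1]
                    else if (gcr[pr[2]] < gcr[pr[1]]) pr[2]
                    else pr[2]
          reasons[[drop_s]] <- c(reasons[[drop_s]], "complete-ld-redundant")
          members <- setdiff(members, drop_s)
          dropped_one <- TRUE
          break
        }
      }
      if (!dropped_one) break
    }
  }
  alive <- snps[lengths(reasons) == 0]

  # step 3: HWE on the unaffected stratum
  for (s in alive) {
    if (!is.na(hwe_p[s]) && hwe_p[s] < hwe_alpha) {
      reasons[[s]] <- c(reasons[[s]], "hwe-violation")
    }
  }

  verdict <- ifelse(lengths(reasons) == 0, "keep", "drop")
  decisions <- data.frame(
    snp_id = snps, gene = unname(genes), maf = unname(maf),
    gcr = unname(gcr), hwe_p = unname(hwe_p), verdict = verdict,
    reasons = vapply(reasons, function(r) paste(r, collapse = ";"), ""),
    stringsAsFactors = FALSE, row.names = NULL)
  kept <- snps[verdict == "keep"]
  excluded_genes <- setdiff(unique(genes), unique(genes[kept]))
  structure(list(decisions = decisions, kept = kept,
                 dropped = setdiff(snps, kept),
                 excluded_genes = excluded_genes,
                 thresholds = list(maf_min = maf_min, gcr_min = gcr_min,
                                   hwe_alpha = hwe_alpha)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  n_genes <- length(unique(x$decisions$gene[x$decisions$verdict == "keep"]))
  cat(sprintf("QC cascade: %d of %d SNPs retained on %d genes\n",
              length(x$kept), nrow(x$decisions), n_genes))
  if (length(x$excluded_genes) > 0) {
    cat("  excluded genes:", paste(x$excluded_genes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a QC report as a delimited table plus JSON
#' @param x a \code{qc_report}
#' @param path output path for the delimited table; a machine-readable JSON
#'   variant goes to \code{<path>.json}
#' @return \code{path}, invisibly
#' @export
write_qc_report <- function(x, path) {
  utils::write.table(x$decisions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(decisions = x$decisions,
                            excluded_genes = x$excluded_genes,
                            thresholds = x$thresholds),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Candidate-gene set arithmetic
#'
#' Intersection and union cardinalities of two candidate-gene lists after
#' case-insensitive symbol normalization (as when merging disease-database
#' gene sets).
#'
#' @param set_a,set_b character vectors of gene symbols
#' @return list with \code{intersection}, \code{union}, and the normalized
#'   member vectors
#' @export
gene_set_summary <- function(set_a, set_b) {
  a <- unique(toupper(trimws(set_a)))
  b <- unique(toupper(trimws(set_b)))
  list(intersection = length(intersect(a, b)),
       union = length(union(a, b)),
       members_intersection = sort(intersect(a, b)),
       members_union = sort(union(a, b)))
}

#' Read a SNP-to-gene map from two-column delimited text
#' @param path file with columns \code{snp_id}, \code{gene} (header optional,
#'   tab or comma separated)
#' @return named character vector snp_id -> gene
#' @export
read_snp_gene_map <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  has_header <- grepl("snp", tolower(header))
  tab <- utils::read.table(path, header = has_header, sep = sep,
                           colClasses = "character")
  stats::setNames(tab[[2]], tab[[1]])
}
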