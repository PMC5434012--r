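#' Cohort of subjects with event-history phenotype and genotype calls
#'
#' A \code{cohort} bundles the subject-level phenotype table (id, event
#' indicator, age, habitual-smoking status) with a character matrix of
#' genotype calls.  The age column holds the onset age for subjects whose
#' event was observed (\code{event = 1}) and the censoring (interview) age
#' otherwise.  Genotype calls use the four-symbol alphabet \code{AA},
#' \code{Aa}, \code{aa}, \code{NA}, with \code{a} the minor allele.
#'
#' @param subjects data.frame with columns \code{id}, \code{event},
#'   \code{age} and optionally \code{smoking} (binary, \code{NA} allowed).
#' @param genotypes character matrix, one row per subject (in the order of
#'   \code{subjects}), one column per SNP; entries in
#'   \code{c("AA", "Aa", "aa", NA)}.  May be \code{NULL} for a
#'   genotype-free cohort.
#' @param metadata named list of free-form metadata.
#'
#' @return An object of class \code{cohort}: a list with elements
#'   \code{subjects}, \code{genotypes}, \code{snp_ids}, \code{metadata}.
#' @export
cohort <- function(subjects, genotypes = NULL, metadata = list()) {
  .stop_if(!is.data.frame(subjects), "subjects must be a data.frame")
  required <- c("id", "event", "age")
  missing_cols <- setdiff(required, names(subjects))
  .stop_if(length(missing_cols) > 0,
           "missing required column(s): ", paste(missing_cols, collapse = ", "))
  subjects$id <- as.character(subjects$id)
  .stop_if(anyDuplicated(subjects$id) > 0, "subject ids must be unique")
  subjects$event <- as.integer(subjects$event)
  .stop_if(!.is_binary01(subjects$event), "event must be 0/1")
  subjects$age <- as.numeric(subjects$age)
  bad_age <- which(!is.finite(subjects$age) | subjects$age <= 0)
  .stop_if(length(bad_age) > 0,
           "non-positive or non-finite age for subject(s): ",
           paste(subjects$id[bad_age], collapse = ", "))
  if (!"smoking" %in% names(subjects)) subjects$smoking <- NA_integer_
  subjects$smoking <- as.integer(subjects$smoking)
  .stop_if(!all(subjects$smoking %in% c(0L, 1L, NA_integer_)),
           "smoking must be 0/1/NA")

  if (is.null(genotypes)) {
    genotypes <- matrix(NA_character_, nrow = nrow(subjects), ncol = 0)
  }
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "character"
  .stop_if(nrow(genotypes) != nrow(subjects),
           "genotypes must have one row per subject")
  ok <- genotypes %in% c("AA", "Aa", "aa") | is.na(genotypes)
  .stop_if(!all(ok), "genotype calls must be AA/Aa/aa/NA after normalization")
  rownames(genotypes) <- subjects$id

  structure(
    list(subjects = subjects[, c("id", "event", "age", "smoking")],
         genotypes = genotypes,
         snp_ids = colnames(genotypes) %||% character(0),
         metadata = metadata),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects (%d events, %d censored), %d SNPs\n",
              n_subjects(x), sum(x$subjects$event),
              sum(1L - x$subjects$event), length(x$snp_ids)))
  if (length(x$snp_ids) > 0) {
    shown <- utils::head(x$snp_ids, 6)
    cat("  SNPs: ", paste(shown, collapse = ", "),
        if (length(x$snp_ids) > 6) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Number of subjects in a cohort
#' @param x a \code{cohort}
#' @return integer count
#' @export
n_subjects <- function(x) nrow(x$subjects)

# ---------------------------------------------------------------------------
# genotype-call normalization

# Accepts AA/Aa/aa (any case arrangement), dosage codes 0/1/2 (copies of the
# "alt" allele), and VCF-style GT strings 0/0, 0/1, 1/1 (either separator).
# Dosage/GT codes are first mapped to hom-ref/het/hom-alt; which homozygote
# is the minor one is decided per SNP from the sample allele frequency, ties
# at 0.5 broken so that the alt allele is called minor (documented,
# lexicographic-order stand-in: alt sorts after ref).
.normalize_calls <- function(x, snp_id = "<snp>") {
  x <- trimws(as.character(x))
  x[x %in% c("NA", ".", "", "./.", ".|.")] <- NA_character_
  out <- rep(NA_character_, length(x))
  up <- toupper(x)
  sym <- !is.na(x) & up %in% c("AA")
  # letter calls: count lower-case 'a' occurrences
  letter <- !is.na(x) & grepl("^[Aa]{2}$", x)
  n_minor_letter <- integer(length(x))
  n_minor_letter[letter] <- vapply(strsplit(x[letter], ""), function(ch) {
    sum(ch == "a")
  }, integer(1))
  out[letter] <- c("AA", "Aa", "aa")[n_minor_letter[letter] + 1L]

  dosage <- !is.na(x) & x %in% c("0", "1", "2")
  gt <- !is.na(x) & grepl("^[01][/|][01]$", x)
  n_alt <- integer(length(x))
  n_alt[dosage] <- as.integer(x[dosage])
  n_alt[gt] <- vapply(strsplit(x[gt], "[/|]"), function(a) {
    sum(a == "1")
  }, integer(1))
  numeric_like <- dosage | gt
  if (any(numeric_like)) {
    alt_freq <- mean(n_alt[numeric_like]) / 2
    # minor allele = lower-frequency allele; tie at 0.5 -> alt is minor
    if (alt_freq <= 0.5) {
      out[numeric_like] <- c("AA", "Aa", "aa")[n_alt[numeric_like] + 1L]
    } else {
      out[numeric_like] <- c("aa", "Aa", "AA")[n_alt[numeric_like] + 1L]
    }
  }

  unparsed <- !is.na(x) & !letter & !numeric_like
  if (any(unparsed)) {
    warning(sprintf("%s: %d unparseable genotype string(s) set to missing (e.g. '%s')",
                    snp_id, sum(unparsed), x[which(unparsed)[1]]),
            call. = FALSE)
  }
  out
}

#' Read a cohort table from delimited text
#'
#' The table must have a header row with columns \code{id}, \code{event},
#' \code{age}, optionally \code{smoking}; every remaining column is taken as
#' a SNP.  Comma or tab separation is auto-detected (or forced via
#' \code{sep}).  Missing tokens are \code{NA}, \code{.} and the empty
#' string.  Genotypes may be letter calls (\code{AA/Aa/aa}), dosages
#' (\code{0/1/2}) or VCF-style \code{0/1} pairs; unparseable strings become
#' missing with a warning.
#'
#' @param path file path.
#' @param sep field separator; \code{NULL} (default) auto-detects tab vs comma.
#' @param max_onset_age optional outlier filter: subjects with an observed
#'   onset age above this threshold are dropped (default \code{NULL}, off).
#' @return a \code{\link{cohort}}.
#' @export
read_cohort <- function(path, sep = NULL, max_onset_age = NULL) {
  .stop_if(!file.exists(path), "file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ".", ""))
  required <- c("id", "event", "age")
  missing_cols <- setdiff(required, names(tab))
  .stop_if(length(missing_cols) > 0,
           "schema error: missing column(s) ", paste(missing_cols, collapse = ", "))

  snp_cols <- setdiff(names(tab), c("id", "event", "age", "smoking"))
  subjects <- data.frame(id = tab$id,
                         event = suppressWarnings(as.integer(tab$event)),
                         age = suppressWarnings(as.numeric(tab$age)),
                         smoking = if ("smoking" %in% names(tab))
                           suppressWarnings(as.integer(tab$smoking)) else NA_integer_,
                         stringsAsFactors = FALSE)
  bad_age <- which(!is.finite(subjects$age) | subjects$age <= 0)
  .stop_if(length(bad_age) > 0,
           "validation error: non-positive age in row(s) ",
           paste(bad_age, collapse = ", "))

  geno <- NULL
  if (length(snp_cols) > 0) {
    geno <- vapply(snp_cols, function(s) .normalize_calls(tab[[s]], s),
                   character(nrow(tab)))
    geno <- matrix(geno, nrow = nrow(tab),
                   dimnames = list(NULL, snp_cols))
  }
  cht <- cohort(subjects, geno, metadata = list(source = path))
  if (!is.null(max_onset_age)) {
    keep <- !(cht$subjects$event == 1L & cht$subjects$age > max_onset_age)
    if (!all(keep)) {
      cht <- cohort(cht$subjects[keep, , drop = FALSE],
                    cht$genotypes[keep, , drop = FALSE],
                    c(cht$metadata, list(max_onset_age = max_onset_age,
                                         n_onset_outliers = sum(!keep))))
    }
  }
  cht
}

#' Write a cohort table (plus a JSON metadata sidecar)
#'
#' @param x a \code{cohort}
#' @param path output path; metadata go to \code{<path>.json}
#' @param sep field separator (default tab)
#' @return \code{path}, invisibly
#' @export
write_cohort <- function(x, path, sep = "\t") {
  tab <- x$subjects
  if (length(x$snp_ids) > 0) {
    tab <- cbind(tab, as.data.frame(x$genotypes, stringsAsFactors = FALSE))
  }
  utils::write.table(tab, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  jsonlite::write_json(x$metadata, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read genotypes from a VCF into a cohort
#'
#' Attaches biallelic-SNP genotype calls from a VCF to an existing cohort's
#' phenotype table (matching on sample id).  Multiallelic records are
#' rejected with a message.  Requires the \pkg{vcfR} package.
#'
#' @param x a \code{cohort} (its phenotype table is kept)
#' @param vcf_path path to an uncompressed or bgzipped VCF
#' @return a \code{cohort} with the VCF-derived genotype matrix
#' @export
read_genotypes_vcf <- function(x, vcf_path) {
  .stop_if(!requireNamespace("vcfR", quietly = TRUE),
           "the vcfR package is required for VCF input")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  .stop_if(any(multi), "multiallelic record(s) rejected: ",
           paste(vcfR::getID(v)[multi], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- vcfR::getID(v)
  samples <- colnames(gt)
  common <- intersect(x$subjects$id, samples)
  .stop_if(length(common) == 0, "no VCF samples match cohort subject ids")
  geno <- matrix(NA_character_, nrow = n_subjects(x), ncol = nrow(gt),
                 dimnames = list(x$subjects$id, ids))
  for (j in seq_len(nrow(gt))) {
    geno[common, j] <- .normalize_calls(gt[j, common], ids[j])
  }
  cohort(x$subjects, geno, c(x$metadata, list(vcf = vcf_path)))
}

# ---------------------------------------------------------------------------
# genotype coding schemes

#' Genotype-to-covariate coding scheme
#'
#' Defines how the three genotype classes map onto regression covariates:
#' \describe{
#'   \item{general}{two indicator covariates for the non-referent genotypes
#'     (default referent \code{Aa}, so the indicators contrast \code{aa} and
#'     \code{AA} against the heterozygote).}
#'   \item{additive}{minor-allele count: \code{AA = 0, Aa = 1, aa = 2}.}
#'   \item{dominant / merged-dominant}{\code{AA = 0, Aa = aa = 1}; the
#'     merged flavour records that it arose from sparse-event merging.}
#'   \item{recessive / merged-recessive}{\code{AA = Aa = 0, aa = 1}.}
#' }
#' The referent genotype always maps to the zero vector.
#'
#' @param scheme one of \code{"general"}, \code{"additive"},
#'   \code{"dominant"}, \code{"recessive"}, \code{"merged-dominant"},
#'   \code{"merged-recessive"}.
#' @param referent referent genotype label; defaults to \code{"Aa"} for the
#'   general scheme and \code{"AA"} otherwise.
#' @return an object of class \code{genotype_coding} with fields
#'   \code{scheme}, \code{referent}, \code{design_map} (genotype -> numeric
#'   vector) and \code{labels} (covariate suffix labels).
#' @export
genotype_coding <- function(scheme = c("general", "additive", "dominant",
                                       "recessive", "merged-dominant",
                                       "merged-recessive"),
                            referent = NULL) {
  scheme <- match.arg(scheme)
  genos <- c("AA", "Aa", "aa")
  if (scheme == "general") {
    referent <- referent %||% "Aa"
    .stop_if(!referent %in% genos, "referent must be AA/Aa/aa")
    others <- setdiff(genos, referent)
    design_map <- lapply(genos, function(g) as.numeric(others == g))
    names(design_map) <- genos
    labels <- others
  } else {
    referent <- referent %||% "AA"
    codes <- switch(scheme,
                    additive = c(AA = 0, Aa = 1, aa = 2),
                    dominant = ,
                    `merged-dominant` = c(AA = 0, Aa = 1, aa = 1),
                    recessive = ,
                    `merged-recessive` = c(AA = 0, Aa = 0, aa = 1))
    design_map <- lapply(genos, function(g) unname(codes[g]))
    names(design_map) <- genos
    labels <- switch(scheme,
                     additive = "add",
                     dominant = , `merged-dominant` = "dom",
                     recessive = , `merged-recessive` = "rec")
  }
  structure(list(scheme = scheme, referent = referent,
                 design_map = design_map, labels = labels,
                 merged = grepl("^merged", scheme)),
            class = "genotype_coding")
}

#' @export
print.genotype_coding <- function(x, ...) {
  cat(sprintf("genotype coding '%s' (referent %s): %s\n", x$scheme, x$referent,
              paste(sprintf("%s=(%s)", names(x$design_map),
                            vapply(x$design_map, paste, "", collapse = ",")),
                    collapse = " ")))
  invisible(x)
}

#' Encode a genotype call under a coding scheme
#'
#' @param call genotype call, one of \code{"AA"}, \code{"Aa"}, \code{"aa"},
#'   or \code{NA}
#' @param coding a \code{\link{genotype_coding}}
#' @return numeric covariate vector (length 2 for the general scheme, 1
#'   otherwise); a missing call yields a vector of \code{NA} of the same
#'   length, the sentinel that excludes the subject from complete cases.
#' @export
encode_genotype <- function(call, coding) {
  k <- length(coding$labels)
  if (length(call) != 1) {
    res <- vapply(call, encode_genotype, numeric(k), coding = coding)
    return(if (k == 1) matrix(res, ncol = 1) else t(res))
  }
  if (is.na(call)) return(rep(NA_real_, k))
  .stop_if(!call %in% names(coding$design_map), "unknown genotype call: ", call)
  coding$design_map[[call]]
}

#' Restrict a cohort to complete cases
#'
#' Drops subjects missing any of the listed genotypes or phenotype
#' covariates, mirroring the per-model complete-case sample sizes of a
#' single-SNP analysis.
#'
#' @param x a \code{cohort}
#' @param snps character vector of SNP ids (may be empty)
#' @param covariates character vector of phenotype covariates, e.g.
#'   \code{"smoking"}
#' @return the filtered \code{cohort}; its metadata records
#'   \code{n_dropped}.  Errors if no subject remains.
#' @export
complete_cases <- function(x, snps = character(0), covariates = character(0)) {
  .stop_if(!all(snps %in% x$snp_ids),
           "unknown SNP id(s): ", paste(setdiff(snps, x$snp_ids), collapse = ", "))
  keep <- rep(TRUE, n_subjects(x))
  for (s in snps) keep <- keep & !is.na(x$genotypes[, s])
  for (cv in covariates) {
    .stop_if(!cv %in% names(x$subjects), "unknown covariate: ", cv)
    keep <- keep & !is.na(x$subjects[[cv]])
  }
  .stop_if(!any(keep), "degenerate input: no complete cases remain")
  cohort(x$subjects[keep, , drop = FALSE],
         x$genotypes[keep, , drop = FALSE],
         c(x$metadata, list(n_dropped = sum(!keep))))
}
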