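#' Command-style pipeline orchestration
#'
#' Dispatches the end-to-end analysis as subcommands over the package's
#' functions, writing every output under \code{out_dir} together with a
#' run manifest (command, arguments, seed, package version, input file
#' digests, output inventory).  Stochastic subcommands require an explicit
#' seed; given identical inputs and seed the numeric outputs are
#' reproducible.
#'
#' Subcommands: \describe{
#'   \item{simulate}{generate a synthetic cohort (\code{--preset table1}
#'     or a default single-SNP config); writes \code{cohort.tsv}.}
#'   \item{qc}{run the QC cascade on \code{--cohort} with
#'     \code{--snp-map}; writes \code{qc_report.tsv(.json)}.}
#'   \item{fit-single}{single-SNP model selection for every SNP (or
#'     \code{--snps}, comma separated); writes
#'     \code{selection_report.tsv(.json)}.}
#'   \item{fit-multi}{joint subset-model search over \code{--snps} using
#'     each SNP's chosen single-SNP coding; writes \code{multi_fit.*}.}
#'   \item{bootstrap}{percentile-bootstrap validation of one SNP's chosen
#'     model (\code{--snps}, first entry); writes
#'     \code{bootstrap_report.tsv(.json)}.}
#'   \item{cluster}{GAP-style Jaccard clustering of carriers/smoking;
#'     writes sorted matrices and Newick trees.}
#'   \item{report}{assemble the per-model coefficient tables written by
#'     fit subcommands into one file.}
#' }
#'
#' @param args character vector of command-line style arguments, e.g.
#'   \code{c("simulate", "--preset", "table1", "--seed", "7",
#'   "--out-dir", "run1")}
#' @return (invisibly) the manifest list; a validation failure raises an
#'   error (nonzero exit under \code{Rscript})
#' @export
pipeline_run <- function(args) {
  .stop_if(length(args) < 1, "usage error: missing subcommand")
  sub <- args[1]
  opts <- .parse_args(args[-1])
  known <- c("simulate", "qc", "fit-single", "fit-multi", "bootstrap",
             "cluster", "report")
  .stop_if(!sub %in% known,
           "usage error: unknown subcommand '", sub, "'")
  out_dir <- opts[["out-dir"]] %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .log("start", sub)

  inputs <- character(0)
  outputs <- character(0)
  seed <- if (!is.null(opts$seed)) as.integer(opts$seed) else NULL

  if (sub == "simulate") {
    .stop_if(is.null(seed), "simulate requires --seed (no clock seeding)")
    config <- if (!is.null(opts$config)) {
      cf <- read_generator_config(opts$config)
      cf$seed <- seed       # the explicit flag wins over the file's seed
      inputs <- c(inputs, opts$config)
      cf
    } else if (identical(opts$preset, "table1")) {
      table1_preset(seed = seed)
    } else {
      generator_config(seed = seed)
    }
    cht <- gen_cohort(config)
    out <- file.path(out_dir, "cohort.tsv")
    write_cohort(cht, out)
    map <- file.path(out_dir, "snp_map.tsv")
    utils::write.table(
      data.frame(snp_id = config$snp_specs$snp_id,
                 gene = config$snp_specs$gene),
      map, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(out, paste0(out, ".json"), map)
  } else if (sub == "qc") {
    cht <- .need_cohort(opts); inputs <- opts$cohort
    .stop_if(is.null(opts[["snp-map"]]), "qc requires --snp-map")
    inputs <- c(inputs, opts[["snp-map"]])
    map <- read_snp_gene_map(opts[["snp-map"]])
    rep <- qc_cascade(cht, map)
    out <- file.path(out_dir, "qc_report.tsv")
    write_qc_report(rep, out)
    outputs <- c(out, paste0(out, ".json"))
  } else if (sub == "fit-single") {
    cht <- .need_cohort(opts); inputs <- opts$cohort
    snps <- .opt_snps(opts) %||% cht$snp_ids
    results <- lapply(snps, function(s) select_model(cht, s))
    out <- file.path(out_dir, "selection_report.tsv")
    write_selection_report(results, out)
    outputs <- c(out, paste0(out, ".json"))
  } else if (sub == "fit-multi") {
    cht <- .need_cohort(opts); inputs <- opts$cohort
    snps <- .opt_snps(opts)
    .stop_if(is.null(snps), "fit-multi requires --snps")
    singles <- lapply(snps, function(s) select_model(cht, s))
    names(singles) <- snps
    spec_list <- lapply(singles, function(r) {
      .stop_if(isTRUE(r$failed), "single-SNP selection failed for ", r$snp_id)
      parts <- if (r$chosen$placement == "none") "location"
               else strsplit(r$chosen$placement, "+", fixed = TRUE)[[1]]
      list(coding = r$chosen$coding %||% genotype_coding("dominant"),
           parts = parts)
    })
    joint <- multi_covariate_search(cht, spec_list,
                                    extra = if (isTRUE(opts$smoking == "yes"))
                                      list(smoking = "location") else list())
    out <- file.path(out_dir, "multi_fit")
    write_fit(joint$fit, out, lrt_result = joint$lrt)
    outputs <- c(paste0(out, ".json"), paste0(out, ".tsv"))
  } else if (sub == "bootstrap") {
    .stop_if(is.null(seed), "bootstrap requires --seed (no clock seeding)")
    cht <- .need_cohort(opts); inputs <- opts$cohort
    snps <- .opt_snps(opts)
    .stop_if(is.null(snps), "bootstrap requires --snps")
    sel <- select_model(cht, snps[1])
    .stop_if(isTRUE(sel$failed), "selection failed for ", snps[1])
    b <- as.integer(opts$resamples %||% 400)
    boot <- bootstrap_mixture(sel$fit, n_resamples = b, seed = seed)
    out <- file.path(out_dir, "bootstrap_report.tsv")
    write_bootstrap_report(boot, out)
    outputs <- c(out, paste0(out, ".json"))
  } else if (sub == "cluster") {
    cht <- .need_cohort(opts); inputs <- opts$cohort
    snps <- .opt_snps(opts) %||% cht$snp_ids
    ba <- binarize(cht, snps)
    gap <- gap_cluster(ba)
    outs <- file.path(out_dir, c("B_sorted.tsv", "G_sorted.tsv",
                                 "P_sorted.tsv", "row_tree.nwk",
                                 "col_tree.nwk"))
    utils::write.table(gap$sorted$B, outs[1], sep = "\t", quote = FALSE)
    utils::write.table(gap$sorted$G, outs[2], sep = "\t", quote = FALSE)
    utils::write.table(gap$sorted$P, outs[3], sep = "\t", quote = FALSE)
    write_tree_newick(gap$row_cluster, outs[4])
    write_tree_newick(gap$col_cluster, outs[5])
    outputs <- outs
  } else if (sub == "report") {
    fits <- list.files(out_dir, pattern = "\\.json$", full.names = TRUE)
    inputs <- fits
    out <- file.path(out_dir, "report.txt")
    con <- file(out, "w")
    for (f in fits) {
      writeLines(c(paste0("== ", basename(f), " =="),
                   readLines(f), ""), con)
    }
    close(con)
    outputs <- out
  }

  manifest <- list(
    command = sub, args = as.list(opts), seed = seed,
    package_version = as.character(utils::packageVersion("eventcure")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = .digests(inputs), outputs = .digests(outputs))
  mpath <- file.path(out_dir, paste0("manifest_", sub, ".json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  .log("done", sub, "->", out_dir)
  invisible(manifest)
}

.parse_args <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    .stop_if(!startsWith(args[i], "--"),
             "usage error: expected --flag, got '", args[i], "'")
    key <- sub("^--", "", args[i])
    .stop_if(i + 1 > length(args), "usage error: --", key, " needs a value")
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

.opt_snps <- function(opts) {
  if (is.null(opts$snps)) NULL else strsplit(opts$snps, ",")[[1]]
}

.need_cohort <- function(opts) {
  .stop_if(is.null(opts$cohort), "this subcommand requires --cohort")
  read_cohort(opts$cohort)
}

.digests <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0) return(list())
  md5 <- tools::md5sum(paths)
  mapply(function(p, h) list(path = p, md5 = unname(h)),
         paths, md5, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

# line-oriented structured logging to stderr
.log <- function(level, ...) {
  message(sprintf("[eventcure] %s: %s", level, paste(..., collapse = " ")))
}
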