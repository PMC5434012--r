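#' Binary subject-by-feature association matrix
#'
#' Codes each subject 1 for a SNP if they carry the minor allele (genotype
#' \code{Aa} or \code{aa}) and 1 for smoking if a habitual smoker; missing
#' genotypes are coded 0 (non-carrier) and counted in a missingness
#' annotation.  Row annotations carry onset status and age for display
#' alongside the sorted matrix.
#'
#' @param x a \code{\link{cohort}}
#' @param snps SNP ids to include
#' @param include_smoking add a habitual-smoking column (default TRUE)
#' @return object of class \code{binary_assoc}: list with \code{values}
#'   (0/1 matrix, rows = subjects), \code{row_covariates} (event, age),
#'   \code{missing} (0/1 matrix marking imputed non-carrier entries)
#' @export
binarize <- function(x, snps, include_smoking = TRUE) {
  .stop_if(!all(snps %in% x$snp_ids),
           "unknown SNP id(s): ", paste(setdiff(snps, x$snp_ids), collapse = ", "))
  g <- x$genotypes[, snps, drop = FALSE]
  vals <- (g %in% c("Aa", "aa"))
  vals <- matrix(as.integer(vals), nrow = nrow(g), dimnames = dimnames(g))
  miss <- matrix(as.integer(is.na(g)), nrow = nrow(g), dimnames = dimnames(g))
  if (include_smoking) {
    smoking <- as.integer(x$subjects$smoking %in% 1L)
    vals <- cbind(vals, smoking = smoking)
    miss <- cbind(miss, smoking = as.integer(is.na(x$subjects$smoking)))
  }
  rownames(vals) <- rownames(miss) <- x$subjects$id
  structure(list(values = vals,
                 row_covariates = x$subjects[, c("id", "event", "age")],
                 missing = miss),
            class = "binary_assoc")
}

#' Jaccard similarity matrix over the rows or columns of a binary matrix
#'
#' \eqn{J(x, y) = |x \wedge y| / |x \vee y|}; a pair of all-zero profiles
#' has similarity 0 by convention (including on the diagonal).
#'
#' @param m 0/1 matrix (or a \code{binary_assoc}, whose \code{values} are
#'   used)
#' @param margin 1 = similarity between rows, 2 = between columns
#' @return symmetric similarity matrix with entries in [0, 1]
#' @export
jaccard_matrix <- function(m, margin = 1) {
  if (inherits(m, "binary_assoc")) m <- m$values
  .stop_if(!all(m %in% c(0, 1)), "matrix entries must be 0/1")
  if (margin == 2) m <- t(m)
  .stop_if(nrow(m) < 2, "need at least 2 profiles")
  inter <- tcrossprod(m)
  sizes <- rowSums(m)
  un <- outer(sizes, sizes, `+`) - inter
  j <- ifelse(un > 0, inter / un, 0)
  dimnames(j) <- list(rownames(m), rownames(m))
  j
}

#' Average-linkage clustering with deterministic leaf ordering
#'
#' Agglomerates on distance \eqn{1 - J} with average linkage, then fixes
#' the leaf order by deterministic flipping of internal nodes: at every
#' merge, among the four orientations of the two subtrees the one
#' minimizing the distance between the adjacent boundary leaves is kept
#' (ties broken by label order).  This is a documented stand-in for
#' elliptical-seriation-guided flipping; it optimizes the same
#' adjacent-leaf-distance objective greedily from the bottom up.
#'
#' @param sim symmetric similarity matrix (e.g. from
#'   \code{\link{jaccard_matrix}})
#' @return object of class \code{cluster_result}: list with \code{tree}
#'   (an \code{hclust}), \code{order} (leaf permutation, by index),
#'   \code{labels}
#' @export
cluster_order <- function(sim) {
  .stop_if(!isSymmetric(unname(sim), tol = 1e-12), "similarity matrix must be symmetric")
  labels <- rownames(sim) %||% as.character(seq_len(nrow(sim)))
  d <- stats::as.dist(1 - sim)
  tree <- stats::hclust(d, method = "average")
  dm <- as.matrix(d)
  n <- nrow(sim)

  # recursively resolve leaf order; each node returns its ordered leaves,
  # choosing among the 4 child orientations
  resolve <- function(node) {
    if (node < 0) return(-node)
    left <- resolve(tree$merge[node, 1])
    right <- resolve(tree$merge[node, 2])
    best <- NULL
    best_key <- NULL
    for (lo in list(left, rev(left))) {
      for (ro in list(right, rev(right))) {
        gap <- dm[lo[length(lo)], ro[1]]
        cand <- c(lo, ro)
        # tie-break deterministically on the label sequence
        key <- list(gap, labels[cand])
        if (is.null(best) || gap < best_key[[1]] - 1e-12 ||
            (abs(gap - best_key[[1]]) <= 1e-12 &&
             paste(labels[cand], collapse = "\r") <
             paste(labels[best], collapse = "\r"))) {
          best <- cand
          best_key <- key
        }
      }
    }
    best
  }
  ord <- if (n == 1) 1L else resolve(nrow(tree$merge))
  tree$order <- as.integer(ord)
  tree$labels <- labels
  structure(list(tree = tree, order = as.integer(ord), labels = labels),
            class = "cluster_result")
}

#' Full GAP-style clustering of a binary association matrix
#'
#' Computes the row (subject) and column (feature) Jaccard similarity
#' matrices G and P, clusters both axes, and returns the sorted triplet
#' (B, G, P) with annotations.
#'
#' @param b a \code{binary_assoc} or plain 0/1 matrix
#' @return object of class \code{gap_result}: list with \code{B}, \code{G},
#'   \code{P} (unsorted), \code{row_cluster}, \code{col_cluster},
#'   \code{sorted} (list B, G, P permuted by the clustering orders,
#'   with row covariates attached when available)
#' @export
gap_cluster <- function(b) {
  ba <- if (inherits(b, "binary_assoc")) b else
    structure(list(values = b, row_covariates = NULL, missing = NULL),
              class = "binary_assoc")
  g <- jaccard_matrix(ba$values, margin = 1)
  p <- jaccard_matrix(ba$values, margin = 2)
  rc <- cluster_order(g)
  cc <- cluster_order(p)
  structure(list(B = ba$values, G = g, P = p,
                 row_cluster = rc, col_cluster = cc,
                 sorted = sorted_export(ba, rc, cc)),
            class = "gap_result")
}

#' Sort the association-matrix triplet by the clustering orders
#'
#' @param b a \code{binary_assoc} (or 0/1 matrix)
#' @param row_cluster,col_cluster \code{cluster_result}s for the two axes
#' @return list with \code{B}, \code{G}, \code{P} permuted, plus
#'   \code{row_covariates} reordered alongside when present
#' @export
sorted_export <- function(b, row_cluster, col_cluster) {
  vals <- if (inherits(b, "binary_assoc")) b$values else b
  ro <- row_cluster$order
  co <- col_cluster$order
  g <- jaccard_matrix(vals, 1)[ro, ro, drop = FALSE]
  p <- jaccard_matrix(vals, 2)[co, co, drop = FALSE]
  out <- list(B = vals[ro, co, drop = FALSE], G = g, P = p)
  if (inherits(b, "binary_assoc") && !is.null(b$row_covariates)) {
    out$row_covariates <- b$row_covariates[ro, , drop = FALSE]
  }
  out
}

#' Export a merge tree in Newick format
#'
#' @param x a \code{cluster_result}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_tree_newick <- function(x, path) {
  phy <- ape::as.phylo(x$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read a gene-by-pathway binary membership table
#'
#' Delimited text with gene symbols in the first column, one column per
#' pathway (0/1 membership); an optional \code{category} row (first column
#' \code{"category"}) annotates each pathway with its top-level category.
#'
#' @param path file path
#' @return list with \code{values} (0/1 matrix genes x pathways) and
#'   \code{categories} (named character vector, possibly empty)
#' @export
read_gene_pathway <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character")
  cat_row <- tab[[1]] == "category"
  categories <- character(0)
  if (any(cat_row)) {
    categories <- unlist(tab[which(cat_row)[1], -1])
    tab <- tab[!cat_row, , drop = FALSE]
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "integer"
  rownames(vals) <- tab[[1]]
  list(values = vals, categories = categories)
}
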