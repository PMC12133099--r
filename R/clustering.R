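# Replicate-agreement QC and hierarchical clustering of growth conditions
# by regulatory response. Rows are experiments (condition, replicate),
# columns are (promoter, position) MI values; distance is 1 - Pearson on
# pairwise-complete columns and linkage is average (UPGMA).

#' Assemble a condition x position MI matrix from footprints
#'
#' @param footprints named list of `footprint` objects (or numeric MI
#'   vectors); names become row labels, typically "condition_rep".
#' @return numeric matrix (experiments x positions) with a
#'   `condition_matrix` class; missing values stay NA (masked, never
#'   zero-filled).
#' @export
condition_matrix <- function(footprints) {
  rows <- lapply(footprints, function(f) {
    if (inherits(f, "footprint")) f$mi else as.numeric(f)
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1) {
    stop("footprints must cover the same positions (align/merge first)",
         call. = FALSE)
  }
  m <- do.call(rbind, rows)
  rownames(m) <- names(footprints) %||%
    paste0("exp", seq_along(footprints))
  class(m) <- c("condition_matrix", class(m))
  m
}

#' Replicate-agreement quality control
#'
#' Computes the pairwise Pearson correlation matrix over the experiments'
#' concatenated MI vectors, each experiment's mean correlation to all
#' others, and flags experiments below `threshold` for exclusion.
#'
#' @param mat a [condition_matrix()] (or plain matrix, experiments in
#'   rows), or a list of footprints.
#' @param threshold minimum mean correlation to the other experiments
#'   (default 0.2, deliberately conservative).
#' @return list with `correlations` (n x n), `mean_correlation` (per
#'   experiment), `excluded` (logical), `threshold`.
#' @export
replicate_qc <- function(mat, threshold = 0.2) {
  if (is.list(mat) && !is.matrix(mat)) mat <- condition_matrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 experiments", call. = FALSE)
  if (threshold > 1) {
    warning("threshold > 1 flags every experiment")
  }
  cc <- cor(t(mat), use = "pairwise.complete.obs")
  mean_r <- (rowSums(cc, na.rm = TRUE) - 1) / (nrow(cc) - 1)
  excluded <- mean_r < threshold
  list(correlations = cc, mean_correlation = mean_r,
       excluded = excluded, threshold = threshold)
}

#' Hierarchically cluster experiments by footprint similarity
#'
#' Distance between two experiments is 1 - Pearson correlation computed
#' over their mutually observed columns (pairwise-complete); linkage is
#' average (UPGMA). Rows with zero variance, or with fewer than
#' `min_overlap` mutually observed columns against some other row, are
#' excluded with a warning. Ties are broken deterministically by row
#' order (stats::hclust convention).
#'
#' @param mat a [condition_matrix()] or list of footprints.
#' @param linkage agglomeration method (default "average").
#' @param min_overlap minimum mutually observed columns per pair
#'   (default 50).
#' @return an object of class `regland_dendrogram` wrapping the `hclust`
#'   result (`$hclust`, `$labels`, `$distance`).
#' @export
cluster_conditions <- function(mat, linkage = "average", min_overlap = 50L) {
  if (is.list(mat) && !is.matrix(mat)) mat <- condition_matrix(mat)
  keep <- apply(mat, 1L, function(r) sd(r, na.rm = TRUE) > 0)
  if (any(!keep)) {
    warning("excluding zero-variance row(s): ",
            paste(rownames(mat)[!keep], collapse = ", "))
    mat <- mat[keep, , drop = FALSE]
  }
  if (nrow(mat) < 2) stop("need at least 2 usable experiments", call. = FALSE)
  n <- nrow(mat)
  obs <- !is.na(mat)
  overlap <- obs %*% t(obs)
  bad <- which(overlap < min_overlap & row(overlap) != col(overlap),
               arr.ind = TRUE)
  if (nrow(bad)) {
    drop <- unique(bad[, 1])
    warning("dropping row(s) with < ", min_overlap,
            " mutually observed positions: ",
            paste(rownames(mat)[drop], collapse = ", "))
    mat <- mat[-drop, , drop = FALSE]
    if (nrow(mat) < 2) stop("fewer than 2 rows after overlap filter",
                            call. = FALSE)
  }
  cc <- cor(t(mat), use = "pairwise.complete.obs")
  d <- as.dist(1 - cc)
  hc <- hclust(d, method = linkage)
  structure(list(hclust = hc, labels = rownames(mat), distance = d,
                 linkage = linkage),
            class = "regland_dendrogram")
}

#' @export
print.regland_dendrogram <- function(x, ...) {
  cat("dendrogram over", length(x$labels), "experiments (",
      x$linkage, "linkage )\n")
  invisible(x)
}

#' Cluster one promoter's conditions, optionally restricted to SITES calls
#'
#' Runs [cluster_conditions()] on the promoter's footprints, keeping only
#' experiments classified SITES when `restrict_to_sites` is TRUE (the
#' conditions in which binding sites were found). With fewer than two
#' eligible experiments this is an informative no-op returning NULL.
#'
#' @param footprints named list of the promoter's footprints.
#' @param classifications optional list/vector of class labels parallel to
#'   `footprints` (from [classify_footprint()]; objects or label strings).
#' @param restrict_to_sites keep only SITES-class experiments
#'   (default TRUE when classifications are given).
#' @param ... passed to [cluster_conditions()].
#' @return a `regland_dendrogram`, or NULL (with a message) when fewer
#'   than 2 experiments are eligible.
#' @export
cluster_promoter_conditions <- function(footprints, classifications = NULL,
                                        restrict_to_sites =
                                          !is.null(classifications), ...) {
  if (restrict_to_sites && !is.null(classifications)) {
    labels <- vapply(classifications, function(cl) {
      if (inherits(cl, "footprint_class")) cl$label else as.character(cl)
    }, "")
    footprints <- footprints[labels == "SITES"]
  }
  if (length(footprints) < 2) {
    message("fewer than 2 eligible experiments; nothing to cluster")
    return(invisible(NULL))
  }
  cluster_conditions(footprints, ...)
}

#' Serialize a dendrogram to Newick
#'
#' Branch lengths derive from the merge heights (each node sits at half
#' its merge height, the ultrametric convention). The output parses back
#' to the same topology and heights.
#'
#' @param dend a `regland_dendrogram` (or `hclust`).
#' @return a Newick string (with trailing semicolon).
#' @export
to_newick <- function(dend) {
  hc <- if (inherits(dend, "regland_dendrogram")) dend$hclust else dend
  ape::write.tree(ape::as.phylo(hc))
}

#' @rdname to_newick
#' @param text a Newick string.
#' @return `from_newick`: an `ape::phylo` tree.
#' @export
from_newick <- function(text) {
  ape::read.tree(text = text)
}
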