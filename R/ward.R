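# Ward minimum-variance hierarchical clustering on retained-PC coordinates,
# tree cutting, and the linkage-method comparison harness.

#' Ward.D2 hierarchical clustering
#'
#' Agglomerative clustering of Euclidean distances under the Ward.D2
#' criterion (heights on the distance scale: merging clusters A and B costs
#' `sqrt(2 |A||B| / (|A|+|B|)) * ||mean_A - mean_B||`, i.e. the square root
#' of twice the increase in within-cluster sum of squares). Computed via
#' [stats::hclust()].
#'
#' @param points numeric matrix (observations x coordinates), typically the
#'   scores of the components retained by [select_components()]; rownames
#'   are used as leaf labels.
#' @param method linkage method passed to [stats::hclust()]
#'   (default `"ward.D2"`).
#' @return an object of class `variant_dendro` wrapping the `hclust` fit:
#'   elements `hclust`, `labels`, `method`.
#' @export
ward_linkage <- function(points, method = "ward.D2") {
  X <- as.matrix(points)
  if (nrow(X) < 2L) stop("hierarchical clustering requires >= 2 points")
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
  hc <- stats::hclust(stats::dist(X), method = method)
  structure(list(hclust = hc, labels = hc$labels, method = method),
            class = "variant_dendro")
}

#' @export
print.variant_dendro <- function(x, ...) {
  cat("Hierarchical clustering (", x$method, "): ", length(x$labels),
      " leaves, max height ", signif(max(x$hclust$height), 4), "\n", sep = "")
  invisible(x)
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k-1 highest merges. Ties at the cut height are resolved by
#' merge order (the order in which [stats::hclust()] recorded them).
#'
#' @param dend a `variant_dendro` (or `hclust`).
#' @param k number of clusters, `1 <= k <= n`.
#' @return named integer assignment vector.
#' @export
cut_dendrogram <- function(dend, k) {
  hc <- if (inherits(dend, "variant_dendro")) dend$hclust else dend
  n <- length(hc$labels)
  if (k < 1L || k > n) stop("k must be in 1..", n)
  stats::cutree(hc, k = k)
}

#' Compare linkage methods by reference-variant resolution
#'
#' For each linkage method, clusters `points`, cuts the tree at `k`
#' clusters, and scores how cleanly the cut separates wild-type from
#' MODY-reference variants: the Adjusted Rand Index between the induced
#' partition of the reference variants and the WILD_TYPE / MODY_REFERENCE
#' dichotomy. Reported sorted by score (best first).
#'
#' @param points numeric matrix with rownames.
#' @param methods linkage methods to compare.
#' @param references data.frame with columns `variant` and
#'   `reference_role`; must contain at least one WILD_TYPE and one
#'   MODY_REFERENCE variant present in `points`.
#' @param k number of clusters at which to cut; defaults to the
#'   [optimal_k()] winner.
#' @param seed seed for the default-k vote.
#' @return data.frame `method`, `ari`, sorted by decreasing `ari`.
#' @export
compare_linkages <- function(points,
                             methods = c("ward.D2", "complete", "single", "average"),
                             references, k = NULL, seed = 1L) {
  X <- as.matrix(points)
  refs <- references[references$reference_role %in%
                       c("WILD_TYPE", "MODY_REFERENCE"), , drop = FALSE]
  refs <- refs[refs$variant %in% rownames(X), , drop = FALSE]
  if (!nrow(refs) || length(unique(refs$reference_role)) < 2L) {
    stop("need WILD_TYPE and MODY_REFERENCE variants among the points")
  }
  if (is.null(k)) k <- optimal_k(X, seed = seed)$winner
  ari <- vapply(methods, function(m) {
    cl <- cut_dendrogram(ward_linkage(X, method = m), k)
    mclust::adjustedRandIndex(cl[refs$variant],
                              as.integer(refs$reference_role == "WILD_TYPE"))
  }, 0)
  out <- data.frame(method = methods, ari = unname(ari),
                    stringsAsFactors = FALSE)
  out[order(-out$ari), , drop = FALSE]
}
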