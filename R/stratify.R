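# The fitting-style front end: polish -> PCA -> component selection ->
# k-means (with validity vote) -> Ward clustering -> zone annotation, as a
# single classed fit object with print/summary/plot methods.

#' Stratify variants from multi-assay functional data
#'
#' Runs the full single-laboratory stratification: polishing (EMSA
#' exclusion, replicate aggregation, position scores, standardization),
#' principal component analysis, retention of the components explaining
#' more than `threshold` of the variance, k-means clustering in retained-PC
#' space (with a five-index validity vote for k when `k` is NULL), Ward.D2
#' hierarchical clustering on the same coordinates, and — when reference
#' variants are present — zone annotation of the k-means clusters along the
#' benign / T2D-risk / MODY continuum.
#'
#' @param ds a [functional_dataset()] at `CONTROL_NORMALIZED` level for one
#'   laboratory.
#' @param annotations a [variant_annotation()] covering all variants.
#' @param threshold cumulative variance share for component retention.
#' @param k number of k-means clusters; NULL to vote via [optimal_k()].
#' @param k_range candidate k values for the vote.
#' @param seed integer seed for all stochastic steps.
#' @param config a [polish_config()].
#' @return an object of class `hnf1a_strat` with elements `polished`,
#'   `pca`, `n_components`, `contributions`, `kvote` (NULL when `k` was
#'   given), `kmeans`, `ward`, `zones` (NULL without references), `seed`,
#'   `call`.
#' @export
stratify_variants <- function(ds, annotations, threshold = 0.85, k = NULL,
                              k_range = 2:8, seed = 1L,
                              config = polish_config()) {
  polished <- polish_dataset(ds, annotations, config)
  decomp <- pca(polished)
  m <- select_components(decomp, threshold)
  contrib <- variable_contributions(decomp, m)
  pts <- decomp$scores[, seq_len(m), drop = FALSE]
  kvote <- NULL
  if (is.null(k)) {
    k_range <- k_range[k_range < nrow(pts)]
    kvote <- optimal_k(pts, k_range = k_range, seed = seed)
    k <- kvote$winner
  }
  km <- km_cluster(pts, k, seed = seed)
  ward <- ward_linkage(pts)
  zones <- NULL
  refs <- annotations[annotations$reference_role != "NONE", , drop = FALSE]
  if (nrow(refs) && any(refs$variant %in% names(km$assignment))) {
    zones <- annotate_zones(km$assignment, refs, points = pts)
  }
  structure(list(polished = polished, pca = decomp, n_components = m,
                 contributions = contrib, kvote = kvote, kmeans = km,
                 ward = ward, zones = zones, threshold = threshold,
                 seed = seed, call = match.call()),
            class = "hnf1a_strat")
}

#' @export
print.hnf1a_strat <- function(x, ...) {
  cat("HNF1A variant stratification\n")
  cat("  ", nrow(x$polished), " variants, ", ncol(x$polished),
      " variables; ", x$n_components, " PCs retained (>",
      100 * x$threshold, "% variance)\n", sep = "")
  cat("  k-means k =", x$kmeans$k,
      if (!is.null(x$kvote)) "(validity-index vote)" else "(fixed)", "\n")
  if (!is.null(x$zones)) {
    cat("  zones:", paste(x$zones$zone, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.hnf1a_strat <- function(object, ...) {
  x <- object
  cat("Variance shares:",
      paste(sprintf("%.3f", x$pca$variance_share), collapse = " "), "\n")
  cat("Retained components:", x$n_components, "\n\n")
  print(x$contributions)
  cat("\n")
  if (!is.null(x$kvote)) print(x$kvote)
  print(x$kmeans)
  if (!is.null(x$zones)) {
    cat("\nCluster zones:\n")
    print(as.data.frame(x$zones))
  }
  invisible(x)
}

#' Plot a stratification fit
#'
#' @param x an `hnf1a_strat` object.
#' @param type `"pc"` (PC1/PC2 scatter colored by cluster), `"scree"`
#'   (variance shares) or `"dendrogram"`.
#' @param ... passed to the underlying plot call.
#' @export
plot.hnf1a_strat <- function(x, type = c("pc", "scree", "dendrogram"), ...) {
  type <- match.arg(type)
  if (type == "scree") {
    graphics::barplot(100 * x$pca$variance_share,
                      names.arg = seq_along(x$pca$variance_share),
                      xlab = "Principal component",
                      ylab = "Variance explained (%)", ...)
  } else if (type == "dendrogram") {
    plot(x$ward$hclust, xlab = "", sub = "",
         ylab = "Ward.D2 height", ...)
  } else {
    s <- x$pca$scores
    graphics::plot(s[, 1L], s[, 2L], col = x$kmeans$assignment, pch = 19,
                   xlab = sprintf("PC1 (%.0f%%)", 100 * x$pca$variance_share[1]),
                   ylab = sprintf("PC2 (%.0f%%)", 100 * x$pca$variance_share[2]),
                   ...)
  }
  invisible(x)
}
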