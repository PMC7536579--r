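# Principal component decomposition of the polished matrix, component
# selection at a cumulative-variance threshold, and per-variable
# contribution decomposition.

#' Principal component analysis of a polished matrix
#'
#' Eigendecomposition of the sample covariance of the (already column
#' centered and unit-variance scaled) polished matrix, computed via
#' [stats::prcomp()]. Columns are re-centered defensively; no rescaling is
#' applied, so standardization remains the polishing step's responsibility.
#' A deterministic sign convention is applied: each loading vector is
#' flipped so that its largest-magnitude entry is positive, making scores
#' and loadings reproducible across platforms.
#'
#' @param x numeric matrix (variants x variables), e.g. a
#'   [polish_dataset()] result; at least 2 rows, no constant columns unless
#'   the matrix is rank deficient by construction.
#' @return an object of class `pca_decomp` with elements `scores`
#'   (variants x components), `loadings` (variables x components, unit
#'   norm), `variance_share` (non-increasing, sums to 1), `sdev`,
#'   `n_variants`, `n_variables`.
#' @export
pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA requires at least 2 rows")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  loadings <- p$rotation
  scores <- p$x
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- p$sdev^2
  structure(list(scores = scores,
                 loadings = loadings,
                 variance_share = ev / sum(ev),
                 sdev = p$sdev,
                 n_variants = nrow(x),
                 n_variables = ncol(x)),
            class = "pca_decomp")
}

#' @export
print.pca_decomp <- function(x, ...) {
  cat("PCA decomposition:", x$n_variants, "variants,", x$n_variables,
      "variables\n")
  cat("Variance shares:",
      paste(sprintf("%.3f", x$variance_share), collapse = " "), "\n")
  invisible(x)
}

#' Number of components exceeding a cumulative-variance threshold
#'
#' Returns the smallest number of leading components whose cumulative
#' variance share strictly exceeds `threshold` (the >85% rule by default).
#' With `threshold = 1`, all components with nonzero share are returned.
#'
#' @param decomp a [pca()] result.
#' @param threshold cumulative variance share in (0, 1].
#' @return integer component count.
#' @export
select_components <- function(decomp, threshold = 0.85) {
  stopifnot(inherits(decomp, "pca_decomp"), threshold > 0, threshold <= 1)
  cs <- cumsum(decomp$variance_share)
  m <- which(cs > threshold)
  if (length(m)) m[1L] else sum(decomp$variance_share > 1e-12)
}

#' Per-variable contributions to the retained components
#'
#' The contribution of variable j to component m is 100 x its squared
#' loading (unit-norm loadings make each component's contributions sum to
#' 100). The overall contribution pools the retained components, weighting
#' each component's contributions by its variance share.
#'
#' @param decomp a [pca()] result.
#' @param n_components number of leading components to retain (e.g. from
#'   [select_components()]).
#' @return an object of class `contribution_table`: list with
#'   `per_component` (variables x components matrix of percentages),
#'   `overall` (named vector of percentages, sums to 100) and
#'   `variance_share` of the retained components.
#' @export
variable_contributions <- function(decomp, n_components = select_components(decomp)) {
  stopifnot(inherits(decomp, "pca_decomp"),
            n_components >= 1L, n_components <= ncol(decomp$loadings))
  m <- seq_len(n_components)
  per_comp <- 100 * decomp$loadings[, m, drop = FALSE]^2
  w <- decomp$variance_share[m]
  overall <- drop(per_comp %*% w) / sum(w)
  structure(list(per_component = per_comp,
                 overall = overall,
                 variance_share = w),
            class = "contribution_table")
}

#' @export
print.contribution_table <- function(x, ...) {
  cat("Variable contributions over", ncol(x$per_component),
      "retained components (%):\n")
  ord <- order(x$overall, decreasing = TRUE)
  print(round(x$overall[ord], 2))
  invisible(x)
}
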