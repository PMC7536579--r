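# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files beyond the curated registry tables.

# Small long-format functional dataset built by hand.
toy_functional <- function(values = c(0.8, 1.0, 1.2), variant = "p.Ala98Val",
                           lab = "Oxford", assay = "TA_HeLa_ALB") {
  functional_dataset(data.frame(
    variant = variant, lab = lab, assay = assay,
    replicate = seq_along(values), value = values,
    stringsAsFactors = FALSE
  ), "CONTROL_NORMALIZED")
}

# Planted Gaussian blobs with labels.
make_blobs <- function(n_per = 15, centers = rbind(c(0, 0), c(4, 0), c(0, 4)),
                       sd = 0.3, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    sweep(matrix(stats::rnorm(n_per * ncol(centers), 0, sd), n_per),
          2, centers[i, ], "+")
  }))
  rownames(X) <- sprintf("v%02d", seq_len(nrow(X)))
  list(points = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# Random hierarchical tree over n labelled leaves (via hclust on random
# points), as both the package tree form and the hclust wrapper.
random_dtree <- function(n, seed) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * 2), n)
  rownames(X) <- letters[seq_len(n)]
  as_dtree(ward_linkage(X))
}

# Brute-force Ward.D2 oracle: at each step recompute the Ward merge cost
# sqrt(2 |A||B| / (|A|+|B|)) * ||mean_A - mean_B|| over all cluster pairs
# and merge the cheapest (ties: smallest first index). Returns merge
# heights and the leaf-set of each merge for comparison with hclust.
bruteforce_ward <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), function(i) i)
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq.int(i + 1L, length(clusters))) {
        a <- clusters[[i]]; b <- clusters[[j]]
        ma <- colMeans(X[a, , drop = FALSE])
        mb <- colMeans(X[b, , drop = FALSE])
        cost <- sqrt(2 * length(a) * length(b) / (length(a) + length(b))) *
          sqrt(sum((ma - mb)^2))
        if (is.null(best) || cost < best$cost - 1e-12) {
          best <- list(cost = cost, i = i, j = j)
        }
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    heights <- c(heights, best$cost)
    merges <- c(merges, list(merged))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  list(heights = heights, merges = merges)
}

# Leaf-sets of each hclust merge, sorted, for oracle comparison.
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    members <- function(x) if (x < 0) -x else sets[[x]]
    sets[[i]] <- sort(c(members(hc$merge[i, 1]), members(hc$merge[i, 2])))
  }
  sets
}

# Exhaustive minimum within-cluster SS over all partitions of n points
# into at most k non-empty groups.
bruteforce_kmeans_wss <- function(X, k) {
  n <- nrow(X)
  assign_next <- function(assignment, i, n_used) {
    if (i > n) {
      wss <- 0
      for (g in unique(assignment)) {
        pts <- X[assignment == g, , drop = FALSE]
        wss <- wss + sum(sweep(pts, 2, colMeans(pts))^2)
      }
      return(wss)
    }
    best <- Inf
    for (g in seq_len(min(n_used + 1L, k))) {
      assignment[i] <- g
      best <- min(best, assign_next(assignment, i + 1L, max(n_used, g)))
    }
    best
  }
  assign_next(integer(n), 1L, 0L)
}

# Default-condition recovery study used by the acceptance tests: polish the
# Oxford half of the default panel for one seed and return everything the
# criteria measure. Cached across test files.
recovery_run <- local({
  cache <- list()
  function(seed) {
    key <- as.character(seed)
    if (!is.null(cache[[key]])) return(cache[[key]])
    panel <- generate_panel(panel_spec(seed = seed))
    ds <- panel$dataset
    sub <- functional_dataset(
      as.data.frame(ds)[ds$lab == "Oxford", , drop = FALSE],
      "CONTROL_NORMALIZED")
    pol <- polish_dataset(sub, panel$annotations)
    dec <- pca(pol)
    m <- select_components(dec)
    pts <- dec$scores[, seq_len(m), drop = FALSE]
    truth <- panel$truth$class_label[match(rownames(pts), panel$truth$variant)]
    out <- list(panel = panel, polished = pol, pca = dec, m = m,
                points = pts, truth = truth,
                kvote = optimal_k(pts, seed = seed),
                km = km_cluster(pts, 3, seed = seed),
                ward = ward_linkage(pts),
                contrib = variable_contributions(dec, m))
    cache[[key]] <<- out
    out
  }
})
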