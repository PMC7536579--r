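# k-means in PC space (k-means++ initialization, Lloyd iterations, best of
# n_init restarts) and a five-index validity vote for the optimal number of
# clusters.

sq_dist <- function(X, C) {
  # n x k matrix of squared Euclidean distances, clamped at 0 for roundoff
  d <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
  d[d < 0] <- 0
  d
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- sq_dist(X, X[centers[1L], , drop = FALSE])[, 1L]
    for (j in 2:k) {
      if (all(d2 == 0)) {
        centers[j] <- sample.int(n, 1L)
      } else {
        centers[j] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, sq_dist(X, X[centers[j], , drop = FALSE])[, 1L])
    }
  }
  X[centers, , drop = FALSE]
}

lloyd <- function(X, centers, max_iter = 100L) {
  n <- nrow(X)
  k <- nrow(centers)
  prev_wss <- Inf
  assignment <- rep(0L, n)
  for (iter in seq_len(max_iter)) {
    d2 <- sq_dist(X, centers)
    new_assignment <- max.col(-d2, ties.method = "first")
    # repair empty clusters: reseed with the point farthest from its centroid
    repeat {
      sizes <- tabulate(new_assignment, k)
      empty <- which(sizes == 0L)
      if (!length(empty)) break
      cur <- d2[cbind(seq_len(n), new_assignment)]
      donors <- which(sizes[new_assignment] > 1L)
      far <- donors[which.max(cur[donors])]
      new_assignment[far] <- empty[1L]
      centers[empty[1L], ] <- X[far, ]
      d2[, empty[1L]] <- sq_dist(X, centers[empty[1L], , drop = FALSE])[, 1L]
    }
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(X[new_assignment == j, , drop = FALSE])
    }
    wss <- sum(sq_dist(X, centers)[cbind(seq_len(n), new_assignment)])
    if (wss > prev_wss + 1e-8) {
      stop("internal error: within-cluster SS increased across a Lloyd iteration")
    }
    converged <- identical(new_assignment, assignment)
    assignment <- new_assignment
    prev_wss <- wss
    if (converged) break
  }
  list(assignment = assignment, centers = centers, wss = prev_wss,
       iterations = iter)
}

#' k-means clustering with k-means++ restarts
#'
#' Lloyd iterations from `n_init` k-means++ initializations; the restart
#' with the lowest total within-cluster sum of squares is kept. Empty
#' clusters are repaired by reseeding with the point farthest from its
#' current centroid. Deterministic given `seed`. The within-cluster sum of
#' squares is asserted to be non-increasing across Lloyd iterations on
#' every run.
#'
#' @param points numeric matrix (observations x coordinates), typically
#'   retained-PC scores.
#' @param k number of clusters, `1 <= k <= nrow(points)`.
#' @param seed integer seed.
#' @param n_init number of k-means++ restarts.
#' @param max_iter Lloyd iteration cap per restart.
#' @return an object of class `km_fit`: `assignment` (named integer
#'   vector), `centroids`, `within_ss`, `k`, `seed`, `n_init`.
#' @export
km_cluster <- function(points, k, seed = 1L, n_init = 25L, max_iter = 100L) {
  X <- as.matrix(points)
  n <- nrow(X)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k (", k, ") exceeds the number of points (", n, ")")
  best <- NULL
  with_seed(seed, {
    for (i in seq_len(n_init)) {
      fit <- lloyd(X, kmeanspp_init(X, k), max_iter)
      if (is.null(best) || fit$wss < best$wss - 1e-12) best <- fit
    }
  })
  assignment <- best$assignment
  names(assignment) <- rownames(X)
  structure(list(assignment = assignment, centroids = best$centers,
                 within_ss = best$wss, k = k, seed = seed, n_init = n_init),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("k-means fit: k =", x$k, " within-SS =", signif(x$within_ss, 6),
      "\nCluster sizes:", paste(tabulate(x$assignment, x$k), collapse = " "),
      "\n")
  invisible(x)
}

# ---- validity indices -------------------------------------------------

index_silhouette <- function(X, fits, d) {
  vapply(fits, function(f) {
    mean(cluster::silhouette(f$assignment, d)[, "sil_width"])
  }, 0)
}

index_ch <- function(X, fits) {
  n <- nrow(X)
  tot <- sum(scale(X, scale = FALSE)^2)
  vapply(fits, function(f) {
    b <- tot - f$within_ss
    (b / (f$k - 1)) / (f$within_ss / (n - f$k))
  }, 0)
}

index_db <- function(X, fits) {
  vapply(fits, function(f) {
    k <- f$k
    s <- vapply(seq_len(k), function(j) {
      pts <- X[f$assignment == j, , drop = FALSE]
      sqrt(mean(sq_dist(pts, f$centroids[j, , drop = FALSE])))
    }, 0)
    dc <- sqrt(sq_dist(f$centroids, f$centroids))
    r <- vapply(seq_len(k), function(i) {
      max(vapply(setdiff(seq_len(k), i),
                 function(j) (s[i] + s[j]) / dc[i, j], 0))
    }, 0)
    mean(r)
  }, 0)
}

log_wss <- function(X, ks, seed, n_init) {
  vapply(seq_along(ks), function(i) {
    log(km_cluster(X, ks[i], seed = seed + i, n_init = n_init)$within_ss)
  }, 0)
}

# Gap statistic with a uniform reference over the bounding box, B draws,
# one-standard-error rule.
index_gap <- function(X, ks, fits, seed, B = 50L, ref_n_init = 5L) {
  obs <- vapply(fits, function(f) log(f$within_ss), 0)
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  ref <- with_seed(seed, {
    sapply(seq_len(B), function(b) {
      Xb <- sapply(seq_along(lo), function(j) stats::runif(nrow(X), lo[j], hi[j]))
      log_wss(Xb, ks, seed = seed + 97L * b, n_init = ref_n_init)
    })
  })
  gap <- rowMeans(ref) - obs
  se <- apply(ref, 1L, stats::sd) * sqrt(1 + 1 / B)
  # smallest k with gap(k) >= gap(k+1) - se(k+1); fall back to argmax
  best <- NA_integer_
  for (i in seq_len(length(ks) - 1L)) {
    if (gap[i] >= gap[i + 1L] - se[i + 1L]) { best <- ks[i]; break }
  }
  if (is.na(best)) best <- ks[which.max(gap)]
  list(gap = gap, se = se, best = best)
}

# Hartigan/elbow: H(k) = (W_k / W_{k+1} - 1) (n - k - 1) measures the
# benefit of the k -> k+1 split; the elbow is the k whose own split gain
# most exceeds the next one's (largest drop H(k-1) - H(k), i.e. adding the
# k-th cluster helped a lot and the (k+1)-th much less).
index_hartigan <- function(X, ks, fits, w_prev, w_next) {
  n <- nrow(X)
  w <- vapply(fits, function(f) f$within_ss, 0)
  w_all <- c(w_prev, w, w_next)
  k_all <- c(min(ks) - 1L, ks, max(ks) + 1L)
  h <- (w_all[-length(w_all)] / pmax(w_all[-1L], 1e-300) - 1) *
    (n - k_all[-length(k_all)] - 1)
  drop <- h[-length(h)] - h[-1L]   # drop[i] = H(k_i - 1) - H(k_i)
  ks[which.max(drop)]
}

# Krzanowski-Lai: KL(k) = |DIFF_k| / |DIFF_{k+1}| with
# DIFF_k = (k-1)^{2/p} W_{k-1} - k^{2/p} W_k; maximized at the true k.
index_kl <- function(X, ks, fits, w_prev, w_next) {
  p <- ncol(X)
  w_all <- c(w_prev, vapply(fits, function(f) f$within_ss, 0), w_next)
  k_all <- c(min(ks) - 1L, ks, max(ks) + 1L)
  d <- (k_all[-length(k_all)]^(2 / p)) * w_all[-length(w_all)] -
    (k_all[-1L]^(2 / p)) * w_all[-1L]
  kl <- abs(d[-length(d)]) / pmax(abs(d[-1L]), 1e-300)
  ks[which.max(kl)]
}

# C-index: (S_w - S_min) / (S_max - S_min), minimized; S_w = sum of
# within-cluster pairwise distances, S_min/S_max = sums of the same number
# of smallest/largest pairwise distances overall.
index_cindex <- function(d, fits) {
  dv <- sort(as.vector(d))
  vapply(fits, function(f) {
    within <- as.vector(d)[as.vector(stats::as.dist(
      outer(f$assignment, f$assignment, "==")))]
    nw <- length(within)
    s_min <- sum(dv[seq_len(nw)])
    s_max <- sum(dv[seq.int(length(dv) - nw + 1L, length(dv))])
    (sum(within) - s_min) / max(s_max - s_min, 1e-300)
  }, 0)
}

# Point-biserial: correlation between pairwise distances and the
# different-cluster indicator, maximized.
index_ptbiserial <- function(d, fits) {
  dv <- as.vector(d)
  vapply(fits, function(f) {
    between <- !as.vector(stats::as.dist(
      outer(f$assignment, f$assignment, "==")))
    stats::cor(dv, as.numeric(between))
  }, 0)
}

#' Validity-index vote for the number of clusters
#'
#' Fits k-means over `k_range` and scores each solution with eight cluster
#' validity indices: mean silhouette width (max), Calinski-Harabasz (max),
#' Davies-Bouldin (min), the gap statistic (uniform bounding-box reference,
#' `B` draws, one-standard-error rule), a Hartigan-style elbow,
#' Krzanowski-Lai (max), C-index (min) and point-biserial correlation
#' (max) — a balance of maximization-type and successive-difference-type
#' indices emulating the breadth of the large index families used for this
#' decision in the field. The winner is the majority vote; ties are broken
#' toward the smallest k among the modal set.
#'
#' @param points numeric matrix (observations x coordinates).
#' @param k_range candidate cluster counts, within (1, n).
#' @param seed integer seed controlling restarts and reference draws.
#' @param n_init k-means++ restarts per k.
#' @param B reference draws for the gap statistic.
#' @return an object of class `k_vote`: `votes` (best k per index),
#'   `winner`, `fits` (the `km_fit` per k), `k_range`.
#' @export
optimal_k <- function(points, k_range = 2:8, seed = 1L, n_init = 25L, B = 50L) {
  X <- as.matrix(points)
  n <- nrow(X)
  if (min(k_range) <= 1L || max(k_range) >= n) {
    stop("k_range must lie strictly between 1 and the number of points")
  }
  if (max(sq_dist(X, X[1L, , drop = FALSE])) == 0) {
    stop("degenerate input: all points identical")
  }
  ks <- sort(unique(as.integer(k_range)))
  fits <- lapply(seq_along(ks), function(i) {
    km_cluster(X, ks[i], seed = seed + i, n_init = n_init)
  })
  names(fits) <- ks
  d <- stats::dist(X)
  sil <- index_silhouette(X, fits, d)
  ch <- index_ch(X, fits)
  db <- index_db(X, fits)
  gap <- index_gap(X, ks, fits, seed = seed + 1000L, B = B)
  w_next <- km_cluster(X, min(max(ks) + 1L, n), seed = seed + 2000L,
                       n_init = n_init)$within_ss
  w_prev <- km_cluster(X, min(ks) - 1L, seed = seed + 3000L,
                       n_init = n_init)$within_ss
  cind <- index_cindex(d, fits)
  ptb <- index_ptbiserial(d, fits)
  votes <- c(silhouette = ks[which.max(sil)],
             calinski_harabasz = ks[which.max(ch)],
             davies_bouldin = ks[which.min(db)],
             gap = gap$best,
             hartigan = index_hartigan(X, ks, fits, w_prev, w_next),
             krzanowski_lai = index_kl(X, ks, fits, w_prev, w_next),
             c_index = ks[which.min(cind)],
             point_biserial = ks[which.max(ptb)])
  tab <- table(votes)
  modal <- as.integer(names(tab)[tab == max(tab)])
  winner <- min(modal)
  structure(list(votes = votes, winner = winner, fits = fits,
                 k_range = ks,
                 indices = list(silhouette = sil, calinski_harabasz = ch,
                                davies_bouldin = db, gap = gap$gap,
                                c_index = cind, point_biserial = ptb)),
            class = "k_vote")
}

#' @export
print.k_vote <- function(x, ...) {
  cat("Optimal-k vote over k =", paste(range(x$k_range), collapse = ".."),
      "\n")
  print(x$votes)
  cat("Winner (majority, ties to smallest k):", x$winner, "\n")
  invisible(x)
}
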