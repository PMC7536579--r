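# Tanglegram logic: a lightweight recursive binary-tree representation of
# dendrograms, restriction to shared leaves, the entanglement coefficient,
# greedy untangling by child swaps, and exhaustive rotation search for
# small trees. Newick export/import (via ape) for interchange.

# A dtree node is either list(label = <chr>, height = 0) or
# list(height = <num>, left = <dtree>, right = <dtree>).

is_leaf <- function(node) !is.null(node$label)

#' Convert a clustering to the package's recursive tree form
#'
#' @param x a `variant_dendro`, `hclust` or `phylo` object (phylo trees must
#'   be rooted and binary; node heights are taken as distance below the
#'   maximum root-to-tip depth).
#' @return an object of class `dtree`.
#' @export
as_dtree <- function(x) {
  if (inherits(x, "dtree")) return(x)
  if (inherits(x, "variant_dendro")) x <- x$hclust
  if (inherits(x, "hclust")) return(dtree_from_hclust(x))
  if (inherits(x, "phylo")) return(dtree_from_phylo(x))
  stop("cannot convert object of class ", paste(class(x), collapse = "/"),
       " to dtree")
}

dtree_from_hclust <- function(hc) {
  build <- function(i) {
    if (i < 0) {
      list(label = hc$labels[-i], height = 0)
    } else {
      list(height = hc$height[i],
           left = build(hc$merge[i, 1L]),
           right = build(hc$merge[i, 2L]))
    }
  }
  structure(build(nrow(hc$merge)), class = "dtree")
}

dtree_from_phylo <- function(phy) {
  if (!ape::is.binary(phy) || !ape::is.rooted(phy)) {
    stop("phylo tree must be rooted and binary")
  }
  depth <- ape::node.depth.edgelength(phy)
  total <- max(depth)
  n_tip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  build <- function(node) {
    if (node <= n_tip) {
      list(label = phy$tip.label[node], height = 0)
    } else {
      ch <- kids[[as.character(node)]]
      list(height = total - depth[node],
           left = build(ch[1L]), right = build(ch[2L]))
    }
  }
  structure(build(n_tip + 1L), class = "dtree")
}

#' Leaf labels of a tree in current left-to-right order
#' @param tree a `dtree`.
#' @return character vector.
#' @export
dtree_leaves <- function(tree) {
  if (is_leaf(tree)) return(tree$label)
  c(dtree_leaves(tree$left), dtree_leaves(tree$right))
}

n_internal <- function(tree) {
  if (is_leaf(tree)) 0L else 1L + n_internal(tree$left) + n_internal(tree$right)
}

dtree_heights <- function(tree) {
  if (is_leaf(tree)) return(numeric(0))
  c(tree$height, dtree_heights(tree$left), dtree_heights(tree$right))
}

#' Newick serialization of a dtree
#'
#' Branch lengths are parent height minus child height, so ultrametric
#' dendrograms round-trip with their merge heights.
#'
#' @param tree a `dtree` (or coercible via [as_dtree()]).
#' @param path optional output file; when given the string is written there.
#' @return the Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  tree <- as_dtree(tree)
  fmt <- function(node, parent_h) {
    bl <- sprintf("%.10g", parent_h - node$height)
    if (is_leaf(node)) {
      paste0(gsub("[,();: ]", "_", node$label), ":", bl)
    } else {
      paste0("(", fmt(node$left, node$height), ",",
             fmt(node$right, node$height), "):", bl)
    }
  }
  s <- paste0("(", fmt(tree$left, tree$height), ",",
              fmt(tree$right, tree$height), ");")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Read a dendrogram from a Newick file
#' @param path Newick file path.
#' @return a `dtree`.
#' @export
read_newick <- function(path) as_dtree(ape::read.tree(path))

#' Restrict two dendrograms to their shared leaves
#'
#' Prunes each tree to the leaves present in both, collapsing unary nodes
#' while preserving the heights of the surviving merges.
#'
#' @param dend_a,dend_b trees coercible via [as_dtree()].
#' @return list of two pruned `dtree`s (`a`, `b`).
#' @export
restrict_to_shared <- function(dend_a, dend_b) {
  a <- as_dtree(dend_a)
  b <- as_dtree(dend_b)
  shared <- intersect(dtree_leaves(a), dtree_leaves(b))
  if (length(shared) < 2L) stop("need at least 2 shared leaves, got ",
                                length(shared))
  list(a = prune_dtree(a, shared), b = prune_dtree(b, shared))
}

prune_dtree <- function(tree, keep) {
  rec <- function(node) {
    if (is_leaf(node)) {
      if (node$label %in% keep) node else NULL
    } else {
      l <- rec(node$left)
      r <- rec(node$right)
      if (is.null(l) && is.null(r)) return(NULL)
      if (is.null(l)) return(r)
      if (is.null(r)) return(l)
      list(height = node$height, left = l, right = r)
    }
  }
  out <- rec(tree)
  if (is.null(out) || is_leaf(out)) stop("pruning left fewer than 2 leaves")
  structure(out, class = "dtree")
}

#' Entanglement coefficient between two leaf orders
#'
#' `sum_s |rank_a(s) - rank_b(s)|^L`, normalized by the same sum for an
#' order against its own reversal (the worst case), giving a value in
#' [0, 1]: 0 for identical orders, 1 for exactly reversed orders.
#'
#' @param order_a,order_b permutations of the same label set (length >= 2).
#' @param L norm exponent (> 0); 1.5 is the tanglegram-family convention.
#' @return numeric scalar in [0, 1].
#' @export
entanglement <- function(order_a, order_b, L = 1.5) {
  stopifnot(L > 0, length(order_a) >= 2L)
  if (!setequal(order_a, order_b) ||
      length(order_a) != length(order_b) ||
      anyDuplicated(order_a) || anyDuplicated(order_b)) {
    stop("orders must be permutations of the same label set")
  }
  n <- length(order_a)
  ra <- seq_len(n)
  rb <- match(order_a, order_b)
  num <- sum(abs(ra - rb)^L)
  den <- sum(abs(seq_len(n) - rev(seq_len(n)))^L)
  num / den
}

# Apply/enumerate child swaps. Internal nodes are indexed in preorder.
flip_dtree <- function(tree, flips) {
  i <- 0L
  rec <- function(node) {
    if (is_leaf(node)) return(node)
    i <<- i + 1L
    if (flips[i]) {
      tmp <- node$left
      node$left <- node$right
      node$right <- tmp
    }
    node$left <- rec(node$left)
    node$right <- rec(node$right)
    node
  }
  structure(rec(tree), class = "dtree")
}

# All leaf orders reachable by child swaps (2^(n-1) for a binary tree with
# n leaves), as a list of character vectors.
enumerate_orders <- function(tree) {
  rec <- function(node) {
    if (is_leaf(node)) return(list(node$label))
    lo <- rec(node$left)
    ro <- rec(node$right)
    out <- vector("list", 2L * length(lo) * length(ro))
    i <- 0L
    for (x in lo) {
      for (y in ro) {
        out[[i <- i + 1L]] <- c(x, y)
        out[[i <- i + 1L]] <- c(y, x)
      }
    }
    out
  }
  rec(tree)
}

#' Exhaustive minimum entanglement over all branch rotations
#'
#' Enumerates every child-swap configuration of both trees (2^(n-1) leaf
#' orders each) and returns the global minimum entanglement. Feasible for
#' small shared leaf sets (n <= ~10).
#'
#' @param dend_a,dend_b trees coercible via [as_dtree()] over the same leaf
#'   set.
#' @param L norm exponent.
#' @return the minimum entanglement (numeric scalar).
#' @export
entanglement_bruteforce <- function(dend_a, dend_b, L = 1.5) {
  a <- as_dtree(dend_a)
  b <- as_dtree(dend_b)
  labels <- sort(dtree_leaves(a))
  stopifnot(identical(labels, sort(dtree_leaves(b))))
  n <- length(labels)
  oa <- enumerate_orders(a)
  ob <- enumerate_orders(b)
  # rank-by-label matrices
  Ra <- t(vapply(oa, function(o) match(labels, o), integer(n)))
  Rb <- t(vapply(ob, function(o) match(labels, o), integer(n)))
  den <- sum(abs(seq_len(n) - rev(seq_len(n)))^L)
  best <- Inf
  for (i in seq_len(nrow(Ra))) {
    num <- rowSums(abs(sweep(Rb, 2L, Ra[i, ]))^L)
    m <- min(num)
    if (m < best) best <- m
  }
  best / den
}

tangle_value <- function(a, b, L) {
  entanglement(dtree_leaves(a), dtree_leaves(b), L)
}

# One greedy pass over the internal nodes of `side` (post-order), accepting
# a child swap iff entanglement strictly decreases.
# One-sided pass: optimal rotation of `side` against the fixed leaf order
# of `other`. Because any subtree occupies a contiguous block of positions
# whatever the rotations inside it, the alignment cost
# sum_s |pos_a(s) - rank_b(s)|^L decomposes over the child-order choice at
# each node; a post-order dynamic program over (node, block offset) yields
# the exact one-sided optimum. Ties keep the current child order.
untangle_pass <- function(side, other, L) {
  other_order <- dtree_leaves(other)
  rank_b <- stats::setNames(seq_along(other_order), other_order)

  # flatten to arrays (post-order ids)
  nodes <- list()
  flatten <- function(node) {
    if (is_leaf(node)) {
      nodes[[length(nodes) + 1L]] <<- list(leaf = TRUE, label = node$label,
                                           size = 1L, height = node$height)
      return(length(nodes))
    }
    l <- flatten(node$left)
    r <- flatten(node$right)
    nodes[[length(nodes) + 1L]] <<- list(leaf = FALSE, left = l, right = r,
                                         size = nodes[[l]]$size + nodes[[r]]$size,
                                         height = node$height)
    length(nodes)
  }
  root <- flatten(side)

  memo_cost <- new.env(parent = emptyenv())
  memo_flip <- new.env(parent = emptyenv())
  solve <- function(id, offset) {
    key <- paste0(id, ":", offset)
    hit <- memo_cost[[key]]
    if (!is.null(hit)) return(hit)
    nd <- nodes[[id]]
    if (nd$leaf) {
      cost <- abs(offset - rank_b[[nd$label]])^L
      memo_cost[[key]] <- cost
      return(cost)
    }
    nl <- nodes[[nd$left]]$size
    nr <- nodes[[nd$right]]$size
    keep <- solve(nd$left, offset) + solve(nd$right, offset + nl)
    flip <- solve(nd$right, offset) + solve(nd$left, offset + nr)
    if (flip < keep - 1e-12) {
      memo_flip[[key]] <- TRUE
      memo_cost[[key]] <- flip
      flip
    } else {
      memo_flip[[key]] <- FALSE
      memo_cost[[key]] <- keep
      keep
    }
  }
  total <- solve(root, 1L)

  rebuild <- function(id, offset) {
    nd <- nodes[[id]]
    if (nd$leaf) return(list(label = nd$label, height = nd$height))
    flip <- isTRUE(memo_flip[[paste0(id, ":", offset)]])
    a <- if (flip) nd$right else nd$left
    b <- if (flip) nd$left else nd$right
    list(height = nd$height,
         left = rebuild(a, offset),
         right = rebuild(b, offset + nodes[[a]]$size))
  }
  out <- structure(rebuild(root, 1L), class = "dtree")
  n <- length(other_order)
  den <- sum(abs(seq_len(n) - rev(seq_len(n)))^L)
  list(tree = out, entanglement = total / den)
}

# Paths (integer vectors of 1=left / 2=right) to internal nodes, post-order.
internal_paths <- function(tree) {
  out <- list()
  rec <- function(node, path) {
    if (is_leaf(node)) return(invisible())
    rec(node$left, c(path, 1L))
    rec(node$right, c(path, 2L))
    out[[length(out) + 1L]] <<- path
  }
  rec(tree, integer(0))
  out
}

swap_at <- function(tree, path) {
  rec <- function(node, path) {
    if (!length(path)) {
      tmp <- node$left
      node$left <- node$right
      node$right <- tmp
      return(node)
    }
    if (path[1L] == 1L) node$left <- rec(node$left, path[-1L])
    else node$right <- rec(node$right, path[-1L])
    node
  }
  structure(rec(tree, path), class = "dtree")
}

#' Tanglegram untangling by alternating one-sided optimization
#'
#' Alternating one-sided search: holding one tree's leaf order fixed, the
#' other tree's child orderings are optimized exactly by a post-order
#' dynamic program over subtree position blocks (a subtree always occupies
#' a contiguous block of leaf positions, so the alignment cost decomposes
#' over the child-order choice at each node); then the sides switch. The
#' search stops after a full round with no improvement, or after
#' `max_rounds` rounds. Topology and merge heights are never changed, only
#' child ordering, so the final entanglement is never above the initial
#' one.
#'
#' For small shared leaf sets (at most `exact_limit` internal nodes on the
#' first tree) the search is exact: every rotation configuration of the
#' first tree is enumerated and the second tree's optimal response
#' computed by the dynamic program, yielding the global joint optimum. For
#' larger trees, alternating descent is restarted from `restarts` seeded
#' random rotation configurations and the best layout kept; the initial
#' configuration is always among the starts, so the final entanglement is
#' never above the initial one.
#'
#' @param dend_a,dend_b trees coercible via [as_dtree()]; they are first
#'   restricted to their shared leaves.
#' @param L norm exponent (see [entanglement()]).
#' @param max_rounds maximum alternating rounds per start.
#' @param restarts seeded random restarts for the heuristic regime.
#' @param exact_limit maximum internal-node count for the exact regime.
#' @param seed seed for the restart draws.
#' @return an object of class `tanglegram`: `tree_a`, `tree_b` (rotated
#'   `dtree`s), `order_a`, `order_b`, `entanglement`,
#'   `initial_entanglement`, `rounds`, `L`.
#' @export
untangle <- function(dend_a, dend_b, L = 1.5, max_rounds = 20L,
                     restarts = 20L, exact_limit = 8L, seed = 1L) {
  tr <- restrict_to_shared(dend_a, dend_b)
  a <- tr$a
  b <- tr$b
  initial <- tangle_value(a, b, L)

  descend <- function(a0, b0) {
    current <- tangle_value(a0, b0, L)
    rounds <- 0L
    repeat {
      rounds <- rounds + 1L
      pa <- untangle_pass(a0, b0, L)
      a0 <- pa$tree
      pb <- untangle_pass(b0, a0, L)
      b0 <- pb$tree
      new <- pb$entanglement
      if (new >= current - 1e-12 || rounds >= max_rounds) {
        return(list(a = a0, b = b0, ent = min(new, current),
                    rounds = rounds))
      }
      current <- new
    }
  }

  ni <- n_internal(a)
  if (ni <= exact_limit) {
    # exact: enumerate all rotations of the first tree, optimal response
    # of the second by dynamic programming
    best <- NULL
    flips <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), ni)))
    for (i in seq_len(nrow(flips))) {
      cand_a <- flip_dtree(a, flips[i, ])
      resp <- untangle_pass(b, cand_a, L)
      if (is.null(best) || resp$entanglement < best$ent - 1e-12) {
        best <- list(a = cand_a, b = resp$tree, ent = resp$entanglement,
                     rounds = 1L)
      }
    }
  } else {
    best <- descend(a, b)
    with_seed(seed, {
      for (r in seq_len(restarts)) {
        start_a <- flip_dtree(a, sample(c(TRUE, FALSE), ni, replace = TRUE))
        cand <- descend(start_a, b)
        if (cand$ent < best$ent - 1e-12) best <- cand
      }
    })
  }

  structure(list(tree_a = best$a, tree_b = best$b,
                 order_a = dtree_leaves(best$a),
                 order_b = dtree_leaves(best$b),
                 entanglement = best$ent,
                 initial_entanglement = initial,
                 rounds = best$rounds, L = L),
            class = "tanglegram")
}

#' @export
print.tanglegram <- function(x, ...) {
  cat("Tanglegram over", length(x$order_a), "shared leaves (L =", x$L, ")\n")
  cat("Entanglement:", signif(x$entanglement, 4),
      "(initial", paste0(signif(x$initial_entanglement, 4), ","),
      x$rounds, "round(s))\n")
  invisible(x)
}

#' Serialize a tanglegram to JSON
#' @param x a `tanglegram`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tanglegram <- function(x, path) {
  stopifnot(inherits(x, "tanglegram"))
  jsonlite::write_json(list(order_a = x$order_a, order_b = x$order_b,
                            entanglement = x$entanglement,
                            initial_entanglement = x$initial_entanglement,
                            rounds = x$rounds, L = x$L),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
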