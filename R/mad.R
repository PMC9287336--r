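# Minimal ancestral deviation (MAD) rooting. A candidate root on a branch
# induces, for every pair of tips (i, j), a putative ancestor: the point on
# the path between i and j closest to the root. Under a strict molecular
# clock that ancestor would sit at the midpoint, so the relative deviation
# 2*d(i, anc)/d(i, j) - 1 measures departure from clocklikeness. MAD places
# the root where the root-mean-square of these deviations over all tip pairs
# is smallest; the optimal position within a branch has a closed form because
# the objective is quadratic in the position.

# undirected edge/adjacency view of a rooted tree, with a binary root
# suppressed (its two incident branches merge into one undirected edge)
unrooted_edges <- function(tree, zero_tol = 1e-8) {
  n <- length(tree$label)
  ed <- data.frame(
    a = tree$parent[-1L], b = seq_len(n)[-1L],
    w = tree$length[-1L]
  )
  if (anyNA(ed$w)) stop("mad_root needs branch lengths on every branch")
  if (any(ed$w <= 0)) {
    warning("zero-length branch(es) treated as 1e-8")
    ed$w[ed$w <= 0] <- zero_tol
  }
  root_kids <- tree$children[[1L]]
  drop_root <- length(root_kids) == 2L
  if (drop_root) {
    # merge the two root branches
    keep <- ed$a != 1L
    merged <- data.frame(a = root_kids[1L], b = root_kids[2L],
                         w = sum(ed$w[ed$a == 1L]))
    ed <- rbind(merged, ed[keep, , drop = FALSE])
  }
  list(edges = ed, root_dropped = drop_root)
}

# all-pairs distances over an undirected weighted tree given its edge list
adjacency_distances <- function(edges, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges$a[r]; b <- edges$b[r]; w <- edges$w[r]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  D <- matrix(NA_real_, n, n)
  for (s in seq_len(n)) {
    if (is.null(adj[[s]])) next
    dist <- rep(NA_real_, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]]
      for (r in seq_len(nrow(nb))) {
        u <- nb[r, 1L]
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + nb[r, 2L]
          queue <- c(queue, u)
        }
      }
    }
    D[s, ] <- dist
  }
  D
}

#' Root a tree by minimal ancestral deviation (MAD)
#'
#' Evaluates every branch of the unrooted topology, computes the closed-form
#' optimal root position within each branch, and returns the placement with
#' the smallest root-mean-square relative deviation of midpoint estimates
#' over all tip pairs. Ties between branches are broken by the
#' lexicographically smallest branch identifier. A perfectly clocklike
#' (ultrametric) tree is rooted at its clock root with deviation 0.
#'
#' @param tree a `rooted_tree` (its current rooting is ignored) with strictly
#'   positive branch lengths and at least 3 tips. Zero-length branches are
#'   treated as 1e-8 with a warning.
#' @param root_label label given to the inserted root node.
#' @return a list of class `mad_rooting` with elements `tree` (the rerooted
#'   `rooted_tree`), `deviation` (the minimized RMS relative deviation),
#'   `branch` (identifier `"<label>|<label>"` of the branch carrying the
#'   root, endpoints in lexicographic order) and `position` (relative
#'   position of the root in `[0, 1]`, measured from the first endpoint).
#' @export
mad_root <- function(tree, root_label = "MADroot") {
  stopifnot(inherits(tree, "rooted_tree"))
  if (n_tips(tree) < 3L) stop("mad_root needs at least 3 tips")
  un <- unrooted_edges(tree)
  edges <- un$edges
  n <- length(tree$label)
  D <- adjacency_distances(edges, n)
  tips <- which(tree$is_tip)

  best <- NULL
  for (r in seq_len(nrow(edges))) {
    a <- edges$a[r]; b <- edges$b[r]; w <- edges$w[r]
    on_b_side <- abs(D[tips, b] + w - D[tips, a]) < 1e-9 * max(1, w + max(D[tips, a]))
    side_a <- tips[!on_b_side]
    side_b <- tips[on_b_side]
    # optimal in-branch position from pairs spanning the branch
    da <- D[side_a, a, drop = TRUE]
    db <- D[side_b, b, drop = TRUE]
    dij <- outer(da, db, "+") + w                    # full pairwise distance
    di <- matrix(da, nrow = length(side_a), ncol = length(side_b))
    num <- sum((dij - 2 * di) / dij^2)
    den <- 2 * w * sum(1 / dij^2)
    rho <- if (den > 0) min(max(num / den, 0), 1) else 0
    dev_span <- (2 * (di + rho * w) / dij - 1)^2
    # same-side pairs: ancestor fixed at their joint node toward the branch
    dev_same <- function(side, anchor) {
      if (length(side) < 2L) return(numeric(0))
      d <- D[side, anchor]
      dd <- outer(d, d, "-")
      pp <- D[side, side]
      v <- (dd / pp)^2
      v[upper.tri(v)]
    }
    sq <- c(as.vector(dev_span), dev_same(side_a, a), dev_same(side_b, b))
    score <- sqrt(mean(sq))
    # branch identifier with lexicographically ordered endpoints
    la <- tree$label[a]; lb <- tree$label[b]
    if (la <= lb) {
      id <- paste0(la, "|", lb); pos <- rho; ends <- c(a, b)
    } else {
      id <- paste0(lb, "|", la); pos <- 1 - rho; ends <- c(b, a)
    }
    cand <- list(score = score, id = id, pos = pos, ends = ends, w = w)
    if (is.null(best) || score < best$score - 1e-12 ||
        (abs(score - best$score) <= 1e-12 && id < best$id)) {
      best <- cand
    }
  }

  rooted <- reroot_at_point(tree, edges, best$ends[1L], best$ends[2L],
                            best$pos * best$w, root_label)
  structure(
    list(tree = rooted, deviation = best$score,
         branch = best$id, position = best$pos),
    class = "mad_rooting"
  )
}

#' @export
print.mad_rooting <- function(x, ...) {
  cat("MAD rooting: branch", x$branch, sprintf("at position %.4f", x$position),
      sprintf("(deviation %.6f)\n", x$deviation))
  invisible(x)
}

# rebuild a rooted_tree with the root at distance `dist_from_u` from node u
# along the undirected edge (u, v)
reroot_at_point <- function(tree, edges, u, v, dist_from_u, root_label) {
  n <- length(tree$label)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges$a[r]; b <- edges$b[r]; w <- edges$w[r]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  w_uv <- edges$w[(edges$a == u & edges$b == v) | (edges$a == v & edges$b == u)][1L]
  lbl <- root_label
  while (lbl %in% tree$label) lbl <- paste0(lbl, "x")

  parent_new <- integer(0)
  length_new <- numeric(0)
  label_new <- character(0)
  add_node <- function(lab, par, len) {
    parent_new[length(parent_new) + 1L] <<- par
    length_new[length(length_new) + 1L] <<- len
    label_new[length(label_new) + 1L] <<- lab
    length(parent_new)
  }
  root_id <- add_node(lbl, 0L, NA_real_)
  # DFS orienting edges away from the root point
  walk <- function(node, from, par_id, len) {
    my_id <- add_node(tree$label[node], par_id, len)
    nb <- adj[[node]]
    for (r in seq_len(nrow(nb))) {
      if (nb[r, 1L] != from) walk(nb[r, 1L], node, my_id, nb[r, 2L])
    }
  }
  # recursion depth ~ tree height; fine for the tree sizes handled here
  walk(u, v, root_id, dist_from_u)
  walk(v, u, root_id, w_uv - dist_from_u)
  # degree-2 pass: the old root may survive as a unary node when the original
  # root had 2 children and the new root lands elsewhere -- it was merged in
  # unrooted_edges, so nothing to suppress here.
  new_rooted_tree(parent_new, length_new, label_new)
}
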