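# Independent oracles and fixture builders used across the suite. Each
# oracle is a direct, unoptimized restatement of the model definition, kept
# free of the production code paths it checks.

# exhaustive minimum reconciliation cost: enumerate the origination node and
# every internal copy-number assignment, paying for each branch transition
# directly from the event-cost definition
brute_dtl_cost <- function(obs, tree, costs = dtl_costs(), c_max = 2) {
  n <- length(tree_labels(tree))
  is_tip <- tree_labels(tree) %in% tip_labels(tree)
  parent <- tree$parent
  tipi <- which(is_tip)
  inti <- which(!is_tip)
  tc <- function(a, b) {
    if (b == a) return(0)
    if (b > a) {
      if (a == 0) (b - a) * costs$transfer
      else (b - a) * min(costs$duplication, costs$transfer)
    } else {
      (a - b) * costs$loss
    }
  }
  states <- rep(0L, n)
  states[tipi] <- obs[tree_labels(tree)[tipi]]
  grid <- as.matrix(expand.grid(rep(list(0:c_max), length(inti))))
  best <- Inf
  for (o in seq_len(n)) {
    for (g in seq_len(nrow(grid))) {
      states[inti] <- grid[g, ]
      if (o != 1L && states[1L] != 0L) next
      cost <- 0
      if (o == 1L) cost <- cost + tc(1L, states[1L])
      for (v in 2:n) {
        a <- states[parent[v]] + as.integer(v == o)
        cost <- cost + tc(a, states[v])
        if (cost >= best) break
      }
      if (cost < best) best <- cost
    }
  }
  best
}

# run the DP against the exhaustive oracle for every profile on a tree;
# returns the number of mismatching profiles
count_dp_mismatches <- function(newick, c_max = 2) {
  tr <- parse_newick(newick)
  tips <- tip_labels(tr)
  grid <- as.matrix(expand.grid(rep(list(0:c_max), length(tips))))
  bad <- 0L
  for (r in seq_len(nrow(grid))) {
    p <- stats::setNames(grid[r, ], tips)
    if (all(p == 0)) next
    dp <- reconcile_parsimony(p, tr, c_max = c_max)$cost
    bf <- brute_dtl_cost(p, tr, c_max = c_max)
    if (abs(dp - bf) > 1e-9) bad <- bad + 1L
  }
  bad
}

# brute-force MAD: evaluate the RMS relative deviation on a uniform grid of
# candidate root positions over every branch, using the generic
# closest-point-ancestor formula for every tip pair
mad_grid_minimum <- function(tree, grid_n = 200) {
  un <- gcevo:::unrooted_edges(tree)
  n <- length(tree_labels(tree))
  D <- gcevo:::adjacency_distances(un$edges, n)
  tips <- which(tree_labels(tree) %in% tip_labels(tree))
  pairs <- t(utils::combn(tips, 2))
  best <- Inf
  best_edge <- NA_character_
  for (r in seq_len(nrow(un$edges))) {
    a <- un$edges$a[r]; b <- un$edges$b[r]; w <- un$edges$w[r]
    da <- D[tips, a]; db <- D[tips, b]
    for (x in seq(0, 1, length.out = grid_n)) {
      dr <- pmin(da + x * w, db + (1 - x) * w)
      i <- pairs[, 1L]; j <- pairs[, 2L]
      dij <- D[cbind(i, j)]
      ii <- match(i, tips); jj <- match(j, tips)
      dianc <- (dr[ii] + dij - dr[jj]) / 2
      sc <- sqrt(mean((2 * dianc / dij - 1)^2))
      if (sc < best) {
        best <- sc
        la <- tree_labels(tree)[a]; lb <- tree_labels(tree)[b]
        best_edge <- paste(sort(c(la, lb)), collapse = "|")
      }
    }
  }
  list(score = best, branch = best_edge)
}

# brute-force minimum number of gain clades: smallest set of nodes whose
# descendant-tip union is exactly the focal set
brute_min_acquisitions <- function(tree, groups, focal) {
  tb <- gcevo:::tips_below(tree)
  labs <- tree_labels(tree)
  focal_tips <- sort(names(groups)[groups == focal])
  cand <- which(vapply(seq_along(labs), function(v) {
    all(labs[tb[[v]]] %in% focal_tips)
  }, logical(1)))
  for (k in seq_along(focal_tips)) {
    for (comb in utils::combn(cand, k, simplify = FALSE)) {
      un <- sort(unique(unlist(lapply(comb, function(v) labs[tb[[v]]]))))
      if (identical(un, focal_tips)) return(k)
    }
  }
  stop("no gain set covers the focal tips")  # unreachable: tips are candidates
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

mutate_seq <- function(s, identity) {
  hit <- stats::runif(length(s)) < (1 - identity)
  if (any(hit)) s[hit] <- sample(AA20, sum(hit), replace = TRUE)
  s
}

# 12-genome panel with 4 AAI genera of 3 genomes (genomes 1+2 conspecific),
# and a species tree that forces genus "d" to be polyphyletic
make_aai_panel <- function(seed, n_proteins = 15, len = 150) {
  set.seed(seed)
  to_set <- function(x) {
    Biostrings::AAStringSet(stats::setNames(
      vapply(x, paste, "", collapse = ""), sprintf("p%03d", seq_along(x))
    ))
  }
  root <- replicate(n_proteins, sample(AA20, len, replace = TRUE), simplify = FALSE)
  panel <- list()
  for (g in c("a", "b", "c", "d")) {
    anc <- lapply(root, mutate_seq, identity = 0.65)
    g1 <- lapply(anc, mutate_seq, identity = 0.92)
    g2 <- lapply(g1, mutate_seq, identity = 0.985)
    g3 <- lapply(anc, mutate_seq, identity = 0.92)
    panel[[paste0(g, "1")]] <- to_set(g1)
    panel[[paste0(g, "2")]] <- to_set(g2)
    panel[[paste0(g, "3")]] <- to_set(g3)
  }
  tree <- parse_newick(
    "((((a1,a2),a3),d3),(((b1,b2),b3),(((c1,c2),c3),(d1,d2))));"
  )
  genus_truth <- list(c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                      c("c1", "c2", "c3"), c("d1", "d2"), "d3")
  species_truth <- list(c("a1", "a2"), "a3", c("b1", "b2"), "b3",
                        c("c1", "c2"), "c3", c("d1", "d2"), "d3")
  list(panel = panel, tree = tree,
       genus_truth = genus_truth, species_truth = species_truth)
}

same_partition <- function(clustering, truth) {
  got <- lapply(clustering, function(cl) sort(cl$members))
  want <- lapply(truth, sort)
  length(got) == length(want) &&
    all(vapply(want, function(w) any(vapply(got, identical, logical(1), w)),
               logical(1)))
}
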