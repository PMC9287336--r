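# Rooted trees are stored as parent-indexed arrays in preorder: node 1 is the
# root and parent[i] < i for every non-root node, so a reverse loop is a
# postorder traversal. This layout is the coordinate system for every
# per-branch quantity downstream (a "branch" is identified by the label of
# the node at its lower end).

new_rooted_tree <- function(parent, length, label) {
  n <- base::length(parent)
  stopifnot(n >= 1L, base::length(length) == n, base::length(label) == n)
  if (sum(parent == 0L) != 1L || parent[1L] != 0L) {
    stop("exactly one root is required and it must be node 1")
  }
  if (any(parent[-1L] >= seq_len(n)[-1L])) {
    stop("nodes must be in preorder (parent index < child index)")
  }
  if (anyDuplicated(label)) {
    stop("duplicate labels: ", paste(unique(label[duplicated(label)]), collapse = ", "))
  }
  bad <- which(!is.na(length) & length < 0)
  if (base::length(bad)) {
    stop("negative branch length at node '", label[bad[1L]], "': ", length[bad[1L]])
  }
  children <- vector("list", n)
  for (i in seq_len(n)[-1L]) {
    children[[parent[i]]] <- c(children[[parent[i]]], i)
  }
  structure(
    list(
      label = as.character(label),
      parent = as.integer(parent),
      length = as.numeric(length),
      children = children,
      is_tip = vapply(children, function(x) base::length(x) == 0L, logical(1))
    ),
    class = "rooted_tree"
  )
}

#' Parse a Newick string into a rooted tree
#'
#' Accepts the Newick dialect written by common maximum-likelihood tree
#' programs: branch lengths optional, internal labels after the closing
#' parenthesis, no quoted labels, no comments. Internal nodes without a label
#' are assigned deterministic labels `N<k>` by preorder index, so the same
#' topology always receives the same labels and these can be used as join
#' keys across analyses.
#'
#' @param text a Newick string, or a path to a file whose first line is one.
#' @return a `rooted_tree` object.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):0.5,C:2);")
#' write_newick(tr)
parse_newick <- function(text) {
  if (base::length(text) != 1L || !is.character(text)) {
    stop("'text' must be a single character string")
  }
  if (!grepl(";", text, fixed = TRUE) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  if (grepl("[", text, fixed = TRUE) || grepl("]", text, fixed = TRUE)) {
    stop("parse error: Newick comments ('[') are not supported")
  }
  if (grepl("'", text, fixed = TRUE) || grepl("\"", text, fixed = TRUE)) {
    stop("parse error: quoted labels are not supported")
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop("parse error: unbalanced parentheses (", n_open, " '(' vs ", n_close, " ')')")
  }
  if (!endsWith(text, ";")) {
    stop("parse error: Newick string must end with ';'")
  }
  phy <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(phy) || is.null(phy$tip.label)) {
    stop("parse error: invalid Newick string")
  }
  if (ape::Ntip(phy) < 2L) {
    stop("parse error: a tree needs at least two tips")
  }
  as_rooted_tree(phy)
}

#' Convert an ape 'phylo' object to a rooted_tree
#'
#' @param phy an object of class `phylo`; must be rooted in ape's sense
#'   (binary root or explicit root node).
#' @return a `rooted_tree`.
#' @export
as_rooted_tree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  phy <- stats::reorder(phy, "cladewise")
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  n <- ntip + nnode
  ape_root <- ntip + 1L
  ape_parent <- integer(n)
  for (r in seq_len(nrow(phy$edge))) {
    ape_parent[phy$edge[r, 2L]] <- phy$edge[r, 1L]
  }
  elen <- rep(NA_real_, n)
  if (!is.null(phy$edge.length)) {
    elen[phy$edge[, 2L]] <- phy$edge.length
  }
  # preorder over ape ids: iterative DFS, children in cladewise order
  adj <- split(phy$edge[, 2L], factor(phy$edge[, 1L], levels = seq_len(n)))
  ord <- integer(0)
  stack <- ape_root
  while (base::length(stack)) {
    v <- stack[base::length(stack)]
    stack <- stack[-base::length(stack)]
    ord <- c(ord, v)
    kids <- adj[[v]]
    if (base::length(kids)) stack <- c(stack, rev(kids))
  }
  pos <- integer(n)
  pos[ord] <- seq_len(n)

  labs_ape <- character(n)
  labs_ape[seq_len(ntip)] <- phy$tip.label
  if (!is.null(phy$node.label)) {
    labs_ape[(ntip + 1L):n] <- phy$node.label
  }
  parent <- integer(n)
  lens <- numeric(n)
  labs <- character(n)
  internal_rank <- 0L
  for (i in seq_len(n)) {
    v <- ord[i]
    parent[i] <- if (v == ape_root) 0L else pos[ape_parent[v]]
    lens[i] <- elen[v]
    lab <- labs_ape[v]
    if (v > ntip) {
      internal_rank <- internal_rank + 1L
      if (is.na(lab) || !nzchar(lab)) lab <- paste0("N", internal_rank)
    }
    labs[i] <- lab
  }
  new_rooted_tree(parent, lens, labs)
}

#' Write a rooted tree as a Newick string
#'
#' @param tree a `rooted_tree`.
#' @param file optional path; when given the string is written there.
#' @param digits significant digits used for branch lengths.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  stopifnot(inherits(tree, "rooted_tree"))
  out <- paste0(newick_assemble(tree, digits), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

# iterative postorder string assembly (safe for deep caterpillars)
newick_assemble <- function(tree, digits = 10) {
  n <- base::length(tree$label)
  frag <- character(n)
  for (i in n:1) {
    lenstr <- if (is.na(tree$length[i])) "" else paste0(":", sprintf("%.*g", digits, tree$length[i]))
    if (tree$is_tip[i]) {
      frag[i] <- paste0(tree$label[i], lenstr)
    } else {
      frag[i] <- paste0("(", paste(frag[tree$children[[i]]], collapse = ","),
                        ")", tree$label[i], lenstr)
    }
  }
  frag[1L]
}

#' @export
print.rooted_tree <- function(x, ...) {
  cat("rooted_tree:", sum(x$is_tip), "tips,", sum(!x$is_tip), "internal nodes\n")
  cat("  root:", x$label[1L], "\n")
  tips <- tip_labels(x)
  cat("  tips:", paste(utils::head(tips, 6), collapse = ", "),
      if (base::length(tips) > 6) "..." else "", "\n")
  invisible(x)
}

#' Tree accessors
#'
#' `n_tips` counts leaves, `tip_labels` returns their labels,
#' `tree_labels` returns all node labels in preorder, `node_index` maps a
#' label to its preorder index, and `clade_tips` lists the tip labels
#' descending from (and including, if a tip) a node.
#'
#' @param tree a `rooted_tree`.
#' @param label a node label.
#' @name tree-accessors
NULL

#' @rdname tree-accessors
#' @export
n_tips <- function(tree) sum(tree$is_tip)

#' @rdname tree-accessors
#' @export
tip_labels <- function(tree) tree$label[tree$is_tip]

#' @rdname tree-accessors
#' @export
tree_labels <- function(tree) tree$label

#' @rdname tree-accessors
#' @export
node_index <- function(tree, label) {
  i <- match(label, tree$label)
  if (anyNA(i)) stop("unknown node label(s): ", paste(label[is.na(i)], collapse = ", "))
  i
}

#' @rdname tree-accessors
#' @export
clade_tips <- function(tree, label) {
  tree$label[tips_below(tree)[[node_index(tree, label)]]]
}

# list of tip indices below each node (node itself when a tip); postorder fill
tips_below <- function(tree) {
  n <- base::length(tree$label)
  out <- vector("list", n)
  for (i in n:1) {
    out[[i]] <- if (tree$is_tip[i]) i else unlist(out[tree$children[[i]]], use.names = FALSE)
  }
  out
}

# all descendant node indices (excluding self)
nodes_below <- function(tree) {
  n <- base::length(tree$label)
  out <- vector("list", n)
  for (i in n:1) {
    kids <- tree$children[[i]]
    out[[i]] <- if (base::length(kids)) c(kids, unlist(out[kids], use.names = FALSE)) else integer(0)
  }
  out
}

# ancestor indices of node i, from its parent up to the root
ancestors_of <- function(tree, i) {
  out <- integer(0)
  p <- tree$parent[i]
  while (p != 0L) {
    out <- c(out, p)
    p <- tree$parent[p]
  }
  out
}

# most recent common ancestor of a set of node indices
mrca_index <- function(tree, idx) {
  stopifnot(base::length(idx) >= 1L)
  if (base::length(idx) == 1L) return(idx)
  anc <- c(idx[1L], ancestors_of(tree, idx[1L]))
  for (i in idx[-1L]) {
    a2 <- c(i, ancestors_of(tree, i))
    anc <- anc[anc %in% a2]
  }
  anc[1L]
}

#' Relative evolutionary divergence (RED)
#'
#' RED interpolates node depth between the root (0) and the tips (1): the
#' value at a node is `RED(parent) + (b / u) * (1 - RED(parent))`, where `b`
#' is the branch above the node and `u` is the mean parent-to-tip distance
#' through the node. RED makes internal nodes comparable across lineages
#' with different substitution rates and is the basis of rank assignment in
#' genome taxonomy.
#'
#' @param tree a `rooted_tree` with branch lengths.
#' @return a named numeric vector (a node metric) over all nodes; 0 at the
#'   root and 1 at every tip.
#' @export
compute_red <- function(tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  n <- base::length(tree$label)
  if (any(is.na(tree$length[-1L]))) stop("compute_red needs branch lengths on all non-root nodes")
  # mean distance from each node down to its descendant tips
  sumd <- numeric(n)
  cnt <- integer(n)
  for (i in n:1) {
    if (tree$is_tip[i]) {
      sumd[i] <- 0
      cnt[i] <- 1L
    } else {
      for (k in tree$children[[i]]) {
        sumd[i] <- sumd[i] + sumd[k] + tree$length[k] * cnt[k]
        cnt[i] <- cnt[i] + cnt[k]
      }
    }
  }
  if (sumd[1L] <= 0) stop("zero mean root-to-tip distance; RED undefined")
  red <- numeric(n)
  red[1L] <- 0
  for (i in seq_len(n)[-1L]) {
    p <- tree$parent[i]
    u <- tree$length[i] + sumd[i] / cnt[i]
    if (u <= 0) stop("zero parent-to-tip distance through node '", tree$label[i], "'")
    red[i] <- red[p] + (tree$length[i] / u) * (1 - red[p])
  }
  stats::setNames(red, tree$label)
}

#' Write a node metric as a two-column TSV
#'
#' @param metric named numeric vector (node label, value).
#' @param path output path.
#' @export
write_node_metric <- function(metric, path) {
  utils::write.table(
    data.frame(node = names(metric), value = unname(metric)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Z-score normalization of per-branch values
#'
#' Centers and scales a vector of per-branch event counts to mean 0 and
#' population standard deviation 1 (no Bessel correction: the branches of the
#' species tree are the whole population, not a sample). Used to draw
#' mechanisms with very different event totals on a common scale.
#'
#' @param values numeric vector (optionally named by branch).
#' @return numeric vector of the same length and names.
#' @export
zscore_normalize <- function(values) {
  if (base::length(values) == 0L) stop("zscore_normalize: empty input")
  if (base::length(values) < 2L) stop("zscore_normalize: need at least two branches")
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  if (sigma == 0) {
    warning("constant input; returning all zeros")
    return(values * 0)
  }
  (values - mu) / sigma
}
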