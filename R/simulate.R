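# Synthetic gene-family histories. Families originate once on the species
# tree and then evolve copy-by-copy along branches under Poisson processes
# of duplication, intra-phylum transfer and loss (rates per unit branch
# length, so event pressure scales with divergence). Transfers copy a
# lineage onto a branch that is neither ancestral nor descendant to the
# donor, the simplest null consistent with an undated reconciliation model.
# Every event is recorded on the branch where it occurs, giving ground truth
# for reconciliation benchmarks.

#' Duplication/transfer/loss rate set
#'
#' @param duplication,transfer,loss non-negative event rates per unit branch
#'   length.
#' @param origination relative origination weight per node in `[0, 1]`;
#'   a scalar means the origination node is drawn uniformly over all nodes.
#' @return a `dtl_rates` list.
#' @export
dtl_rates <- function(duplication = 0, transfer = 0, loss = 0, origination = 1) {
  vals <- c(duplication, transfer, loss)
  if (any(vals < 0)) stop("rates must be non-negative")
  if (any(origination < 0) || any(origination > 1)) stop("origination weight must lie in [0, 1]")
  structure(list(duplication = duplication, transfer = transfer,
                 loss = loss, origination = origination),
            class = "dtl_rates")
}

#' Simulate a species tree under a pure-birth (Yule) process
#'
#' Starting from the root split, lineages branch at per-lineage rate
#' `birth_rate`; after the n-th lineage appears a final exponential waiting
#' time at the full rate elapses before the present, so the expected
#' root-to-tip depth is `sum(1/(k * birth_rate))` for `k = 2..n`. The result
#' is ultrametric with tips labelled `g01, g02, ...` and internal nodes
#' `N1, N2, ...` in preorder.
#'
#' @param n_leaves number of tips (>= 3).
#' @param birth_rate speciation rate per lineage.
#' @param seed optional integer seed (set via [set.seed()]).
#' @return a `rooted_tree`.
#' @export
simulate_species_tree <- function(n_leaves, birth_rate = 1, seed = NULL) {
  if (n_leaves < 3L) stop("n_leaves must be at least 3")
  if (birth_rate <= 0) stop("birth_rate must be positive")
  if (!is.null(seed)) set.seed(seed)
  # node bookkeeping: birth time of the branch above each node; active set
  parent <- c(0L, 1L, 1L)
  birth <- c(NA_real_, 0, 0)
  active <- c(2L, 3L)
  t_now <- 0
  k <- 2L
  while (k < n_leaves) {
    t_now <- t_now + stats::rexp(1, k * birth_rate)
    split <- active[sample.int(length(active), 1L)]
    id1 <- length(parent) + 1L
    id2 <- length(parent) + 2L
    parent <- c(parent, split, split)
    birth <- c(birth, t_now, t_now)
    active <- c(setdiff(active, split), id1, id2)
    k <- k + 1L
  }
  t_now <- t_now + stats::rexp(1, n_leaves * birth_rate)
  n <- length(parent)
  has_kids <- tabulate(parent, nbins = n) > 0
  end_time <- ifelse(has_kids, NA, t_now)
  # end time of internal branches = birth time of their children
  for (i in seq_len(n)[-1L]) {
    if (has_kids[i]) end_time[i] <- birth[which(parent == i)[1L]]
  }
  len <- end_time - birth
  # order into preorder and label
  ord <- integer(0)
  stack <- 1L
  kids_of <- split(seq_len(n), factor(parent, levels = seq_len(n)))
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ord <- c(ord, v)
    kk <- kids_of[[v]]
    if (length(kk)) stack <- c(stack, rev(kk))
  }
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  lab <- character(n)
  tip_i <- 0L
  int_i <- 0L
  for (i in seq_len(n)) {
    v <- ord[i]
    if (has_kids[v]) {
      int_i <- int_i + 1L
      lab[i] <- paste0("N", int_i)
    } else {
      tip_i <- tip_i + 1L
      lab[i] <- sprintf("g%02d", tip_i)
    }
  }
  new_rooted_tree(c(0L, pos[parent[ord[-1L]]]), len[ord], lab)
}

#' Simulate one gene family on a species tree
#'
#' Gillespie simulation of a gene family: a single copy originates at a node
#' (uniformly chosen unless given) and every extant copy then experiences
#' duplication, transfer and loss as independent Poisson processes along
#' branches. A transferred copy restarts at the top of a uniformly chosen
#' branch that is neither ancestral nor descendant to the donor branch.
#'
#' @param tree a `rooted_tree` with branch lengths.
#' @param rates a [dtl_rates()] object.
#' @param seed optional integer seed.
#' @param origination_node optional node label forcing the origination point.
#' @param family_id identifier stored in the result.
#' @param make_gene_tree when `TRUE`, also return the genealogy of surviving
#'   copies as a Newick string with tips named `<genome>_<copy#>`.
#' @param max_lineages guard against runaway supercritical simulations.
#' @return a `simulated_family` list with elements `family`, `origination`
#'   (node label), `counts` (named integer copy counts per tip), `events`
#'   (node-by-mechanism truth matrix), `transfers` (donor/recipient records),
#'   `gene_tree` (Newick or `NA`), and `ledger` (internal lineage
#'   bookkeeping used by conservation checks).
#' @export
simulate_family <- function(tree, rates, seed = NULL, origination_node = NULL,
                            family_id = "fam1", make_gene_tree = FALSE,
                            max_lineages = 1e5) {
  stopifnot(inherits(tree, "rooted_tree"), inherits(rates, "dtl_rates"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$label)
  if (any(is.na(tree$length[-1L]))) stop("simulate_family needs branch lengths")
  orig <- if (is.null(origination_node)) {
    sample.int(n, 1L)
  } else {
    node_index(tree, origination_node)
  }
  desc <- nodes_below(tree)
  recipients <- vector("list", n)
  for (i in seq_len(n)[-1L]) {
    lineal <- c(i, ancestors_of(tree, i), desc[[i]])
    recipients[[i]] <- setdiff(seq_len(n)[-1L], lineal)
  }
  mech <- c("origination", "duplication", "transfer", "loss")
  ev <- matrix(0, n, 4L, dimnames = list(tree$label, mech))
  ev[orig, "origination"] <- 1
  counts <- stats::setNames(integer(sum(tree$is_tip)), tip_labels(tree))
  transfers <- list()
  rtot <- rates$duplication + rates$transfer + rates$loss

  # genealogy vertices (only kept when make_gene_tree)
  gpar <- integer(0); glen <- numeric(0); glab <- character(0)
  gadd <- function(par, len, lab = "") {
    gpar[length(gpar) + 1L] <<- par
    glen[length(glen) + 1L] <<- len
    glab[length(glab) + 1L] <<- lab
    length(gpar)
  }
  groot <- gadd(0L, 0)

  speciation_adds <- 0L
  total_lineages <- 1L
  # stack entries: branch node, position along branch, genealogy parent,
  # accumulated distance since that genealogy vertex
  stack <- list()
  push <- function(node, pos, gp, gd) stack[[length(stack) + 1L]] <<- c(node, pos, gp, gd)

  spawn_children <- function(node, gp, gd) {
    kids <- tree$children[[node]]
    vid <- gadd(gp, gd)
    speciation_adds <<- speciation_adds + length(kids) - 1L
    for (k in kids) push(k, 0, vid, 0)
  }

  if (orig == 1L) {
    # origination at the root: the copy appears at the root node itself
    spawn_children(1L, groot, 0)
  } else {
    push(orig, 0, groot, 0)
  }

  while (length(stack)) {
    if (total_lineages > max_lineages) stop("lineage cap exceeded; lower the rates")
    st <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- st[1L]; pos <- st[2L]; gp <- st[3L]; gd <- st[4L]
    len <- tree$length[node]
    repeat {
      dt <- if (rtot > 0) stats::rexp(1, rtot) else Inf
      if (pos + dt >= len) {
        gd <- gd + (len - pos)
        if (tree$is_tip[node]) {
          lab <- tree$label[node]
          counts[lab] <- counts[lab] + 1L
          gadd(gp, gd, paste0(lab, "_", counts[lab]))
        } else {
          spawn_children(node, gp, gd)
          total_lineages <- total_lineages + length(tree$children[[node]]) - 1L
        }
        break
      }
      pos <- pos + dt
      gd <- gd + dt
      type <- sample(c("D", "T", "L"), 1L,
                     prob = c(rates$duplication, rates$transfer, rates$loss))
      if (type == "L") {
        ev[node, "loss"] <- ev[node, "loss"] + 1
        break
      }
      vid <- gadd(gp, gd)
      gp <- vid
      gd <- 0
      if (type == "D") {
        ev[node, "duplication"] <- ev[node, "duplication"] + 1
        push(node, pos, vid, 0)
        total_lineages <- total_lineages + 1L
      } else {
        rec_set <- recipients[[node]]
        if (length(rec_set)) {
          ev[node, "transfer"] <- ev[node, "transfer"] + 1
          rec <- rec_set[sample.int(length(rec_set), 1L)]
          transfers[[length(transfers) + 1L]] <-
            data.frame(donor = tree$label[node], recipient = tree$label[rec],
                       tpp = 1, stringsAsFactors = FALSE)
          push(rec, 0, vid, 0)
          total_lineages <- total_lineages + 1L
        }
      }
    }
  }

  gene_tree <- NA_character_
  if (make_gene_tree && sum(counts) >= 2L) {
    gene_tree <- genealogy_newick(gpar, glen, glab)
  }
  structure(
    list(
      family = family_id,
      origination = tree$label[orig],
      counts = counts,
      events = ev,
      transfers = if (length(transfers)) do.call(rbind, transfers) else
        data.frame(donor = character(0), recipient = character(0), tpp = numeric(0)),
      gene_tree = gene_tree,
      ledger = list(speciation_adds = speciation_adds)
    ),
    class = "simulated_family"
  )
}

# prune extinct genealogy vertices, suppress unary chains, emit Newick.
# glen[i] is the edge length above vertex i; labelled vertices are surviving
# gene copies (genealogy tips).
genealogy_newick <- function(gpar, glen, glab) {
  n <- length(gpar)
  keep <- nzchar(glab)
  for (i in n:1) {
    if (keep[i] && gpar[i] > 0L) keep[gpar[i]] <- TRUE
  }
  if (sum(nzchar(glab)) < 2L) return(NA_character_)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    if (keep[i] && gpar[i] > 0L) kids[[gpar[i]]] <- c(kids[[gpar[i]]], i)
  }
  build <- function(i, extra) {
    # fold unary unlabelled chains into the accumulated branch length
    while (!nzchar(glab[i]) && length(kids[[i]]) == 1L) {
      extra <- extra + glen[i]
      i <- kids[[i]][1L]
    }
    if (nzchar(glab[i])) {
      return(sprintf("%s:%.8g", glab[i], glen[i] + extra))
    }
    inner <- paste(vapply(kids[[i]], function(k) build(k, 0), character(1)),
                   collapse = ",")
    sprintf("(%s):%.8g", inner, glen[i] + extra)
  }
  root <- 1L
  while (!nzchar(glab[root]) && length(kids[[root]]) == 1L) {
    root <- kids[[root]][1L]
  }
  if (nzchar(glab[root]) || length(kids[[root]]) < 2L) return(NA_character_)
  inner <- paste(vapply(kids[[root]], function(k) build(k, 0), character(1)),
                 collapse = ",")
  paste0("(", inner, ");")
}

#' Censor observed copy counts by genome completeness
#'
#' Emulates metagenome-assembled genomes: each gene copy in genome `g` is
#' retained independently with probability `completeness[g]`. Truth event
#' tables are untouched (censoring is observational, not evolutionary).
#'
#' @param family a `simulated_family`.
#' @param completeness named numeric vector in `[0, 1]` covering every tip,
#'   or a single value recycled to all tips.
#' @param seed optional integer seed.
#' @return the family with censored `counts`.
#' @export
censor_by_completeness <- function(family, completeness, seed = NULL) {
  stopifnot(inherits(family, "simulated_family"))
  if (!is.null(seed)) set.seed(seed)
  tips <- names(family$counts)
  if (length(completeness) == 1L && is.null(names(completeness))) {
    completeness <- stats::setNames(rep(completeness, length(tips)), tips)
  }
  if (!all(tips %in% names(completeness))) {
    stop("completeness must cover every tip of the species tree")
  }
  cv <- completeness[tips]
  if (any(cv < 0 | cv > 1)) stop("completeness values must lie in [0, 1]")
  family$counts <- stats::setNames(
    as.integer(stats::rbinom(length(tips), family$counts, cv)), tips
  )
  family
}

#' Simulate a pair of proteomes at a controlled amino-acid identity
#'
#' The second proteome is derived from the first by substituting each site
#' independently with probability `1 - target_identity`, drawing the
#' replacement uniformly from the 20 standard amino acids (so the realized
#' identity is slightly above the nominal target: `t + (1 - t)/20`).
#' Ortholog naming is preserved one-to-one, which lets downstream
#' reciprocal-best-hit statistics be validated against a known truth.
#'
#' @param n_proteins number of proteins per proteome.
#' @param length protein length (aa).
#' @param target_identity fraction in `(0, 1]`.
#' @param seed optional integer seed.
#' @return list with `a` and `b`, both [Biostrings::AAStringSet] objects with
#'   matching names.
#' @export
simulate_divergent_proteomes <- function(n_proteins, length, target_identity,
                                         seed = NULL) {
  if (target_identity <= 0 || target_identity > 1) {
    stop("target_identity must lie in (0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  nm <- sprintf("p%04d", seq_len(n_proteins))
  a <- character(n_proteins)
  b <- character(n_proteins)
  for (i in seq_len(n_proteins)) {
    s <- sample(aa, length, replace = TRUE)
    m <- s
    hit <- stats::runif(length) < (1 - target_identity)
    if (any(hit)) m[hit] <- sample(aa, sum(hit), replace = TRUE)
    a[i] <- paste(s, collapse = "")
    b[i] <- paste(m, collapse = "")
  }
  list(a = Biostrings::AAStringSet(stats::setNames(a, nm)),
       b = Biostrings::AAStringSet(stats::setNames(b, nm)))
}

#' Write family membership and truth-event tables
#'
#' `write_family_counts` emits a long TSV (family, genome, copy_count);
#' `write_truth_events` emits the per-branch truth events
#' (family, branch, mechanism, count), nonzero rows only.
#'
#' @param families list of `simulated_family` objects.
#' @param path output file.
#' @name family-io
NULL

#' @rdname family-io
#' @export
write_family_counts <- function(families, path) {
  rows <- do.call(rbind, lapply(families, function(f) {
    data.frame(family = f$family, genome = names(f$counts),
               copy_count = unname(f$counts), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname family-io
#' @export
write_truth_events <- function(families, path) {
  rows <- do.call(rbind, lapply(families, function(f) {
    idx <- which(f$events != 0, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(family = f$family,
               branch = rownames(f$events)[idx[, 1L]],
               mechanism = colnames(f$events)[idx[, 2L]],
               count = f$events[idx], stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
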