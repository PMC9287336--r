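# Parsimony reconciliation of a gene-family copy-number profile against the
# species tree. The state space is the copy number (0..c_max) at every node;
# a branch transition is paid for with duplications (gain while present),
# transfers (gain from absence: the copy arrives from a non-lineal branch)
# and losses. Exactly one origination is placed, at the cost-minimizing
# node, and is itself free. This is an undated analogue of probabilistic
# reconciliation whose downstream consumables -- per-branch event counts and
# per-node copy numbers -- are identical in kind, and it admits an exhaustive
# oracle on small trees.

#' Event costs for parsimony reconciliation
#'
#' Defaults follow the usual ordering of reconciliation costs: losses are
#' cheapest, duplications intermediate, transfers dearest, so vertical
#' explanations are preferred where they exist. Origination is free but
#' exactly one is required.
#'
#' @param duplication,transfer,loss positive costs.
#' @return a `dtl_costs` list.
#' @export
dtl_costs <- function(duplication = 2, transfer = 3, loss = 1) {
  if (any(c(duplication, transfer, loss) <= 0)) stop("costs must be positive")
  structure(list(duplication = duplication, transfer = transfer, loss = loss),
            class = "dtl_costs")
}

# transition cost/ events from `a` copies (parent side, after any origination
# credit) to `b` copies (child side). Gains from zero are transfers; gains
# while present use the cheaper of duplication/transfer (duplication on tie,
# so transfer counts stay minimal); shrinkage is loss.
trans_decode <- function(a, b, costs) {
  if (b == a) return(c(cost = 0, d = 0, t = 0, l = 0))
  if (b > a) {
    g <- b - a
    if (a == 0) {
      c(cost = g * costs$transfer, d = 0, t = g, l = 0)
    } else if (costs$duplication <= costs$transfer) {
      c(cost = g * costs$duplication, d = g, t = 0, l = 0)
    } else {
      c(cost = g * costs$transfer, d = 0, t = g, l = 0)
    }
  } else {
    c(cost = (a - b) * costs$loss, d = 0, t = 0, l = a - b)
  }
}

# K x K penalized transition matrices; rows = parent-side state 0..c_max,
# cols = child state. `orig` adds the free origination copy to the parent
# side before transitions are paid.
trans_matrices <- function(c_max, costs, tie_eps) {
  K <- c_max + 1L
  Tn <- matrix(0, K, K)
  To <- matrix(0, K, K)
  for (a in 0:c_max) {
    for (b in 0:c_max) {
      x <- trans_decode(a, b, costs)
      Tn[a + 1L, b + 1L] <- x["cost"] + tie_eps * x["t"]
      y <- trans_decode(a + 1L, b, costs)
      To[a + 1L, b + 1L] <- y["cost"] + tie_eps * y["t"]
    }
  }
  list(Tn = Tn, To = To)
}

row_min <- function(m) m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
row_argmin <- function(m) max.col(-m, ties.method = "first")

#' Parsimony duplication-transfer-loss reconciliation of a copy profile
#'
#' Finds the minimum-cost event history explaining observed per-genome copy
#' counts of one gene family on the species tree, by dynamic programming over
#' per-node copy numbers. Ties are broken in favour of fewer transfers, then
#' by preorder position of the origination node, so results are
#' deterministic.
#'
#' When `completeness` is supplied, a copy absent from genome `g` may
#' alternatively be explained as present but unobserved, at cost
#' `-log2(completeness[g])` times the loss cost (a genome of completeness 1
#' cannot hide copies, so there the explanation is unavailable).
#'
#' @param profile named non-negative integer vector of observed copy counts;
#'   names must be tips of `tree` (tips not named are taken as 0).
#' @param tree a `rooted_tree`.
#' @param costs a [dtl_costs()] object.
#' @param completeness optional named completeness fractions in `[0, 1]` per
#'   genome (or a single value).
#' @param c_max copy-number cap of the dynamic program.
#' @param family_id identifier stored in the result.
#' @return a `reconciled_family` list: `family`, `origination` (node label),
#'   `events` (node x mechanism matrix), `copies` (named per-node copy
#'   number), `transfers` (records with donor, recipient, tpp = 1),
#'   and `cost`.
#' @export
reconcile_parsimony <- function(profile, tree, costs = dtl_costs(),
                                completeness = NULL, c_max = 8,
                                family_id = "fam1") {
  stopifnot(inherits(tree, "rooted_tree"), inherits(costs, "dtl_costs"))
  tips <- tip_labels(tree)
  if (is.null(names(profile))) stop("profile must be named by genome")
  unknown <- setdiff(names(profile), tips)
  if (length(unknown)) stop("profile genomes not in tree: ", paste(unknown, collapse = ", "))
  obs <- stats::setNames(integer(length(tips)), tips)
  obs[names(profile)] <- as.integer(profile)
  if (any(obs < 0)) stop("copy counts must be non-negative")
  if (all(obs == 0)) stop("all-zero profile: the family was never observed")
  if (max(obs) > c_max) {
    stop("observed copy number ", max(obs), " exceeds c_max = ", c_max,
         "; increase the cap")
  }
  n <- length(tree$label)
  K <- c_max + 1L
  tie_eps <- 1e-9 * min(costs$duplication, costs$transfer, costs$loss)
  tm <- trans_matrices(c_max, costs, tie_eps)

  unobs_cost <- NULL
  if (!is.null(completeness)) {
    if (length(completeness) == 1L && is.null(names(completeness))) {
      completeness <- stats::setNames(rep(completeness, length(tips)), tips)
    }
    if (!all(tips %in% names(completeness))) {
      stop("completeness must cover every genome in the tree")
    }
    cv <- completeness[tips]
    if (any(cv < 0 | cv > 1)) stop("completeness values must lie in [0, 1]")
    unobs_cost <- ifelse(cv >= 1, Inf, -log2(pmax(cv, .Machine$double.xmin)) * costs$loss)
    names(unobs_cost) <- tips
  }

  # leaf state costs: without completeness the state is pinned to the
  # observation; with it, extra unobserved copies are allowed at a price
  leaf_cost <- matrix(Inf, n, K)
  for (i in which(tree$is_tip)) {
    o <- obs[tree$label[i]]
    leaf_cost[i, o + 1L] <- 0
    if (!is.null(unobs_cost) && o < c_max) {
      ks <- (o + 1L):c_max
      leaf_cost[i, ks + 1L] <- (ks - o) * unobs_cost[tree$label[i]]
    }
  }

  run_dp <- function(orig) {
    down <- matrix(0, n, K)
    for (v in n:1) {
      if (tree$is_tip[v]) {
        down[v, ] <- leaf_cost[v, ]
      } else {
        acc <- numeric(K)
        for (ch in tree$children[[v]]) {
          M <- if (ch == orig) tm$To else tm$Tn
          acc <- acc + row_min(M + matrix(down[ch, ], K, K, byrow = TRUE))
        }
        down[v, ] <- acc
      }
    }
    if (orig == 1L) {
      # origination at the root: root enters with the free copy
      tot <- tm$To[1L, ] + down[1L, ]
      k <- which.min(tot)
      list(total = tot[k], root_state = k - 1L, down = down)
    } else {
      list(total = down[1L, 1L], root_state = 0L, down = down)
    }
  }

  best <- NULL
  for (orig in seq_len(n)) {   # preorder scan doubles as the final tie-break
    res <- run_dp(orig)
    if (is.null(best) || res$total < best$total - 1e-12) {
      best <- c(res, list(orig = orig))
    }
  }
  if (!is.finite(best$total)) {
    stop("no feasible reconciliation under c_max = ", c_max)
  }

  # backtrace with the winning origination node
  orig <- best$orig
  down <- best$down
  state <- integer(n)
  state[1L] <- best$root_state
  mech <- c("origination", "duplication", "transfer", "loss")
  ev <- matrix(0, n, 4L, dimnames = list(tree$label, mech))
  ev[orig, "origination"] <- 1
  for (v in seq_len(n)) {
    if (tree$is_tip[v]) next
    for (ch in tree$children[[v]]) {
      M <- if (ch == orig) tm$To else tm$Tn
      state[ch] <- row_argmin(M + matrix(down[ch, ], K, K, byrow = TRUE))[state[v] + 1L] - 1L
    }
  }
  # root-branch events when origination is at the root
  total_cost <- 0
  add_events <- function(a, b, v) {
    x <- trans_decode(a, b, costs)
    ev[v, "duplication"] <<- ev[v, "duplication"] + x["d"]
    ev[v, "transfer"] <<- ev[v, "transfer"] + x["t"]
    ev[v, "loss"] <<- ev[v, "loss"] + x["l"]
    total_cost <<- total_cost + x["cost"]
  }
  if (orig == 1L) add_events(1L, state[1L], 1L)
  for (v in seq_len(n)[-1L]) {
    a <- state[tree$parent[v]] + as.integer(v == orig)
    add_events(a, state[v], v)
  }
  # unobserved-copy surcharge (completeness path) folded into the cost
  if (!is.null(unobs_cost)) {
    for (i in which(tree$is_tip)) {
      extra <- state[i] - obs[tree$label[i]]
      if (extra > 0) total_cost <- total_cost + extra * unobs_cost[tree$label[i]]
    }
  }

  # transfer records: donor = smallest-preorder non-lineal branch carrying
  # the family (parsimony does not identify donors; this is a deterministic
  # convention, flagged with tpp = 1)
  transfers <- list()
  t_counts <- ev[, "transfer"]
  if (any(t_counts > 0)) {
    desc <- nodes_below(tree)
    for (v in which(t_counts > 0)) {
      lineal <- c(v, ancestors_of(tree, v), desc[[v]])
      cand <- setdiff(which(state > 0), lineal)
      donor <- if (length(cand)) tree$label[min(cand)] else NA_character_
      for (j in seq_len(t_counts[v])) {
        transfers[[length(transfers) + 1L]] <- data.frame(
          donor = donor, recipient = tree$label[v], tpp = 1,
          stringsAsFactors = FALSE
        )
      }
    }
  }

  structure(
    list(
      family = family_id,
      origination = tree$label[orig],
      events = ev,
      copies = stats::setNames(as.numeric(state), tree$label),
      transfers = if (length(transfers)) do.call(rbind, transfers) else
        data.frame(donor = character(0), recipient = character(0), tpp = numeric(0)),
      cost = unname(total_cost)
    ),
    class = "reconciled_family"
  )
}

#' @export
print.reconciled_family <- function(x, ...) {
  tot <- colSums(x$events)
  cat("reconciled_family", x$family, "- origination at", x$origination,
      sprintf("(cost %.3f)\n", x$cost))
  cat(sprintf("  events: %d duplication, %d transfer, %d loss\n",
              round(tot["duplication"]), round(tot["transfer"]), round(tot["loss"])))
  invisible(x)
}

#' Ancestral presence calls from per-node copy numbers
#'
#' @param fam a `reconciled_family` (or anything with a named `copies`
#'   vector).
#' @param threshold presence threshold in `(0, 1]`; a node is called present
#'   when its copy number is at least the threshold.
#' @return named logical vector over nodes.
#' @export
ancestral_presence <- function(fam, threshold = 0.5) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  fam$copies >= threshold
}

#' Read / write reconciliation event tables
#'
#' `read_rec_table` ingests a whitespace-delimited reconciliation summary in
#' the style of probabilistic reconciliation output: one row per family and
#' branch with real-valued (possibly fractional, e.g. posterior-mean) event
#' counts. Required columns (case-insensitive): `family`, `branch`,
#' `duplications`, `transfers`, `losses`, `originations`, `copies`; extra
#' columns are ignored. `write_rec_table` writes reconciled families in the
#' same layout, so the pair round-trips.
#'
#' @param path file path.
#' @param branch_map optional data frame with columns `branch_id` and
#'   `tree_label` used to translate the table's branch identifiers onto
#'   species-tree labels; every branch id in the table must be mappable.
#' @return a list of per-family records, each with `family`, `events`
#'   (branch x mechanism matrix), `copies` (named numeric) and an empty
#'   `transfers` data frame (transfer records live in their own table, see
#'   [read_transfer_table()]).
#' @export
read_rec_table <- function(path, branch_map = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "", quote = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df) <- tolower(names(df))
  required <- c("family", "branch", "duplications", "transfers", "losses",
                "originations", "copies")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("reconciliation table is missing column(s): ",
         paste(missing, collapse = ", "),
         " (expected header: ", paste(required, collapse = " "), ")")
  }
  if (!is.null(branch_map)) {
    m <- match(df$branch, branch_map$branch_id)
    if (anyNA(m)) {
      stop("unmappable branch id(s): ",
           paste(unique(df$branch[is.na(m)]), collapse = ", "))
    }
    df$branch <- branch_map$tree_label[m]
  }
  mech <- c("origination", "duplication", "transfer", "loss")
  lapply(split(df, df$family), function(d) {
    ev <- cbind(origination = d$originations, duplication = d$duplications,
                transfer = d$transfers, loss = d$losses)
    rownames(ev) <- d$branch
    list(
      family = d$family[1L],
      events = ev,
      copies = stats::setNames(d$copies, d$branch),
      transfers = data.frame(donor = character(0), recipient = character(0),
                             tpp = numeric(0))
    )
  })
}

#' @rdname read_rec_table
#' @param families list of `reconciled_family` objects (or records as
#'   returned by `read_rec_table`).
#' @export
write_rec_table <- function(families, path) {
  rows <- do.call(rbind, lapply(families, function(f) {
    data.frame(family = f$family,
               branch = rownames(f$events),
               duplications = f$events[, "duplication"],
               transfers = f$events[, "transfer"],
               losses = f$events[, "loss"],
               originations = f$events[, "origination"],
               copies = unname(f$copies[rownames(f$events)]),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a donor/recipient transfer-record table
#'
#' Whitespace-delimited with (case-insensitive) columns `donor`, `recipient`
#' and `tpp` (transfer posterior probability; use 1 for parsimony calls);
#' an optional `family` column is carried through.
#'
#' @param path file path.
#' @return data frame of transfer records.
#' @export
read_transfer_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "", quote = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df) <- tolower(names(df))
  missing <- setdiff(c("donor", "recipient", "tpp"), names(df))
  if (length(missing)) {
    stop("transfer table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df
}
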