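# Branch x mechanism aggregation and the headline statistics built on it:
# gain composition, punctuation scores and donor/recipient transfer
# matrices. Gains are intra-phylum transfers + originations + duplications;
# losses are carried as their own column.

MECHANISMS <- c("origination", "duplication", "transfer", "loss")

#' Round half away from zero
#'
#' Plain half-up rounding (0.5 rounds to 1), used for all printed integer
#' percentages; base R's `round()` rounds half to even, which does not
#' reproduce conventional reported percentages.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Aggregate per-family events into a branch-by-mechanism table
#'
#' @param families list of `reconciled_family` objects (or records read by
#'   [read_rec_table()]).
#' @param tree optional `rooted_tree` fixing branch order to tree preorder;
#'   every family branch label must then be a tree node. Without a tree the
#'   branch set of the first family is used and all families must match it.
#' @return numeric matrix (branches x mechanisms) of class
#'   `branch_event_table`.
#' @export
aggregate_events <- function(families, tree = NULL) {
  if (!is.null(tree)) {
    branches <- tree_labels(tree)
  } else if (length(families)) {
    branches <- rownames(families[[1L]]$events)
  } else {
    stop("aggregate_events needs a tree when the family list is empty")
  }
  tab <- matrix(0, length(branches), length(MECHANISMS),
                dimnames = list(branches, MECHANISMS))
  for (f in families) {
    ev <- f$events
    bad <- setdiff(rownames(ev), branches)
    if (length(bad)) {
      stop("family ", f$family, " has branches not in the species tree: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    if (is.null(tree) && !setequal(rownames(ev), branches)) {
      stop("family ", f$family, " uses a different branch set")
    }
    tab[rownames(ev), colnames(ev)] <- tab[rownames(ev), colnames(ev)] + ev
  }
  structure(tab, class = c("branch_event_table", "matrix", "array"))
}

#' Gain composition of a branch event table
#'
#' Splits total gene gains into intra-phylum transfers, originations and
#' duplications, with integer percentages rounded half-up (so the printed
#' percentages need not sum to exactly 100). Losses are reported separately.
#'
#' @param table a `branch_event_table`, or a named numeric vector of totals
#'   with elements `transfer`, `origination`, `duplication` (and optionally
#'   `loss`).
#' @return a `gain_composition` list: `counts`, `total_gains`, `percent`,
#'   `losses`.
#' @export
gain_composition <- function(table) {
  totals <- if (is.matrix(table)) colSums(table) else table
  need <- c("transfer", "origination", "duplication")
  if (!all(need %in% names(totals))) {
    stop("need totals for: ", paste(need, collapse = ", "))
  }
  counts <- totals[need]
  total <- sum(counts)
  pct <- if (total > 0) {
    round_half_up(100 * counts / total)
  } else {
    warning("zero total gains; percentages undefined")
    stats::setNames(rep(NA_real_, 3L), need)
  }
  structure(
    list(counts = counts, total_gains = total, percent = pct,
         losses = if ("loss" %in% names(totals)) unname(totals["loss"]) else NA_real_),
    class = "gain_composition"
  )
}

#' @export
print.gain_composition <- function(x, ...) {
  cat("Gene content gains:", format(x$total_gains, big.mark = ","), "total\n")
  for (m in names(x$counts)) {
    cat(sprintf("  %-12s %10s  (%s%% of gains)\n", m,
                format(x$counts[[m]], big.mark = ","),
                ifelse(is.na(x$percent[[m]]), "-", x$percent[[m]])))
  }
  if (!is.na(x$losses)) cat("Losses:", format(x$losses, big.mark = ","), "\n")
  invisible(x)
}

#' Punctuation score of a per-branch event distribution
#'
#' The punctuation score is the sum of events on the 10% of branches with
#' the highest event numbers, divided by 10% of the sum of events on all
#' branches. A uniform spread gives 1; complete concentration on a single
#' branch gives 10 (for at least 10 branches). The number of "top" branches
#' is `max(1, round_half_up(top_fraction * n))`; ties at the boundary are
#' resolved by taking exactly `k` branches largest-first in stable order.
#'
#' @param per_branch non-negative numeric vector of per-branch event counts.
#' @param top_fraction fraction of branches forming the "top" set.
#' @param rounding how a fractional branch count is resolved: half-up
#'   rounding (default), floor or ceiling.
#' @return a `punctuation_score` list with `score`, `k` and `n`.
#' @export
punctuation_score <- function(per_branch, top_fraction = 0.1,
                              rounding = c("round", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  x <- as.numeric(per_branch)
  if (!length(x)) stop("punctuation_score: empty input")
  if (any(x < 0)) stop("punctuation_score: negative event counts")
  tot <- sum(x)
  if (tot == 0) stop("punctuation_score: all branches have zero events")
  n <- length(x)
  k <- switch(rounding,
              round = round_half_up(top_fraction * n),
              floor = floor(top_fraction * n),
              ceiling = ceiling(top_fraction * n))
  k <- max(1L, as.integer(k))
  top <- sum(sort(x, decreasing = TRUE)[seq_len(k)])
  structure(list(score = top / (top_fraction * tot), k = k, n = n),
            class = "punctuation_score")
}

#' @export
print.punctuation_score <- function(x, ...) {
  cat(sprintf("punctuation score %.3f (top %d of %d branches)\n",
              x$score, x$k, x$n))
  invisible(x)
}

#' Punctuation scores for every mechanism of a branch event table
#'
#' Mechanisms with no events at all get an `NA` score (the statistic is
#' undefined for an all-zero distribution).
#'
#' @param table a `branch_event_table`.
#' @param ... passed to [punctuation_score()].
#' @return data frame with columns `mechanism`, `k`, `score`, sorted by
#'   decreasing score.
#' @export
punctuation_scores <- function(table, ...) {
  rows <- lapply(colnames(table), function(m) {
    if (sum(table[, m]) == 0) {
      return(data.frame(mechanism = m, k = NA_integer_, score = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ps <- punctuation_score(table[, m], ...)
    data.frame(mechanism = m, k = ps$k, score = ps$score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$score, na.last = TRUE), , drop = FALSE]
}

#' Donor-by-recipient transfer count matrix
#'
#' Counts transfer records whose posterior support (TPP) reaches the
#' threshold. Row sums are transfers donated per branch, column sums
#' transfers received.
#'
#' @param records data frame with columns `donor`, `recipient`, `tpp`.
#' @param tpp_threshold minimum TPP for a record to be counted, in `[0, 1]`.
#' @param branches optional character vector fixing matrix dimensions (e.g.
#'   `tree_labels(tree)`); otherwise the union of labels in the records.
#' @return integer matrix donors x recipients.
#' @export
transfer_matrix <- function(records, tpp_threshold = 0.5, branches = NULL) {
  if (tpp_threshold < 0 || tpp_threshold > 1) stop("tpp_threshold must lie in [0, 1]")
  keep <- records[!is.na(records$tpp) & records$tpp >= tpp_threshold, , drop = FALSE]
  if (is.null(branches)) {
    branches <- sort(unique(c(records$donor, records$recipient)))
  }
  m <- matrix(0L, length(branches), length(branches),
              dimnames = list(donor = branches, recipient = branches))
  if (nrow(keep)) {
    for (r in seq_len(nrow(keep))) {
      m[keep$donor[r], keep$recipient[r]] <- m[keep$donor[r], keep$recipient[r]] + 1L
    }
  }
  m
}
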