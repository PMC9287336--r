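# Gene-tree level analysis of how often a focal group acquired a gene
# independently. The computable core is the count of maximal clades composed
# entirely of focal-group sequences on a (MAD-)rooted gene tree: under a
# gains-only model in which the gene is never transmitted between those
# clades, each maximal focal clade requires its own acquisition on its stem,
# so the count is the minimum number of independent acquisitions.

#' Medoid sequence of a protein family
#'
#' The medoid is the family member minimizing the summed pairwise distance to
#' all other members, computed on an aligned family under a substitution
#' matrix: `d(a, b) = 1 - S(a, b) / max(S(a, a), S(b, b))`, with `S` the
#' summed matrix score over columns where both sequences are ungapped. Ties
#' go to the lexicographically smallest identifier. The medoid is the
#' family's search representative for annotation and origination screens.
#'
#' @param seqs aligned sequences: a named character vector or
#'   [Biostrings::AAStringSet], all of equal (aligned) length, gaps as `-`.
#' @param matrix substitution matrix name available in Biostrings
#'   (default `"BLOSUM62"`).
#' @return the medoid sequence id.
#' @export
medoid_sequence <- function(seqs, matrix = "BLOSUM62") {
  if (inherits(seqs, "AAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named")
  }
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences are not aligned (unequal lengths)")
  }
  if (length(seqs) == 1L) return(names(seqs))
  sm <- get_substitution_matrix(matrix)
  chars <- strsplit(seqs, "", fixed = TRUE)
  score <- function(x, y) {
    ok <- x != "-" & y != "-"
    if (!any(ok)) return(NA_real_)
    sum(sm[cbind(x[ok], y[ok])])
  }
  n <- length(seqs)
  self <- vapply(chars, function(x) score(x, x), numeric(1))
  if (any(is.na(self) | self <= 0)) {
    stop("degenerate sequence (all gaps or non-positive self-score)")
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- score(chars[[i]], chars[[j]])
      d <- if (is.na(s)) 1 else 1 - s / max(self[i], self[j])
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  tot <- rowSums(D)
  ids <- names(seqs)
  best <- which(tot <= min(tot) + 1e-12)
  ids[best][order(ids[best])][1L]
}

get_substitution_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Test whether a focal group is monophyletic on a rooted tree
#'
#' @param tree a `rooted_tree`.
#' @param groups named character vector: tip label -> group label.
#' @param focal the focal group label.
#' @return `TRUE` iff the smallest clade containing every focal tip contains
#'   only focal tips.
#' @export
monophyly_test <- function(tree, groups, focal) {
  focal_tips <- names(groups)[groups == focal]
  focal_tips <- intersect(focal_tips, tip_labels(tree))
  if (!length(focal_tips)) stop("no tips belong to the focal group")
  idx <- node_index(tree, focal_tips)
  m <- mrca_index(tree, idx)
  setequal(clade_tips(tree, tree$label[m]), focal_tips)
}

#' Minimum independent acquisitions of a gene by a focal group
#'
#' Counts the maximal clades of the (rooted) gene tree whose tips all belong
#' to the focal group. Under a gains-only (Dollo-style) model with no
#' transmission between those clades, this is the minimum number of
#' independent acquisitions consistent with the tip labelling; it equals 1
#' exactly when the focal group is monophyletic.
#'
#' @param tree a `rooted_tree` gene tree. When `reroot = "mad"` the tree is
#'   first rerooted by minimal ancestral deviation (the standard choice for
#'   gene trees that carry no outgroup information).
#' @param groups named character vector tip label -> group label.
#' @param focal focal group label.
#' @param reroot `"none"` (use the rooting as given) or `"mad"`.
#' @return an `acquisition_report` list: `monophyletic`, `min_acquisitions`,
#'   `gain_clades` (stem labels of the maximal focal clades), `rooting`.
#' @export
min_acquisitions <- function(tree, groups, focal, reroot = c("none", "mad")) {
  reroot <- match.arg(reroot)
  stopifnot(inherits(tree, "rooted_tree"))
  rooting <- "as-given"
  if (reroot == "mad") {
    tree <- mad_root(tree)$tree
    rooting <- "MAD"
  }
  focal_tips <- names(groups)[groups == focal]
  focal_tips <- intersect(focal_tips, tip_labels(tree))
  if (!length(focal_tips)) stop("no tips belong to the focal group")

  n <- length(tree$label)
  all_focal <- logical(n)
  for (v in n:1) {
    all_focal[v] <- if (tree$is_tip[v]) {
      tree$label[v] %in% focal_tips
    } else {
      all(all_focal[tree$children[[v]]])
    }
  }
  maximal <- which(all_focal & (tree$parent == 0L | !all_focal[pmax(tree$parent, 1L)]))
  structure(
    list(
      monophyletic = length(maximal) == 1L,
      min_acquisitions = length(maximal),
      gain_clades = tree$label[maximal],
      rooting = rooting
    ),
    class = "acquisition_report"
  )
}

#' @export
print.acquisition_report <- function(x, ...) {
  cat("acquisition report:", x$min_acquisitions, "independent acquisition(s);",
      if (x$monophyletic) "focal group monophyletic" else "focal group polyphyletic",
      paste0("(rooting: ", x$rooting, ")\n"))
  invisible(x)
}

#' Read a tip-to-group assignment table
#'
#' Two-column TSV (tip, group) with header.
#'
#' @param path file path.
#' @return named character vector tip -> group.
#' @export
read_groups <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df) <- tolower(names(df))
  if (!all(c("tip", "group") %in% names(df))) {
    stop("group table needs columns 'tip' and 'group'")
  }
  stats::setNames(df$group, df$tip)
}
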