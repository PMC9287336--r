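# Genome quality filtering, average amino acid identity (AAI) and rank
# clustering, completeness adjustments, proteome novelty and marker/family
# filters -- the statistics used to delimit genera/species and to summarize
# metagenome-assembled genome (MAG) panels.

#' Filter genomes on completeness and contamination
#'
#' Retention uses strict inequalities: completeness strictly above
#' `min_completeness` and contamination strictly below `max_contamination`
#' (so a genome exactly at a threshold is excluded). The conventional MAG
#' screens are (45, 10) for inclusion and (70, 5) for a higher-quality set.
#'
#' @param records data frame with numeric columns `completeness` and
#'   `contamination` (percent).
#' @param min_completeness,max_contamination percent thresholds.
#' @return the retained rows of `records`.
#' @export
filter_genomes <- function(records, min_completeness = 45, max_contamination = 10) {
  stopifnot(all(c("completeness", "contamination") %in% names(records)))
  if (min_completeness < 0 || min_completeness > 100 || max_contamination < 0) {
    stop("invalid thresholds")
  }
  records[records$completeness > min_completeness &
            records$contamination < max_contamination, , drop = FALSE]
}

#' Average amino acid identity (AAI) between two proteomes
#'
#' Computes local alignments (BLOSUM62, affine gaps) between all protein
#' pairs, takes reciprocal best hits by alignment score, and averages the
#' percent identity of the RBH alignments. With no RBH pair above the score
#' floor the AAI is undefined and flagged as such (never silently 0).
#'
#' @param a,b [Biostrings::AAStringSet] proteomes (non-empty).
#' @param gap_opening,gap_extension affine gap penalties.
#' @param min_score minimum alignment score for a hit to count.
#' @return an `aai_result` list: `aai` (percent, `NA` when undefined),
#'   `n_pairs` (number of RBH pairs used), `defined` (logical).
#' @export
compute_aai <- function(a, b, gap_opening = 10, gap_extension = 0.5,
                        min_score = 0) {
  if (!length(a) || !length(b)) stop("empty proteome")
  if (is.null(names(a)) || is.null(names(b))) stop("proteomes must be named")
  na <- length(a); nb <- length(b)
  S <- matrix(-Inf, na, nb)
  for (j in seq_len(nb)) {
    S[, j] <- Biostrings::pairwiseAlignment(
      a, b[[j]], type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = gap_opening, gapExtension = gap_extension,
      scoreOnly = TRUE
    )
  }
  best_ab <- max.col(S, ties.method = "first")          # best b for each a
  best_ba <- max.col(t(S), ties.method = "first")       # best a for each b
  rbh_a <- which(best_ba[best_ab] == seq_len(na) &
                   S[cbind(seq_len(na), best_ab)] > min_score)
  if (!length(rbh_a)) {
    return(structure(list(aai = NA_real_, n_pairs = 0L, defined = FALSE),
                     class = "aai_result"))
  }
  pids <- vapply(rbh_a, function(i) {
    aln <- Biostrings::pairwiseAlignment(
      a[[i]], b[[best_ab[i]]], type = "local",
      substitutionMatrix = "BLOSUM62",
      gapOpening = gap_opening, gapExtension = gap_extension
    )
    Biostrings::pid(aln, type = "PID1")
  }, numeric(1))
  structure(list(aai = mean(pids), n_pairs = length(rbh_a), defined = TRUE),
            class = "aai_result")
}

#' @export
print.aai_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("AAI %.2f%% over %d reciprocal best hit pairs\n", x$aai, x$n_pairs))
  } else {
    cat("AAI undefined (no reciprocal best hits above the score floor)\n")
  }
  invisible(x)
}

#' Pairwise AAI matrix over a panel of proteomes
#'
#' @param proteomes named list of [Biostrings::AAStringSet] objects.
#' @param ... passed to [compute_aai()].
#' @return symmetric percent matrix with 100 on the diagonal; pairs with
#'   undefined AAI are `NA`.
#' @export
aai_matrix <- function(proteomes, ...) {
  n <- length(proteomes)
  ids <- names(proteomes)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- compute_aai(proteomes[[i]], proteomes[[j]], ...)
      m[i, j] <- m[j, i] <- r$aai
    }
  }
  m
}

#' Delimit taxa by AAI clustering with polyphyly splitting
#'
#' Average-linkage agglomerative clustering of the AAI matrix, cut so that
#' clusters hold together at or above the AAI threshold (70% for genera, 95%
#' for species by convention). Each cluster is then checked against the
#' species-tree topology: clusters that are polyphyletic on the tree are
#' split into their maximal monophyletic components, reflecting the rule that
#' an AAI-cohesive but polyphyletic group is treated as separate taxa.
#'
#' @param matrix symmetric AAI percent matrix (row/col names = genome ids).
#' @param threshold AAI percent threshold.
#' @param tree a `rooted_tree` whose tips include every genome in the matrix.
#' @param rank optional label (`"genus"`, `"species"`, ...) carried through.
#' @return a list of `taxon_cluster` records (`rank`, `members`,
#'   `threshold`), plus a `membership` attribute: named vector genome ->
#'   cluster id.
#' @export
cluster_taxa <- function(matrix, threshold, tree, rank = NULL) {
  ids <- rownames(matrix)
  if (is.null(ids)) stop("AAI matrix must have genome ids as dimnames")
  missing_tips <- setdiff(ids, tip_labels(tree))
  if (length(missing_tips)) {
    stop("genomes not on the species tree: ", paste(missing_tips, collapse = ", "))
  }
  if (length(ids) == 1L) {
    groups <- stats::setNames(1L, ids)
  } else {
    d <- stats::as.dist(100 - matrix)
    if (anyNA(d)) stop("AAI matrix contains undefined pairs")
    hc <- stats::hclust(d, method = "average")
    groups <- stats::cutree(hc, h = 100 - threshold)
  }
  clusters <- list()
  membership <- character(length(ids))
  names(membership) <- ids
  for (g in sort(unique(groups))) {
    members <- ids[groups == g]
    comps <- monophyletic_components(tree, members, universe = ids)
    for (ci in seq_along(comps)) {
      cid <- if (length(comps) > 1L) paste0("C", g, ".", ci) else paste0("C", g)
      clusters[[length(clusters) + 1L]] <- structure(
        list(rank = rank, members = comps[[ci]], threshold = threshold),
        class = "taxon_cluster"
      )
      membership[comps[[ci]]] <- cid
    }
  }
  structure(clusters, membership = membership, class = "taxon_clustering")
}

#' @export
print.taxon_clustering <- function(x, ...) {
  cat(length(x), "cluster(s)\n")
  for (cl in x) {
    cat(sprintf("  [%s @ %s%%] %s\n", ifelse(is.null(cl$rank), "-", cl$rank),
                cl$threshold, paste(cl$members, collapse = ", ")))
  }
  invisible(x)
}

# maximal clades of `tree` whose descendant tips, restricted to the
# clustered genome universe, lie entirely inside `members`. Tips outside the
# universe (e.g. outgroups) are ignored, i.e. monophyly is judged on the
# induced subtree of the clustered genomes.
monophyletic_components <- function(tree, members, universe = members) {
  n <- length(tree$label)
  tb <- tips_below(tree)
  pure <- logical(n)
  has_member <- logical(n)
  for (v in n:1) {
    tips_v <- intersect(tree$label[tb[[v]]], universe)
    has_member[v] <- any(tips_v %in% members)
    pure[v] <- has_member[v] && all(tips_v %in% members)
  }
  maximal <- which(pure & (tree$parent == 0L | !pure[pmax(tree$parent, 1L)]))
  lapply(maximal, function(v) intersect(tree$label[tb[[v]]], members))
}

#' Adjust a measured genome quantity for completeness
#'
#' Linear extrapolation: `adjusted = measured / (completeness / 100)`. Used
#' for genome size and CDS counts of incomplete MAGs.
#'
#' @param measured numeric (bp, CDS count, ...).
#' @param completeness percent in `(0, 100]`.
#' @return adjusted value(s).
#' @export
adjust_for_completeness <- function(measured, completeness) {
  if (any(completeness <= 0 | completeness > 100)) {
    stop("completeness must lie in (0, 100]")
  }
  measured / (completeness / 100)
}

#' Proteome novelty: percentage of proteins without a close homologue
#'
#' A protein has a close homologue iff it retains at least one hit after
#' removing hits that fail any filter: e-value above `max_evalue`, percent
#' identity below `min_pid`, alignment length below `min_alen`, or bit score
#' below `min_bitscore`. Novelty is the percentage of proteins with no
#' surviving hit.
#'
#' @param hits data frame with columns `query`, `pid`, `alen`, `evalue`,
#'   `bitscore` (one row per hit; proteins without hits simply do not
#'   appear).
#' @param n_proteins total number of proteins in the proteome.
#' @param max_evalue,min_pid,min_alen,min_bitscore filter thresholds
#'   (defaults are the conventional arCOG screen: 1e-5 / 35% / 80 aa / 100
#'   bits).
#' @return novelty percentage.
#' @export
proteome_novelty <- function(hits, n_proteins, max_evalue = 1e-5, min_pid = 35,
                             min_alen = 80, min_bitscore = 100) {
  if (n_proteins <= 0) stop("n_proteins must be positive")
  keep <- hits$evalue <= max_evalue & hits$pid >= min_pid &
    hits$alen >= min_alen & hits$bitscore >= min_bitscore
  with_hit <- unique(hits$query[keep])
  if (length(unique(hits$query)) > n_proteins) {
    stop("more distinct queries than n_proteins")
  }
  100 * (n_proteins - length(with_hit)) / n_proteins
}

#' Select single-copy marker families
#'
#' A family qualifies when no genome carries two or more copies and the
#' fraction of genomes carrying exactly one copy is at least `min_fraction`
#' (boundary inclusive: "at least 50%" keeps a family present in exactly half
#' the genomes).
#'
#' @param copy_matrix integer matrix, families x genomes.
#' @param min_fraction required occupancy in `(0, 1]`.
#' @return character vector of retained family ids (rownames).
#' @export
select_markers <- function(copy_matrix, min_fraction = 0.5) {
  if (min_fraction <= 0 || min_fraction > 1) stop("min_fraction must lie in (0, 1]")
  single <- apply(copy_matrix, 1L, function(x) all(x <= 1L))
  occ <- rowMeans(copy_matrix == 1L)
  rownames(copy_matrix)[single & occ >= min_fraction]
}

#' Filter gene families on sequence length and family size
#'
#' Sequences shorter than `min_aa` residues are removed first; families left
#' with fewer than `min_seqs` sequences are then dropped entirely (so a
#' four-member family with one short sequence is removed).
#'
#' @param families named list of character vectors (or
#'   [Biostrings::AAStringSet]s) of protein sequences.
#' @param min_aa minimum sequence length (amino acids).
#' @param min_seqs minimum family size after the length filter.
#' @return the filtered named list.
#' @export
filter_families <- function(families, min_aa = 30, min_seqs = 4) {
  out <- lapply(families, function(f) {
    if (inherits(f, "AAStringSet")) f <- as.character(f)
    f[nchar(f) >= min_aa]
  })
  out[vapply(out, length, integer(1)) >= min_seqs]
}

#' Summary statistics of a genome panel
#'
#' Means and ranges of completeness, contamination and any of the optional
#' columns `size`, `cds`, `novelty` present in the records, plus the 16S
#' rRNA recovery rate (percentage of genomes with at least one 16S gene,
#' rounded half-up to an integer).
#'
#' @param records data frame with `completeness`, `contamination`, and
#'   optionally `size`, `cds`, `novelty`, `rrna_16s` (16S gene count per
#'   genome).
#' @return a `genome_summary` list.
#' @export
summarize_genomes <- function(records) {
  if (!nrow(records)) stop("no genome records")
  fields <- intersect(c("completeness", "contamination", "size", "cds", "novelty"),
                      names(records))
  stats_of <- function(x) c(mean = mean(x), min = min(x), max = max(x))
  out <- lapply(fields, function(f) stats_of(records[[f]]))
  names(out) <- fields
  p16 <- NA_real_
  if ("rrna_16s" %in% names(records)) {
    p16 <- round_half_up(100 * sum(records$rrna_16s >= 1) / nrow(records))
  }
  structure(list(n = nrow(records), stats = out, p16s_recovery = p16),
            class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat("genome panel:", x$n, "genomes\n")
  for (f in names(x$stats)) {
    s <- x$stats[[f]]
    cat(sprintf("  %-13s mean %.3g (range %.3g-%.3g)\n", f, s["mean"], s["min"], s["max"]))
  }
  if (!is.na(x$p16s_recovery)) {
    cat("  16S recovery:", x$p16s_recovery, "%\n")
  }
  invisible(x)
}
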