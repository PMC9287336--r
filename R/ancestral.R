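# Ancestral genome content and its functional interpretation. Presence sets
# per node come from reconciled copy numbers; gains and losses between a
# parent ancestor and its descendant are computed at the level of KEGG
# ortholog (KO) identifiers, not gene families: a function is only lost when
# no family carrying it remains.

#' Ancestral genome presence sets
#'
#' @param families list of `reconciled_family` objects (or [read_rec_table()]
#'   records) sharing one species tree.
#' @param threshold copy-number presence threshold, see
#'   [ancestral_presence()].
#' @return named list: node label -> character vector of family ids present.
#' @export
ancestral_genomes <- function(families, threshold = 0.5) {
  if (!length(families)) stop("empty family list")
  nodes <- names(families[[1L]]$copies)
  sets <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(sets)) sets[[i]] <- character(0)
  for (f in families) {
    pres <- names(f$copies)[f$copies >= threshold]
    for (nd in pres) sets[[nd]] <- c(sets[[nd]], f$family)
  }
  sets
}

# family set -> KO set under a named map (families without a KO contribute
# nothing)
ko_set <- function(families, ko_map) {
  kos <- ko_map[intersect(families, names(ko_map))]
  sort(unique(kos[!is.na(kos) & nzchar(kos)]))
}

#' Functional gain/loss delta between a parent and child ancestor
#'
#' A KO is gained on the branch when some family carrying it is present in
#' the child but none was in the parent; it is lost when the parent carried
#' it and no family in the child still does. Deltas are therefore computed on
#' KO sets, so losing one of two families that map to the same KO is not a
#' functional loss.
#'
#' @param parent,child character vectors of family ids present in the two
#'   ancestral genomes.
#' @param ko_map named character vector family id -> KO identifier (`NA` or
#'   missing entries are unannotated families).
#' @return list with `gained` and `lost` (disjoint KO character vectors).
#' @export
functional_delta <- function(parent, child, ko_map) {
  pk <- ko_set(parent, ko_map)
  ck <- ko_set(child, ko_map)
  list(gained = setdiff(ck, pk), lost = setdiff(pk, ck))
}

#' Functional deltas on every branch of the species tree
#'
#' @param genomes node -> family set list from [ancestral_genomes()].
#' @param tree the `rooted_tree` the genomes were reconstructed on.
#' @param ko_map named character vector family id -> KO.
#' @return named list (child node label -> delta) over all non-root nodes.
#' @export
functional_deltas <- function(genomes, tree, ko_map) {
  n <- length(tree$label)
  out <- list()
  for (v in seq_len(n)[-1L]) {
    p <- tree$label[tree$parent[v]]
    c_ <- tree$label[v]
    out[[c_]] <- functional_delta(genomes[[p]], genomes[[c_]], ko_map)
  }
  out
}

#' Write functional deltas as a long TSV (branch, direction, KO)
#'
#' @param deltas output of [functional_deltas()].
#' @param path output file.
#' @export
write_deltas <- function(deltas, path) {
  rows <- do.call(rbind, lapply(names(deltas), function(b) {
    d <- deltas[[b]]
    rbind(
      if (length(d$gained)) data.frame(branch = b, direction = "gain", ko = d$gained),
      if (length(d$lost)) data.frame(branch = b, direction = "loss", ko = d$lost)
    )
  }))
  if (is.null(rows)) rows <- data.frame(branch = character(0),
                                        direction = character(0), ko = character(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify the source of a gene-family origination
#'
#' An origination is called an inter-phyla lateral transfer when the family
#' representative has homologues outside the focal group in a reference hit
#' table; the putative source is the taxon of the best remaining hit by bit
#' score (lexicographic tie-break, with a warning). With no remaining hits
#' the origination stays unresolved: de novo formation and transfer from an
#' unsampled donor cannot be told apart.
#'
#' @param family family id (matched against a `query` column when present).
#' @param node origination node label (carried through).
#' @param hits data frame with columns `taxon` and `bitscore` (and optionally
#'   `query`).
#' @param focal_group taxon label to exclude (matches within the focal group
#'   are not evidence of inter-phylum transfer).
#' @return an `origination_call` list: `family`, `node`, `classification`
#'   (`"inter_phyla_LGT"` or `"unresolved"`), `source`, `bitscore`.
#' @export
classify_origination <- function(family, node, hits, focal_group) {
  h <- hits
  if ("query" %in% names(h)) h <- h[h$query == family, , drop = FALSE]
  h <- h[!is.na(h$taxon) & h$taxon != focal_group, , drop = FALSE]
  if (!nrow(h)) {
    return(structure(list(family = family, node = node,
                          classification = "unresolved",
                          source = NA_character_, bitscore = NA_real_),
                     class = "origination_call"))
  }
  best <- max(h$bitscore)
  cand <- sort(unique(h$taxon[h$bitscore == best]))
  if (length(cand) > 1L) {
    warning("bit-score tie between ", paste(cand, collapse = ", "),
            "; taking the lexicographically first")
  }
  structure(list(family = family, node = node,
                 classification = "inter_phyla_LGT",
                 source = cand[1L], bitscore = best),
            class = "origination_call")
}

#' Map trait gains onto the species tree and count independent gains
#'
#' A trait is present at a node when its ancestral genome carries any (or,
#' with `require_all = TRUE`, all) of the trait's KOs. A gain branch is a
#' branch whose child has the trait while its parent does not (presence at
#' the root counts as one gain on the root stem); the number of gain branches
#' is the number of independent acquisitions implied by the ancestral
#' reconstruction, and a loss/regain along one lineage contributes two.
#'
#' @param trait_kos character vector of KO identifiers defining the trait.
#' @param genomes node -> family set list from [ancestral_genomes()].
#' @param tree the species `rooted_tree`.
#' @param ko_map named character vector family id -> KO.
#' @param require_all require every trait KO (multi-subunit traits) rather
#'   than any.
#' @return list with `gain_branches` (labels), `count`, and the per-node
#'   logical `presence` vector.
#' @export
map_trait_gains <- function(trait_kos, genomes, tree, ko_map,
                            require_all = FALSE) {
  stopifnot(length(trait_kos) >= 1L)
  pres <- vapply(tree$label, function(nd) {
    kos <- ko_set(genomes[[nd]], ko_map)
    if (require_all) all(trait_kos %in% kos) else any(trait_kos %in% kos)
  }, logical(1))
  gains <- character(0)
  if (pres[1L]) gains <- tree$label[1L]
  for (v in seq_along(tree$label)[-1L]) {
    if (pres[v] && !pres[tree$parent[v]]) gains <- c(gains, tree$label[v])
  }
  list(gain_branches = gains, count = length(gains), presence = pres)
}

#' Read a family-to-KO annotation map
#'
#' Two-column TSV (family, ko) with header.
#'
#' @param path file path.
#' @return named character vector family -> KO.
#' @export
read_ko_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df) <- tolower(names(df))
  if (!all(c("family", "ko") %in% names(df))) {
    stop("KO map needs columns 'family' and 'ko'")
  }
  stats::setNames(df$ko, df$family)
}

#' Read a homology hit table
#'
#' Whitespace/tab-delimited with header columns (case-insensitive): `query`,
#' `subject`, `taxon`, `pid`, `alen`, `evalue`, `bitscore`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_hit_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "", quote = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df) <- tolower(names(df))
  need <- c("query", "subject", "taxon", "pid", "alen", "evalue", "bitscore")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("hit table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(df$pid < 0 | df$pid > 100)) stop("percent identity must lie in [0, 100]")
  if (any(df$evalue < 0)) stop("e-values must be non-negative")
  df
}
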