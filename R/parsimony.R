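# Maximum-parsimony inference: Fitch scoring, random-addition starting
# trees, close-neighbor-interchange search, nonparametric bootstrap,
# majority-rule consensus with sub-threshold collapse, outgroup rooting.
#
# Characters are unordered 20-state with unit cost; bootstrap resampling is
# by columns of the complete-deletion matrix and is carried as integer
# column weights into the C++ scorer.  Given a seed, the whole pipeline is
# deterministic; among equally parsimonious trees the first found under the
# seeded search order is kept.

# encode a char_matrix as tip x column bitmasks in the tree's tip order
.encode_states <- function(cmat, tip_order) {
  if (!setequal(cmat$taxa, tip_order)) {
    stop("tree taxa and character-matrix taxa differ", call. = FALSE)
  }
  mat <- cmat$mat[match(tip_order, cmat$taxa), , drop = FALSE]
  idx <- match(mat, AA20)
  if (anyNA(idx)) {
    stop("character matrix contains gaps or unknown states; apply complete_deletion first",
         call. = FALSE)
  }
  matrix(bitwShiftL(1L, idx - 1L), nrow = nrow(mat), ncol = ncol(mat))
}

#' Fitch parsimony score of a tree
#'
#' Minimum number of unordered state changes summed over columns, computed
#' by the classic set-intersection/union pass.  The score is invariant to
#' root placement; the tree must be binary (a basal trifurcation, i.e. an
#' unrooted binary tree, is also accepted).
#'
#' @param tree a phylo whose tip labels equal the matrix taxa.
#' @param cmat a `char_matrix` (see [complete_deletion()]).
#' @param weights optional integer column weights (bootstrap resampling).
#' @return integer number of steps.
#' @export
fitch_score <- function(tree, cmat, weights = NULL) {
  stopifnot(inherits(tree, "phylo"))
  states <- .encode_states(cmat, tree$tip.label)
  if (is.null(weights)) weights <- rep(1L, ncol(states))
  po <- ape::reorder.phylo(tree, "postorder")
  as.integer(cpp_fitch_edge(po$edge, length(tree$tip.label), states,
                            as.integer(weights)))
}

.edge_to_phylo <- function(edge, tip_labels, score = NULL) {
  nTip <- length(tip_labels)
  tr <- list(edge = edge, tip.label = tip_labels,
             Nnode = max(edge) - nTip)
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr <- ape::read.tree(text = ape::write.tree(tr))  # normalize numbering
  if (!is.null(score)) attr(tr, "parsimony_score") <- as.integer(score)
  tr
}

#' Random-addition starting tree
#'
#' Taxa are inserted in a seeded random order, each at the attachment point
#' minimizing the Fitch score of the partial tree (first-encountered
#' minimum; deterministic given the seed).
#'
#' @param cmat a `char_matrix`.
#' @param seed integer RNG seed.
#' @param weights optional integer column weights.
#' @return a phylo with attribute `parsimony_score`.
#' @export
random_addition_tree <- function(cmat, seed = 1, weights = NULL) {
  taxa <- cmat$taxa
  n <- length(taxa)
  if (n < 4L) {
    # trivial: single topology
    nwk <- if (n == 2L) sprintf("(%s,%s);", taxa[1], taxa[2]) else
      sprintf("(%s,(%s,%s));", taxa[1], taxa[2], taxa[3])
    tr <- ape::read.tree(text = nwk)
    attr(tr, "parsimony_score") <- fitch_score(tr, cmat, weights)
    return(tr)
  }
  states <- .encode_states(cmat, taxa)
  if (is.null(weights)) weights <- rep(1L, ncol(states))
  ord <- with_seed(seed, sample.int(n))
  res <- cpp_random_addition(states, as.integer(weights), ord)
  .edge_to_phylo(res$edge, taxa, res$score)
}

#' Close-neighbor-interchange search
#'
#' Hill-climbs over the neighborhood of topologies reachable by at most
#' `level` successive nearest-neighbor-interchange moves, taking the best
#' strictly improving move each round; never returns a tree worse than the
#' start.
#'
#' @param start_tree binary phylo over the matrix taxa.
#' @param cmat a `char_matrix`.
#' @param level neighborhood depth (default 2, the classic "search level
#'   2").
#' @param weights optional integer column weights.
#' @return a phylo with attribute `parsimony_score`.
#' @export
cni_search <- function(start_tree, cmat, level = 2, weights = NULL) {
  taxa <- start_tree$tip.label
  states <- .encode_states(cmat, taxa)
  if (is.null(weights)) weights <- rep(1L, ncol(states))
  tr <- start_tree
  if (!ape::is.binary.phylo(tr)) tr <- ape::multi2di(tr)
  if (!ape::is.rooted(tr)) tr <- ape::root(tr, outgroup = taxa[1],
                                           resolve.root = TRUE)
  tr <- ape::reorder.phylo(tr, "cladewise")
  res <- cpp_cni(states, as.integer(weights), tr$edge, length(taxa),
                 as.integer(level))
  .edge_to_phylo(res$edge, taxa, res$score)
}

# one full MP search: n_starts random-addition replicates, each refined by
# CNI, best tree kept (first found on ties)
.mp_search <- function(states, taxa, weights, n_starts, level, seed) {
  orders <- with_seed(seed, t(vapply(seq_len(n_starts), function(i)
    sample.int(length(taxa)), integer(length(taxa)))))
  res <- cpp_mp_search(states, as.integer(weights), orders,
                       as.integer(level))
  .edge_to_phylo(res$edge, taxa, res$score)
}

#' Maximum-parsimony tree search
#'
#' Random addition of sequences (`n_starts` replicates) followed by
#' close-neighbor-interchange refinement, as in the classic MP protocol.
#'
#' @param cmat a `char_matrix`.
#' @param n_starts number of random-addition replicates (default 10).
#' @param level CNI search level (default 2).
#' @param seed integer RNG seed.
#' @return a phylo with attribute `parsimony_score`.
#' @export
mp_tree <- function(cmat, n_starts = 10, level = 2, seed = 1) {
  states <- .encode_states(cmat, cmat$taxa)
  .mp_search(states, cmat$taxa, rep(1L, ncol(states)), n_starts, level, seed)
}

#' Nonparametric bootstrap over matrix columns
#'
#' Each replicate resamples columns with replacement to the original
#' length, then runs the full MP search (random addition + CNI).
#'
#' @param cmat a `char_matrix`.
#' @param n_reps bootstrap replicates (classic setting 500).
#' @param seed integer RNG seed.
#' @param n_starts,level search parameters per replicate.
#' @return list of phylo trees, length `n_reps`.
#' @export
bootstrap_trees <- function(cmat, n_reps = 500, seed = 1, n_starts = 10,
                            level = 2) {
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  states <- .encode_states(cmat, cmat$taxa)
  ncol_full <- ncol(states)
  lapply(seq_len(n_reps), function(r) {
    rs <- derive_seed(seed, r)
    idx <- with_seed(rs, sample.int(ncol_full, ncol_full, replace = TRUE))
    tab <- tabulate(idx, nbins = ncol_full)
    keep <- which(tab > 0L)
    .mp_search(states[, keep, drop = FALSE], cmat$taxa, tab[keep],
               n_starts, level, derive_seed(rs, 1L))
  })
}

# ---- consensus -------------------------------------------------------------

# nontrivial splits of an unrooted tree, each canonicalized as the sorted
# taxon set on the side NOT containing `ref` (taxon names)
.splits_of <- function(tree, taxa, ref) {
  n <- length(taxa)
  tr <- ape::reorder.phylo(tree, "postorder")
  idx <- match(tr$tip.label, taxa)
  nTip <- length(tr$tip.label)
  below <- vector("list", nTip + tr$Nnode)
  for (i in seq_len(nTip)) below[[i]] <- idx[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  ref_i <- match(ref, taxa)
  out <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2]
    if (ch <= nTip) next
    side <- below[[ch]]
    if (ref_i %in% side) side <- setdiff(seq_len(n), side)
    if (length(side) < 2L || length(side) > n - 2L) next
    out <- c(out, paste(sort(side), collapse = ","))
  }
  unique(out)
}

#' Majority-rule bootstrap consensus
#'
#' Retains exactly the bipartitions occurring in at least `collapse_below`
#' percent of the input trees; every retained edge is annotated with its
#' exact percentage (node labels).  If `outgroup` is given the consensus is
#' returned rooted on it, ready for [extract_subfamilies()].
#'
#' @param trees list of phylo over identical leaf sets.
#' @param collapse_below retention threshold in percent (default 50).
#' @param outgroup optional taxon label to root the consensus on.
#' @return a phylo; node labels carry support percentages (root empty).
#' @export
majority_consensus <- function(trees, collapse_below = 50, outgroup = NULL) {
  if (!length(trees)) stop("no trees", call. = FALSE)
  taxa <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    if (!setequal(tr$tip.label, taxa)) {
      stop("trees have inconsistent leaf sets", call. = FALSE)
    }
  }
  ref <- if (!is.null(outgroup)) {
    if (!outgroup %in% taxa) stop("outgroup not among taxa", call. = FALSE)
    outgroup
  } else taxa[1]

  counts <- table(unlist(lapply(trees, .splits_of, taxa = taxa, ref = ref)))
  pct <- 100 * as.numeric(counts) / length(trees)
  keep <- pct >= collapse_below
  clades <- lapply(names(counts)[keep], function(s)
    as.integer(strsplit(s, ",", fixed = TRUE)[[1]]))
  support <- pct[keep]

  # nest retained clades (all pairwise compatible by majority rule)
  ord <- order(vapply(clades, length, integer(1)))
  clades <- clades[ord]; support <- support[ord]
  nC <- length(clades)
  parent <- rep(0L, nC)  # 0 = top level
  if (nC > 1L) {
    for (i in seq_len(nC - 1L)) {
      for (j in (i + 1L):nC) {
        if (all(clades[[i]] %in% clades[[j]])) { parent[i] <- j; break }
      }
    }
  }
  tip_parent <- rep(0L, length(taxa))
  for (t in seq_along(taxa)) {
    holders <- which(vapply(clades, function(cl) t %in% cl, logical(1)))
    if (length(holders)) tip_parent[t] <- holders[which.min(
      vapply(clades[holders], length, integer(1)))]
  }
  build <- function(ci) {
    kids_cl <- which(parent == ci)
    kids_t <- which(tip_parent == ci)
    parts <- c(vapply(kids_cl, build, character(1)), taxa[kids_t])
    if (ci == 0L) sprintf("(%s)root", paste(parts, collapse = ",")) else
      sprintf("(%s)%s", paste(parts, collapse = ","),
              format(round_half_up(support[ci]), trim = TRUE))
  }
  # exclude the reference taxon from nesting (it is never inside a clade)
  nwk <- paste0(build(0L), ";")
  tr <- ape::read.tree(text = nwk)
  tr$node.label[tr$node.label == "root"] <- ""
  if (!is.null(outgroup)) {
    # reference = outgroup: every clade is an ingroup clade; already rooted
    # with the outgroup attached at the top level
    attr(tr, "outgroup") <- outgroup
  }
  attr(tr, "n_trees") <- length(trees)
  tr
}

#' Root a tree on an outgroup taxon
#'
#' Places the root on the edge subtending the outgroup; support labels are
#' treated as edge labels so they stay attached to the correct bipartition.
#'
#' @param tree a phylo.
#' @param outgroup_taxon a tip label.
#' @return rooted phylo with attribute `outgroup`.
#' @export
root_with_outgroup <- function(tree, outgroup_taxon) {
  if (!outgroup_taxon %in% tree$tip.label) {
    stop(sprintf("outgroup taxon '%s' not in tree", outgroup_taxon),
         call. = FALSE)
  }
  has_labels <- !is.null(tree$node.label)
  tr <- ape::root(tree, outgroup = outgroup_taxon, resolve.root = TRUE,
                  edgelabel = has_labels)
  attr(tr, "outgroup") <- outgroup_taxon
  tr
}
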