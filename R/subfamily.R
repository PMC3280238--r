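# Subfamily extraction from the rooted consensus tree, per-subfamily
# consensus sequences, and the systematic NaTx<i>.<k> nomenclature
# (trivial names are kept alongside; numbering follows the chronological
# order of description within each subfamily).

#' Extract subfamilies from a rooted consensus tree
#'
#' Subfamilies are maximal ingroup clades whose support meets
#' `min_support` and whose parent edge is either below the threshold or
#' root-adjacent; taxa attached directly to an unsupported backbone become
#' singleton subfamilies (the real-data analogue: toxins on independent
#' branches get their own subfamily).  The outgroup is excluded from
#' grouping.
#'
#' @param rooted_tree phylo rooted with the outgroup (e.g.
#'   [majority_consensus()] with `outgroup`, or [root_with_outgroup()]);
#'   node labels are support percentages.
#' @param outgroup outgroup tip label; defaults to the tree's `outgroup`
#'   attribute.
#' @param min_support support threshold in percent (default 50).
#' @return list of `subfamily` objects: index, members (tree order),
#'   support (NA for singletons).
#' @export
extract_subfamilies <- function(rooted_tree, outgroup = NULL,
                                min_support = 50) {
  if (is.null(outgroup)) outgroup <- attr(rooted_tree, "outgroup")
  if (is.null(outgroup)) {
    stop("tree is not outgroup-rooted (no outgroup given or recorded)",
         call. = FALSE)
  }
  if (!outgroup %in% rooted_tree$tip.label) {
    stop("outgroup not among tips", call. = FALSE)
  }
  tr <- rooted_tree
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  kids_of <- function(node) tr$edge[tr$edge[, 1] == node, 2]
  support_of <- function(node) {
    lab <- tr$node.label[node - ntip]
    suppressWarnings(as.numeric(lab))
  }
  tips_below <- function(node) {
    if (node <= ntip) return(tr$tip.label[node])
    unlist(lapply(kids_of(node), tips_below))
  }
  out <- list()
  emit <- function(members, support) {
    out[[length(out) + 1L]] <<- structure(
      list(index = length(out) + 1L, members = members, support = support),
      class = "subfamily")
  }
  descend <- function(node, at_crown) {
    if (node <= ntip) {
      if (tr$tip.label[node] != outgroup) {
        emit(tr$tip.label[node], NA_real_)
      }
      return(invisible())
    }
    sup <- support_of(node)
    members <- tips_below(node)
    if (outgroup %in% members || at_crown) {
      for (k in kids_of(node)) descend(k, FALSE)
      return(invisible())
    }
    if (!is.na(sup) && sup >= min_support) {
      emit(members, sup)
    } else {
      for (k in kids_of(node)) descend(k, FALSE)
    }
  }
  # start at the root: the side containing the outgroup keeps being opened,
  # and the ingroup crown (the clade complementary to the outgroup) is a
  # trivial split, never itself a subfamily
  root_kids <- kids_of(root)
  ingroup_kids <- root_kids[vapply(root_kids, function(k)
    !(outgroup %in% tips_below(k)), logical(1))]
  if (length(ingroup_kids) == 1L && ingroup_kids > ntip) {
    descend(ingroup_kids, TRUE)
  } else {
    for (k in ingroup_kids) descend(k, FALSE)
  }
  out
}

#' @export
print.subfamily <- function(x, ...) {
  cat(sprintf("<subfamily %d> %d member(s)%s: %s\n", x$index,
              length(x$members),
              if (!is.na(x$support)) sprintf(" (support %g%%)", x$support)
              else "",
              paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Majority consensus sequence of an aligned subfamily
#'
#' Per column, the residue with relative frequency above
#' `majority_threshold`; columns without a majority emit the ambiguity
#' symbol `x` (lower case, the usual variable-position convention);
#' gap-majority columns are dropped from the consensus.
#'
#' @param subfamily_alignment named character vector / `msa` rows of the
#'   subfamily members (equal length, aligned).
#' @param majority_threshold required relative frequency (default 0.5,
#'   exclusive).
#' @return consensus string.
#' @export
consensus_sequence <- function(subfamily_alignment, majority_threshold = 0.5) {
  seqs <- vapply(subfamily_alignment, as.character, character(1))
  if (!length(seqs)) stop("empty subfamily", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("subfamily members must be aligned (equal length)", call. = FALSE)
  }
  mat <- do.call(rbind, lapply(seqs, split_chars))
  n <- nrow(mat)
  cols <- apply(mat, 2L, function(col) {
    gap_frac <- mean(!col %in% AA20)
    if (gap_frac > majority_threshold) return(NA_character_)
    res <- col[col %in% AA20]
    tab <- sort(table(res), decreasing = TRUE)
    if (tab[1] / n > majority_threshold) names(tab)[1] else "x"
  })
  paste(cols[!is.na(cols)], collapse = "")
}

#' Assign the systematic NaTx nomenclature
#'
#' Members of subfamily i are named `NaTx<i>.<k>`, k following the
#' chronological order of description supplied as a rank vector; trivial
#' names are retained alongside (the map is keyed by them).
#'
#' @param subfamilies list of `subfamily` objects.
#' @param description_order named numeric vector: taxon -> description
#'   rank (smaller = earlier).
#' @return named character vector taxon -> systematic name.
#' @export
assign_nomenclature <- function(subfamilies, description_order) {
  out <- character(0)
  for (sf in subfamilies) {
    ranks <- description_order[sf$members]
    if (anyNA(ranks)) {
      stop(sprintf("missing description rank for: %s",
                   paste(sf$members[is.na(ranks)], collapse = ", ")),
           call. = FALSE)
    }
    if (anyDuplicated(ranks)) {
      stop(sprintf("duplicate description ranks within subfamily %d",
                   sf$index), call. = FALSE)
    }
    ord <- order(ranks)
    nm <- sprintf("NaTx%d.%d", sf$index, seq_along(sf$members))
    out[sf$members[ord]] <- nm
  }
  out
}

#' Structured subfamily report
#'
#' Per subfamily: members with percent identity to the first-described
#' member (which counts as 100%), the consensus sequence, and, when a mass
#' reconciliation is supplied, each member's mass status.
#'
#' @param subfamilies list of `subfamily` objects.
#' @param alignment `msa` covering all members.
#' @param description_order taxon -> rank (see [assign_nomenclature()]).
#' @param reconciliation optional `mass_reconciliation`.
#' @param majority_threshold consensus threshold.
#' @return a `subfamily_report`: list with `table` (data.frame: subfamily,
#'   systematic_name, taxon, identity_pct, mass_status) and `consensus`
#'   (named character vector per subfamily).
#' @export
subfamily_report <- function(subfamilies, alignment, description_order,
                             reconciliation = NULL,
                             majority_threshold = 0.5) {
  aln <- unclass(as_msa(alignment))
  names_map <- assign_nomenclature(subfamilies, description_order)
  mass_status <- function(taxon) {
    if (is.null(reconciliation)) return("")
    if (taxon %in% reconciliation$pairs$id_theoretical) return("match")
    if (taxon %in% reconciliation$unmatched_theoretical) return("unmatched")
    ""
  }
  rows <- list()
  consensus <- character(0)
  for (sf in subfamilies) {
    ranks <- description_order[sf$members]
    first <- sf$members[which.min(ranks)]
    first_seq <- gsub("-", "", aln[[first]], fixed = TRUE)
    for (m in sf$members[order(ranks)]) {
      ident <- if (m == first) 100 else {
        q <- gsub("-", "", aln[[m]], fixed = TRUE)
        percent_identity(global_align(q, first_seq), reference = "b")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subfamily = sf$index, systematic_name = names_map[[m]], taxon = m,
        identity_pct = ident, mass_status = mass_status(m),
        stringsAsFactors = FALSE)
    }
    consensus[sprintf("NaTx%d", sf$index)] <-
      consensus_sequence(aln[sf$members], majority_threshold)
  }
  structure(list(table = do.call(rbind, rows), consensus = consensus),
            class = "subfamily_report")
}

#' @export
print.subfamily_report <- function(x, ...) {
  nsf <- length(unique(x$table$subfamily))
  cat(sprintf("<subfamily_report> %d subfamilies, %d members\n",
              nsf, nrow(x$table)))
  print(x$table, row.names = FALSE)
  cat("\nConsensus sequences:\n")
  for (nm in names(x$consensus)) cat(sprintf("  %s  %s\n", nm,
                                             x$consensus[[nm]]))
  invisible(x)
}

#' Write a subfamily report to TSV + consensus FASTA
#'
#' @param report a `subfamily_report`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_subfamily_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "subfamilies.tsv")
  fa <- file.path(dir, "consensus.fasta")
  utils::write.table(report$table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  # consensus may contain 'x'; keep plain text FASTA by hand for symbols
  con <- file(fa, "w")
  on.exit(close(con))
  for (nm in names(report$consensus)) {
    writeLines(sprintf(">%s", nm), con)
    writeLines(report$consensus[[nm]], con)
  }
  invisible(c(tsv = tsv, fasta = fa))
}
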