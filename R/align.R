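# Pairwise global alignment with affine gaps, reference-length percent
# identity (the convention behind printed toxin identities: the designated
# reference toxin counts as 100%), progressive multiple alignment over an
# identity-distance guide tree, and complete-deletion column filtering
# producing the parsimony character matrix.

SUPPORTED_MATRICES <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80",
                        "BLOSUM100", "PAM30", "PAM40", "PAM70", "PAM120",
                        "PAM250")

.matrix_env <- new.env(parent = emptyenv())

get_substitution_matrix <- function(matrix_name) {
  if (!matrix_name %in% SUPPORTED_MATRICES) {
    stop(sprintf("unknown substitution matrix '%s'", matrix_name),
         call. = FALSE)
  }
  if (is.null(.matrix_env[[matrix_name]])) {
    e <- new.env()
    utils::data(list = matrix_name, package = "Biostrings", envir = e)
    .matrix_env[[matrix_name]] <- e[[matrix_name]][AA20, AA20]
  }
  .matrix_env[[matrix_name]]
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment under an affine gap model (a gap of length L
#' costs `gap_open + gap_extend * L`).  Tie-breaking in the traceback is
#' deterministic: diagonal, then up, then left.
#'
#' @param a,b amino-acid strings over the 20 standard residues.
#' @param matrix_name substitution matrix (default `"BLOSUM62"`).
#' @param gap_open,gap_extend gap penalties (ClustalW-like defaults 10 and
#'   0.5).
#' @return a `pairwise_alignment`: list with aligned strings `seq_a`,
#'   `seq_b` (gap character `-`), `score`, `matches`.
#' @export
global_align <- function(a, b, matrix_name = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  S <- get_substitution_matrix(matrix_name)
  ca <- check_protein(a, "a"); cb <- check_protein(b, "b")
  res <- cpp_nw_align(match(ca, AA20) - 1L, match(cb, AA20) - 1L, S,
                      gap_open, gap_extend)
  moves <- res$moves
  out_a <- character(length(moves)); out_b <- character(length(moves))
  i <- 0L; j <- 0L
  for (k in seq_along(moves)) {
    m <- moves[k]
    if (m == 1L) { i <- i + 1L; j <- j + 1L; out_a[k] <- ca[i]; out_b[k] <- cb[j] }
    else if (m == 2L) { i <- i + 1L; out_a[k] <- ca[i]; out_b[k] <- "-" }
    else { j <- j + 1L; out_a[k] <- "-"; out_b[k] <- cb[j] }
  }
  aligned_a <- paste(out_a, collapse = "")
  aligned_b <- paste(out_b, collapse = "")
  structure(list(seq_a = aligned_a, seq_b = aligned_b,
                 score = res$score,
                 matches = sum(out_a == out_b & out_a != "-")),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score %.1f, %d matches / %d columns\n",
              x$score, x$matches, nchar(x$seq_a)))
  cat(" ", x$seq_a, "\n ", x$seq_b, "\n", sep = "")
  invisible(x)
}

#' Percent identity under the reference-length convention
#'
#' identity = 100 * matches / (ungapped length of the reference sequence),
#' rounded to the nearest integer -- the convention used when the
#' first-described toxin of a subfamily counts as 100%.
#'
#' @param alignment a `pairwise_alignment`.
#' @param reference which input is the reference: `"a"` or `"b"`.
#' @return integer percentage.
#' @export
percent_identity <- function(alignment, reference = c("a", "b")) {
  reference <- match.arg(reference)
  ref <- if (reference == "a") alignment$seq_a else alignment$seq_b
  ref_len <- nchar(gsub("-", "", ref, fixed = TRUE))
  round_half_up(100 * alignment$matches / ref_len)
}

# ---- multiple alignment ----------------------------------------------------

as_msa <- function(seqs) {
  seqs <- vapply(seqs, as.character, character(1))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (length(unique(nchar(seqs))) != 1L) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  structure(seqs, class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences, %d columns\n", length(x), nchar(x[[1]])))
  invisible(x)
}

.profile_of <- function(aln_chars) {
  L <- length(aln_chars[[1]])
  counts <- matrix(0, nrow = L, ncol = length(AA20),
                   dimnames = list(NULL, AA20))
  for (s in aln_chars) {
    idx <- match(s, AA20)
    ok <- !is.na(idx)
    ij <- cbind(which(ok), idx[ok])
    counts[ij] <- counts[ij] + 1
  }
  counts / length(aln_chars)
}

.merge_profiles <- function(A, B, S, gap_open, gap_extend) {
  # A, B: lists of char vectors (aligned groups)
  pa <- .profile_of(A); pb <- .profile_of(B)
  colscore <- pa %*% S %*% t(pb)
  res <- cpp_profile_align(colscore, gap_open, gap_extend)
  moves <- res$moves
  ai <- integer(0); bi <- integer(0)
  i <- 0L; j <- 0L
  for (m in moves) {
    if (m == 1L) { i <- i + 1L; j <- j + 1L; ai <- c(ai, i); bi <- c(bi, j) }
    else if (m == 2L) { i <- i + 1L; ai <- c(ai, i); bi <- c(bi, NA) }
    else { j <- j + 1L; ai <- c(ai, NA); bi <- c(bi, j) }
  }
  expand <- function(chars, idx) {
    out <- rep("-", length(idx))
    out[!is.na(idx)] <- chars[idx[!is.na(idx)]]
    out
  }
  c(lapply(A, expand, idx = ai), lapply(B, expand, idx = bi))
}

#' Progressive multiple sequence alignment
#'
#' Pairwise identity distances feed a neighbor-joining guide tree; profiles
#' are merged in guide-tree postorder with the same affine-gap DP as
#' [global_align()].  Columns in which every sequence carries a cysteine
#' are reported in the `cys_columns` attribute as a scaffold sanity check.
#' A user-curated alignment can bypass this function entirely (see
#' [read_alignment()]); the downstream stages accept it unchanged.
#'
#' @param seqs named character vector of >= 2 unaligned sequences.
#' @inheritParams global_align
#' @return an `msa` (named character vector of equal-length aligned
#'   sequences) with attribute `cys_columns`.
#' @export
progressive_msa <- function(seqs, matrix_name = "BLOSUM62", gap_open = 10,
                            gap_extend = 0.5) {
  seqs <- vapply(seqs, as.character, character(1))
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  S <- get_substitution_matrix(matrix_name)

  if (n == 2L) {
    merged <- .merge_profiles(list(split_chars(seqs[[1]])),
                              list(split_chars(seqs[[2]])),
                              S, gap_open, gap_extend)
    names(merged) <- names(seqs)
    return(.finish_msa(merged))
  }

  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- global_align(seqs[[i]], seqs[[j]], matrix_name, gap_open,
                         gap_extend)
      d <- 1 - al$matches / nchar(al$seq_a)
      D[i, j] <- d; D[j, i] <- d
    }
  }
  guide <- ape::nj(stats::as.dist(D))
  guide <- ape::root(guide, outgroup = names(seqs)[1], resolve.root = TRUE)
  guide <- ape::multi2di(guide)

  # merge following the rooted guide tree
  merge_node <- function(node) {
    ntip <- length(guide$tip.label)
    if (node <= ntip) {
      lab <- guide$tip.label[node]
      return(setNames(list(split_chars(seqs[[lab]])), lab))
    }
    kids <- guide$edge[guide$edge[, 1] == node, 2]
    sub <- lapply(kids, merge_node)
    out <- sub[[1]]
    for (k in seq_along(sub)[-1]) {
      merged <- .merge_profiles(out, sub[[k]], S, gap_open, gap_extend)
      names(merged) <- c(names(out), names(sub[[k]]))
      out <- merged
    }
    out
  }
  merged <- merge_node(length(guide$tip.label) + 1L)
  merged <- merged[names(seqs)]  # restore input order
  .finish_msa(merged)
}

.finish_msa <- function(merged) {
  out <- vapply(merged, paste, character(1), collapse = "")
  msa <- as_msa(out)
  mat <- do.call(rbind, lapply(merged, identity))
  cys <- which(apply(mat, 2L, function(col) all(col == "C")))
  attr(msa, "cys_columns") <- unname(cys)
  msa
}

#' Complete-deletion character matrix
#'
#' Retains exactly the alignment columns in which every taxon carries a
#' standard residue; gaps (`-`, `.`) and unknown states (`X`, `?`) remove
#' the whole column before phylogenetic scoring.
#'
#' @param msa an `msa` or named character vector of aligned sequences.
#' @return a `char_matrix`: list with `taxa`, `mat` (taxa x positions
#'   character matrix), `n_positions`, `kept_columns` (original indices).
#' @export
complete_deletion <- function(msa) {
  seqs <- unclass(as_msa(msa))
  mat <- do.call(rbind, lapply(seqs, split_chars))
  rownames(mat) <- names(seqs)
  ok <- apply(mat, 2L, function(col) all(col %in% AA20))
  if (!any(ok)) {
    stop(sprintf(paste0("complete deletion removed every column ",
                        "(%d columns, all with gaps or unknown states)"),
                 ncol(mat)), call. = FALSE)
  }
  structure(list(taxa = names(seqs),
                 mat = mat[, ok, drop = FALSE],
                 n_positions = sum(ok),
                 kept_columns = which(ok)),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("<char_matrix> %d taxa x %d positions (complete deletion)\n",
              length(x$taxa), x$n_positions))
  invisible(x)
}

# ---- I/O -------------------------------------------------------------------

#' Read an alignment (FASTA or Clustal)
#'
#' Files starting with a `CLUSTAL` header are parsed as Clustal `.aln`;
#' anything else is read as aligned FASTA.
#'
#' @param path alignment file.
#' @return an `msa`.
#' @export
read_alignment <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^CLUSTAL", first)) {
    lines <- readLines(path)[-1L]
    lines <- lines[nzchar(trimws(lines))]
    lines <- lines[!grepl("^\\s", lines)]  # drop conservation lines
    parts <- strsplit(trimws(lines), "\\s+")
    ids <- vapply(parts, `[[`, character(1), 1L)
    segs <- vapply(parts, `[[`, character(1), 2L)
    seqs <- vapply(split(segs, factor(ids, levels = unique(ids))),
                   paste, character(1), collapse = "")
    return(as_msa(seqs))
  }
  x <- Biostrings::readAAStringSet(path)
  as_msa(setNames(as.character(x), names(x)))
}

#' Write an alignment in Clustal format
#'
#' @param msa an `msa`.
#' @param path output path.
#' @param width residues per block line.
#' @return invisibly, `path`.
#' @export
write_clustal <- function(msa, path, width = 60) {
  seqs <- unclass(as_msa(msa))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("CLUSTAL W formatted alignment (natx)", con)
  writeLines("", con)
  L <- nchar(seqs[[1]])
  idw <- max(nchar(names(seqs))) + 3L
  for (s in seq.int(1L, L, by = width)) {
    e <- min(s + width - 1L, L)
    for (i in seq_along(seqs)) {
      writeLines(sprintf("%-*s%s", idw, names(seqs)[i],
                         substr(seqs[[i]], s, e)), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Write a character matrix as relaxed PHYLIP
#'
#' @param cm a `char_matrix`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_character_matrix <- function(cm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(cm$taxa), cm$n_positions), con)
  for (i in seq_along(cm$taxa)) {
    writeLines(sprintf("%s  %s", cm$taxa[i],
                       paste(cm$mat[i, ], collapse = "")), con)
  }
  invisible(path)
}
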