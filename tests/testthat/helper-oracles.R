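# Independent oracles and small fixture builders shared across the suite.
# Each oracle is a deliberately naive brute-force implementation, kept
# separate from the package code paths it checks.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_peptide <- function(len, include_cys = TRUE) {
  alpha <- if (include_cys) AA else setdiff(AA, "C")
  paste(sample(alpha, len, replace = TRUE), collapse = "")
}

# ---- mass oracle: per-atom composition summation ---------------------------
# residue elemental compositions (C, H, N, O, S) and the atomic weights the
# standard residue-mass tables are based on
ATOM_W <- c(C = 12.0110, H = 1.00794, N = 14.00674, O = 15.9994, S = 32.06)
RESIDUE_ATOMS <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))

oracle_average_mass <- function(seq, n_disulfides = 0, amidated = FALSE) {
  ch <- strsplit(seq, "")[[1]]
  atoms <- Reduce(`+`, RESIDUE_ATOMS[ch])
  atoms <- atoms + c(0, 2, 0, 1, 0)            # + H2O
  atoms <- atoms - c(0, 2 * n_disulfides, 0, 0, 0)  # -2H per bridge
  if (amidated) atoms <- atoms + c(0, 1, 1, -1, 0)  # -OH +NH2
  sum(atoms * ATOM_W)
}

# ---- quality-trimming oracle: exhaustive interval scan ---------------------
oracle_trim <- function(qual, window, min_q) {
  n <- length(qual)
  best <- NULL
  for (s in seq_len(n)) {
    for (e in seq.int(s, n)) {
      if (e - s + 1L < window) next
      ok <- all(vapply(s:(e - window + 1L), function(ws)
        mean(qual[ws:(ws + window - 1L)]) >= min_q, logical(1)))
      if (ok && (is.null(best) || (e - s) > (best[2] - best[1]))) {
        best <- c(s, e)
      }
    }
  }
  best  # 1-based inclusive interval or NULL
}

# ---- global-alignment oracle: exhaustive alignment enumeration -------------
# maximal score over all global alignments under gap cost open + extend * L
oracle_align_score <- function(a, b, S, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, acc, last) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, acc); return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1L, j + 1L, acc + S[ca[i], cb[j]], "m")
    }
    if (i <= length(ca)) {
      cost <- gap_extend + if (last == "u") 0 else gap_open
      rec(i + 1L, j, acc - cost, "u")
    }
    if (j <= length(cb)) {
      cost <- gap_extend + if (last == "l") 0 else gap_open
      rec(i, j + 1L, acc - cost, "l")
    }
  }
  rec(1L, 1L, 0, "")
  best
}

# ---- parsimony oracles -----------------------------------------------------
# minimum changes for one column by enumerating internal-node assignments
oracle_column_steps <- function(tree, states) {
  # states: named character vector over tips
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  alphabet <- unique(unname(states))
  assignments <- do.call(expand.grid,
                         c(rep(list(alphabet), nnode),
                           stringsAsFactors = FALSE))
  tipst <- states[tr$tip.label]
  best <- Inf
  for (r in seq_len(nrow(assignments))) {
    lab <- c(tipst, unlist(assignments[r, ], use.names = FALSE))
    cost <- sum(lab[tr$edge[, 1]] != lab[tr$edge[, 2]])
    best <- min(best, cost)
  }
  best
}

oracle_fitch <- function(tree, mat) {
  # mat: taxa x columns character matrix with rownames
  sum(vapply(seq_len(ncol(mat)), function(c)
    oracle_column_steps(tree, setNames(mat[, c], rownames(mat))), numeric(1)))
}

# all unrooted binary topologies over the given labels, by recursive
# addition of each leaf to every edge (n = 6 -> 105 trees)
all_topologies <- function(labels) {
  stopifnot(length(labels) >= 3L)
  trees <- list(ape::read.tree(text = sprintf("(%s,%s,%s);",
                                              labels[1], labels[2],
                                              labels[3])))
  for (k in seq.int(4L, length(labels))) {
    nxt <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edge))) {
        t2 <- suppressWarnings(
          ape::bind.tree(tr, ape::read.tree(text = sprintf("(%s:1);",
                                                           labels[k])),
                         where = tr$edge[e, 2], position = 0.5))
        nxt[[length(nxt) + 1L]] <- t2
      }
    }
    trees <- nxt
  }
  trees
}

# canonical set of nontrivial splits of an unrooted tree (sorted taxon
# strings of the side not containing the alphabetically first taxon)
split_set <- function(tree) {
  taxa <- sort(tree$tip.label)
  tr <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  ntip <- length(tr$tip.label)
  below <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    below[[tr$edge[e, 1]]] <- c(below[[tr$edge[e, 1]]], below[[tr$edge[e, 2]]])
  }
  out <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2]
    if (ch <= ntip) next
    side <- below[[ch]]
    if (taxa[1] %in% side) side <- setdiff(taxa, side)
    if (length(side) >= 2L && length(side) <= length(taxa) - 2L) {
      out <- c(out, paste(sort(side), collapse = "|"))
    }
  }
  sort(unique(out))
}

# rooted clade tip-sets of a tree (for planted-clade recovery checks)
clade_sets <- function(tree) {
  labs <- tree$tip.label
  ntip <- length(labs)
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- labs[i]
  for (e in seq_len(nrow(po$edge))) {
    below[[po$edge[e, 1]]] <- c(below[[po$edge[e, 1]]], below[[po$edge[e, 2]]])
  }
  lapply((ntip + 1L):(ntip + tree$Nnode), function(v) sort(below[[v]]))
}

# build a char_matrix directly from a character matrix with rownames
make_cmat <- function(mat) {
  structure(list(taxa = rownames(mat), mat = mat,
                 n_positions = ncol(mat),
                 kept_columns = seq_len(ncol(mat))),
            class = "char_matrix")
}

make_read <- function(seq, qual, id = "r1") {
  structure(list(id = id, seq = seq, qual = as.integer(qual)),
            class = "est_read")
}
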