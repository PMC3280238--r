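# Synthetic toxin gene families with known ground truth.
#
# The generator plants a rooted family tree whose ingroup is a set of
# subfamily clades hanging off a weakly resolved backbone (long subfamily
# stems, short backbone edges), mirroring the fan-like shape of real NaScTx
# consensus trees where deep order collapses below 50% bootstrap.  Mature
# peptides evolve along the tree by per-site i.i.d. replacement with frozen
# cysteine scaffold positions; precursors add a signal peptide and an
# optional C-terminal pro-sequence (GK / GKK / GKRK); cDNAs are reverse
# translated and fragmented into error-bearing quality-scored reads.

# branch lengths of the planted world (arbitrary units; substitution
# probability per site per branch = sub_rate * length, capped at 0.95)
BL_WITHIN <- 0.15   # edges inside a subfamily clade
BL_STEM <- 0.35     # subfamily stem: makes clades distinct
BL_BACKBONE <- 0.001 # backbone: hard polytomy, collapses in consensus
BL_OUTGROUP <- 0.05  # near-ancestral outgroup (see methods vignette)

OUTGROUP_LABEL <- "OUT"

CTERM_MOTIFS <- c("", "GK", "GKK", "GKRK")

# most-frequent-codon reverse translation table; codon choice is irrelevant
# downstream, a fixed table keeps output deterministic
CODON_PREF <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
                Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
                L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
                S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")
STOP_CODON <- "TAA"

#' Simulate a planted family tree
#'
#' Builds a rooted binary tree with `n_subfamilies` monophyletic ingroup
#' clades of `taxa_per_subfamily` taxa each plus one outgroup leaf
#' (`"OUT"`).  Subfamily stems are long and backbone edges short, so
#' downstream bootstrap consensus recovers the clades but collapses their
#' order, as in real NaScTx trees.
#'
#' @param n_subfamilies number of planted clades (>= 2).
#' @param taxa_per_subfamily taxa per clade (>= 1).
#' @param seed integer RNG seed; the same call with the same seed is
#'   byte-identical.
#' @return an `ape` phylo object with positive branch lengths; ingroup tips
#'   are labelled `sfXX_tY`.
#' @export
simulate_family_tree <- function(n_subfamilies, taxa_per_subfamily, seed) {
  if (!is.numeric(n_subfamilies) || n_subfamilies < 2 ||
      !is.numeric(taxa_per_subfamily) || taxa_per_subfamily < 1) {
    stop("need n_subfamilies >= 2 and taxa_per_subfamily >= 1", call. = FALSE)
  }
  n_subfamilies <- as.integer(n_subfamilies)
  taxa_per_subfamily <- as.integer(taxa_per_subfamily)
  with_seed(seed, {
    clades <- vapply(seq_len(n_subfamilies), function(i) {
      labs <- sprintf("sf%02d_t%d", i, seq_len(taxa_per_subfamily))
      sprintf("%s:%s", .random_subtree(labs), BL_STEM)
    }, character(1))
    backbone <- clades[1]
    for (i in seq_len(n_subfamilies - 1L)) {
      backbone <- sprintf("(%s,%s):%s", backbone, clades[i + 1L], BL_BACKBONE)
    }
    nwk <- sprintf("(%s,%s:%s);", backbone, OUTGROUP_LABEL, BL_OUTGROUP)
    ape::read.tree(text = nwk)
  })
}

# random binary topology over labels (no branch length on the returned
# subtree root); every edge inside the clade gets length BL_WITHIN
.random_subtree <- function(labels) {
  if (length(labels) == 1L) {
    return(labels)
  }
  labels <- sample(labels)
  k <- sample.int(length(labels) - 1L, 1L)
  sprintf("(%s:%s,%s:%s)",
          .random_subtree(labels[seq_len(k)]), BL_WITHIN,
          .random_subtree(labels[-seq_len(k)]), BL_WITHIN)
}

#' Evolve mature peptides along a tree
#'
#' A root scaffold of length `scaffold_len` carries `n_cys` cysteines at
#' fixed positions; sequences then evolve by per-site i.i.d. replacement
#' (substitution probability per branch = `sub_rate` times branch length,
#' capped at 0.95), drawing uniformly among the 19 non-cysteine residues.
#' Cysteine columns and the C-terminal residue are never substituted, and
#' mutable sites never become cysteine, so every leaf has exactly `n_cys`
#' cysteines and an unambiguous C-terminus for the amidation rule.
#'
#' @param tree phylo with branch lengths (e.g. [simulate_family_tree()]).
#' @param scaffold_len mature length, 55--79 (default 72).
#' @param n_cys even cysteine count in 6--8 (default 8, four bridges).
#' @param sub_rate substitution rate multiplier (>= 0).
#' @param seed integer RNG seed.
#' @return named character vector of mature sequences, one per tip.
#' @export
evolve_mature_peptides <- function(tree, scaffold_len = 72, n_cys = 8,
                                   sub_rate = 0.15, seed = 1) {
  if (n_cys %% 2 != 0) stop("n_cys must be even", call. = FALSE)
  if (n_cys < 6 || n_cys > 8) stop("n_cys must be 6 or 8", call. = FALSE)
  if (scaffold_len < 55 || scaffold_len > 79) {
    stop("scaffold_len must be in [55, 79]", call. = FALSE)
  }
  if (sub_rate < 0) stop("sub_rate must be >= 0", call. = FALSE)
  stopifnot(inherits(tree, "phylo"))

  cys_pos <- round(seq(6, scaffold_len - 2, length.out = n_cys))
  mutable_alpha <- setdiff(AA20, "C")

  with_seed(seed, {
    root_seq <- sample(mutable_alpha, scaffold_len, replace = TRUE)
    root_seq[cys_pos] <- "C"
    root_seq[scaffold_len] <- sample(c("S", "N", "P", "T", "V"), 1L)
    frozen <- c(cys_pos, scaffold_len)
    mutable <- setdiff(seq_len(scaffold_len), frozen)

    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    seqs <- vector("list", nnode)
    root <- ntip + 1L
    seqs[[root]] <- root_seq
    # preorder: ape edges are not guaranteed preorder, reorder them
    edge <- ape::reorder.phylo(tree, "cladewise")$edge
    elen <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (e in seq_len(nrow(edge))) {
      par <- edge[e, 1L]; child <- edge[e, 2L]
      s <- seqs[[par]]
      p <- min(0.95, sub_rate * elen[e])
      if (p > 0 && length(mutable)) {
        hit <- mutable[runif(length(mutable)) < p]
        for (i in hit) {
          s[i] <- sample(setdiff(mutable_alpha, s[i]), 1L)
        }
      }
      seqs[[child]] <- s
    }
    out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                  character(1))
    names(out) <- tree$tip.label
    out
  })
}

#' Build a precursor record around a mature peptide
#'
#' Precursor protein = signal peptide + mature + C-terminal pro-sequence;
#' a valid coding sequence (ATG ... stop) is emitted by most-frequent-codon
#' reverse translation.  The amidation truth flag is `TRUE` iff a non-empty
#' motif was appended.
#'
#' @param mature mature amino-acid sequence.
#' @param signal_len signal peptide length, 18--22.
#' @param cterm_motif one of `""`, `"GK"`, `"GKK"`, `"GKRK"`.
#' @param seed integer RNG seed (signal peptide composition).
#' @param id record identifier.
#' @return a `precursor_record`: list with id, cds, protein, 1-based
#'   inclusive intervals signal / mature / cterm_pro (NULL if none), and
#'   the truth flag `amidated`.
#' @export
build_precursor <- function(mature, signal_len = 20, cterm_motif = "GKK",
                            seed = 1, id = "precursor") {
  if (signal_len < 18 || signal_len > 22) {
    stop("signal_len must be in [18, 22]", call. = FALSE)
  }
  if (!cterm_motif %in% CTERM_MOTIFS) {
    stop(sprintf("cterm_motif must be one of %s",
                 paste(shQuote(CTERM_MOTIFS), collapse = ", ")), call. = FALSE)
  }
  check_protein(mature, "mature")
  with_seed(seed, {
    # hydrophobic-core signal peptide starting with Met
    hydrophobic <- c("L", "A", "V", "I", "F", "M", "C", "S", "T", "G")
    signal <- c("M", sample(hydrophobic, signal_len - 1L, replace = TRUE))
    signal <- paste(signal, collapse = "")
    protein <- paste0(signal, mature, cterm_motif)
    cds <- paste0(paste(CODON_PREF[split_chars(protein)], collapse = ""),
                  STOP_CODON)
    n_sig <- signal_len
    n_mat <- nchar(mature)
    n_sig <- as.integer(n_sig)
    n_mat <- as.integer(n_mat)
    rec <- list(id = id, cds = cds, protein = protein,
                signal = c(1L, n_sig),
                mature = c(n_sig + 1L, n_sig + n_mat),
                cterm_pro = if (nzchar(cterm_motif))
                  c(n_sig + n_mat + 1L, n_sig + n_mat + nchar(cterm_motif))
                else NULL,
                amidated = nzchar(cterm_motif))
    class(rec) <- "precursor_record"
    rec
  })
}

#' @export
print.precursor_record <- function(x, ...) {
  cat(sprintf("<precursor_record %s> %d aa (signal %d-%d, mature %d-%d%s)%s\n",
              x$id, nchar(x$protein), x$signal[1], x$signal[2],
              x$mature[1], x$mature[2],
              if (!is.null(x$cterm_pro))
                sprintf(", pro %d-%d", x$cterm_pro[1], x$cterm_pro[2]) else "",
              if (x$amidated) " [amidated]" else ""))
  invisible(x)
}

#' Fragment a coding sequence into EST-like reads
#'
#' Emulates single-pass cDNA reads: substitution errors at a fixed rate,
#' Phred-style qualities from a two-state (high/low) profile with a
#' low-quality 3' tail (so a Q20 windowed trimmer has something to cut),
#' and an optional fraction of reads prefixed with cloning-vector sequence.
#' Clean read starts are stratified over the CDS, guaranteeing >= 1x
#' coverage whenever `n_reads * read_len >= 2 * nchar(cds)`.
#'
#' @param cds nucleotide template.
#' @param n_reads number of reads (0 allowed).
#' @param read_len read length; must be <= nchar(vector) + nchar(cds).
#' @param error_rate per-base substitution probability in \[0, 1).
#' @param vector optional vector sequence for 5' contamination.
#' @param vector_frac fraction of reads carrying a vector prefix.
#' @param seed integer RNG seed.
#' @param id_prefix read id prefix.
#' @return list of `est_read` records (id, seq, qual as integer Phred).
#' @export
fragment_to_ests <- function(cds, n_reads, read_len = 150, error_rate = 0.01,
                             vector = NULL, vector_frac = 0.3, seed = 1,
                             id_prefix = "read") {
  if (error_rate < 0 || error_rate >= 1) {
    stop("error_rate must be in [0, 1)", call. = FALSE)
  }
  vec <- if (is.null(vector)) "" else vector
  if (read_len > nchar(vec) + nchar(cds)) {
    stop("read_len exceeds template length", call. = FALSE)
  }
  if (n_reads == 0) return(list())
  with_seed(seed, {
    template <- split_chars(paste0(vec, cds))
    vlen <- nchar(vec)
    tlen <- length(template)
    has_vector <- if (vlen > 0) runif(n_reads) < vector_frac else
      rep(FALSE, n_reads)
    # stratified clean starts tile the CDS
    clean_span <- max(1L, tlen - read_len + 1L - vlen)
    strata <- ceiling(seq_len(n_reads) / n_reads * clean_span)
    lows <- c(1L, head(strata, -1L) + 1L)
    reads <- vector("list", n_reads)
    for (r in seq_len(n_reads)) {
      if (has_vector[r]) {
        start <- sample.int(vlen, 1L)
        start <- min(start, tlen - read_len + 1L)
      } else if (r == 1L) {
        # 5'-anchored first read (single-pass reads start at the insert)
        start <- min(vlen + 1L, tlen - read_len + 1L)
      } else if (r == n_reads && n_reads > 1L) {
        start <- tlen - read_len + 1L
      } else {
        lo <- min(vlen + lows[r], tlen - read_len + 1L)
        hi <- min(vlen + strata[r], tlen - read_len + 1L)
        start <- if (hi > lo) sample(lo:hi, 1L) else lo
      }
      seq <- template[start:(start + read_len - 1L)]
      if (error_rate > 0) {
        err <- which(runif(read_len) < error_rate)
        for (i in err) seq[i] <- sample(setdiff(DNA4, seq[i]), 1L)
      }
      tail_len <- sample.int(max(1L, read_len %/% 3L), 1L) - 1L
      qual <- sample(30:40, read_len, replace = TRUE)
      if (tail_len > 0) {
        qual[(read_len - tail_len + 1L):read_len] <-
          sample(5:15, tail_len, replace = TRUE)
      }
      reads[[r]] <- structure(list(id = sprintf("%s_%03d", id_prefix, r),
                                   seq = paste(seq, collapse = ""),
                                   qual = as.integer(qual)),
                              class = "est_read")
    }
    reads
  })
}

# bundled 50-nt mock cloning vector (exact-prefix contamination model)
MOCK_VECTOR <- "GTTGTAAAACGACGGCCAGTGAATTCGAGCTCGGTACCCGGGGATCCTCT"

#' Simulate a full toxin family with ground truth
#'
#' Convenience wrapper planting a family tree, mature peptides, and one
#' precursor per taxon.  Signal length and C-terminal motif are conserved
#' within a subfamily, as observed for real precursors.
#'
#' @param n_subfamilies,taxa_per_subfamily,sub_rate,scaffold_len,n_cys,seed
#'   see [simulate_family_tree()] and [evolve_mature_peptides()].
#' @return a `truth_bundle`: list with `true_tree`, `true_subfamily_of`
#'   (named integer; 0 marks the outgroup), `true_precursors`, `matures`,
#'   and `seed`.
#' @export
simulate_toxin_family <- function(n_subfamilies = 14, taxa_per_subfamily = 4,
                                  sub_rate = 0.15, scaffold_len = 72,
                                  n_cys = 8, seed = 1) {
  tree <- simulate_family_tree(n_subfamilies, taxa_per_subfamily, seed)
  matures <- evolve_mature_peptides(tree, scaffold_len, n_cys, sub_rate,
                                    derive_seed(seed, 1L))
  taxa <- tree$tip.label
  sf <- setNames(integer(length(taxa)), taxa)
  ing <- taxa != OUTGROUP_LABEL
  sf[ing] <- as.integer(sub("^sf([0-9]+)_.*$", "\\1", taxa[ing]))
  sig_len <- with_seed(derive_seed(seed, 2L),
                       sample(18:22, n_subfamilies, replace = TRUE))
  motifs <- with_seed(derive_seed(seed, 3L),
                      sample(CTERM_MOTIFS, n_subfamilies, replace = TRUE))
  precursors <- lapply(seq_along(taxa), function(i) {
    k <- sf[i]
    build_precursor(matures[[i]],
                    signal_len = if (k == 0L) 20L else sig_len[k],
                    cterm_motif = if (k == 0L) "" else motifs[k],
                    seed = derive_seed(seed, 100L + i),
                    id = taxa[i])
  })
  names(precursors) <- taxa
  structure(list(true_tree = tree, true_subfamily_of = sf,
                 true_precursors = precursors, matures = matures,
                 seed = seed),
            class = "truth_bundle")
}

#' Write a truth bundle to disk
#'
#' Emits plain-text artifacts: mature proteins and CDS FASTA, the true tree
#' as Newick, and a truth table TSV (taxon, subfamily, signal_len, motif,
#' amidated).
#'
#' @param bundle a `truth_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_truth_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "truth_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matures = file.path(dir, "matures.fasta"),
             cds = file.path(dir, "cds.fasta"),
             tree = file.path(dir, "true_tree.nwk"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(bundle$matures),
                              paths["matures"])
  cds <- vapply(bundle$true_precursors, `[[`, character(1), "cds")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds), paths["cds"])
  ape::write.tree(bundle$true_tree, paths["tree"])
  truth <- data.frame(
    taxon = names(bundle$true_subfamily_of),
    subfamily = unname(bundle$true_subfamily_of),
    signal_len = vapply(bundle$true_precursors, function(p)
      p$signal[2] - p$signal[1] + 1L, integer(1)),
    motif = vapply(bundle$true_precursors, function(p)
      if (is.null(p$cterm_pro)) "" else
        substr(p$protein, p$cterm_pro[1], p$cterm_pro[2]), character(1)),
    amidated = vapply(bundle$true_precursors, `[[`, logical(1), "amidated"),
    stringsAsFactors = FALSE)
  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
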