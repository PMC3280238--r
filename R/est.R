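# Simplified EST cleanup and clustering: Phred-style windowed quality
# trimming, exact-match vector masking, and single-linkage contig/singlet
# partitioning under the ">95 identical per 100 nucleotides" rule.
#
# Coordinates are 0-based half-open internally; reports are 1-based
# inclusive.  The bundled read generator introduces substitutions only, so
# overlap detection is an exact exhaustive ungapped offset scan.

#' Read FASTQ into est_read records
#'
#' @param path FASTQ file (Phred+33).
#' @return list of `est_read` records (id, seq, qual integer vector).
#' @export
read_fastq <- function(path) {
  # harmless metadata-column note from Biostrings' FASTQ reader
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  q <- as(Biostrings::quality(x), "IntegerList")
  lapply(seq_along(x), function(i) {
    structure(list(id = names(x)[i],
                   seq = as.character(x[[i]]),
                   qual = as.integer(q[[i]])),
              class = "est_read")
  })
}

#' Write est_read records as FASTQ
#'
#' @param reads list of `est_read` records.
#' @param path output path (Phred+33).
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  if (!length(reads)) {
    file.create(path)
    return(invisible(path))
  }
  seqs <- Biostrings::DNAStringSet(vapply(reads, `[[`, character(1), "seq"))
  names(seqs) <- vapply(reads, `[[`, character(1), "id")
  quals <- Biostrings::PhredQuality(vapply(reads, function(r)
    rawToChar(as.raw(r$qual + 33L)), character(1)))
  qs <- Biostrings::QualityScaledDNAStringSet(seqs, quals)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Quality trimming by sliding-window mean
#'
#' Keeps the longest interval in which every sliding window of length
#' `window` has mean quality >= `min_q`; reads with no qualifying interval
#' of at least `window` bases are rejected (NULL).  Defaults mirror the
#' classic EST pipeline setting: window 100, quality 20.
#'
#' @param read an `est_read` (id, seq, qual).
#' @param window window length (>= 1).
#' @param min_q minimum mean quality per window.
#' @return a trimmed `est_read` carrying `kept_interval` (0-based
#'   half-open, relative to the input read), or NULL if rejected.
#' @export
trim_quality <- function(read, window = 100, min_q = 20) {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  window <- as.integer(window)
  n <- nchar(read$seq)
  if (length(read$qual) != n) {
    stop(sprintf("read %s: quality length %d != sequence length %d",
                 read$id, length(read$qual), n), call. = FALSE)
  }
  if (n < window) return(NULL)
  # mean quality of every window; a kept interval [s, e) is valid iff all
  # window starts s .. e-window qualify, i.e. a run of qualifying starts
  cs <- cumsum(c(0L, read$qual))
  wmean <- (cs[(window + 1L):(n + 1L)] - cs[seq_len(n - window + 1L)]) / window
  ok <- wmean >= min_q
  if (!any(ok)) return(NULL)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  good <- which(runs$values)
  lens <- runs$lengths[good] + window - 1L
  best <- good[which.max(lens)]   # ties: first (leftmost) run
  s0 <- starts[best]              # 1-based window start
  e0 <- ends[best] + window - 1L  # 1-based last base
  structure(list(id = read$id,
                 seq = substr(read$seq, s0, e0),
                 qual = read$qual[s0:e0],
                 kept_interval = c(s0 - 1L, e0)),
            class = "est_read")
}

#' Mask cloning-vector sequence at read ends
#'
#' Removes any exact occurrence, at either read end, of a vector substring
#' (forward or reverse-complement) of length >= `min_match`.  Reads without
#' a hit pass through unchanged.
#'
#' @param read an `est_read`.
#' @param vector vector nucleotide sequence.
#' @param min_match minimum exact match length (>= 10).
#' @return the read with matched terminal segments removed.
#' @export
mask_vector <- function(read, vector, min_match = 15) {
  if (min_match < 10) stop("min_match must be >= 10", call. = FALSE)
  targets <- c(vector, revcomp(vector))
  n <- nchar(read$seq)
  lead <- .end_match(read$seq, targets, min_match, from_start = TRUE)
  trail <- .end_match(read$seq, targets, min_match, from_start = FALSE)
  if (lead + trail >= n) {  # wholly vector
    lead <- n; trail <- 0L
  }
  if (lead == 0L && trail == 0L) return(read)
  s0 <- lead + 1L
  e0 <- n - trail
  base <- if (is.null(read$kept_interval)) 0L else read$kept_interval[1]
  out <- structure(list(id = read$id,
                        seq = substr(read$seq, s0, e0),
                        qual = if (e0 >= s0) read$qual[s0:e0] else integer(),
                        kept_interval = c(base + s0 - 1L, base + e0)),
                   class = "est_read")
  out
}

# longest terminal segment (>= min_match) occurring exactly in any target
.end_match <- function(seq, targets, min_match, from_start) {
  n <- nchar(seq)
  best <- 0L
  hi <- min(n, max(nchar(targets)))
  if (hi < min_match) return(best)
  for (L in rev(seq.int(min_match, hi))) {
    piece <- if (from_start) substr(seq, 1L, L) else substr(seq, n - L + 1L, n)
    if (any(vapply(targets, function(t) grepl(piece, t, fixed = TRUE),
                   logical(1)))) {
      best <- L
      break  # longest first
    }
  }
  best
}

#' Cluster ESTs into contigs and singlets
#'
#' Single-linkage clustering: two reads link iff their best ungapped
#' overlap of length >= `min_overlap` has more than `min_identity`
#' identical positions per 100 (i.e. identity fraction >
#' `min_identity`/100).  Contig consensus is the column-wise majority over
#' the offset layout, ties resolved alphabetically (A < C < G < T).
#'
#' @param reads list of `est_read` records (trimmed and masked).
#' @param min_overlap minimum overlap length (default 100).
#' @param min_identity identities per 100 positions required, exclusive
#'   (default 95: the ">95 out of 100" rule).
#' @return a `contig_set`: list with `contigs` (each: consensus, members)
#'   and `singlets` (read ids).  Every input read appears exactly once.
#' @export
cluster_ests <- function(reads, min_overlap = 100, min_identity = 95) {
  reads <- Filter(function(r) nchar(r$seq) > 0, reads)
  n <- length(reads)
  if (n == 0L) {
    return(structure(list(contigs = list(), singlets = character()),
                     class = "contig_set"))
  }
  chs <- lapply(reads, function(r) split_chars(r$seq))
  ids <- vapply(reads, `[[`, character(1), "id")

  # shared exact 20-mer prefilter: a >95%-identity overlap of >= 100 nt
  # almost surely contains one, and pairs without any cannot cluster
  kmer <- 20L
  km_env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    L <- nchar(reads[[i]]$seq)
    if (L < kmer) next
    for (s in seq.int(1L, L - kmer + 1L)) {
      k <- substr(reads[[i]]$seq, s, s + kmer - 1L)
      km_env[[k]] <- c(km_env[[k]], i)
    }
  }
  cand <- new.env(hash = TRUE, parent = emptyenv())
  for (k in ls(km_env)) {
    hits <- unique(km_env[[k]])
    if (length(hits) < 2L) next
    for (a in seq_len(length(hits) - 1L)) {
      for (b in (a + 1L):length(hits)) {
        key <- paste(sort(c(hits[a], hits[b])), collapse = "_")
        cand[[key]] <- TRUE
      }
    }
  }

  # union-find over reads, recording best offsets for linked pairs
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  offsets <- vector("list", n)  # adjacency: list of c(j, offset)

  if (n > 1L) {
    for (key in ls(cand)) {
      ij <- as.integer(strsplit(key, "_", fixed = TRUE)[[1]])
      i <- ij[1]; j <- ij[2]
      {
        ov <- .best_overlap(chs[[i]], chs[[j]], min_overlap)
        if (!is.null(ov) && ov$identity * 100 > min_identity) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
          offsets[[i]] <- c(offsets[[i]], list(c(j, ov$offset)))
          offsets[[j]] <- c(offsets[[j]], list(c(i, -ov$offset)))
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)

  contigs <- list()
  singlets <- character()
  for (g in groups) {
    if (length(g) == 1L) {
      singlets <- c(singlets, ids[g])
      next
    }
    contigs[[length(contigs) + 1L]] <-
      .layout_consensus(g, chs, ids, offsets)
  }
  # deterministic ordering independent of input order
  if (length(contigs)) {
    ord <- order(vapply(contigs, function(ct) min(ct$members), character(1)))
    contigs <- contigs[ord]
  }
  singlets <- sort(singlets)
  structure(list(contigs = contigs, singlets = singlets),
            class = "contig_set")
}

# best ungapped overlap between two char vectors: slide b against a over all
# offsets allowing an overlap >= min_overlap, keep the overlap with maximum
# identity fraction, ties broken by longer overlap then smaller offset
.best_overlap <- function(a, b, min_overlap) {
  la <- length(a); lb <- length(b)
  if (min(la, lb) < min_overlap) return(NULL)
  best <- NULL
  for (off in (-(lb - min_overlap)):(la - min_overlap)) {
    s_a <- max(1L, 1L + off); e_a <- min(la, lb + off)
    len <- e_a - s_a + 1L
    if (len < min_overlap) next
    s_b <- s_a - off
    m <- sum(a[s_a:e_a] == b[s_b:(s_b + len - 1L)])
    idf <- m / len
    if (is.null(best) || idf > best$identity ||
        (idf == best$identity && len > best$len)) {
      best <- list(offset = off, len = len, identity = idf)
    }
  }
  best
}

# BFS over the link graph to place every member on a common coordinate
# system, then column-majority consensus
.layout_consensus <- function(g, chs, ids, offsets) {
  pos <- setNames(rep(NA_integer_, length(g)), g)
  pos[as.character(g[1])] <- 0L
  queue <- g[1]
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    for (ad in offsets[[i]]) {
      j <- ad[1]
      if (!as.character(j) %in% names(pos)) next
      if (is.na(pos[as.character(j)])) {
        # read j starts at pos(i) - offset(i vs j)... offset recorded as
        # b (=j) shifted by `off` relative to a (=i): a[k+off] ~ b[k],
        # so j's start in i's frame is +off
        pos[as.character(j)] <- pos[as.character(i)] + ad[2]
        queue <- c(queue, j)
      }
    }
  }
  pos <- pos - min(pos, na.rm = TRUE)
  width <- max(vapply(seq_along(g), function(k)
    pos[as.character(g[k])] + length(chs[[g[k]]]), integer(1)))
  counts <- matrix(0L, nrow = 4L, ncol = width, dimnames = list(DNA4, NULL))
  for (k in seq_along(g)) {
    i <- g[k]
    p <- pos[as.character(i)]
    ch <- chs[[i]]
    idx <- cbind(match(ch, DNA4), p + seq_along(ch))
    keep <- !is.na(idx[, 1])
    for (r in which(keep)) {
      counts[idx[r, 1], idx[r, 2]] <- counts[idx[r, 1], idx[r, 2]] + 1L
    }
  }
  consensus <- paste(DNA4[apply(counts, 2L, which.max)], collapse = "")
  list(consensus = consensus, members = sort(ids[g]))
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("<contig_set> %d contig(s), %d singlet(s)\n",
              length(x$contigs), length(x$singlets)))
  for (i in seq_along(x$contigs)) {
    cat(sprintf("  contig %d: %d nt, %d reads\n", i,
                nchar(x$contigs[[i]]$consensus),
                length(x$contigs[[i]]$members)))
  }
  invisible(x)
}

#' Write a contig set to FASTA + membership TSV
#'
#' @param cs a `contig_set`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_contig_set <- function(cs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "contigs.fasta")
  tsv <- file.path(dir, "membership.tsv")
  seqs <- c(vapply(cs$contigs, `[[`, character(1), "consensus"),
            character(0))
  names(seqs) <- if (length(seqs)) sprintf("contig%03d", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa)
  rows <- do.call(rbind, c(
    lapply(seq_along(cs$contigs), function(i)
      data.frame(unit = sprintf("contig%03d", i), type = "contig",
                 read = cs$contigs[[i]]$members, stringsAsFactors = FALSE)),
    lapply(cs$singlets, function(s)
      data.frame(unit = s, type = "singlet", read = s,
                 stringsAsFactors = FALSE))))
  if (is.null(rows)) rows <- data.frame(unit = character(), type = character(),
                                        read = character())
  utils::write.table(rows, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa = fa, tsv = tsv))
}
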