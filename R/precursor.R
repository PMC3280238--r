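# Precursor annotation: ORF finding, signal-peptide cleavage anchored on
# reference mature N-termini, C-terminal pro-peptide removal with
# amidation, and nearest-reference alpha/beta classification.
#
# The C-terminal rule encodes the standard maturation model: precursors
# ending in Gly followed by 1-3 basic residues are trimmed by a
# carboxypeptidase and the Gly donates its amine, leaving the new terminal
# residue amidated (-0.98 Da relative to the free acid).

MIN_ORF_CODONS <- 50L
SIGNAL_RANGE <- 18:22

#' Translate the longest ATG-initiated open reading frame
#'
#' Scans the three forward frames (venom-gland libraries are directional)
#' for ATG-initiated ORFs, ending at the first in-frame stop or at the end
#' of the sequence, and returns the longest translation.
#'
#' @param cds nucleotide string, length >= 150.
#' @return amino-acid string (stop excluded).
#' @export
find_orf <- function(cds) {
  if (nchar(cds) < 150) stop("cds shorter than 150 nt", call. = FALSE)
  code <- Biostrings::GENETIC_CODE
  ch <- split_chars(toupper(cds))
  n <- length(ch)
  best <- ""
  best_start <- Inf
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    codons <- vapply(starts, function(s) paste(ch[s:(s + 2L)], collapse = ""),
                     character(1))
    aa <- code[codons]
    aa[is.na(aa)] <- "X"
    atg <- which(codons == "ATG")
    stops <- which(aa == "*")
    for (a in atg) {
      stop_after <- stops[stops > a]
      end <- if (length(stop_after)) stop_after[1] - 1L else length(aa)
      prot <- paste(aa[a:end], collapse = "")
      if (nchar(prot) > nchar(best) ||
          (nchar(prot) == nchar(best) && starts[a] < best_start)) {
        best <- prot
        best_start <- starts[a]
      }
    }
  }
  if (nchar(best) < MIN_ORF_CODONS) {
    stop(sprintf("no ATG-initiated ORF of >= %d codons found", MIN_ORF_CODONS),
         call. = FALSE)
  }
  best
}

#' Cleave the signal peptide from a precursor protein
#'
#' With an explicit `cleavage_site` k, the signal is residues 1..k.  With
#' `"auto"`, the site is anchored on known mature toxins, as done in
#' practice when a predictor is unavailable: for each candidate k in
#' 18..22, the 10-mer starting at k+1 is compared position-wise with the
#' first 10 residues of every reference mature, and the k with the highest
#' identity wins (ties: smallest k).
#'
#' @param protein precursor amino-acid string.
#' @param cleavage_site integer k, or `"auto"`.
#' @param reference_matures named character vector (or AAStringSet) of
#'   reference mature sequences; required for `"auto"`.
#' @return list with `signal`, `proprotein` (everything after the signal),
#'   and `site` (k).
#' @export
cleave_signal <- function(protein, cleavage_site = "auto",
                          reference_matures = NULL) {
  n <- nchar(protein)
  if (identical(cleavage_site, "auto")) {
    if (is.null(reference_matures) || !length(reference_matures)) {
      stop("auto cleavage requires non-empty reference_matures", call. = FALSE)
    }
    refs <- as.character(reference_matures)
    ref10 <- lapply(refs, function(r) split_chars(substr(r, 1L, 10L)))
    best_k <- NA_integer_
    best_id <- -1
    for (k in SIGNAL_RANGE) {
      if (k + 10L > n) break
      q <- split_chars(substr(protein, k + 1L, k + 10L))
      ident <- max(vapply(ref10, function(r)
        mean(q[seq_along(r)] == r), numeric(1)))
      if (ident > best_id) {  # strict >: ties keep the smallest k
        best_id <- ident
        best_k <- k
      }
    }
    if (is.na(best_k) || best_id <= 0.5) {
      stop("no reference mature matches above identity 0.5", call. = FALSE)
    }
    k <- best_k
  } else {
    k <- as.integer(cleavage_site)
    if (is.na(k) || k < 1L || k >= n) {
      stop("cleavage_site out of range", call. = FALSE)
    }
  }
  list(signal = substr(protein, 1L, k),
       proprotein = substr(protein, k + 1L, n),
       site = k)
}

#' Remove the C-terminal pro-sequence and set the amidation flag
#'
#' If the sequence ends with Gly followed by 1--3 residues all in {K, R},
#' the basics and the Gly are removed and the peptide is flagged amidated;
#' otherwise it is returned unchanged.  Trailing basic runs longer than 3
#' are left untouched and flagged for review (`flag = "long_basic_run"`).
#'
#' @param proprotein mature region including any C-terminal pro-sequence.
#' @param id identifier carried into the result.
#' @return a `mature_peptide`: list with id, seq, n_cys, n_disulfides,
#'   amidated, motif_removed, flag.
#' @export
process_cterm <- function(proprotein, id = "peptide") {
  if (!nzchar(proprotein)) stop("empty sequence", call. = FALSE)
  ch <- split_chars(proprotein)
  n <- length(ch)
  t <- 0L
  while (t < n && ch[n - t] %in% c("K", "R")) t <- t + 1L
  flag <- NA_character_
  motif <- ""
  amidated <- FALSE
  seq <- proprotein
  if (t >= 1L && t <= 3L && n - t >= 1L && ch[n - t] == "G") {
    motif <- substr(proprotein, n - t, n)
    seq <- substr(proprotein, 1L, n - t - 1L)
    amidated <- TRUE
  } else if (t > 3L && n - t >= 1L && ch[n - t] == "G") {
    flag <- "long_basic_run"
  }
  ch2 <- split_chars(seq)
  n_cys <- sum(ch2 == "C")
  structure(list(id = id, seq = seq, n_cys = n_cys,
                 n_disulfides = n_cys %/% 2L,
                 amidated = amidated, motif_removed = motif, flag = flag),
            class = "mature_peptide")
}

#' @export
print.mature_peptide <- function(x, ...) {
  cat(sprintf("<mature_peptide %s> %d aa, %d Cys (%d bridges)%s%s\n",
              x$id, nchar(x$seq), x$n_cys, x$n_disulfides,
              if (x$amidated) sprintf(", amidated (-%s)", x$motif_removed)
              else "",
              if (!is.na(x$flag)) sprintf(" [%s]", x$flag) else ""))
  invisible(x)
}

#' Classify a mature toxin as alpha- or beta-like
#'
#' Nearest-reference label by percent identity (reference-length
#' convention); `"ambiguous"` when the best alpha and best beta identities
#' differ by less than 5 percentage points.
#'
#' @param mature mature sequence (string or `mature_peptide`).
#' @param alpha_refs,beta_refs non-empty named character vectors of
#'   reference matures.
#' @return list with `label` in alpha-like / beta-like / ambiguous,
#'   `best_alpha`, `best_beta` (percent identities).
#' @export
classify_candidate <- function(mature, alpha_refs, beta_refs) {
  if (!length(alpha_refs) || !length(beta_refs)) {
    stop("reference sets must be non-empty", call. = FALSE)
  }
  seq <- if (inherits(mature, "mature_peptide")) mature$seq else
    as.character(mature)
  best_vs <- function(refs) {
    max(vapply(as.character(refs), function(r) {
      percent_identity(global_align(seq, r), reference = "b")
    }, numeric(1)))
  }
  a <- best_vs(alpha_refs)
  b <- best_vs(beta_refs)
  label <- if (abs(a - b) < 5) "ambiguous" else
    if (a > b) "alpha-like" else "beta-like"
  list(label = label, best_alpha = a, best_beta = b)
}

#' Annotate a precursor end-to-end
#'
#' ORF translation, signal cleavage, C-terminal processing; returns the
#' fully annotated `precursor_record` plus the `mature_peptide`.
#'
#' @param cds nucleotide sequence (or an already-translated protein via
#'   `protein =`).
#' @param id record id.
#' @param cleavage_site,reference_matures see [cleave_signal()].
#' @param protein optional protein, skipping [find_orf()].
#' @return list with `record` (`precursor_record`) and `mature`
#'   (`mature_peptide`).
#' @export
annotate_precursor <- function(cds = NULL, id = "precursor",
                               cleavage_site = "auto",
                               reference_matures = NULL, protein = NULL) {
  if (is.null(protein)) {
    if (is.null(cds)) stop("need cds or protein", call. = FALSE)
    protein <- find_orf(cds)
  }
  cl <- cleave_signal(protein, cleavage_site, reference_matures)
  mat <- process_cterm(cl$proprotein, id = id)
  n <- nchar(protein)
  n_pro <- nchar(mat$motif_removed)
  rec <- structure(list(
    id = id, cds = if (is.null(cds)) "" else cds, protein = protein,
    signal = c(1L, cl$site),
    mature = c(cl$site + 1L, n - n_pro),
    cterm_pro = if (n_pro > 0L) c(n - n_pro + 1L, n) else NULL,
    amidated = mat$amidated), class = "precursor_record")
  list(record = rec, mature = mat)
}

#' Batch-annotate precursors and write results
#'
#' @param cds_set named character vector / DNAStringSet of CDS (or use
#'   `proteins`).
#' @param reference_matures references for auto signal cleavage.
#' @param proteins optional named protein vector, skipping ORF finding.
#' @param cleavage_site passed to [cleave_signal()].
#' @return list with `matures` (named character vector) and `annotation`
#'   (data.frame: id, signal_start, signal_end, mature_start, mature_end,
#'   motif_removed, amidated, n_cys).
#' @export
annotate_precursors <- function(cds_set = NULL, reference_matures = NULL,
                                proteins = NULL, cleavage_site = "auto") {
  src <- if (is.null(proteins)) cds_set else proteins
  nm <- names(src)
  src <- as.character(src)
  names(src) <- nm
  ids <- names(src)
  if (is.null(ids)) ids <- paste0("seq", seq_along(src))
  anns <- lapply(seq_along(src), function(i) {
    if (is.null(proteins)) {
      annotate_precursor(cds = src[[i]], id = ids[i],
                         cleavage_site = cleavage_site,
                         reference_matures = reference_matures)
    } else {
      annotate_precursor(protein = src[[i]], id = ids[i],
                         cleavage_site = cleavage_site,
                         reference_matures = reference_matures)
    }
  })
  matures <- setNames(vapply(anns, function(a) a$mature$seq, character(1)),
                      ids)
  annotation <- do.call(rbind, lapply(anns, function(a) {
    r <- a$record
    data.frame(id = r$id,
               signal_start = r$signal[1], signal_end = r$signal[2],
               mature_start = r$mature[1], mature_end = r$mature[2],
               motif_removed = a$mature$motif_removed,
               amidated = r$amidated, n_cys = a$mature$n_cys,
               stringsAsFactors = FALSE)
  }))
  list(matures = matures, annotation = annotation)
}
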