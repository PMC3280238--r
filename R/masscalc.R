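# Theoretical peptide masses with disulfide and amidation corrections, and
# reconciliation of theoretical vs experimentally measured masses.
#
# Constants: a disulfide bridge removes two hydrogens; C-terminal amidation
# replaces the terminal -OH by -NH2 (net -0.98 Da).  Residue masses are read
# once from a versioned plain-text table bundled with the package so results
# are bit-stable across environments.

MASS_TABLE_VERSION <- "v1"

WATER_AVG <- 18.0153
WATER_MONO <- 18.0106
BRIDGE_AVG <- 2.0159
BRIDGE_MONO <- 2.0157
AMIDE_AVG <- 0.9847
AMIDE_MONO <- 0.9840

.mass_env <- new.env(parent = emptyenv())

#' Bundled residue mass table
#'
#' Standard average and monoisotopic residue (i.e. water-free) masses for the
#' 20 amino acids, as used by [average_mass()] and [monoisotopic_mass()].
#'
#' @return a data.frame with columns `residue`, `average`, `monoisotopic`.
#' @export
residue_masses <- function() {
  if (is.null(.mass_env$tab)) {
    path <- system.file("extdata",
                        sprintf("residue_masses_%s.tsv", MASS_TABLE_VERSION),
                        package = "natx", mustWork = TRUE)
    .mass_env$tab <- utils::read.table(path, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE)
  }
  .mass_env$tab
}

.mass_lookup <- function(kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  tab <- residue_masses()
  setNames(tab[[kind]], tab$residue)
}

.sum_mass <- function(seq, n_disulfides, amidated, kind) {
  ch <- check_protein(seq)
  if (is.null(n_disulfides)) n_disulfides <- sum(ch == "C") %/% 2L
  if (n_disulfides < 0 || 2L * n_disulfides > sum(ch == "C")) {
    stop("n_disulfides inconsistent with cysteine count", call. = FALSE)
  }
  lk <- .mass_lookup(kind)
  water <- if (kind == "average") WATER_AVG else WATER_MONO
  bridge <- if (kind == "average") BRIDGE_AVG else BRIDGE_MONO
  amide <- if (kind == "average") AMIDE_AVG else AMIDE_MONO
  sum(lk[ch]) + water - bridge * n_disulfides - amide * isTRUE(amidated)
}

#' Theoretical average mass of a mature peptide
#'
#' Sum of residue average masses plus one water, minus 2.0159 Da per
#' disulfide bridge and 0.9847 Da when the C-terminus is amidated.  Full
#' precision is returned; reports conventionally print one decimal.
#'
#' @param seq amino-acid string over the 20 standard residues.
#' @param n_disulfides number of disulfide bridges; defaults to
#'   `floor(ncys/2)` (all cysteines paired).
#' @param amidated logical, C-terminal amidation.
#' @return mass in Da.
#' @examples
#' average_mass("G")  # 75.0672, glycine free acid
#' @export
average_mass <- function(seq, n_disulfides = NULL, amidated = FALSE) {
  .sum_mass(seq, n_disulfides, amidated, "average")
}

#' Theoretical monoisotopic mass of a mature peptide
#'
#' Companion to [average_mass()] for mass-spectrometry users: monoisotopic
#' residue table, water 18.0106 Da, -2.0157 Da per bridge, -0.9840 Da for
#' amidation.
#'
#' @inheritParams average_mass
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(seq, n_disulfides = NULL, amidated = FALSE) {
  .sum_mass(seq, n_disulfides, amidated, "monoisotopic")
}

#' Mass result for an annotated mature peptide
#'
#' @param peptide a `mature_peptide` (from [process_cterm()]) or an
#'   amino-acid string.
#' @param id identifier used in reports.
#' @inheritParams average_mass
#' @return a one-row data.frame: id, average_da, monoisotopic_da,
#'   n_disulfides, amidated.
#' @export
mass_result <- function(peptide, id = NULL, n_disulfides = NULL,
                        amidated = NULL) {
  if (inherits(peptide, "mature_peptide")) {
    if (is.null(id)) id <- peptide$id
    if (is.null(n_disulfides)) n_disulfides <- peptide$n_disulfides
    if (is.null(amidated)) amidated <- peptide$amidated
    seq <- peptide$seq
  } else {
    seq <- as.character(peptide)
    if (is.null(id)) id <- "peptide"
    if (is.null(amidated)) amidated <- FALSE
  }
  data.frame(id = id,
             average_da = average_mass(seq, n_disulfides, amidated),
             monoisotopic_da = monoisotopic_mass(seq, n_disulfides, amidated),
             n_disulfides = if (is.null(n_disulfides))
               sum(split_chars(seq) == "C") %/% 2L else n_disulfides,
             amidated = amidated,
             stringsAsFactors = FALSE)
}

#' Reconcile theoretical against experimental masses
#'
#' Greedy one-to-one matching by smallest absolute mass difference under a
#' tolerance; entries left over on either side are reported unmatched.  The
#' default tolerance of 1.5 Da accepts typical theoretical/experimental gaps
#' for ~7 kDa venom peptides while rejecting distinct-peptide mismatches
#' tens of Da apart.
#'
#' @param theoretical data.frame with columns `id` and `average_da` (e.g.
#'   rbind of [mass_result()] rows), or a named numeric vector of masses.
#' @param experimental data.frame with columns `id` and `experimental_da`,
#'   a named numeric vector, or the path of a TSV file with those columns.
#' @param tolerance_da match tolerance in Da (> 0).
#' @return an object of class `mass_reconciliation`: list with `pairs`
#'   (id_theoretical, id_experimental, theoretical, experimental, delta,
#'   verdict), `unmatched_theoretical`, `unmatched_experimental`,
#'   `tolerance_da`.
#' @export
reconcile_masses <- function(theoretical, experimental, tolerance_da = 1.5) {
  if (!is.numeric(tolerance_da) || tolerance_da <= 0) {
    stop("tolerance_da must be > 0", call. = FALSE)
  }
  theo <- .as_mass_df(theoretical, "average_da")
  expd <- .as_mass_df(experimental, "experimental_da")

  pairs <- data.frame(id_theoretical = character(), id_experimental = character(),
                      theoretical = numeric(), experimental = numeric(),
                      delta = numeric(), verdict = character(),
                      stringsAsFactors = FALSE)
  if (nrow(theo) && nrow(expd)) {
    cand <- expand.grid(i = seq_len(nrow(theo)), j = seq_len(nrow(expd)))
    cand$delta <- expd$experimental_da[cand$j] - theo$average_da[cand$i]
    cand <- cand[abs(cand$delta) <= tolerance_da, , drop = FALSE]
    # deterministic greedy: smallest |delta|, ties broken by id order
    cand <- cand[order(abs(cand$delta), theo$id[cand$i], expd$id[cand$j]), ,
                 drop = FALSE]
    used_i <- logical(nrow(theo)); used_j <- logical(nrow(expd))
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (used_i[i] || used_j[j]) next
      used_i[i] <- TRUE; used_j[j] <- TRUE
      pairs <- rbind(pairs, data.frame(
        id_theoretical = theo$id[i], id_experimental = expd$id[j],
        theoretical = theo$average_da[i], experimental = expd$experimental_da[j],
        delta = cand$delta[r], verdict = "match", stringsAsFactors = FALSE))
    }
  } else {
    used_i <- logical(nrow(theo)); used_j <- logical(nrow(expd))
  }
  out <- list(pairs = pairs,
              unmatched_theoretical = theo$id[!used_i],
              unmatched_experimental = expd$id[!used_j],
              tolerance_da = tolerance_da)
  class(out) <- "mass_reconciliation"
  out
}

.as_mass_df <- function(x, col) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- utils::read.table(x, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  }
  if (is.numeric(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("m", seq_along(x))
    x <- setNames(data.frame(ids, as.numeric(x), stringsAsFactors = FALSE),
                  c("id", col))
  }
  if (!is.data.frame(x) || !all(c("id", col) %in% names(x))) {
    stop(sprintf("malformed mass table: need columns 'id' and '%s'", col),
         call. = FALSE)
  }
  if (!is.numeric(x[[col]]) || anyNA(x[[col]])) {
    stop(sprintf("malformed mass table: column '%s' must be numeric", col),
         call. = FALSE)
  }
  x[, c("id", col)]
}

#' @export
print.mass_reconciliation <- function(x, ...) {
  cat(sprintf("Mass reconciliation (tolerance %.2f Da): %d matched, %d/%d unmatched\n",
              x$tolerance_da, nrow(x$pairs),
              length(x$unmatched_theoretical), length(x$unmatched_experimental)))
  if (nrow(x$pairs)) {
    df <- x$pairs
    df$theoretical <- sprintf("%.1f", df$theoretical)
    df$experimental <- sprintf("%.1f", df$experimental)
    df$delta <- sprintf("%+.1f", df$delta)
    print(df, row.names = FALSE)
  }
  invisible(x)
}
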