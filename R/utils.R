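# Shared small helpers: residue alphabet, seeded evaluation, partition scores.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

DNA4 <- c("A", "C", "G", "T")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All generators in the package are
# pure functions of their arguments because of this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage seed from a master seed; kept below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * k) %% 2147483647)
}

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

check_protein <- function(seq, what = "sequence") {
  ch <- split_chars(seq)
  bad <- setdiff(unique(ch), AA20)
  if (length(bad)) {
    stop(sprintf("%s contains nonstandard residue(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(ch)
}

#' Adjusted Rand index between two partitions
#'
#' Used to compare a recovered subfamily partition with a planted truth.
#' Labels are matched by name when both vectors are named.
#'
#' @param a,b partition label vectors (same elements; matched by names when
#'   present).
#' @return a single number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      stop("partitions are over different element sets", call. = FALSE)
    }
    b <- b[names(a)]
  }
  if (length(a) != length(b)) stop("partitions differ in length", call. = FALSE)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_i * sum_j / n
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# round() uses banker's rounding; printed identities/supports use half-up.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
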