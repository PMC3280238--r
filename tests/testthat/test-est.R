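# EST cleanup: windowed quality trimming against a brute-force interval
# oracle, exact-match vector masking on both strands, and the >95/100
# single-linkage contig clustering.

test_that("trim_quality keeps/rejects whole reads at the extremes", {
  r_hi <- make_read(strrep("A", 200), rep(30L, 200))
  t_hi <- trim_quality(r_hi, window = 100, min_q = 20)
  expect_identical(t_hi$kept_interval, c(0L, 200L))
  expect_identical(t_hi$seq, r_hi$seq)

  r_lo <- make_read(strrep("A", 200), rep(10L, 200))
  expect_null(trim_quality(r_lo, window = 100, min_q = 20))

  # shorter than one window -> rejected
  expect_null(trim_quality(make_read(strrep("A", 50), rep(40L, 50)),
                           window = 100))
  expect_error(trim_quality(make_read("ACGT", rep(30L, 3))), "length")
  expect_error(trim_quality(make_read("ACGT", rep(30L, 4)), window = 0),
               "window")
})

test_that("trim_quality matches the exhaustive interval oracle", {
  # 150 nt Q30 then 100 nt Q5, window 100: trailing windows keep averaging
  # >= 20 until they contain more than 40 Q5 bases, so the retained
  # interval runs to base 190 (confirmed by the brute-force oracle)
  qual <- c(rep(30L, 150), rep(5L, 100))
  r <- make_read(strrep("A", 250), qual)
  tr <- trim_quality(r, window = 100, min_q = 20)
  oracle <- oracle_trim(qual, 100, 20)
  expect_identical(tr$kept_interval, c(oracle[1] - 1L, oracle[2]))
  expect_identical(tr$kept_interval, c(0L, 190L))

  # randomized agreement with the brute-force scan (small windows)
  set.seed(421)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    qual <- sample(5:40, n, replace = TRUE)
    r <- make_read(paste(sample(c("A", "C", "G", "T"), n, TRUE),
                         collapse = ""), qual)
    w <- sample(3:10, 1)
    got <- trim_quality(r, window = w, min_q = 20)
    want <- oracle_trim(qual, w, 20)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_identical(got$kept_interval, c(want[1] - 1L, want[2]),
                       info = sprintf("case %d", i))
    }
  }
})

test_that("trimming is idempotent", {
  set.seed(77)
  for (i in 1:10) {
    qual <- sample(5:40, 80, replace = TRUE)
    r <- make_read(paste(sample(c("A", "C", "G", "T"), 80, TRUE),
                         collapse = ""), qual)
    t1 <- trim_quality(r, window = 10, min_q = 20)
    if (is.null(t1)) next
    t2 <- trim_quality(t1, window = 10, min_q = 20)
    expect_identical(t2$seq, t1$seq)
    expect_identical(t2$qual, t1$qual)
  }
})

test_that("mask_vector removes terminal vector matches on both strands", {
  vec <- natx:::MOCK_VECTOR  # 50 nt
  insert <- strrep("ACGTT", 40)
  r <- make_read(paste0(vec, insert), rep(30L, 50 + 200))
  m <- mask_vector(r, vec, min_match = 15)
  expect_identical(m$seq, insert)
  expect_identical(m$kept_interval, c(50L, 250L))

  r2 <- make_read(insert, rep(30L, 200))
  expect_identical(mask_vector(r2, vec, min_match = 15)$seq, insert)

  # reverse-complement vector at the 3' end
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(vec)))
  r3 <- make_read(paste0(insert, rc), rep(30L, 250))
  expect_identical(mask_vector(r3, vec, min_match = 15)$seq, insert)

  # partial terminal match above min_match is removed too
  r4 <- make_read(paste0(substr(vec, 31, 50), insert), rep(30L, 220))
  expect_identical(mask_vector(r4, vec, min_match = 15)$seq, insert)
  expect_error(mask_vector(r2, vec, min_match = 5), "min_match")
})

test_that("cluster_ests partitions reads per the >95/100 rule", {
  cds <- build_precursor(random_peptide(70), 20, "GK", seed = 11)$cds
  a <- make_read(substr(cds, 1, 300), rep(30L, 300), id = "a")
  b <- make_read(substr(cds, 1, 300), rep(30L, 300), id = "b")
  cs <- cluster_ests(list(a, b))
  expect_length(cs$contigs, 1L)
  expect_length(cs$singlets, 0L)
  expect_setequal(cs$contigs[[1]]$members, c("a", "b"))

  # no 100-nt overlap -> two singlets
  c1 <- make_read(substr(cds, 1, 120), rep(30L, 120), id = "c1")
  c2 <- make_read(substr(cds, 150, 269), rep(30L, 120), id = "c2")
  cs2 <- cluster_ests(list(c1, c2))
  expect_length(cs2$contigs, 0L)
  expect_setequal(cs2$singlets, c("c1", "c2"))

  # identity exactly at the threshold (95/100, not >95) does not link
  set.seed(5151)
  x <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  y <- x
  for (p in seq(10, 190, by = 20)) {  # 10 mismatches over the 200-nt overlap
    old <- substr(y, p, p)
    substr(y, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  cs3 <- cluster_ests(list(make_read(x, rep(30L, 200), "x"),
                           make_read(y, rep(30L, 200), "y")))
  expect_length(cs3$contigs, 0L)

  expect_length(cluster_ests(list())$singlets, 0L)
})

test_that("contig consensus reconstructs the planted CDS", {
  cds <- build_precursor(random_peptide(75), 21, "GKK", seed = 12)$cds
  reads <- fragment_to_ests(cds, 10, read_len = 150, error_rate = 0.01,
                            seed = 13)
  cs <- cluster_ests(reads)
  expect_length(cs$contigs, 1L)
  expect_length(cs$singlets, 0L)
  expect_identical(cs$contigs[[1]]$consensus, cds)
})

test_that("clustering partitions every read exactly once, independent of
           input order", {
  cds1 <- build_precursor(random_peptide(64), 20, "", seed = 14)$cds
  cds2 <- build_precursor(random_peptide(64), 20, "", seed = 15)$cds
  reads <- c(fragment_to_ests(cds1, 6, 140, 0.01, seed = 16,
                              id_prefix = "a"),
             fragment_to_ests(cds2, 6, 140, 0.01, seed = 17,
                              id_prefix = "b"),
             list(make_read(paste(sample(c("A", "C", "G", "T"), 150, TRUE),
                                  collapse = ""), rep(30L, 150), "lone")))
  cs <- cluster_ests(reads)
  all_ids <- vapply(reads, `[[`, character(1), "id")
  placed <- c(unlist(lapply(cs$contigs, `[[`, "members")), cs$singlets)
  expect_setequal(placed, all_ids)
  expect_length(placed, length(all_ids))   # exactly once
  expect_true(all(vapply(cs$contigs, function(ct)
    length(ct$members) >= 2L, logical(1))))

  perm <- withr::with_seed(3, sample(seq_along(reads)))
  cs_shuffled <- cluster_ests(reads[perm])
  part <- function(x) {
    groups <- c(lapply(x$contigs, `[[`, "members"),
                as.list(x$singlets))
    sort(vapply(groups, function(g) paste(sort(g), collapse = "+"),
                character(1)))
  }
  expect_identical(part(cs_shuffled), part(cs))
})

test_that("FASTQ round trip preserves reads and qualities", {
  reads <- fragment_to_ests(
    build_precursor(random_peptide(64), 20, "GK", seed = 18)$cds,
    4, 120, 0.01, seed = 19)
  f <- tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  back <- read_fastq(f)
  expect_identical(vapply(back, `[[`, character(1), "seq"),
                   vapply(reads, `[[`, character(1), "seq"))
  expect_identical(lapply(back, `[[`, "qual"), lapply(reads, `[[`, "qual"))
})
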