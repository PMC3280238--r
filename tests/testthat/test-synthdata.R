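# Generator contracts: leaf counts, determinism, frozen cysteine scaffold,
# planted clade signal, precursor architecture, read simulation.

test_that("simulate_family_tree honors counts, structure and determinism", {
  tr <- simulate_family_tree(2, 3, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_length(tr$tip.label, 7)            # 2*3 ingroup + outgroup
  expect_true("OUT" %in% tr$tip.label)
  expect_true(all(tr$edge.length > 0))
  # planted clades are monophyletic
  cs <- clade_sets(tr)
  for (i in 1:2) {
    expect_true(any(vapply(cs, identical, logical(1),
                           y = sort(sprintf("sf%02d_t%d", i, 1:3)))))
  }
  expect_length(simulate_family_tree(14, 4, seed = 7)$tip.label, 57)
  expect_identical(ape::write.tree(simulate_family_tree(3, 2, seed = 1)),
                   ape::write.tree(simulate_family_tree(3, 2, seed = 1)))
  expect_error(simulate_family_tree(1, 3, seed = 1), "n_subfamilies")
  expect_error(simulate_family_tree(3, 0, seed = 1), "n_subfamilies")
})

test_that("evolve_mature_peptides freezes the cysteine scaffold", {
  tr <- simulate_family_tree(3, 3, seed = 2)
  seqs <- evolve_mature_peptides(tr, scaffold_len = 64, n_cys = 8,
                                 sub_rate = 0.3, seed = 4)
  expect_named(seqs)
  expect_setequal(names(seqs), tr$tip.label)
  chs <- strsplit(seqs, "")
  # exactly 8 cysteines, all at identical positions
  cys_pos <- lapply(chs, function(x) which(x == "C"))
  expect_true(all(vapply(cys_pos, length, integer(1)) == 8L))
  expect_length(unique(cys_pos), 1L)
  expect_error(evolve_mature_peptides(tr, n_cys = 7, seed = 1), "even")
  expect_error(evolve_mature_peptides(tr, scaffold_len = 90, seed = 1),
               "scaffold_len")
})

test_that("zero substitution rate leaves all leaves identical to the root", {
  tr <- simulate_family_tree(2, 2, seed = 3)
  seqs <- evolve_mature_peptides(tr, sub_rate = 0, seed = 9)
  expect_length(unique(unname(seqs)), 1L)
})

test_that("within-subfamily identity exceeds between-subfamily identity", {
  tr <- simulate_family_tree(2, 4, seed = 5)
  seqs <- evolve_mature_peptides(tr, sub_rate = 0.3, seed = 6)
  chs <- do.call(rbind, strsplit(seqs, ""))
  rownames(chs) <- names(seqs)
  pid <- function(a, b) mean(chs[a, ] == chs[b, ])
  sf <- sub("_t[0-9]+$", "", names(seqs))
  within <- c(); between <- c()
  ing <- names(seqs)[names(seqs) != "OUT"]
  for (i in seq_len(length(ing) - 1)) {
    for (j in seq.int(i + 1, length(ing))) {
      p <- pid(ing[i], ing[j])
      if (sf[match(ing[i], names(seqs))] == sf[match(ing[j], names(seqs))]) {
        within <- c(within, p)
      } else {
        between <- c(between, p)
      }
    }
  }
  expect_gt(mean(within), mean(between))
})

test_that("build_precursor plants architecture and emits a valid CDS", {
  mature <- "KKDGYPVDDKGCKYECAINNKNCNSECKLRRGNYGYCYFWKLACYCEGLPDNTP"
  p <- build_precursor(mature, signal_len = 20, cterm_motif = "GKK",
                       seed = 1, id = "To9like")
  expect_s3_class(p, "precursor_record")
  expect_true(endsWith(p$protein, "GKK"))
  expect_true(p$amidated)
  expect_identical(p$signal, c(1L, 20L))
  expect_identical(substr(p$protein, p$mature[1], p$mature[2]), mature)
  # round trip: translating the emitted CDS recovers signal+mature+motif
  tx <- as.character(Biostrings::translate(Biostrings::DNAString(
    substr(p$cds, 1, nchar(p$cds) - 3))))
  expect_identical(tx, p$protein)
  expect_true(startsWith(p$cds, "ATG"))

  p0 <- build_precursor(mature, 20, "", seed = 1)
  expect_false(p0$amidated)
  expect_null(p0$cterm_pro)
  expect_error(build_precursor(mature, 20, "GKKK", seed = 1), "cterm_motif")
  expect_error(build_precursor(mature, 30, "GK", seed = 1), "signal_len")
})

test_that("fragment_to_ests: exact substrings at zero error, determinism,
           coverage and vector contamination", {
  p <- build_precursor(random_peptide(64), 20, "GK", seed = 2)
  cds <- p$cds
  reads <- fragment_to_ests(cds, 8, read_len = 120, error_rate = 0,
                            seed = 3)
  for (r in reads) {
    expect_true(grepl(r$seq, cds, fixed = TRUE))
    expect_length(r$qual, nchar(r$seq))
  }
  # coverage >= 1x when n_reads * read_len >= 2 * len(cds)
  cov <- integer(nchar(cds))
  for (r in reads) {
    s <- regexpr(r$seq, cds, fixed = TRUE)
    cov[s:(s + nchar(r$seq) - 1L)] <- cov[s:(s + nchar(r$seq) - 1L)] + 1L
  }
  expect_true(all(cov >= 1L))

  expect_identical(fragment_to_ests(cds, 0, seed = 1), list())
  r1 <- fragment_to_ests(cds, 5, error_rate = 0.01, seed = 42)
  r2 <- fragment_to_ests(cds, 5, error_rate = 0.01, seed = 42)
  expect_identical(r1, r2)
  expect_error(fragment_to_ests(cds, 5, error_rate = 1.2, seed = 1),
               "error_rate")

  vec <- natx:::MOCK_VECTOR
  rv <- fragment_to_ests(cds, 40, read_len = 100, error_rate = 0,
                         vector = vec, vector_frac = 0.5, seed = 8)
  n_vec <- sum(vapply(rv, function(r)
    grepl(substr(r$seq, 1, 20), vec, fixed = TRUE), logical(1)))
  expect_gt(n_vec, 5)   # a substantial fraction carries vector prefix
  expect_lt(n_vec, 35)
})

test_that("simulate_toxin_family bundles a consistent truth", {
  b <- simulate_toxin_family(3, 2, sub_rate = 0.2, seed = 5)
  expect_s3_class(b, "truth_bundle")
  expect_setequal(names(b$true_subfamily_of), b$true_tree$tip.label)
  ing <- b$true_subfamily_of[b$true_subfamily_of > 0]
  expect_setequal(unique(ing), 1:3)          # contiguous from 1
  expect_identical(b$true_subfamily_of[["OUT"]], 0L)
  # precursor truth: protein contains the mature at the planted interval
  for (tx in names(b$matures)) {
    p <- b$true_precursors[[tx]]
    expect_identical(substr(p$protein, p$mature[1], p$mature[2]),
                     b$matures[[tx]])
    if (p$amidated) {
      expect_identical(substr(p$protein, p$cterm_pro[1], p$cterm_pro[1]), "G")
    }
  }
  # byte-for-byte reproducibility
  b2 <- simulate_toxin_family(3, 2, sub_rate = 0.2, seed = 5)
  expect_identical(b$matures, b2$matures)
  expect_identical(ape::write.tree(b$true_tree), ape::write.tree(b2$true_tree))

  d <- tempfile()
  paths <- write_truth_bundle(b, d)
  expect_true(all(file.exists(paths)))
  truth <- read.delim(paths[["truth"]])
  expect_identical(nrow(truth), 7L)
})
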