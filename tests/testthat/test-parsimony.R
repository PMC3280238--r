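# Parsimony: Fitch scoring against exhaustive state-assignment enumeration,
# rooting invariance, random-addition and CNI search behavior (including
# the exhaustive 105-topology oracle), bootstrap and majority consensus.

test_that("fitch_score handles the canonical 4-taxon worked case", {
  mat <- rbind(t1 = "A", t2 = "A", t3 = "R", t4 = "R")
  cm <- make_cmat(mat)
  t_ab <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  t_ax <- ape::read.tree(text = "((t1,t3),(t2,t4));")
  expect_identical(fitch_score(t_ab, cm), 1L)
  expect_identical(fitch_score(t_ax, cm), 2L)
  # identical column contributes nothing
  cm0 <- make_cmat(rbind(t1 = "W", t2 = "W", t3 = "W", t4 = "W"))
  expect_identical(fitch_score(t_ab, cm0), 0L)
  expect_error(fitch_score(t_ab, make_cmat(rbind(x = "A", y = "A",
                                                 z = "A", w = "A"))),
               "taxa")
})

test_that("fitch_score equals exhaustive enumeration on small matrices", {
  set.seed(41)
  for (rep in 1:12) {
    n <- sample(4:6, 1)
    ncol <- sample(2:5, 1)
    taxa <- paste0("t", seq_len(n))
    mat <- matrix(sample(c("A", "C", "G", "T"), n * ncol, TRUE), nrow = n,
                  dimnames = list(taxa, NULL))
    tr <- ape::rtree(n, tip.label = sample(taxa))
    cm <- make_cmat(mat)
    expect_identical(fitch_score(tr, cm), as.integer(oracle_fitch(tr, mat)),
                     info = sprintf("rep %d", rep))
  }
})

test_that("fitch_score is invariant under re-rooting across every edge", {
  set.seed(42)
  taxa <- paste0("t", 1:8)
  tr <- ape::rtree(8, tip.label = taxa)
  mat <- matrix(sample(c("A", "R", "N", "D"), 8 * 6, TRUE), nrow = 8,
                dimnames = list(taxa, NULL))
  cm <- make_cmat(mat)
  ref <- fitch_score(tr, cm)
  un <- ape::unroot(tr)
  cs <- clade_sets(un)
  for (side in cs) {
    og <- setdiff(taxa, side)
    rooted <- ape::root(un, outgroup = side, resolve.root = TRUE)
    expect_identical(fitch_score(rooted, cm), ref)
  }
  for (tp in taxa) {
    expect_identical(
      fitch_score(ape::root(un, outgroup = tp, resolve.root = TRUE), cm),
      ref)
  }
})

test_that("random_addition_tree minimizes over the three 4-taxon
           topologies and is seed-deterministic", {
  set.seed(43)
  taxa <- paste0("t", 1:4)
  mat <- matrix(sample(c("A", "C", "G", "T"), 4 * 6, TRUE), nrow = 4,
                dimnames = list(taxa, NULL))
  cm <- make_cmat(mat)
  tops <- c("((t1,t2),(t3,t4));", "((t1,t3),(t2,t4));",
            "((t1,t4),(t2,t3));")
  scores <- vapply(tops, function(s)
    fitch_score(ape::read.tree(text = s), cm), integer(1))
  ra <- random_addition_tree(cm, seed = 7)
  expect_identical(attr(ra, "parsimony_score"), min(scores))

  r1 <- random_addition_tree(cm, seed = 9)
  r2 <- random_addition_tree(cm, seed = 9)
  expect_identical(ape::write.tree(r1), ape::write.tree(r2))
})

test_that("random addition never loses to the input-order caterpillar", {
  set.seed(44)
  for (rep in 1:5) {
    n <- 7
    taxa <- paste0("t", seq_len(n))
    mat <- matrix(sample(c("A", "C", "G", "T", "W"), n * 10, TRUE),
                  nrow = n, dimnames = list(taxa, NULL))
    cm <- make_cmat(mat)
    cat_nwk <- paste0(paste(rep("(", n - 1), collapse = ""), taxa[1], ",",
                      paste(vapply(2:n, function(i)
                        paste0(taxa[i], ")"), character(1)),
                        collapse = ","), ";")
    caterpillar <- ape::read.tree(text = cat_nwk)
    ra <- random_addition_tree(cm, seed = rep)
    expect_lte(attr(ra, "parsimony_score"),
               fitch_score(caterpillar, cm))
  }
})

test_that("cni_search: fixed point at the optimum, recovers the planted
           6-taxon topology (105-topology oracle), monotone on random
           starts", {
  # planted 6-taxon matrix with clean signal for ((t1,t2,t3),(t4,t5,t6))
  taxa <- paste0("t", 1:6)
  mat <- rbind(
    t1 = c("A", "A", "R", "N", "D", "C", "A", "G"),
    t2 = c("A", "A", "R", "N", "D", "C", "G", "A"),
    t3 = c("A", "A", "R", "D", "D", "C", "A", "A"),
    t4 = c("W", "W", "K", "N", "E", "C", "A", "G"),
    t5 = c("W", "W", "K", "N", "E", "C", "G", "A"),
    t6 = c("W", "W", "K", "D", "E", "C", "A", "A"))
  cm <- make_cmat(mat)
  # exhaustive oracle over all 105 topologies, scored by enumeration
  tops <- all_topologies(taxa)
  oracle_scores <- vapply(tops, oracle_fitch, numeric(1), mat = mat)
  best_sets <- unique(lapply(tops[oracle_scores == min(oracle_scores)],
                             split_set))
  got <- cni_search(random_addition_tree(cm, seed = 3), cm)
  expect_identical(attr(got, "parsimony_score"),
                   as.integer(min(oracle_scores)))
  expect_true(list(split_set(got)) %in% best_sets)
  # the planted split {t1,t2,t3} | {t4,t5,t6} is recovered
  expect_true(any(grepl("t4\\|t5\\|t6|t1\\|t2\\|t3", split_set(got))))

  # starting at the optimum stays there
  again <- cni_search(got, cm)
  expect_identical(ape::write.tree(again), ape::write.tree(got))

  # monotonicity over 100 random starts
  set.seed(45)
  mat2 <- matrix(sample(c("A", "C", "G", "T"), 7 * 12, TRUE), nrow = 7,
                 dimnames = list(paste0("t", 1:7), NULL))
  cm2 <- make_cmat(mat2)
  for (s in 1:100) {
    start <- random_addition_tree(cm2, seed = 1000 + s)
    out <- cni_search(start, cm2)
    expect_lte(attr(out, "parsimony_score"),
               attr(start, "parsimony_score"))
  }
})

test_that("bootstrap replicates: counts, degenerate matrix, determinism", {
  taxa <- paste0("t", 1:5)
  inv <- make_cmat(matrix("A", 5, 1, dimnames = list(taxa, NULL)))
  bt <- bootstrap_trees(inv, n_reps = 5, seed = 2)
  expect_length(bt, 5L)
  for (tr in bt) expect_identical(attr(tr, "parsimony_score"), 0L)

  set.seed(46)
  mat <- matrix(sample(c("A", "C", "G", "T"), 5 * 8, TRUE), nrow = 5,
                dimnames = list(taxa, NULL))
  cm <- make_cmat(mat)
  expect_length(bootstrap_trees(cm, n_reps = 1, seed = 3), 1L)
  b1 <- bootstrap_trees(cm, n_reps = 4, seed = 9)
  b2 <- bootstrap_trees(cm, n_reps = 4, seed = 9)
  expect_identical(lapply(b1, ape::write.tree), lapply(b2, ape::write.tree))
  expect_error(bootstrap_trees(cm, n_reps = 0, seed = 1), "n_reps")
})

test_that("clearly separated planted clades appear in nearly all
           replicates", {
  b <- simulate_toxin_family(2, 4, sub_rate = 0.15, seed = 47)
  # the two planted clades, without the rogue long-branch outgroup whose
  # unstable attachment is a separate (real) phenomenon
  ing <- b$matures[names(b$matures) != "OUT"]
  cm <- complete_deletion(progressive_msa(ing))
  bt <- bootstrap_trees(cm, n_reps = 100, seed = 48)
  clade1 <- sort(sprintf("sf01_t%d", 1:4))
  clade2 <- sort(sprintf("sf02_t%d", 1:4))
  has_split <- function(tr, cl) {
    any(vapply(split_set(tr), function(s)
      identical(sort(strsplit(s, "|", fixed = TRUE)[[1]]), cl) ||
        identical(sort(setdiff(tr$tip.label,
                               strsplit(s, "|", fixed = TRUE)[[1]])), cl),
      logical(1)))
  }
  f1 <- mean(vapply(bt, has_split, logical(1), cl = clade1))
  f2 <- mean(vapply(bt, has_split, logical(1), cl = clade2))
  expect_gte(f1, 0.95)
  expect_gte(f2, 0.95)
})

test_that("majority_consensus retains exactly the frequent splits with
           exact percentages", {
  t_ab <- ape::read.tree(text = "((t1,t2),(t3,t4),t5);")
  t_ax <- ape::read.tree(text = "((t1,t3),(t2,t4),t5);")
  cons1 <- majority_consensus(list(t_ab, t_ab, t_ab))
  expect_identical(sort(cons1$node.label[cons1$node.label != ""]),
                   c("100", "100"))
  expect_identical(split_set(cons1), split_set(t_ab))

  # a split present in 2/3 of trees: retained with support 67
  cons2 <- majority_consensus(list(t_ab, t_ab, t_ax))
  expect_true("67" %in% cons2$node.label)
  # splits below 50% are collapsed
  cons3 <- majority_consensus(list(
    t_ab, t_ax, ape::read.tree(text = "((t1,t4),(t2,t3),t5);")))
  expect_length(split_set(cons3), 0L)

  expect_error(majority_consensus(list(
    t_ab, ape::read.tree(text = "((t1,t2),(t3,t6),t5);"))), "leaf sets")
})

test_that("consensus supports equal recomputed split frequencies and match
           the ape oracle topology", {
  set.seed(49)
  b <- simulate_toxin_family(2, 3, sub_rate = 0.2, seed = 50)
  cm <- complete_deletion(progressive_msa(b$matures))
  bt <- bootstrap_trees(cm, n_reps = 40, seed = 51)
  cons <- majority_consensus(bt, outgroup = "OUT")
  # every labelled clade's support equals its recomputed frequency
  ntip <- length(cons$tip.label)
  cs <- clade_sets(cons)
  labs <- cons$node.label
  for (k in seq_along(cs)) {
    if (k == 1L || labs[k] == "") next  # skip the root
    clade <- cs[[k]]
    freq <- mean(vapply(bt, function(tr) {
      any(vapply(split_set(tr), function(s) {
        side <- sort(strsplit(s, "|", fixed = TRUE)[[1]])
        identical(side, clade) ||
          identical(sort(setdiff(tr$tip.label, side)), clade)
      }, logical(1)))
    }, logical(1)))
    expect_identical(as.integer(labs[k]),
                     as.integer(floor(100 * freq + 0.5)),
                     info = paste(clade, collapse = "+"))
  }
  # ape::consensus as an independent oracle for the retained topology
  oracle <- ape::consensus(bt, p = 0.5)
  expect_setequal(split_set(cons), split_set(oracle))
})

test_that("root_with_outgroup preserves bipartitions and places the
           outgroup at the root", {
  set.seed(52)
  taxa <- c(paste0("t", 1:6), "OG")
  tr <- ape::unroot(ape::rtree(7, tip.label = sample(taxa)))
  rooted <- root_with_outgroup(tr, "OG")
  expect_true(ape::is.rooted(rooted))
  # outgroup is a child of the root
  ntip <- length(rooted$tip.label)
  root_children <- rooted$edge[rooted$edge[, 1] == ntip + 1L, 2]
  expect_true(match("OG", rooted$tip.label) %in% root_children)
  # bipartition multiset preserved through root/unroot round trip
  expect_setequal(split_set(ape::unroot(rooted)), split_set(tr))
  expect_error(root_with_outgroup(tr, "nope"), "not in tree")
})
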