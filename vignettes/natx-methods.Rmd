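---
title: "natx: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{natx: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind natx, and states plainly what a green test establishes
and what it does not.

## 1. The biological model

Sodium-channel scorpion toxins (NaScTx) are 55–79 residue peptides with
6–8 cysteines forming 3–4 disulfide bridges.  They are translated as
precursors: an 18–22 residue signal peptide, the mature toxin, and
optionally a short C-terminal pro-sequence.  The maturation rule natx
implements is the standard one: if the translated precursor ends in Gly
followed by one to three basic residues (observed tails: GK, GKK, GKRK),
a carboxypeptidase removes the basics and the Gly donates its amine to
the new C-terminal residue, which is therefore amidated.  Relative to the
free acid this changes the average mass by −0.9847 Da; each disulfide
bridge removes two hydrogens (−2.0159 Da average, −2.0157 monoisotopic).

Trailing basic runs longer than three are left unprocessed and flagged
(`long_basic_run`) rather than guessed at: the rule is an empirical
generalization of observed tails, and longer runs are outside it.

Note an intrinsic ambiguity of the rule: a genuine mature peptide whose
last residues happen to be Gly+basics is indistinguishable from an
amidation substrate.  The synthetic generator therefore freezes the
mature C-terminal residue to a non-Gly, non-basic residue, which is why
the planted-motif recovery criterion can demand 100% accuracy; on real
sequences the rule is a hypothesis, usually confirmed by the measured
mass (amidated vs free acid differ by 0.98 Da).

## 2. Mass calculation

`average_mass()` and `monoisotopic_mass()` sum residue masses from a
versioned plain-text table (`inst/extdata/residue_masses_v1.tsv`, the
standard average/monoisotopic residue masses), add one water (18.0153 /
18.0106 Da) and apply the corrections above.  By default all cysteines
are assumed paired (`n_disulfides = floor(n_cys/2)`), overridable per
record.  Comparisons run at full precision; reports print one decimal.

`reconcile_masses()` matches theoretical against measured masses by
greedy smallest-|Δ| one-to-one assignment under a tolerance, default
1.5 Da: wide enough for instrument-level disagreement on ~7 kDa peptides,
narrow enough to keep genuinely different peptides (tens of Da apart)
unmatched.  Ties break on identifiers, so the result is independent of
row order.

The test-suite oracle recomputes masses from residue elemental
compositions times atomic weights (C 12.011, H 1.00794, N 14.00674,
O 15.9994, S 32.06 — the weights underlying the standard residue tables);
agreement is required within 0.05 Da on random peptides.

## 3. EST cleanup

`trim_quality()` keeps the longest interval in which *every* sliding
window of length 100 has mean Phred quality ≥ 20 (the classic EST
pipeline setting); reads with no qualifying interval are rejected.  One
consequence worth knowing: a Q30 read with a Q5 tail keeps up to 40 tail
bases, because windows straddling the boundary still average ≥ 20.  The
exhaustive-interval oracle in the tests confirms this is what the stated
rule implies.

`mask_vector()` removes exact terminal matches (≥ `min_match`, default
15 nt, forward or reverse-complement) of a cloning-vector sequence.

`cluster_ests()` implements the ">95 identical per 100 nt" rule as
single-linkage clustering over best ungapped overlaps of ≥ 100 nt.  A
full overlap-layout-consensus assembler is out of scope; because the
bundled read simulator introduces substitutions only (no indels), an
exhaustive offset scan *is* the exact best local overlap (a banded
alignment with band width zero), and the column-majority consensus over
the offset layout reconstructs the template.  A shared exact 20-mer
prefilter keeps the pairwise stage near-linear; a >95%-identity overlap
of ≥100 nt without a shared 20-mer is vanishingly unlikely.  Ties in
consensus columns resolve alphabetically (A<C<G<T) for reproducibility.
Coordinates are 0-based half-open internally, 1-based inclusive in
reports.

## 4. Precursor annotation

`find_orf()` scans the three forward frames (directional library) for
ATG-initiated frames ending at the first in-frame stop (or the sequence
end) and keeps the longest translation, requiring ≥ 50 codons.

Signal cleavage does not re-implement a signal-peptide predictor.  As in
practice, the site is anchored on known matures: for each candidate site
k in 18–22, the 10-mer at k+1 is compared position-wise to the first ten
residues of every reference mature; the best identity wins (ties take the
smallest k), and anything ≤ 0.5 identity is an error rather than a guess.
This matches how mature start sites are actually assigned when
characterized homologs exist, and recovers ≥ 95% of planted sites when
the references include the true subfamily.

`classify_candidate()` assigns alpha-like/beta-like by nearest reference
percent identity, with an "ambiguous" band when the best identities of
the two classes are within 5 percentage points — toxins genuinely similar
to both classes exist, and pretending otherwise would be overconfident.

## 5. Alignment and the character matrix

`global_align()` is a standard Needleman–Wunsch with affine gaps (a gap
of length L costs `gap_open + gap_extend·L`), BLOSUM62 and gap 10/0.5 by
default — ClustalW-like settings, since no specific series is mandated.
Traceback tie-breaking is fixed (diagonal, then up, then left).
`percent_identity()` divides matches by the *ungapped reference length*
and rounds half-up to an integer: this is the convention under which the
first-described toxin of a subfamily counts as 100%.

`progressive_msa()` builds pairwise identity distances, a neighbor-
joining guide tree, and merges profiles (residue-frequency columns scored
through the substitution matrix) in guide-tree order with the same affine
DP.  Manual curation is honored by `read_alignment()`: a user-supplied
Clustal or FASTA alignment bypasses the aligner entirely and flows
through the rest of the pipeline unchanged — manual adjustment is not
reproducible algorithmically, so it is treated as input.

`complete_deletion()` keeps exactly the columns where every taxon has one
of the 20 residues; `-`, `.`, `X` and `?` remove the column.  The count
of retained positions is recorded (`n_positions`), since parsimony
results are only interpretable relative to it.

## 6. Maximum parsimony

Characters are unordered 20-state with unit cost.  `fitch_score()` is the
classic two-set pass, implemented in C++ over bitmask-encoded columns
with integer column weights (so bootstrap resampling is just a weight
vector).  The score is root-invariant; trees must be binary (a basal
trifurcation — an unrooted binary tree — is accepted).

The search protocol mirrors the classic MP setup: `random_addition_tree()`
inserts taxa in seeded random order at the score-minimizing attachment;
`cni_search()` hill-climbs with best-improving nearest-neighbor-
interchange moves and, at level 2 (the default), explores pairs of
successive NNI moves once no single move improves.  "Search level" is
interpreted as the NNI move depth of the examined neighborhood; the level
is configurable.  Among equally parsimonious trees the first found under
the seeded order is kept — tie sets are not enumerated, matching the
single-consensus-tree reporting convention.

`bootstrap_trees()` resamples matrix columns with replacement to the
original length, then runs the full search (10 random-addition starts +
CNI) per replicate.  `majority_consensus()` counts bipartitions exactly
and retains those at ≥ 50% (configurable), annotating each retained edge
with its exact percentage; with an outgroup given, splits are oriented
away from it and the consensus is returned rooted.  All percentages are
exact counts over the replicate trees — the tests recompute them
independently from the stored replicates.

## 7. Subfamily extraction and nomenclature

`extract_subfamilies()` applies an explicit, testable surrogate for the
by-eye clustering used on real trees: subfamilies are maximal ingroup
clades with support ≥ 50% whose parent is unsupported or root-adjacent;
taxa hanging directly off the unresolved backbone become singleton
subfamilies (the analogue of toxins "forming independent branches").
`consensus_sequence()` emits the majority residue per column (> 0.5 by
default), lower-case `x` where there is no majority, and drops
gap-majority columns.  `assign_nomenclature()` numbers members within
each subfamily by the supplied chronological description ranks —
`NaTx<subfamily>.<member>` — keeping trivial names alongside.

Duplication semantics worth stating: duplicating a member that carries
the majority residue leaves the consensus unchanged; duplicating a
minority holder can decay a 2/3 majority to a tie (`x`), and a duplicate
can resolve a 50/50 tie.  This is a property of the majority rule itself,
not an implementation choice.

## 8. The synthetic world

`simulate_toxin_family()` plants: a rooted tree with `n_subfamilies`
monophyletic clades plus an outgroup; mature peptides of `scaffold_len`
(default 72) residues with `n_cys` (default 8) frozen cysteine columns,
evolved by per-site i.i.d. replacement drawn uniformly from the
non-cysteine residues (probability per branch = `sub_rate` × branch
length, capped at 0.95); per-subfamily conserved signal lengths (18–22)
and C-terminal motifs drawn from {∅, GK, GKK, GKRK}; reverse-translated
CDS via a fixed most-frequent-codon table; and EST reads with
substitution errors, two-state (high/low) Phred qualities with a
low-quality 3' tail, stratified 5'-anchored starts, and optional
exact-prefix vector contamination from a bundled 50-nt mock vector.

Branch lengths encode a *rapid radiation*: subfamily stems 0.35,
within-clade edges 0.15, backbone edges 0.001 (an effectively hard
polytomy — the deep order is intended to collapse below 50% bootstrap, as
it does in real NaScTx consensus trees), and an outgroup branch of 0.05.
Two of these deserve comment:

* **The backbone is essentially zero.**  Early designs used 0.02–0.05;
  any backbone edge that happens to carry even one substitution produces
  a ≥ 50%-supported composite clade, which the maximal-clade extraction
  rule then absorbs into a giant spurious "subfamily".  A hard polytomy
  is the world in which the 50%-support surrogate rule means what it is
  supposed to mean.
* **The outgroup is near-ancestral.**  A deeply divergent outgroup (like
  a real heterologous toxin) attaches to an unresolved crown at a
  *data-stable* chance position, so the complement of its preferred
  neighbor acquires > 50% support across bootstrap replicates and again
  becomes a giant clade.  Simulating the outgroup as a short-branch
  ancestral proxy keeps its attachment tie-broken per replicate.  This is
  a known behavior of bootstrap support under polytomies, and it is the
  main feature of real data that the generator deliberately does *not*
  emulate.

What a green planted-truth test establishes: on data with clear clade
signal, an unresolved backbone and no indels, the full pipeline (MSA →
complete deletion → bootstrap MP → consensus → extraction) recovers the
planted subfamilies.  What it does not establish: performance under
indels and alignment error, rate heterogeneity, biased codon usage, or a
strongly divergent outgroup — and chance shared substitutions between two
clade stems can still merge a pair of subfamilies (the adjusted-Rand
criterion tolerates roughly one such event in fourteen clades).  The
recovery criteria are stochastic; they are pinned to fixed seeds and
verified to reflect typical behavior, not certainties.

## 9. Numerical and formatting conventions

* Printed identities and bootstrap supports round half-up (printed
  values never show banker's rounding artifacts).
* Masses: full precision internally, one decimal in reports.
* Intervals: 0-based half-open internally (EST stage), 1-based inclusive
  in all user-facing annotation.
* All generators and searches are pure functions of their arguments
  including `seed`; the pipeline derives per-stage seeds from one master
  seed and writes md5 checksums of every output into `manifest.json`.
* Consensus-column, alignment-traceback and equal-parsimony ties all
  break deterministically (documented above) so identical inputs give
  byte-identical outputs.

## 10. Known limitations

* No indel evolution, so the progressive aligner is exercised mostly in
  the gap-free regime on synthetic data (real gaps enter via the
  user-supplied alignment path).
* The EST stage is a bookkeeping-faithful simplification: no base-caller,
  no chimera detection, no true OLC assembly.
* CNI "search level 2" follows the NNI-depth interpretation; the
  original implementation's exact move set is undocumented, so
  edge-exact topological agreement with published trees is not claimed —
  clade-level agreement is the testable contract.
* Subfamily boundaries on real data ultimately involve curation; the
  extraction rule is a surrogate, and a curated partition can be imposed
  by supplying the alignment and tree directly.
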