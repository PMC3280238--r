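Package: natx
Title: Annotation and Parsimony-Based Classification of Scorpion
    Sodium-Channel Toxins
Version: 0.1.0
Authors@R:
    person("natx", "maintainers", email = "natx@example.org", role = c("aut", "cre"))
Description: Tools for turning scorpion venom-gland cDNA sequences into
    annotated mature sodium-channel toxins (NaScTx) and for clustering them
    into NaTx subfamilies. Covers simplified EST quality trimming, vector
    masking and contig clustering; precursor annotation (open reading frame,
    signal-peptide cleavage anchored on reference matures, C-terminal
    pro-peptide removal with amidation); theoretical average and monoisotopic
    peptide masses with disulfide and amidation corrections reconciled against
    experimental mass tables; global and progressive multiple alignment with
    complete-deletion filtering; from-scratch maximum-parsimony inference
    (Fitch scoring, random-addition starting trees, close-neighbor-interchange
    search, nonparametric bootstrap, majority-rule consensus, outgroup
    rooting); and subfamily extraction with consensus sequences and systematic
    NaTx nomenclature. A synthetic-data generator with known ground truth
    makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    withr
Config/testthat/edition: 3
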