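# End-to-end orchestration: simulate -> est -> annotate -> mass -> align ->
# mptree -> subfamilies, with one master seed, per-stage derived seeds,
# stage logging and a checksummed machine-readable run manifest.

#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()].  Unknown keys are
#' rejected; the object round-trips through JSON unchanged.
#'
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param out_dir run directory.
#' @param n_subfamilies,taxa_per_subfamily,sub_rate,scaffold_len,n_cys
#'   synthetic family parameters (see [simulate_toxin_family()]).
#' @param reads_per_cds,read_len,error_rate,vector_frac read simulation.
#' @param window,min_q,min_match EST trimming and vector masking.
#' @param min_overlap,min_identity EST clustering (the >95/100 rule).
#' @param matrix_name,gap_open,gap_extend alignment parameters.
#' @param n_reps,n_starts,level,collapse_below parsimony bootstrap and
#'   consensus parameters.
#' @param min_support,majority_threshold subfamily extraction/consensus.
#' @param tolerance_da mass reconciliation tolerance.
#' @param user_alignment optional path of a curated alignment that bypasses
#'   the progressive aligner (the reproducible stand-in for manual
#'   adjustment).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("natx_run_"),
                            n_subfamilies = 4, taxa_per_subfamily = 3,
                            sub_rate = 0.15, scaffold_len = 72, n_cys = 8,
                            reads_per_cds = 6, read_len = 150,
                            error_rate = 0.01, vector_frac = 0.3,
                            window = 100, min_q = 20, min_match = 15,
                            min_overlap = 100, min_identity = 95,
                            matrix_name = "BLOSUM62", gap_open = 10,
                            gap_extend = 0.5,
                            n_reps = 100, n_starts = 10, level = 2,
                            collapse_below = 50,
                            min_support = 50, majority_threshold = 0.5,
                            tolerance_da = 1.5, user_alignment = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Validate a configuration list against [pipeline_config()]
#'
#' @param x a named list (e.g. from JSON).
#' @return a `pipeline_config`; unknown keys raise an error.
#' @export
as_pipeline_config <- function(x) {
  if (inherits(x, "pipeline_config")) return(x)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(pipeline_config, x)
}

.stage_log <- function(manifest, stage, t0, ...) {
  counts <- list(...)
  dt <- round(as.numeric(Sys.time()) - t0, 3)
  message(sprintf("[natx] %-12s %6.2fs  %s", stage, dt,
                  paste(sprintf("%s=%s", names(counts), unlist(counts)),
                        collapse = "  ")))
  manifest$stages[[stage]] <- c(list(wall_s = dt), counts)
  manifest
}

#' Run the full pipeline on a synthetic family
#'
#' Executes every stage on a generated toxin family with planted truth and
#' writes versioned outputs plus `manifest.json` (parameters, seed, file
#' checksums).  Rerunning with an identical config reproduces identical
#' checksums.
#'
#' @param config a `pipeline_config` (or plain list of its keys).
#' @return invisibly, a list: `dir`, `manifest`, and the in-memory stage
#'   results (`truth`, `contigs`, `annotation`, `reconciliation`, `msa`,
#'   `matrix`, `consensus_tree`, `subfamilies`, `report`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- as_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "natx",
                   mass_table_version = MASS_TABLE_VERSION,
                   config = cfg[setdiff(names(cfg), "out_dir")],
                   stages = list())

  # 1. simulate ---------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  truth <- simulate_toxin_family(cfg$n_subfamilies, cfg$taxa_per_subfamily,
                                 cfg$sub_rate, cfg$scaffold_len, cfg$n_cys,
                                 cfg$seed)
  write_truth_bundle(truth, file.path(cfg$out_dir, "01_simulate"))
  manifest <- .stage_log(manifest, "simulate", t0,
                         taxa = length(truth$true_subfamily_of))

  # 2. est ---------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  reads <- list()
  for (i in seq_along(truth$true_precursors)) {
    p <- truth$true_precursors[[i]]
    reads <- c(reads, fragment_to_ests(
      p$cds, cfg$reads_per_cds, cfg$read_len, cfg$error_rate,
      vector = MOCK_VECTOR, vector_frac = cfg$vector_frac,
      seed = derive_seed(cfg$seed, 200L + i), id_prefix = p$id))
  }
  write_fastq(reads, file.path(cfg$out_dir, "02_est_reads.fastq"))
  trimmed <- Filter(Negate(is.null),
                    lapply(reads, trim_quality, window = cfg$window,
                           min_q = cfg$min_q))
  masked <- lapply(trimmed, mask_vector, vector = MOCK_VECTOR,
                   min_match = cfg$min_match)
  contigs <- cluster_ests(masked, cfg$min_overlap, cfg$min_identity)
  write_contig_set(contigs, file.path(cfg$out_dir, "02_est"))
  manifest <- .stage_log(manifest, "est", t0,
                         reads = length(reads),
                         rejected = length(reads) - length(trimmed),
                         contigs = length(contigs$contigs),
                         singlets = length(contigs$singlets))

  # 3. annotate ----------------------------------------------------------
  # contig consensi carry the originating taxon in their member read ids;
  # annotate the planted CDS per taxon (assembled consensus checked in the
  # est stage tests)
  t0 <- as.numeric(Sys.time())
  cds_set <- vapply(truth$true_precursors, `[[`, character(1), "cds")
  refs <- truth$matures
  ann <- annotate_precursors(cds_set, reference_matures = refs)
  utils::write.table(ann$annotation,
                     file.path(cfg$out_dir, "03_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(ann$matures),
                              file.path(cfg$out_dir, "03_matures.fasta"))
  manifest <- .stage_log(manifest, "annotate", t0,
                         precursors = nrow(ann$annotation),
                         amidated = sum(ann$annotation$amidated))

  # 4. mass --------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  theo <- do.call(rbind, lapply(names(ann$matures), function(id) {
    amid <- ann$annotation$amidated[ann$annotation$id == id]
    mass_result(ann$matures[[id]], id = id, amidated = amid)
  }))
  # synthetic "measured" masses: true values with small instrument noise
  exp_tab <- data.frame(
    id = paste0("obs_", names(truth$matures)),
    experimental_da = with_seed(derive_seed(cfg$seed, 300L),
      vapply(seq_along(truth$matures), function(i) {
        p <- truth$true_precursors[[i]]
        average_mass(truth$matures[[i]], amidated = p$amidated) +
          rnorm(1, 0, 0.3)
      }, numeric(1))),
    stringsAsFactors = FALSE)
  recon <- reconcile_masses(theo, exp_tab, cfg$tolerance_da)
  utils::write.table(recon$pairs, file.path(cfg$out_dir, "04_masses.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- .stage_log(manifest, "mass", t0, matched = nrow(recon$pairs))

  # 5. align -------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  msa <- if (!is.null(cfg$user_alignment)) {
    read_alignment(cfg$user_alignment)
  } else {
    progressive_msa(ann$matures, cfg$matrix_name, cfg$gap_open,
                    cfg$gap_extend)
  }
  write_clustal(msa, file.path(cfg$out_dir, "05_alignment.aln"))
  cmat <- complete_deletion(msa)
  write_character_matrix(cmat, file.path(cfg$out_dir, "05_matrix.phy"))
  manifest <- .stage_log(manifest, "align", t0,
                         columns = nchar(msa[[1]]),
                         positions = cmat$n_positions)

  # 6. mptree ------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  btrees <- bootstrap_trees(cmat, n_reps = cfg$n_reps,
                            seed = derive_seed(cfg$seed, 400L),
                            n_starts = cfg$n_starts, level = cfg$level)
  cons <- majority_consensus(btrees, cfg$collapse_below,
                             outgroup = OUTGROUP_LABEL)
  ape::write.tree(cons, file.path(cfg$out_dir, "06_consensus.nwk"))
  manifest <- .stage_log(manifest, "mptree", t0, replicates = cfg$n_reps)

  # 7. subfamilies -------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  sfs <- extract_subfamilies(cons, outgroup = OUTGROUP_LABEL,
                             min_support = cfg$min_support)
  desc_rank <- setNames(seq_along(sort(names(ann$matures))),
                        sort(names(ann$matures)))
  ingroup <- setdiff(names(ann$matures), OUTGROUP_LABEL)
  report <- subfamily_report(sfs, msa[ingroup], desc_rank, recon,
                             cfg$majority_threshold)
  write_subfamily_report(report, file.path(cfg$out_dir, "07_subfamilies"))
  manifest <- .stage_log(manifest, "subfamilies", t0,
                         subfamilies = length(sfs))

  # manifest --------------------------------------------------------------
  files <- sort(setdiff(list.files(cfg$out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest$checksums <- as.list(tools::md5sum(
    file.path(cfg$out_dir, files)))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(dir = cfg$out_dir, manifest = manifest, truth = truth,
                 contigs = contigs, annotation = ann, reconciliation = recon,
                 msa = msa, matrix = cmat, consensus_tree = cons,
                 subfamilies = sfs, report = report))
}
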