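# End-to-end orchestration: synthetic data -> ribosome-profiling QC ->
# differential TE -> proteomics -> cross-layer integration -> motif and
# set enrichment, with a TSV/JSON report bundle.

#' Pipeline configuration
#'
#' Bundles the synthetic-cohort settings, the experiment design, the call
#' thresholds used at every stage, and the master seed from which all
#' substream seeds are derived.
#'
#' @param n_genes Synthetic cohort size.
#' @param design An [experiment_design()].
#' @param sim A [simulation_config()].
#' @param mode_fractions,effect_sizes Passed to [generate_gene_specs()].
#' @param n_footprints Footprint reads simulated for QC.
#' @param thresholds Named list of call thresholds; defaults:
#'   `te_fdr = 0.1`, `te_fc = 1.5`, `prot_fdr = 0.05`, `prot_fc = 3`,
#'   `rna_fc = 2`, `rfp_fc = 2`, `buffer_prot_fc = 2`, `withdrawal_fc = 2`,
#'   `withdrawal_fdr = 0.05`.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_genes = 2000,
                            design = experiment_design(),
                            sim = simulation_config(),
                            mode_fractions = default_mode_fractions(),
                            effect_sizes = default_effect_sizes(),
                            n_footprints = 50000,
                            thresholds = list(), seed = 1) {
  def <- list(te_fdr = 0.1, te_fc = 1.5, prot_fdr = 0.05, prot_fc = 3,
              rna_fc = 2, rfp_fc = 2, buffer_prot_fc = 2,
              withdrawal_fc = 2, withdrawal_fdr = 0.05)
  unknown <- setdiff(names(thresholds), names(def))
  if (length(unknown))
    stopf("unknown threshold(s): %s", paste(unknown, collapse = ", "))
  def[names(thresholds)] <- thresholds
  if (any(unlist(def) <= 0)) stopf("all thresholds must be > 0")
  structure(list(n_genes = n_genes, design = design, sim = sim,
                 mode_fractions = mode_fractions,
                 effect_sizes = effect_sizes,
                 n_footprints = n_footprints,
                 thresholds = def, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates the multi-omics dataset, runs QC, differential TE for each
#' committed state against the reference, proteomics statistics (including
#' the single-inhibitor withdrawal cultures), cross-layer integration and
#' 3'UTR ARE enrichment, and collects everything into a summary list.  With
#' `out_dir` set, all stage tables are written as TSV plus a
#' `summary.json`; every file carries the configuration hash in a comment
#' header, and reruns with the same config and seed are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return (Invisibly) a list: `data` (the simulated layers and ground
#'   truth) and `summary` (per-stage results: `qc`, `te_sets`, `buffering`,
#'   `regulatory_modes`, `inhibitor_classes`, `correlations`,
#'   `enrichment`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  des <- config$design
  ref <- des$reference
  alts <- setdiff(des$conditions, c(ref, "CHL", "PDL"))
  thr <- config$thresholds
  hash <- config_hash(unclass(config))

  ## --- synthetic cohort -------------------------------------------------
  specs <- generate_gene_specs(config$n_genes, config$mode_fractions,
                               config$effect_sizes,
                               seed = derive_seed(config$seed, "specs"))
  counts <- simulate_counts(specs, des, config$sim,
                            seed = derive_seed(config$seed, "counts"))
  prot_design <- experiment_design(
    conditions = c(des$conditions, "CHL", "PDL"),
    n_rna_reps = des$n_rna_reps, n_rfp_reps = des$n_rfp_reps,
    n_prot_reps = des$n_prot_reps, library_depth = 0)
  prot <- simulate_proteins(specs, prot_design, config$sim,
                            conditions = prot_design$conditions,
                            seed = derive_seed(config$seed, "proteins"))
  tx <- simulate_transcripts(specs,
                             seed = derive_seed(config$seed, "transcripts"))
  fp_tx <- tx[tx$cds_len > 1000, , drop = FALSE]
  te_w <- stats::setNames(2^specs$base_log2_cpm, specs$gene_id)
  fps <- simulate_footprints(fp_tx, te_w[fp_tx$gene_id],
                             n_reads = config$n_footprints,
                             seed = derive_seed(config$seed, "footprints"))

  ## --- ribosome-profiling QC -------------------------------------------
  offset <- estimate_psite_offset(fps, fp_tx)
  meta_prof <- metagene_profile(fps, fp_tx)
  cds_counts <- count_cds_reads(fps, fp_tx)
  cov_by_region <- tapply(meta_prof$mean_coverage, meta_prof$region, mean)
  qc <- list(psite_mode = offset$mode,
             cds_reads_assigned = sum(cds_counts),
             mean_coverage = as.list(cov_by_region))

  ## --- differential TE --------------------------------------------------
  te_res <- lapply(alts, function(alt)
    differential_te(counts$rna, counts$rfp, counts$meta, ref, alt,
                    fdr_max = thr$te_fdr, fc_min = thr$te_fc))
  names(te_res) <- alts
  te_sets <- if (length(alts) >= 2)
    partition_te_sets(te_res[[1]], te_res[[2]], labels = alts[1:2])
  else NULL

  ## --- proteomics -------------------------------------------------------
  pmeta <- prot$meta
  filtered <- filter_reproducible(prot$intensity, pmeta,
                                  min_valid = des$n_prot_reps)
  imputed <- impute_missing(filtered, seed = derive_seed(config$seed,
                                                         "impute"))
  prot_res <- lapply(c(alts, "CHL", "PDL"), function(cond)
    differential_protein(imputed, pmeta, ref, cond,
                         fc_min = thr$prot_fc, fdr_max = thr$prot_fdr))
  names(prot_res) <- c(alts, "CHL", "PDL")
  exclusive <- state_exclusive_proteins(prot$intensity, pmeta,
                                        conditions = c(ref, alts),
                                        min_valid = des$n_prot_reps)

  ## --- integration ------------------------------------------------------
  main_alt <- alts[1]
  triplets <- lapply(alts, function(alt)
    assemble_triplets(te_res[[alt]], prot_res[[alt]], prot$groups))
  names(triplets) <- alts
  modes <- classify_regulatory_mode(triplets[[main_alt]],
                                    rna_fc = thr$rna_fc,
                                    rfp_fc = thr$rfp_fc)
  buffered <- detect_buffering(triplets[[main_alt]],
                               protein_fc_max = thr$buffer_prot_fc)
  wd_calls <- prot_res[[main_alt]][prot_res[[main_alt]]$called, ]
  wd <- classify_inhibitor_dependency(
    wd_calls, prot_res[["CHL"]], prot_res[["PDL"]],
    fc_min = thr$withdrawal_fc, fdr_max = thr$withdrawal_fdr)
  correlations <- layer_correlations(triplets[[main_alt]])

  ## --- 3'UTR ARE enrichment --------------------------------------------
  are_hits <- scan_exact_motif(tx$utr3)
  hit_genes <- tx$gene_id[are_hits > 0]
  universe <- triplets[[main_alt]]$gene_id
  buffered_up <- intersect(buffered$gene_id[buffered$delta_te > 0], universe)
  enrich <- NULL
  if (length(buffered_up) >= 5) {
    enrich <- motif_presence_enrichment(intersect(hit_genes, universe),
                                        buffered_up, universe)
    rnd <- with_seed(derive_seed(config$seed, "random-set"),
                     sample(universe, length(buffered_up)))
    ctrl <- motif_presence_enrichment(intersect(hit_genes, universe),
                                      rnd, universe)
    enrich <- rbind(cbind(set = c("higher_te_in_reference", "random"),
                          rbind(enrich, ctrl)))
  }

  mode_counts <- table(factor(modes$mode,
                              levels = c("transcriptional", "translational",
                                         "post_translational",
                                         "unclassified")))
  class_counts <- table(factor(wd$class,
                               levels = c("CP", "2i", "P", "C", "none")))
  summary <- list(
    qc = qc,
    te_sets = list(
      n_tested = sum(te_res[[main_alt]]$passes_filter),
      n_called = lapply(te_res, function(r) sum(r$called)),
      partition = if (!is.null(te_sets))
        lapply(te_sets[1:3], length) else NULL),
    buffering = list(n_buffered = nrow(buffered),
                     n_triplets = nrow(triplets[[main_alt]])),
    regulatory_modes = list(
      counts = as.list(mode_counts),
      percent = as.list(round(100 * mode_counts /
                                max(1, sum(mode_counts)), 1))),
    inhibitor_classes = as.list(class_counts),
    correlations = list(
      rna_rfp = unname(correlations["log2fc_rna", "log2fc_rfp"]),
      te_protein = unname(correlations["delta_te", "log2fc_protein"]),
      rna_protein = unname(correlations["log2fc_rna", "log2fc_protein"])),
    enrichment = if (!is.null(enrich)) enrich else
      list(note = "too few buffered genes for enrichment"),
    n_exclusive = sum(exclusive$exclusive),
    config_hash = hash
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- paste0("config_hash=", hash)
    wt <- function(df, name) {
      con <- file(file.path(out_dir, name), "w")
      on.exit(close(con))
      writeLines(paste0("# ", hdr), con)
      utils::write.table(df, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    wt(specs, "ground_truth.tsv")
    write_matrix_tsv(counts$rna, file.path(out_dir, "rna_counts.tsv"), hdr)
    write_matrix_tsv(counts$rfp, file.path(out_dir, "rfp_counts.tsv"), hdr)
    write_meta_tsv(rbind(counts$meta, prot$meta),
                   file.path(out_dir, "samples.tsv"), hdr)
    write_matrix_tsv(prot$intensity,
                     file.path(out_dir, "protein_intensity.tsv"), hdr)
    for (alt in alts) {
      wt(te_res[[alt]], sprintf("te_%s_vs_%s.tsv", alt, ref))
      wt(prot_res[[alt]], sprintf("protein_%s_vs_%s.tsv", alt, ref))
      wt(triplets[[alt]], sprintf("triplets_%s_vs_%s.tsv", alt, ref))
    }
    if (!is.null(te_sets)) wt(te_sets$table, "te_partition.tsv")
    wt(modes, "regulatory_modes.tsv")
    wt(buffered, "buffered_genes.tsv")
    wt(wd, "inhibitor_classes.tsv")
    wt(as.data.frame(offset$histogram), "psite_histogram.tsv")
    wt(meta_prof, "metagene_profile.tsv")
    if (!is.null(enrich)) wt(enrich, "are_enrichment.tsv")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(
    data = list(specs = specs, counts = counts, proteins = prot,
                transcripts = tx, footprints = fps),
    results = list(te = te_res, te_sets = te_sets, protein = prot_res,
                   triplets = triplets, modes = modes, buffered = buffered,
                   inhibitor = wd, correlations = correlations,
                   enrichment = enrich, exclusive = exclusive,
                   qc = list(offset = offset, metagene = meta_prof,
                             cds_counts = cds_counts)),
    summary = summary
  ))
}
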