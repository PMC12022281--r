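#' Simulate and analyse a complete reporter experiment
#'
#' Generates gene models, variants with planted PSI effects, the barcoded
#' oligo pool, and per-replicate reporter sequencing data for one or more
#' simulated cell lines; then runs the quantification (read classification,
#' UMI deduplication, per-barcode PSI) and SDV-calling pipeline, returning
#' results next to the ground truth. Cell lines share true PSI values and
#' differ only by independent sampling noise.
#'
#' @param n_variants number of variants (default 200).
#' @param fraction_sdv fraction with a true effect (default 0.2).
#' @param effect_range true |delta-PSI| range for SDV (default c(10, 50)).
#' @param barcodes_per_construct barcodes per allele (default 4).
#' @param n_replicates transfection replicates (default 3).
#' @param depth expected molecules per barcode per replicate (default 500).
#' @param umi_dup_rate,seq_error_rate read-simulation noise (defaults 0.1,
#'   0.001); ignored at `level = "counts"`.
#' @param level `"reads"` (full nucleotide-level path) or `"counts"`
#'   (molecule-count shortcut; same statistical model, no sequences).
#' @param n_cell_lines simulated cell lines (default 1).
#' @param fdr_regime FDR regime for SDV calls (default 0.01).
#' @param min_reads minimum informative molecules per barcode (default 10).
#' @param seed master seed; all component seeds derive from it.
#' @return list with `truth`, `manifest`, `bc_psi` (per cell line) and
#'   `results` (per cell line, from [sdv_call_table()]).
#' @export
simulate_reporter_experiment <- function(n_variants = 200L,
                                         fraction_sdv = 0.2,
                                         effect_range = c(10, 50),
                                         barcodes_per_construct = 4L,
                                         n_replicates = 3L, depth = 500,
                                         umi_dup_rate = 0.1,
                                         seq_error_rate = 0.001,
                                         level = c("reads", "counts"),
                                         n_cell_lines = 1L,
                                         fdr_regime = 0.01,
                                         min_reads = 10L, seed = 1L) {
  level <- match.arg(level)
  base_seed <- (as.integer(seed) %% 100000L) * 10000L
  models <- sim_gene_models(n_genes = n_variants + 20L,
                            seed = base_seed + 1L)
  regions <- select_test_regions(models$exons, models$genome)
  if (nrow(regions) < n_variants) stop("not enough eligible regions simulated")
  sim <- sim_variants(regions, models$genome, fraction_sdv = fraction_sdv,
                      effect_range = effect_range, n_variants = n_variants,
                      seed = base_seed + 2L)
  pool <- assemble_pool(regions, sim$variants,
                        barcodes_per_construct = barcodes_per_construct,
                        seed = base_seed + 3L)
  truth <- sim$truth[variant_id %in% pool$variant_id]

  results <- list()
  bc_psi_all <- list()
  for (cl in seq_len(n_cell_lines)) {
    psi_list <- vector("list", n_replicates)
    for (rep_i in seq_len(n_replicates)) {
      rseed <- base_seed + 100L * cl + rep_i
      if (level == "reads") {
        rr <- sim_reporter_reads(pool, truth, depth = depth,
                                 umi_dup_rate = umi_dup_rate,
                                 seq_error_rate = seq_error_rate,
                                 seed = rseed)
        psi <- quantify_replicate(rr$reads, pool, min_reads = min_reads)
      } else {
        counts <- sim_molecule_counts(pool, truth, depth = depth,
                                      seed = rseed)
        psi <- compute_psi(counts, min_reads = min_reads)
      }
      psi[, replicate := rep_i]
      psi_list[[rep_i]] <- psi
    }
    bc_psi <- data.table::rbindlist(psi_list, fill = TRUE)
    bc_psi_all[[cl]] <- bc_psi
    results[[cl]] <- sdv_call_table(bc_psi, pool, regime = fdr_regime)
  }
  names(results) <- paste0("cell_line_", seq_len(n_cell_lines))
  names(bc_psi_all) <- names(results)
  list(truth = truth, manifest = pool, bc_psi = bc_psi_all,
       results = results)
}

#' Compare pipeline SDV calls with simulation truth
#'
#' @param result per-variant table from [sdv_call_table()].
#' @param truth truth table from [sim_variants()].
#' @return list with `r_delta_psi` (Pearson correlation of estimated vs true
#'   delta-PSI over evaluable variants), `sensitivity` (fraction of true SDV
#'   called), `fdp` (false discovery proportion among calls), and counts.
#' @export
evaluate_against_truth <- function(result, truth) {
  m <- merge(as_dt(result), as_dt(truth), by = "variant_id")
  ev <- m[evaluable == TRUE]
  r <- if (nrow(ev) >= 3L && stats::sd(ev$true_delta_psi) > 0 &&
           stats::sd(ev$delta_psi) > 0) {
    stats::cor(ev$delta_psi, ev$true_delta_psi)
  } else NA_real_
  called <- ev$sdv_class != "NEUTRAL"
  tp <- sum(called & ev$is_sdv)
  fp <- sum(called & !ev$is_sdv)
  fn <- sum(!called & ev$is_sdv)
  list(r_delta_psi = r,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fdp = if (tp + fp > 0) fp / (tp + fp) else 0,
       n_evaluable = nrow(ev), tp = tp, fp = fp, fn = fn)
}
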