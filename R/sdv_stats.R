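#' Two-tailed Welch t-test of per-barcode PSI between alleles
#'
#' Compares the per-barcode PSI samples of the REF and ALT alleles (pooled
#' over transfection replicates, barcodes being the replication unit) with
#' an unequal-variance two-tailed t-test. Degenerate inputs are handled
#' explicitly: two zero-variance samples with equal means give p = 1, with
#' unequal means the smallest representable double (flagged via attribute).
#'
#' @param psi_ref,psi_alt numeric vectors of per-barcode PSI values.
#' @return p-value (numeric scalar).
#' @export
test_delta_psi <- function(psi_ref, psi_alt) {
  if (length(psi_ref) < 2L || length(psi_alt) < 2L) {
    stop("insufficient n: need at least 2 observations per allele")
  }
  v1 <- stats::var(psi_ref)
  v2 <- stats::var(psi_alt)
  if (v1 == 0 && v2 == 0) {
    if (mean(psi_ref) == mean(psi_alt)) return(1)
    p <- .Machine$double.xmin
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  stats::t.test(psi_alt, psi_ref, var.equal = FALSE)$p.value
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment over the jointly tested variants
#' of one cell line.
#'
#' @param p numeric vector of p-values (NAs propagate).
#' @return numeric vector of q-values, same order as `p`.
#' @export
adjust_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Classify a variant as splicing LOSS / GAIN / NEUTRAL
#'
#' A variant is an SDV when |delta-PSI| reaches 5 percentage points and its
#' FDR is below the chosen regime (0.05 or 0.01); the sign of delta-PSI
#' separates LOSS (exon inclusion decreased by ALT) from GAIN.
#'
#' @param delta_psi numeric vector (percent, ALT - REF).
#' @param fdr numeric vector of q-values.
#' @param regime FDR regime, 0.05 or 0.01 (default 0.01).
#' @param delta_threshold magnitude threshold in percent (default 5).
#' @return character vector: "LOSS", "GAIN" or "NEUTRAL" (NA inputs give NA).
#' @export
call_sdv <- function(delta_psi, fdr, regime = 0.01, delta_threshold = 5) {
  out <- rep(NA_character_, length(delta_psi))
  ok <- !is.na(delta_psi) & !is.na(fdr)
  out[ok] <- "NEUTRAL"
  out[ok & delta_psi <= -delta_threshold & fdr < regime] <- "LOSS"
  out[ok & delta_psi >= delta_threshold & fdr < regime] <- "GAIN"
  out
}

#' Percentage of abnormal transcripts associated with the ALT allele
#'
#' `100 - (PSI(ALT) / PSI(REF)) * 100`; negative values (ALT > REF) are
#' reported as-is. Undefined (NA) when PSI(REF) is 0.
#'
#' @param psi_ref,psi_alt PSI percentages.
#' @return numeric vector (NA where PSI(REF) = 0).
#' @export
abnormal_transcript_pct <- function(psi_ref, psi_alt) {
  out <- 100 - (psi_alt / psi_ref) * 100
  out[psi_ref == 0] <- NA_real_
  out
}

#' Sensitivity, specificity and effect-size correlation against a benchmark
#'
#' @param called logical vector: variant called positive by the assay.
#' @param truth logical vector: benchmark label.
#' @param effect_called,effect_truth optional paired continuous effect
#'   measures for the Pearson correlation.
#' @return list with `sensitivity`, `specificity` (percent, NA when the
#'   truth lacks the class) and `pearson_r` (NA when effects not supplied).
#' @export
benchmark_metrics <- function(called, truth, effect_called = NULL,
                              effect_truth = NULL) {
  stopifnot(length(called) == length(truth))
  tp <- sum(called & truth)
  fn <- sum(!called & truth)
  tn <- sum(!called & !truth)
  fp <- sum(called & !truth)
  sens <- if (tp + fn == 0L) NA_real_ else 100 * tp / (tp + fn)
  spec <- if (tn + fp == 0L) NA_real_ else 100 * tn / (tn + fp)
  r <- NA_real_
  if (!is.null(effect_called) && !is.null(effect_truth)) {
    r <- stats::cor(effect_called, effect_truth,
                    use = "pairwise.complete.obs")
  }
  list(sensitivity = sens, specificity = spec, pearson_r = r,
       tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Concordance of PSI / delta-PSI and SDV calls between two cell lines
#'
#' @param a,b variant-level result tables with columns `variant_id, psi_ref,
#'   psi_alt, delta_psi` and optionally `sdv_class`.
#' @return list with Pearson `r_psi` (REF-allele PSI), `r_delta_psi`,
#'   `n_shared`, and SDV overlap counts (`both`, `only_a`, `only_b`) when
#'   classes are present. Correlations are NA (flagged) below 3 shared
#'   variants.
#' @export
cross_cell_line_concordance <- function(a, b) {
  a <- as_dt(a); b <- as_dt(b)
  m <- merge(a, b, by = "variant_id", suffixes = c("_a", "_b"))
  m <- m[!is.na(delta_psi_a) & !is.na(delta_psi_b)]
  n <- nrow(m)
  if (n < 3L) {
    return(list(r_psi = NA_real_, r_delta_psi = NA_real_, n_shared = n,
                flagged = TRUE))
  }
  psi_a <- c(m$psi_ref_a, m$psi_alt_a)
  psi_b <- c(m$psi_ref_b, m$psi_alt_b)
  out <- list(r_psi = stats::cor(psi_a, psi_b),
              r_delta_psi = stats::cor(m$delta_psi_a, m$delta_psi_b),
              n_shared = n, flagged = FALSE)
  if (all(c("sdv_class_a", "sdv_class_b") %in% names(m))) {
    sa <- m$sdv_class_a != "NEUTRAL"
    sb <- m$sdv_class_b != "NEUTRAL"
    out$sdv_overlap <- c(both = sum(sa & sb), only_a = sum(sa & !sb),
                         only_b = sum(!sa & sb))
  }
  out
}

#' Variant-level SDV calling from per-barcode PSI values
#'
#' Convenience wrapper running [aggregate_variant()], the per-variant Welch
#' t-test, joint BH adjustment over all evaluable variants, and
#' [call_sdv()].
#'
#' @param bc_psi per-barcode PSI table (`barcode, psi, replicate`).
#' @param manifest pool manifest.
#' @param regime FDR regime (default 0.01).
#' @param delta_threshold delta-PSI magnitude threshold (default 5).
#' @param min_bc minimum barcodes per allele per replicate (default 2).
#' @return data.table, one row per variant, with `psi_ref, psi_alt,
#'   delta_psi, p_value, fdr, sdv_class` (non-evaluable variants keep NA
#'   statistics and their exclusion reason).
#' @export
sdv_call_table <- function(bc_psi, manifest, regime = 0.01,
                           delta_threshold = 5, min_bc = 2L) {
  bc_psi <- as_dt(bc_psi)
  manifest <- as_dt(manifest)
  agg <- aggregate_variant(bc_psi, manifest, min_bc = min_bc)
  x <- manifest[, .(barcode, variant_id, allele)][bc_psi, on = "barcode",
                                                  nomatch = NULL]
  pv <- x[, {
    pr <- psi[allele == "REF"]
    pa <- psi[allele == "ALT"]
    p <- if (length(pr) >= 2L && length(pa) >= 2L) {
      as.numeric(test_delta_psi(pr, pa))
    } else NA_real_
    .(p_value = p)
  }, by = variant_id]
  res <- pv[agg, on = "variant_id"]
  res[!(evaluable), p_value := NA_real_]
  res[, fdr := NA_real_]
  res[(evaluable), fdr := adjust_fdr(p_value)]
  res[, sdv_class := call_sdv(delta_psi, fdr, regime = regime,
                              delta_threshold = delta_threshold)]
  data.table::setorder(res, variant_id)
  res[]
}
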