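#' Somatic cell score transform
#'
#' `SCS = 3 + log2(SCC / 100,000)`, the log transform applied to somatic
#' cell counts (cells per mL) before GWAS.
#'
#' @param scc somatic cell count(s), must be > 0.
#' @return numeric vector of scores.
#' @export
scs_transform <- function(scc) {
  if (any(scc <= 0)) stop("domain error: SCC must be positive")
  3 + log2(scc / 1e5)
}

#' Genome-wide Bonferroni threshold on the -log10 scale
#'
#' @param alpha family-wise error rate (0 < alpha < 1, default 0.05).
#' @param n_tests number of independent tests (default 50,000).
#' @return `-log10(alpha / n_tests)`.
#' @export
bonferroni_neglog_threshold <- function(alpha = 0.05, n_tests = 50000L) {
  if (alpha <= 0 || alpha >= 1) stop("domain error: alpha must be in (0,1)")
  if (n_tests < 1) stop("domain error: n_tests must be >= 1")
  -log10(alpha / n_tests)
}

#' Filter GWAS summary statistics to candidate variants
#'
#' Applies, as a conjunction: MAF > `maf_min`; -log10 p > `neglogp_min`.
#' When `for_assay = TRUE`, additionally requires a well-formed rsID,
#' imputation r-squared > `r2_min`, and (if an eligible-region table is
#' supplied) position inside one of the regions. Output order is
#' deterministic (chrom, pos).
#'
#' @param summary_stats table with columns `chrom, pos, maf, neg_log10_p`
#'   and, for the assay-bound set, `rsid` and `imputation_r2`.
#' @param maf_min MAF threshold (default 0.005).
#' @param neglogp_min significance threshold (default 6).
#' @param for_assay apply the extra reporter-assay filters (default FALSE).
#' @param r2_min imputation accuracy threshold for the assay-bound set
#'   (default 0.4).
#' @param regions optional table `chrom, start, end` of eligible regions
#'   (BED-like, 1-based inclusive).
#' @return filtered data.table, sorted by chrom then pos.
#' @export
select_candidates <- function(summary_stats, maf_min = 0.005,
                              neglogp_min = 6, for_assay = FALSE,
                              r2_min = 0.4, regions = NULL) {
  s <- as_dt(summary_stats)
  need <- c("chrom", "pos", "maf", "neg_log10_p")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop("schema error: missing columns: ",
                         paste(miss, collapse = ", "))
  out <- s[maf > maf_min & neg_log10_p > neglogp_min]
  if (for_assay) {
    if (!all(c("rsid", "imputation_r2") %in% names(out))) {
      stop("schema error: assay-bound selection needs rsid and imputation_r2")
    }
    out <- out[!is.na(normalize_rsid(rsid)) & imputation_r2 > r2_min]
    if (!is.null(regions)) {
      reg <- as_dt(regions)
      out <- out[reg, on = .(chrom, pos >= start, pos <= end),
                 nomatch = NULL,
                 .(chrom, pos = x.pos, maf, neg_log10_p, rsid, imputation_r2)]
      out <- unique(out)
    }
  }
  data.table::setorder(out, chrom, pos)
  out[]
}

#' Define QTL confidence intervals from candidate variants
#'
#' Greedy peak extraction per chromosome (within a trait x breed set): the
#' lead is the remaining candidate with the largest -log10 p above
#' `neglogp_min`; peak members are candidates within +/-`window` of the lead
#' whose significance reaches the upper third of the peak; the confidence
#' interval spans the member positions. Members are removed and the search
#' repeats; an interval overlapping an earlier one is merged into it.
#'
#' @param candidates table `chrom, pos, neg_log10_p` (e.g. from
#'   [select_candidates()]).
#' @param neglogp_min significance floor for leads (default 6).
#' @param window half-window around the lead in bp (default 2e6).
#' @param peak_rule `"fraction_of_lead"` (default; member -log10 p at least
#'   2/3 of the lead's) or `"upper_third_of_range"` (member -log10 p in the
#'   top third of the [floor, lead] range).
#' @param sdv_positions optional table `chrom, pos` of validated SDV, used
#'   to set `contains_sdv`.
#' @return data.table of QTL: `qtl_id, chrom, lead_pos, lead_neg_log10_p,
#'   ci_start, ci_end, n_members, contains_sdv`.
#' @export
define_qtl <- function(candidates, neglogp_min = 6, window = 2e6,
                       peak_rule = c("fraction_of_lead",
                                     "upper_third_of_range"),
                       sdv_positions = NULL) {
  peak_rule <- match.arg(peak_rule)
  cand <- as_dt(candidates)
  if (nrow(cand) == 0L) {
    return(data.table::data.table(qtl_id = integer(0), chrom = character(0),
                                  lead_pos = integer(0),
                                  lead_neg_log10_p = numeric(0),
                                  ci_start = integer(0), ci_end = integer(0),
                                  n_members = integer(0),
                                  contains_sdv = logical(0)))
  }
  out <- list()
  for (ch in unique(cand$chrom)) {
    rem <- cand[chrom == ch][order(pos)]
    intervals <- list()
    while (nrow(rem) && max(rem$neg_log10_p) > neglogp_min) {
      lead_i <- which.max(rem$neg_log10_p)
      lead_pos <- rem$pos[lead_i]
      lead_nlp <- rem$neg_log10_p[lead_i]
      cutoff <- if (peak_rule == "fraction_of_lead") {
        (2 / 3) * lead_nlp
      } else {
        neglogp_min + (2 / 3) * (lead_nlp - neglogp_min)
      }
      mem <- abs(rem$pos - lead_pos) <= window & rem$neg_log10_p >= cutoff
      ci <- range(rem$pos[mem])
      merged <- FALSE
      for (j in seq_along(intervals)) {
        iv <- intervals[[j]]
        if (ci[1] <= iv$ci_end && ci[2] >= iv$ci_start) {
          iv$ci_start <- min(iv$ci_start, ci[1])
          iv$ci_end <- max(iv$ci_end, ci[2])
          iv$n_members <- iv$n_members + sum(mem)
          intervals[[j]] <- iv
          merged <- TRUE
          break
        }
      }
      if (!merged) {
        intervals[[length(intervals) + 1L]] <- list(
          chrom = ch, lead_pos = lead_pos, lead_neg_log10_p = lead_nlp,
          ci_start = ci[1], ci_end = ci[2], n_members = sum(mem))
      }
      rem <- rem[!mem]
    }
    out <- c(out, intervals)
  }
  if (!length(out)) {
    return(define_qtl(cand[0]))
  }
  res <- data.table::rbindlist(lapply(out, data.table::as.data.table))
  data.table::setorder(res, chrom, ci_start)
  res[, qtl_id := seq_len(.N)]
  res[, contains_sdv := FALSE]
  if (!is.null(sdv_positions)) {
    sp <- as_dt(sdv_positions)
    for (i in seq_len(nrow(res))) {
      res$contains_sdv[i] <- any(sp$chrom == res$chrom[i] &
                                   sp$pos >= res$ci_start[i] &
                                   sp$pos <= res$ci_end[i])
    }
  }
  data.table::setcolorder(res, c("qtl_id", "chrom", "lead_pos",
                                 "lead_neg_log10_p", "ci_start", "ci_end",
                                 "n_members", "contains_sdv"))
  res[]
}

#' Extrapolate the genome-wide share of SDV-containing QTL
#'
#' Scales the observed percentage of QTL containing at least one validated
#' SDV by the fraction of exonic regions the assay can interrogate and by
#' the fraction of eligible variants that survived QC:
#' `observed * (100 / coverage) * (n_selected / n_analyzed)`. Results above
#' 100 are capped and flagged.
#'
#' @param observed_pct_qtl_plus observed percent of QTL with an SDV.
#' @param region_coverage_pct percent of exonic regions assayable.
#' @param n_selected variants selected for the assay.
#' @param n_analyzed variants surviving assay QC.
#' @return list with `pct` (possibly capped) and `capped` flag.
#' @export
qtl_sdv_extrapolation <- function(observed_pct_qtl_plus, region_coverage_pct,
                                  n_selected, n_analyzed) {
  if (region_coverage_pct <= 0 || n_analyzed <= 0 || n_selected <= 0 ||
      observed_pct_qtl_plus < 0) {
    stop("domain error: inputs must be positive")
  }
  pct <- observed_pct_qtl_plus * (100 / region_coverage_pct) *
    (n_selected / n_analyzed)
  capped <- pct > 100
  list(pct = min(pct, 100), capped = capped)
}
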