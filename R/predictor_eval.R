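#' Harmonise raw splice-predictor scores
#'
#' Four-class tools (acceptor/donor gain/loss, each in [0, 1]) are reduced
#' to a single per-variant score: the maximum of the four class scores, with
#' a negative sign when the maximum is a loss class (loss wins ties, the
#' conservative reading for spliceogenicity direction). Signed-score tools
#' (one score in [-1, 1]) pass through. `harmonized_abs` is always the
#' absolute value of `harmonized_signed`.
#'
#' @param scores data.table with `variant_id, tool` and either the four
#'   class columns (`acceptor_gain, acceptor_loss, donor_gain, donor_loss`)
#'   or `signed_score` (rows may carry either; class columns take
#'   precedence when any is non-NA and non-zero... rows with all four class
#'   scores present use the 4-class rule, otherwise `signed_score`).
#' @return input with `harmonized_signed` and `harmonized_abs` appended.
#' @export
harmonize_scores <- function(scores) {
  s <- data.table::copy(as_dt(scores))
  cls <- c("acceptor_gain", "acceptor_loss", "donor_gain", "donor_loss")
  for (cc in cls) if (!cc %in% names(s)) s[, (cc) := NA_real_]
  if (!"signed_score" %in% names(s)) s[, signed_score := NA_real_]

  has4 <- stats::complete.cases(s[, cls, with = FALSE])
  m4 <- as.matrix(s[, cls, with = FALSE])
  if (any(m4[has4, ] < 0 | m4[has4, ] > 1)) {
    bad <- s$variant_id[has4][rowSums(m4[has4, , drop = FALSE] < 0 |
                                        m4[has4, , drop = FALSE] > 1) > 0]
    stop("validation error: class score outside [0,1] for: ",
         paste(utils::head(unique(bad), 5), collapse = ", "))
  }
  sg <- s$signed_score
  if (any(!is.na(sg) & abs(sg) > 1)) {
    stop("validation error: signed score outside [-1,1] for: ",
         paste(utils::head(s$variant_id[!is.na(sg) & abs(sg) > 1], 5),
               collapse = ", "))
  }
  hs <- rep(NA_real_, nrow(s))
  if (any(has4)) {
    sub <- m4[has4, , drop = FALSE]
    mx <- apply(sub, 1L, max)
    loss_mx <- pmax(sub[, "acceptor_loss"], sub[, "donor_loss"])
    hs[has4] <- ifelse(loss_mx >= mx & mx > 0, -mx, mx)
  }
  use_signed <- !has4 & !is.na(sg)
  hs[use_signed] <- sg[use_signed]
  if (anyNA(hs)) stop("variants without any usable score: ",
                      paste(utils::head(s$variant_id[is.na(hs)], 5),
                            collapse = ", "))
  s[, harmonized_signed := hs]
  s[, harmonized_abs := abs(hs)]
  s[]
}

#' Predicted-spliceogenic flag at a threshold regime
#'
#' @param harmonized_abs absolute harmonised scores.
#' @param regime threshold: 0.2 (high recall), 0.5 (recommended) or 0.8
#'   (high precision); any numeric accepted.
#' @return logical vector.
#' @export
score_predicted <- function(harmonized_abs, regime = 0.2) {
  harmonized_abs >= regime
}

#' Convert gene models into a predictor-ready annotation table
#'
#' Produces one row per gene with comma-joined exon coordinate lists in
#' ascending genomic order (GENCODE-like layout:
#' `#NAME CHROM STRAND TX_START TX_END EXON_STARTS EXON_ENDS`), using the
#' canonical transcript where tagged, otherwise the transcript with the
#' longest total exonic span. A second table restricted to canonical
#' transcripts is returned alongside, for tools that only consider those.
#'
#' @param gene_models GTF path or exon table (see [load_gene_models()]); an
#'   optional logical column `canonical` marks tagged transcripts.
#' @return list of data.tables `genes` and `canonical`, each with columns
#'   `name, chrom, strand, tx_start, tx_end, exon_starts, exon_ends`.
#' @export
convert_gtf_to_predictor_annotation <- function(gene_models) {
  ex <- load_gene_models(gene_models)
  src <- if (is.character(gene_models) && length(gene_models) == 1L &&
             file.exists(gene_models)) NULL else as_dt(gene_models)
  if (!is.null(src) && "canonical" %in% names(src)) {
    can <- unique(src[canonical == TRUE, .(transcript_id)])
    ex[, canonical := transcript_id %in% can$transcript_id]
  } else {
    ex[, canonical := FALSE]
  }
  ex <- ex[, .(gene_id, transcript_id, chrom, start, end, strand, canonical)]
  if (nrow(ex) == 0L) stop("no exons in gene models")

  tx <- ex[, .(span = sum(end - start + 1L), canonical = canonical[1]),
           by = .(gene_id, transcript_id)]
  pick <- tx[order(-canonical, -span),
             .(transcript_id = transcript_id[1],
               used_canonical_tag = canonical[1]), by = gene_id]
  row_for <- function(txids) {
    sub <- ex[transcript_id %in% txids]
    sub <- sub[order(chrom, start)]
    sub[, .(name = gene_id[1], chrom = chrom[1], strand = strand[1],
            tx_start = min(start), tx_end = max(end),
            exon_starts = paste(sort(start), collapse = ","),
            exon_ends = paste(sort(end), collapse = ",")),
        by = transcript_id][, transcript_id := NULL][]
  }
  genes <- data.table::rbindlist(lapply(pick$transcript_id, row_for))
  can_tx <- tx[canonical == TRUE, transcript_id]
  canonical <- if (length(can_tx)) {
    data.table::rbindlist(lapply(can_tx, row_for))
  } else genes
  list(genes = genes, canonical = canonical)
}

#' Write a predictor annotation table
#' @param annot a table from [convert_gtf_to_predictor_annotation()].
#' @param path output path (tab-separated with a `#NAME` header).
#' @export
write_predictor_annotation <- function(annot, path) {
  a <- as_dt(annot)
  hdr <- "#NAME\tCHROM\tSTRAND\tTX_START\tTX_END\tEXON_STARTS\tEXON_ENDS"
  body <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s", a$name, a$chrom, a$strand,
                  a$tx_start, a$tx_end, a$exon_starts, a$exon_ends)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' True-positive / true-negative rates by score bin
#'
#' Bins partition [0, 1]; within each bin the TP rate is the fraction of
#' variants that are label-positive, and the TN rate the fraction that are
#' label-negative (reported for bins below/above the prediction threshold
#' respectively, with counts alongside). Empty bins are flagged.
#'
#' @param harmonized_abs absolute scores.
#' @param positive logical Vex-seq labels (SDV = TRUE).
#' @param bins vector of bin edges partitioning [0, 1]
#'   (default c(0, .2, .5, .8, 1)).
#' @return data.table per bin: `bin, n, n_positive, tp_rate, tn_rate,
#'   empty`.
#' @export
tp_tn_by_bin <- function(harmonized_abs, positive,
                         bins = c(0, 0.2, 0.5, 0.8, 1)) {
  stopifnot(length(harmonized_abs) == length(positive))
  cut_ <- cut(harmonized_abs, breaks = bins, include.lowest = TRUE,
              right = FALSE)
  # top bin closed on the right
  cut_[harmonized_abs == bins[length(bins)]] <-
    levels(cut_)[length(levels(cut_))]
  dt <- data.table::data.table(bin = cut_, positive = positive)
  out <- dt[, .(n = .N, n_positive = sum(positive)), by = bin]
  out <- out[data.table::data.table(bin = factor(levels(cut_),
                                                 levels = levels(cut_))),
             on = "bin"]
  out[is.na(n), `:=`(n = 0L, n_positive = 0L)]
  out[, tp_rate := data.table::fifelse(n > 0L, n_positive / n, NA_real_)]
  out[, tn_rate := data.table::fifelse(n > 0L, 1 - n_positive / n, NA_real_)]
  out[, empty := n == 0L]
  out[]
}

#' ROC curve and AUC with tie-grouped steps
#'
#' Scores are ranked in descending order; tied scores form a single ROC
#' step. The AUC is computed by the trapezoid rule and equals the
#' Mann-Whitney pairwise-concordance statistic.
#'
#' @param score numeric scores (higher = more likely positive).
#' @param positive logical labels.
#' @return list with `roc` (data.table `threshold, fpr, tpr`) and `auc`.
#' @export
roc_auc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  np <- sum(positive)
  nn <- sum(!positive)
  if (np == 0L || nn == 0L) stop("ROC requires both classes in the labels")
  o <- order(score, decreasing = TRUE)
  s <- score[o]
  y <- positive[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  roc <- data.table::data.table(threshold = s[last],
                                fpr = fp[last] / nn, tpr = tp[last] / np)
  roc <- rbind(data.table::data.table(threshold = Inf, fpr = 0, tpr = 0), roc)
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

# independent O(P*N) concordance oracle used in the test-suite
auc_pairwise_oracle <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

#' Confusion metrics over a grid of sub-threshold score cutoffs
#'
#' For each threshold t: predicted = |score| >= t; reports TP/FP/TN/FN
#' counts, sensitivity, specificity and accuracy. The predicted-positive
#' count is non-increasing in t.
#'
#' @param harmonized_abs absolute scores.
#' @param positive logical labels.
#' @param thresholds numeric grid (default seq(0, 0.2, by = 0.01)).
#' @return data.table, one row per threshold.
#' @export
threshold_scan <- function(harmonized_abs, positive,
                           thresholds = seq(0, 0.2, by = 0.01)) {
  out <- lapply(thresholds, function(t) {
    pred <- harmonized_abs >= t
    tp <- sum(pred & positive); fp <- sum(pred & !positive)
    fn <- sum(!pred & positive); tn <- sum(!pred & !positive)
    data.table::data.table(
      threshold = t, tp = tp, fp = fp, tn = tn, fn = fn,
      n_predicted = tp + fp,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      accuracy = (tp + tn) / length(positive))
  })
  data.table::rbindlist(out)
}

#' Predicted-positive rates per annotation group
#'
#' For a set of scored variants grouped by e.g. consequence or phenotype
#' class: the number and percentage (1 decimal) predicted spliceogenic at a
#' threshold regime.
#'
#' @param harmonized_abs absolute scores.
#' @param group character vector of group labels.
#' @param regime score threshold (default 0.2, high recall).
#' @return data.table `group, n, n_predicted, pct_predicted`.
#' @export
positive_set_summary <- function(harmonized_abs, group, regime = 0.2) {
  dt <- data.table::data.table(score = harmonized_abs, group = group)
  out <- dt[, .(n = .N, n_predicted = sum(score >= regime)), by = group]
  out[, pct_predicted := round(100 * n_predicted / n, 1)]
  out[]
}

#' Call-rate percentage from counts
#'
#' Percentage (1 decimal) of positives among n, the arithmetic used for all
#' printed call-rate summaries.
#'
#' @param k positives, @param n total.
#' @export
call_rate_pct <- function(k, n) {
  round(100 * k / n, 1)
}

#' Select a score-balanced subset of candidates
#'
#' Stratifies the candidate pool over absolute-score bins and draws equal
#' (as far as feasible) numbers per bin; shortfalls in sparse bins are
#' redistributed to the remaining bins round-robin. Deterministic given the
#' seed.
#'
#' @param scores data.table with `variant_id` and `harmonized_abs`.
#' @param n_target subset size.
#' @param bins bin edges (default c(0, 0.02, 0.2, 0.5, 0.8, 1)).
#' @param seed integer seed.
#' @return data.table subset of `scores`, with the per-bin quota table in
#'   attribute `"quota"`.
#' @export
select_balanced_set <- function(scores, n_target,
                                bins = c(0, 0.02, 0.2, 0.5, 0.8, 1),
                                seed = 1L) {
  s <- as_dt(scores)
  if (n_target >= nrow(s)) return(s)
  set.seed(seed)
  b <- cut(s$harmonized_abs, breaks = bins, include.lowest = TRUE)
  avail <- as.integer(table(b))
  nb <- length(avail)
  quota <- integer(nb)
  remaining <- n_target
  open <- avail > 0L
  # water-filling: repeatedly split the remainder over bins that still have
  # capacity
  while (remaining > 0L && any(quota < avail)) {
    cap <- which(quota < avail)
    share <- remaining %/% length(cap)
    extra <- remaining %% length(cap)
    add <- pmin(avail[cap] - quota[cap],
                share + (seq_along(cap) <= extra))
    quota[cap] <- quota[cap] + add
    remaining <- remaining - sum(add)
  }
  idx <- unlist(lapply(seq_len(nb), function(i) {
    pool <- which(as.integer(b) == i)
    if (quota[i] == 0L) return(integer(0))
    sort(sample(pool, quota[i]))
  }))
  out <- s[idx]
  data.table::setattr(out, "quota",
                      data.table::data.table(bin = levels(b), available = avail,
                                             selected = quota))
  out
}
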