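CODON_STOPS <- c("TAA", "TAG", "TGA")

# first stop codon at or after `from` (1-based), scanning in frame; NA if none
first_stop <- function(mrna, from) {
  len <- nchar(mrna)
  pos <- from
  while (pos + 2L <= len) {
    if (substr(mrna, pos, pos + 2L) %in% CODON_STOPS) return(pos)
    pos <- pos + 3L
  }
  NA_integer_
}

#' Transcript consequence of skipping one internal exon
#'
#' Builds the exon-skipped mRNA and classifies the consequence on the
#' primary transcript/protein structure:
#' * `DEL_ATG` - the skipped exon carries (part of) the translation start;
#' * `UTR3_DEL` - the exon lies entirely 3' of the stop codon;
#' * `PTC` - translating the skipped form from the original start meets a
#'   stop codon at a position other than the original terminus (the
#'   skipped-form exon containing it is recorded; a PTC in the last exon is
#'   not predicted to trigger NMD);
#' * `IFD` - translation reaches the original stop in frame (in-frame
#'   deletion).
#' A frameshifted skip whose first stop falls beyond the original terminus
#' is reported as PTC in the exon containing that stop (typically the last
#' exon); a frameshift with no stop at all is flagged `no_stop`.
#'
#' @param exons data.table with `exon_rank` and `exon_seq` (transcript
#'   order).
#' @param cds_start,cds_end CDS span in spliced-mRNA coordinates, 1-based
#'   inclusive, stop codon included.
#' @param skipped_rank rank of the internal exon removed.
#' @param nmd_rule `"last_exon"` (default: a PTC anywhere before the last
#'   exon of the skipped form triggers NMD) or `"junction_50nt"` (canonical
#'   rule: PTC more than 50 nt upstream of the final exon-exon junction).
#' @return list with `consequence`, `ptc_exon` (skipped-form rank or NA),
#'   `nmd_predicted`, `frame_preserved`, and `flag` (e.g. "no_stop").
#' @export
splice_consequence <- function(exons, cds_start, cds_end, skipped_rank,
                               nmd_rule = c("last_exon", "junction_50nt")) {
  nmd_rule <- match.arg(nmd_rule)
  exons <- as_dt(exons)
  data.table::setorder(exons, exon_rank)
  n_ex <- nrow(exons)
  if (skipped_rank <= 1L || skipped_rank >= n_ex) {
    stop("skipped exon must be internal")
  }
  mrna <- paste(exons$exon_seq, collapse = "")
  cds_len <- cds_end - cds_start + 1L
  if (cds_len %% 3L != 0L) stop("model error: CDS length not divisible by 3")
  if (!substr(mrna, cds_end - 2L, cds_end) %in% CODON_STOPS) {
    stop("model error: CDS does not end with a stop codon")
  }
  ref_stop <- first_stop(mrna, cds_start)
  if (is.na(ref_stop) || ref_stop != cds_end - 2L) {
    stop("model error: internal stop codon in the reference CDS")
  }

  lens <- nchar(exons$exon_seq)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  s <- starts[skipped_rank]
  e <- ends[skipped_rank]

  res <- list(consequence = NA_character_, ptc_exon = NA_integer_,
              nmd_predicted = FALSE, frame_preserved = NA, flag = "")

  if (s <= cds_start + 2L && e >= cds_start) {
    res$consequence <- "DEL_ATG"
    return(res)
  }
  if (s > cds_end) {
    res$consequence <- "UTR3_DEL"
    return(res)
  }
  if (e < cds_start) {
    res$consequence <- "UTR5_DEL"  # outside the four printed classes
    return(res)
  }

  # coding portion removed (the exon may extend past the stop codon)
  coding_removed <- min(e, cds_end) - max(s, cds_start) + 1L
  res$frame_preserved <- coding_removed %% 3L == 0L

  keep <- setdiff(seq_len(n_ex), skipped_rank)
  skipped_mrna <- paste(exons$exon_seq[keep], collapse = "")
  new_lens <- lens[keep]
  new_ends <- cumsum(new_lens)

  stop_pos <- first_stop(skipped_mrna, cds_start)  # exon is 3' of the start
  orig_stop_equiv <- if (e <= cds_end) cds_end - 2L - (e - s + 1L) else NA_integer_

  if (is.na(stop_pos)) {
    res$flag <- "no_stop"
    return(res)
  }
  if (!is.na(orig_stop_equiv) && stop_pos == orig_stop_equiv) {
    res$consequence <- "IFD"
    return(res)
  }
  res$consequence <- "PTC"
  res$ptc_exon <- findInterval(stop_pos - 1L, new_ends) + 1L
  last_rank <- length(keep)
  if (nmd_rule == "last_exon") {
    res$nmd_predicted <- res$ptc_exon < last_rank
  } else {
    last_junction <- if (last_rank >= 2L) new_ends[last_rank - 1L] else 0L
    res$nmd_predicted <- (last_junction - (stop_pos + 2L)) > 50L
  }
  res
}

#' LoF / GoF labels for the two alleles of an SDV
#'
#' Applies only when skipping the test exon is predicted deleterious (a
#' PTC triggering NMD, or loss of the initiation codon): the allele that
#' decreases exon inclusion is loss-of-function, the other allele
#' gain-of-function. PTC in the last exon, in-frame deletions and 3'UTR
#' deletions are non-predictable (UNKNOWN).
#'
#' @param consequence consequence string from [splice_consequence()].
#' @param nmd_predicted logical from [splice_consequence()].
#' @param delta_psi significant delta-PSI (ALT - REF, percent).
#' @return list with `ref` and `alt` labels ("LOF", "GOF" or "UNKNOWN").
#' @export
allele_functional_class <- function(consequence, nmd_predicted, delta_psi) {
  deleterious <- (consequence == "PTC" && isTRUE(nmd_predicted)) ||
    consequence == "DEL_ATG"
  if (!deleterious || is.na(delta_psi) || delta_psi == 0) {
    return(list(ref = "UNKNOWN", alt = "UNKNOWN"))
  }
  if (delta_psi < 0) list(ref = "GOF", alt = "LOF")
  else list(ref = "LOF", alt = "GOF")
}

#' Enrichment of conserved variants in splicing-effect categories
#'
#' For LOSS vs NEUTRAL and GAIN vs NEUTRAL: builds the 2x2 table
#' (conservation-positive yes/no x category), reports the fold change of
#' the positive percentage relative to NEUTRAL and the two-tailed Fisher
#' exact p-value.
#'
#' @param category character vector: "LOSS", "GAIN" or "NEUTRAL".
#' @param conserved logical vector (e.g. GERP score > 0).
#' @return data.table per comparison: `category, n, n_conserved,
#'   pct_conserved, fold_change, p_value, flagged`.
#' @export
gerp_enrichment <- function(category, conserved) {
  stopifnot(length(category) == length(conserved))
  dt <- data.table::data.table(category = category, conserved = conserved)
  neu <- dt[category == "NEUTRAL"]
  out <- lapply(c("LOSS", "GAIN"), function(cat) {
    sub <- dt[category == cat]
    if (nrow(sub) == 0L || nrow(neu) == 0L) {
      return(data.table::data.table(category = cat, n = nrow(sub),
                                    n_conserved = sum(sub$conserved),
                                    pct_conserved = NA_real_,
                                    fold_change = NA_real_,
                                    p_value = NA_real_, flagged = TRUE))
    }
    p_cat <- mean(sub$conserved)
    p_neu <- mean(neu$conserved)
    tab <- matrix(c(sum(sub$conserved), sum(!sub$conserved),
                    sum(neu$conserved), sum(!neu$conserved)), nrow = 2)
    fc <- if (p_neu == 0) NA_real_ else p_cat / p_neu
    data.table::data.table(category = cat, n = nrow(sub),
                           n_conserved = sum(sub$conserved),
                           pct_conserved = 100 * p_cat,
                           fold_change = fc,
                           p_value = stats::fisher.test(tab)$p.value,
                           flagged = p_neu == 0)
  })
  data.table::rbindlist(out)
}

#' Colocalise SDV with published e/sQTL SNP lists by rsID
#'
#' @param sdv_rsids character vector of SDV rsIDs.
#' @param qtl_tables named list of character vectors of rsIDs, one per
#'   source (e.g. `single_eqtl, single_sqtl, multi_eqtl, multi_sqtl`).
#' @return list with `flags` (data.table: rsid + one logical column per
#'   source + `any_hit`) and `summary` (`n`, `n_hit`, `pct_hit`); malformed
#'   rsIDs are skipped and counted in `summary$n_skipped`.
#' @export
colocalize_qtl <- function(sdv_rsids, qtl_tables) {
  ids <- normalize_rsid(sdv_rsids)
  skipped <- sum(is.na(ids))
  ids <- ids[!is.na(ids)]
  flags <- data.table::data.table(rsid = ids)
  for (src in names(qtl_tables)) {
    ref <- normalize_rsid(qtl_tables[[src]])
    flags[, (src) := rsid %in% ref[!is.na(ref)]]
  }
  hit_cols <- names(qtl_tables)
  flags[, any_hit := rowSums(as.matrix(.SD)) > 0, .SDcols = hit_cols]
  list(flags = flags[],
       summary = list(n = nrow(flags), n_hit = sum(flags$any_hit),
                      pct_hit = call_rate_pct(sum(flags$any_hit),
                                              nrow(flags)),
                      n_skipped = skipped))
}
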