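# Reporter read geometry (mirrors the sequencing layout of the assay):
# read 1 (75 nt) starts at the 5' end of the reporter cDNA and spans the
# exon1 / (test exon or exon3) junction; read 2 (225 nt) starts with the
# 10-nt UMI, then reads the reverse strand from the 3' end of the cDNA,
# i.e. reverse complement of (... junction ... exon3 | barcode).
R1_LENGTH <- 75L
R2_LENGTH <- 225L

#' Reference transcript forms for a test exon
#'
#' @param exon_seq test-exon sequence(s), transcript orientation.
#' @return list with `included` (exon1 + test exon + exon3) and `excluded`
#'   (exon1 + exon3) mature transcript sequences.
#' @export
reference_forms <- function(exon_seq) {
  list(included = paste0(REPORTER_EXON1, exon_seq, REPORTER_EXON3),
       excluded = paste0(REPORTER_EXON1, REPORTER_EXON3))
}

# Junction windows of k bases each side, per test exon. The exon1|exon3
# window of the excluded form is identical from both reads.
junction_windows <- function(exon_seq, k) {
  e1 <- nchar(REPORTER_EXON1)
  list(
    inc1 = paste0(substr(REPORTER_EXON1, e1 - k + 1L, e1),
                  substr(exon_seq, 1L, k)),
    inc2 = paste0(substr(exon_seq, nchar(exon_seq) - k + 1L, nchar(exon_seq)),
                  substr(REPORTER_EXON3, 1L, k)),
    exc = paste0(substr(REPORTER_EXON1, e1 - k + 1L, e1),
                 substr(REPORTER_EXON3, 1L, k))
  )
}

#' Classify reporter read pairs as inclusion / exclusion / ambiguous
#'
#' A read pair supports INCLUSION if read 1 matches the exon1|test-exon
#' junction or read 2 matches the test-exon|exon3 junction of the included
#' form (k matched bases on each side of the junction); it supports
#' EXCLUSION if either read matches the exon1|exon3 junction. Conflicting or
#' absent evidence yields AMBIGUOUS.
#'
#' @param r1 read-1 sequences (sense strand of the cDNA 5' end).
#' @param mrna_tail sense-strand tails of the transcript recovered from
#'   read 2 (barcode and UMI already stripped; see [parse_reporter_reads()]).
#' @param exon_seq test-exon sequence for each read pair (vector recycled
#'   against reads).
#' @param k matched bases required on each side of a junction (default 8).
#' @return character vector: "INCLUSION", "EXCLUSION" or "AMBIGUOUS".
#' @export
classify_reads <- function(r1, mrna_tail, exon_seq, k = 8L) {
  e1 <- nchar(REPORTER_EXON1)
  e3 <- nchar(REPORTER_EXON3)
  stopifnot(k >= 1L, e1 + k <= R1_LENGTH)
  n <- length(r1)
  exon_seq <- rep_len(exon_seq, n)
  out <- rep("AMBIGUOUS", n)
  dt <- data.table::data.table(idx = seq_len(n), r1 = r1, tail = mrna_tail,
                               exon = exon_seq)
  dt[, tlen := nchar(tail)]
  r1w <- substr(dt$r1, e1 - k + 1L, e1 + k)
  r2w <- substr(dt$tail, dt$tlen - e3 - k + 1L, dt$tlen - e3 + k)
  win <- dt[, junction_windows(exon[1L], k), by = exon]
  dt <- win[dt, on = "exon"]
  inc <- (r1w[dt$idx] == dt$inc1) | (r2w[dt$idx] == dt$inc2)
  exc <- (r1w[dt$idx] == dt$exc) | (r2w[dt$idx] == dt$exc)
  cls <- rep("AMBIGUOUS", n)
  cls[inc & !exc] <- "INCLUSION"
  cls[exc & !inc] <- "EXCLUSION"
  out[dt$idx] <- cls
  out
}

#' Classify a single read pair
#'
#' Convenience scalar wrapper around [classify_reads()] taking raw read-2
#' sequence (UMI + reverse strand).
#'
#' @inheritParams classify_reads
#' @param r2 raw read-2 sequence.
#' @param barcode_length barcode length used in the pool.
#' @export
classify_read <- function(r1, r2, exon_seq, k = 8L, barcode_length = 12L) {
  parsed <- parse_reporter_reads(r1, r2, barcode_length = barcode_length)
  classify_reads(parsed$r1, parsed$mrna_tail, exon_seq, k = k)
}

#' Parse raw reporter read pairs into UMI, barcode and transcript tail
#'
#' Read 2 is UMI (10 nt) followed by the reverse complement of the 3' end of
#' the cDNA, which itself ends with the construct barcode.
#'
#' @param r1,r2 character vectors of read sequences.
#' @param barcode_length barcode length (default 12).
#' @return data.table with columns `r1, umi, barcode, mrna_tail`.
#' @export
parse_reporter_reads <- function(r1, r2, barcode_length = 12L) {
  umi <- substr(r2, 1L, UMI_LENGTH)
  sense <- revcomp(substr(r2, UMI_LENGTH + 1L, nchar(r2)))
  bc <- substr(sense, nchar(sense) - barcode_length + 1L, nchar(sense))
  tail <- substr(sense, 1L, nchar(sense) - barcode_length)
  data.table::data.table(r1 = r1, umi = umi, barcode = bc, mrna_tail = tail)
}

# Barcode assignment with unique 1-mismatch rescue, via a precomputed map of
# all single-substitution mutants of the whitelist. Mutants reachable from
# two whitelist barcodes are ambiguous and left unassigned.
build_barcode_map <- function(whitelist) {
  len <- nchar(whitelist[1])
  stopifnot(all(nchar(whitelist) == len))
  keys <- whitelist
  vals <- whitelist
  for (i in seq_len(len)) {
    for (b in DNA_BASES) {
      mut <- whitelist
      substr(mut, i, i) <- b
      keep <- mut != whitelist
      keys <- c(keys, mut[keep])
      vals <- c(vals, whitelist[keep])
    }
  }
  dup <- keys[duplicated(keys)]
  amb <- unique(dup[!dup %in% whitelist])
  keep <- !keys %in% amb
  stats::setNames(vals[keep], keys[keep])
}

assign_barcodes <- function(observed, barcode_map) {
  out <- barcode_map[observed]
  unname(out)
}

#' Collapse reads to molecules by UMI within barcode
#'
#' Records sharing a barcode and an identical UMI collapse to one molecule;
#' the molecule's junction class is the majority class of its reads, with
#' ties (and all-ambiguous groups) resolved to AMBIGUOUS. Records with a
#' malformed UMI (length != 10 or non-ACGT) are dropped and counted.
#'
#' @param obs data.table with columns `barcode, umi, junction_class`.
#' @return data.table of molecules (`barcode, umi, junction_class`) with the
#'   number of dropped malformed records in attribute `"n_malformed_umi"`.
#' @export
dedupe_umis <- function(obs) {
  obs <- as_dt(obs)
  ok <- nchar(obs$umi) == UMI_LENGTH & !grepl("[^ACGT]", obs$umi)
  dropped <- sum(!ok)
  obs <- obs[ok]
  mol <- obs[, {
    ni <- sum(junction_class == "INCLUSION")
    ne <- sum(junction_class == "EXCLUSION")
    cls <- if (ni > ne) "INCLUSION" else if (ne > ni) "EXCLUSION" else "AMBIGUOUS"
    .(junction_class = cls)
  }, by = .(barcode, umi)]
  data.table::setattr(mol, "n_malformed_umi", dropped)
  mol[]
}

#' Per-barcode PSI from deduplicated molecule counts
#'
#' PSI = 100 * inclusion / (inclusion + exclusion); AMBIGUOUS molecules are
#' excluded from the denominator. Barcodes with fewer than `min_reads`
#' informative molecules are dropped (never reported as PSI 0).
#'
#' @param molecules data.table from [dedupe_umis()], or a pre-tallied table
#'   with columns `barcode, inclusion, exclusion` (and optionally
#'   `ambiguous`).
#' @param min_reads minimum informative molecules per barcode (default 10).
#' @return data.table `barcode, inclusion, exclusion, ambiguous, psi` for
#'   surviving barcodes; dropped barcodes in attribute `"dropped"`.
#' @export
compute_psi <- function(molecules, min_reads = 10L) {
  molecules <- as_dt(molecules)
  if ("junction_class" %in% names(molecules)) {
    tal <- molecules[, .(
      inclusion = sum(junction_class == "INCLUSION"),
      exclusion = sum(junction_class == "EXCLUSION"),
      ambiguous = sum(junction_class == "AMBIGUOUS")), by = barcode]
  } else {
    tal <- data.table::copy(molecules)
    if (!"ambiguous" %in% names(tal)) tal[, ambiguous := 0L]
  }
  tal[, informative := inclusion + exclusion]
  keep <- tal$informative >= min_reads & tal$informative > 0L
  dropped <- tal[!keep, .(barcode, inclusion, exclusion, ambiguous)]
  out <- tal[keep]
  out[, psi := 100 * inclusion / informative]
  out[, informative := NULL]
  data.table::setattr(out, "dropped", dropped)
  out[]
}

#' Quantify one replicate of reporter reads
#'
#' Full read-level path: parse read pairs, assign barcodes against the
#' whitelist (exact, else unique 1-mismatch rescue), classify junctions,
#' deduplicate UMIs, and compute per-barcode PSI.
#'
#' @param reads data.table with columns `r1, r2` (raw sequences).
#' @param manifest pool manifest (for the test-exon sequence per barcode).
#' @param whitelist character vector of validated barcodes (default: all
#'   manifest barcodes).
#' @param min_reads minimum informative molecules per barcode.
#' @param k junction match half-width.
#' @param barcode_length barcode length.
#' @return per-barcode PSI table as from [compute_psi()], with assignment
#'   statistics in attribute `"stats"`.
#' @export
quantify_replicate <- function(reads, manifest, whitelist = NULL,
                               min_reads = 10L, k = 8L,
                               barcode_length = 12L) {
  manifest <- as_dt(manifest)
  if (is.null(whitelist)) whitelist <- manifest$barcode
  parsed <- parse_reporter_reads(reads$r1, reads$r2, barcode_length)
  bc_map <- build_barcode_map(whitelist)
  parsed[, barcode := assign_barcodes(barcode, bc_map)]
  n_total <- nrow(parsed)
  parsed <- parsed[!is.na(barcode)]
  n_assigned <- nrow(parsed)
  exon_by_bc <- manifest[, .(barcode, exon_seq)]
  parsed <- exon_by_bc[parsed, on = "barcode", nomatch = NULL]
  parsed[, junction_class := classify_reads(r1, mrna_tail, exon_seq, k = k)]
  mol <- dedupe_umis(parsed[, .(barcode, umi, junction_class)])
  psi <- compute_psi(mol, min_reads = min_reads)
  data.table::setattr(psi, "stats", list(
    n_reads = n_total, n_assigned = n_assigned,
    n_molecules = nrow(mol),
    n_malformed_umi = attr(mol, "n_malformed_umi")))
  psi
}

#' Aggregate per-barcode PSI to per-variant PSI and delta-PSI
#'
#' Joins per-barcode PSI values (across replicates) to the pool manifest and
#' reports, per variant, the mean PSI of surviving barcodes for each allele
#' and `delta_psi = psi_alt - psi_ref`. A variant is evaluable only if each
#' allele retains at least `min_bc` expressed barcodes in every replicate
#' and at least one allele has PSI > 0; others are flagged NOT_EVALUABLE
#' with a reason, never silently reported.
#'
#' @param bc_psi data.table with columns `barcode, psi, replicate`.
#' @param manifest pool manifest mapping barcode to variant and allele.
#' @param min_bc minimum expressed barcodes per allele per replicate.
#' @return data.table, one row per variant: `variant_id, psi_ref, psi_alt,
#'   delta_psi, n_bc_ref, n_bc_alt, evaluable, reason`.
#' @export
aggregate_variant <- function(bc_psi, manifest, min_bc = 2L) {
  bc_psi <- as_dt(bc_psi)
  if (!"replicate" %in% names(bc_psi)) bc_psi[, replicate := 1L]
  manifest <- as_dt(manifest)
  x <- manifest[, .(barcode, variant_id, allele)][bc_psi, on = "barcode",
                                                  nomatch = NULL]
  # barcodes per allele within each replicate
  per_rep <- x[, .(n_bc = .N), by = .(variant_id, allele, replicate)]
  n_rep <- length(unique(bc_psi$replicate))
  rep_ok <- per_rep[, .(
    ok = all(n_bc >= min_bc) && .N == n_rep), by = .(variant_id, allele)]
  both <- data.table::dcast(rep_ok, variant_id ~ allele, value.var = "ok",
                            fill = FALSE)
  for (cc in c("REF", "ALT")) if (!cc %in% names(both)) both[[cc]] <- FALSE

  summ <- x[, .(psi = mean(psi), n_bc = .N), by = .(variant_id, allele)]
  wide <- data.table::dcast(summ, variant_id ~ allele,
                            value.var = c("psi", "n_bc"))
  for (cc in c("psi_REF", "psi_ALT")) {
    if (!cc %in% names(wide)) wide[[cc]] <- NA_real_
  }
  for (cc in c("n_bc_REF", "n_bc_ALT")) {
    if (!cc %in% names(wide)) wide[[cc]] <- 0L
  }
  out <- both[wide, on = "variant_id"]
  out[, evaluable := REF & ALT]
  out[, reason := data.table::fifelse(evaluable, "",
                                      "insufficient_barcodes")]
  zero <- !is.na(out$psi_REF) & !is.na(out$psi_ALT) &
    out$psi_REF == 0 & out$psi_ALT == 0
  out[zero & evaluable, reason := "no_splicing_event"]
  out[zero, evaluable := FALSE]
  res <- out[, .(variant_id,
                 psi_ref = psi_REF, psi_alt = psi_ALT,
                 delta_psi = data.table::fifelse(evaluable,
                                                 psi_ALT - psi_REF, NA_real_),
                 n_bc_ref = n_bc_REF, n_bc_alt = n_bc_ALT,
                 evaluable, reason)]
  data.table::setorder(res, variant_id)
  res[]
}
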