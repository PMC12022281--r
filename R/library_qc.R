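# Plasmid-library sequencing geometry: 150-nt paired-end reads spanning the
# insert; read 1 from the 5' end of the construct, read 2 the reverse
# complement of its 3' end. The barcode therefore sits at a fixed offset
# from the construct 3' end (just 5' of the MfeI/SpeI linker).
PL_READ_LENGTH <- 150L

barcode_span_from_end <- function(barcode_length = 12L) {
  # positions of the barcode counted from the construct 3' end (1-based)
  hi <- nchar(OLIGO_LINKER) + nchar(OLIGO_FLANK3)
  c(hi + 1L, hi + barcode_length)  # from-end offsets: (33, 44) for 12-nt BCs
}

# vectorised per-pair mismatch counts between equal-length strings
string_mismatches <- function(x, y) {
  stopifnot(length(x) == length(y))
  out <- integer(length(x))
  for (i in seq_along(x)) out[i] <- sum(utf8ToInt(x[i]) != utf8ToInt(y[i]))
  out
}

#' Match plasmid-library read pairs to the designed pool
#'
#' Replaces alignment by deterministic string matching: the barcode is
#' extracted from read 2 at its designed offset and assigned exactly, else
#' by unique 1-mismatch rescue (ambiguous rescues stay unassigned). For PL1
#' the insert is reconstructed from the pair and compared to the designed
#' full sequence (barcode positions masked); pairs disagreeing in their
#' overlap are counted as conflicting and excluded from both the total and
#' the correct tally.
#'
#' @param pl1_reads,pl2_reads data.tables with columns `r1, r2`; `pl2_reads`
#'   may be NULL (tallies then report `pl2_reads = 0` for all barcodes).
#' @param manifest pool manifest from [assemble_pool()].
#' @param max_mismatches per-pair error budget for a read to count as
#'   "correct" (default 0, exact).
#' @param barcode_length barcode length (default 12).
#' @return data.table per designed barcode: `barcode, construct_id,
#'   pl1_reads, pl1_correct_reads, pl1_conflicting, bc_exact_seen,
#'   pl2_reads`.
#' @export
match_reads_to_design <- function(pl1_reads, pl2_reads, manifest,
                                  max_mismatches = 0L, barcode_length = 12L) {
  manifest <- as_dt(manifest)
  bc_map <- build_barcode_map(manifest$barcode)
  span <- barcode_span_from_end(barcode_length)

  extract_bc <- function(r2) {
    # barcode occupies bases span[1]..span[2] from the construct 3' end,
    # i.e. read-2 positions span[1]..span[2], reverse complemented
    revcomp(substr(r2, span[1], span[2]))
  }

  tally_pl1 <- function(reads) {
    if (is.null(reads) || nrow(reads) == 0L) {
      warning("empty read set: returning empty tallies")
      return(data.table::data.table(barcode = character(0),
                                    total = integer(0),
                                    correct = integer(0),
                                    conflicting = integer(0),
                                    exact = integer(0)))
    }
    reads <- as_dt(reads)
    obs_bc <- extract_bc(reads$r2)
    assigned <- assign_barcodes(obs_bc, bc_map)
    keep <- !is.na(assigned)
    reads <- reads[keep]
    reads[, barcode := assigned[keep]]
    reads[, bc_exact := obs_bc[keep] == barcode]
    dsg <- manifest[, .(barcode, full_sequence)]
    reads <- dsg[reads, on = "barcode", nomatch = NULL]
    reads[, len := nchar(full_sequence)]
    sense2 <- revcomp(reads$r2)
    # reconstruct the insert: r1 head + full 3'-end read
    head_len <- pmax(reads$len - PL_READ_LENGTH, 0L)
    recon <- paste0(substr(reads$r1, 1L, head_len), sense2)
    # pair consistency over the overlap
    ov_start <- pmax(reads$len - PL_READ_LENGTH + 1L, 1L)
    ov1 <- substr(reads$r1, ov_start, pmin(PL_READ_LENGTH, reads$len))
    ov2 <- substr(sense2, 1L, nchar(ov1))
    conflict <- ov1 != ov2
    # compare to design with the barcode positions masked
    mask <- function(s, len) {
      lo <- len - span[2] + 1L
      hi <- len - span[1] + 1L
      paste0(substr(s, 1L, lo - 1L), strrep("N", span[2] - span[1] + 1L),
             substr(s, hi + 1L, len))
    }
    mm <- string_mismatches(mask(recon, reads$len),
                            mask(reads$full_sequence, reads$len))
    reads[, conflict_ := conflict]
    reads[, correct_ := !conflict & mm <= max_mismatches]
    reads[, .(total = sum(!conflict_), correct = sum(correct_),
              conflicting = sum(conflict_),
              exact = sum(bc_exact & !conflict_)),
          by = barcode]
  }

  tally_pl2 <- function(reads) {
    if (is.null(reads) || nrow(reads) == 0L) {
      return(data.table::data.table(barcode = character(0),
                                    pl2 = integer(0)))
    }
    reads <- as_dt(reads)
    assigned <- assign_barcodes(extract_bc(reads$r2), bc_map)
    data.table::data.table(barcode = assigned[!is.na(assigned)])[
      , .(pl2 = .N), by = barcode]
  }

  t1 <- tally_pl1(pl1_reads)
  t2 <- tally_pl2(pl2_reads)
  out <- manifest[, .(barcode, construct_id)]
  out <- t1[out, on = "barcode"]
  out <- t2[out, on = "barcode"]
  for (cc in c("total", "correct", "conflicting", "exact", "pl2")) {
    data.table::set(out, i = which(is.na(out[[cc]])), j = cc, value = 0L)
  }
  out[, .(barcode, construct_id, pl1_reads = total,
          pl1_correct_reads = correct, pl1_conflicting = conflicting,
          bc_exact_seen = exact > 0L, pl2_reads = pl2)]
}

#' Validate barcodes from PL1/PL2 tallies
#'
#' Applies the library filters in order (first failure wins): barcode absent
#' from PL1; barcode never observed without mutation (synthesis error);
#' fraction of correct PL1 reads below `min_correct_frac`; barcode absent
#' from PL2. Survivors are VALID and form the whitelist.
#'
#' @param tallies output of [match_reads_to_design()].
#' @param min_correct_frac minimum fraction of correct PL1 reads
#'   (default 0.85).
#' @return data.table of BarcodeRecord rows (`barcode, construct_id,
#'   pl1_reads, pl1_correct_reads, pl2_reads, status`), with a summary list
#'   (counts per status and percent valid) as attribute `"summary"`.
#' @export
validate_barcodes <- function(tallies, min_correct_frac = 0.85) {
  t <- as_dt(tallies)
  status <- rep("VALID", nrow(t))
  status[t$pl1_reads > 0L & !t$bc_exact_seen] <- "BC_MUTATED"
  status[t$pl1_reads > 0L & t$bc_exact_seen &
           t$pl1_correct_reads / t$pl1_reads < min_correct_frac] <- "LOW_FIDELITY"
  status[t$pl1_reads == 0L] <- "ABSENT_PL1"
  ok <- status == "VALID"
  status[ok & t$pl2_reads == 0L] <- "ABSENT_PL2"
  out <- t[, .(barcode, construct_id, pl1_reads, pl1_correct_reads,
               pl2_reads)]
  out[, status := status]
  counts <- table(factor(out$status,
                         levels = c("VALID", "ABSENT_PL1", "BC_MUTATED",
                                    "LOW_FIDELITY", "ABSENT_PL2")))
  data.table::setattr(out, "summary",
                      list(counts = counts,
                           pct_valid = 100 * mean(out$status == "VALID")))
  out[]
}
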