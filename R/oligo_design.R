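#' Load gene models from a GTF file or data frame
#'
#' Accepts a path to a GTF file (read with rtracklayer) or a data frame with
#' columns `gene_id, transcript_id, exon_rank, chrom, start, end, strand`
#' (1-based inclusive coordinates).
#'
#' @param x GTF path or data frame of exons.
#' @return data.table of exons, one row per transcript exon.
#' @export
load_gene_models <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    gr <- rtracklayer::import(x, format = "gtf")
    gr <- gr[gr$type == "exon"]
    dt <- data.table::data.table(
      gene_id = as.character(gr$gene_id),
      transcript_id = as.character(gr$transcript_id),
      exon_rank = as.integer(gr$exon_number),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    )
  } else {
    dt <- as_dt(x)
    need <- c("gene_id", "transcript_id", "exon_rank", "chrom", "start",
              "end", "strand")
    miss <- setdiff(need, names(dt))
    if (length(miss)) stop("gene models missing columns: ",
                           paste(miss, collapse = ", "))
    dt <- dt[, need, with = FALSE]
    dt[, exon_rank := as.integer(exon_rank)]
  }
  data.table::setorder(dt, chrom, transcript_id, exon_rank)
  dt[]
}

#' Load a genome as a named character vector
#'
#' @param x FASTA path, `Biostrings::DNAStringSet`, or named character vector.
#' @return named character vector of chromosome sequences.
#' @export
load_genome <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "DNAStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (is.character(x) && !is.null(names(x))) return(x)
  stop("genome must be a FASTA path, DNAStringSet or named character vector")
}

subseq_chr <- function(genome, chrom, start, end) {
  substr(genome[[chrom]], start, end)
}

#' Select eligible test regions from gene models
#'
#' Scans every exon of every transcript and keeps internal exons of
#' `exon_min`-`exon_max` nt whose fixed-length intronic flanks (50 nt
#' upstream, 20 nt downstream in transcript orientation) fit between the
#' neighbouring exons and whose test sequence (upstream flank + exon +
#' downstream flank) is free of MfeI/SpeI sites. Minus-strand features are
#' reverse-complemented into transcript orientation.
#'
#' @param gene_models exon table or GTF path (see [load_gene_models()]).
#' @param genome genome (see [load_genome()]).
#' @param exon_min,exon_max allowed test-exon length range (default 13-98).
#' @param flank_up,flank_down intronic flank lengths (default 50/20).
#' @return data.table of accepted regions (one row per region) with columns
#'   `region_id, gene_id, transcript_id, exon_rank, chrom, start, end,
#'   strand, exon_seq, upstream_flank, downstream_flank, test_sequence`.
#'   Rejected exons with reason codes are attached as attribute `"rejected"`.
#' @export
select_test_regions <- function(gene_models, genome,
                                exon_min = 13L, exon_max = 98L,
                                flank_up = 50L, flank_down = 20L) {
  ex <- load_gene_models(gene_models)
  genome <- load_genome(genome)

  bad_chr <- setdiff(unique(ex$chrom), names(genome))
  if (length(bad_chr)) stop("coordinate error: chromosomes absent from genome: ",
                            paste(bad_chr, collapse = ", "))
  chr_len <- nchar(genome)[ex$chrom]
  if (any(ex$start < 1L | ex$end > chr_len | ex$start > ex$end)) {
    stop("coordinate error: exon coordinates outside genome bounds")
  }

  ex[, n_exons := max(exon_rank), by = transcript_id]
  ex[, len := end - start + 1L]
  # genomic coordinates of neighbouring exons in the same transcript
  data.table::setorder(ex, transcript_id, exon_rank)
  ex[, `:=`(prev_end = data.table::shift(end),
            prev_start = data.table::shift(start),
            next_start = data.table::shift(start, type = "lead"),
            next_end = data.table::shift(end, type = "lead")),
     by = transcript_id]

  reject <- function(mask, reason) {
    data.table::data.table(transcript_id = ex$transcript_id[mask],
                           exon_rank = ex$exon_rank[mask], reason = reason)
  }
  rejected <- list()
  alive <- rep(TRUE, nrow(ex))

  term <- ex$exon_rank == 1L | ex$exon_rank == ex$n_exons
  rejected$terminal <- reject(alive & term, "terminal_exon")
  alive <- alive & !term

  short <- ex$len < exon_min
  rejected$short <- reject(alive & short, "exon_too_short")
  alive <- alive & !short
  long <- ex$len > exon_max
  rejected$long <- reject(alive & long, "exon_too_long")
  alive <- alive & !long

  # flank span in genomic coordinates
  gflank5 <- ifelse(ex$strand == "+", flank_up, flank_down)  # left of exon
  gflank3 <- ifelse(ex$strand == "+", flank_down, flank_up)  # right of exon
  span_lo <- ex$start - gflank5
  span_hi <- ex$end + gflank3
  oob <- span_lo < 1L | span_hi > chr_len
  rejected$oob <- reject(alive & oob, "flank_out_of_bounds")
  alive <- alive & !oob

  # neighbouring exon intrusion: the flank must stay intronic
  left_nb <- ifelse(ex$strand == "+", ex$prev_end, ex$next_end)
  right_nb <- ifelse(ex$strand == "+", ex$next_start, ex$prev_start)
  clash <- (!is.na(left_nb) & left_nb >= span_lo) |
           (!is.na(right_nb) & right_nb <= span_hi)
  rejected$clash <- reject(alive & clash, "flank_overlap")
  alive <- alive & !clash

  keep <- ex[alive]
  if (nrow(keep)) {
    raw <- mapply(subseq_chr, chrom = keep$chrom,
                  start = keep$start - ifelse(keep$strand == "+", flank_up,
                                              flank_down),
                  end = keep$end + ifelse(keep$strand == "+", flank_down,
                                          flank_up),
                  MoreArgs = list(genome = genome), USE.NAMES = FALSE)
    test_seq <- ifelse(keep$strand == "+", raw, revcomp(raw))
    keep[, test_sequence := test_seq]
    keep[, upstream_flank := substr(test_sequence, 1L, flank_up)]
    keep[, exon_seq := substr(test_sequence, flank_up + 1L, flank_up + len)]
    keep[, downstream_flank := substr(test_sequence, flank_up + len + 1L,
                                      nchar(test_sequence))]
    site <- has_restriction_site(keep$test_sequence)
    rejected$site <- data.table::data.table(
      transcript_id = keep$transcript_id[site],
      exon_rank = keep$exon_rank[site], reason = "restriction_site")
    keep <- keep[!site]
  }

  data.table::setorder(keep, chrom, start, transcript_id)
  out <- if (nrow(keep)) {
    keep[, .(region_id = paste0(transcript_id, ":e", exon_rank),
             gene_id, transcript_id, exon_rank, chrom, start, end,
             strand, exon_seq, upstream_flank, downstream_flank,
             test_sequence)]
  } else {
    data.table::data.table(
      region_id = character(0), gene_id = character(0),
      transcript_id = character(0), exon_rank = integer(0),
      chrom = character(0), start = integer(0), end = integer(0),
      strand = character(0), exon_seq = character(0),
      upstream_flank = character(0), downstream_flank = character(0),
      test_sequence = character(0))
  }
  rej <- data.table::rbindlist(rejected)
  data.table::setattr(out, "rejected", rej)
  out
}

#' Assemble the barcoded oligonucleotide pool
#'
#' For each biallelic SNP lying inside a test region, emits
#' `2 x barcodes_per_construct` constructs (REF and ALT alleles, each tagged
#' with its own barcodes). The full oligo is
#' `5' invariant | upstream flank | exon | downstream flank | barcode |
#' MfeI/SpeI linker | 3' invariant`; constructs in which either restriction
#' site occurs outside the linker (e.g. created by the ALT allele) are
#' excluded and reported in the `"excluded"` attribute.
#'
#' @param regions output of [select_test_regions()].
#' @param variants data frame with columns `chrom, pos, ref, alt` and
#'   optionally `variant_id` (biallelic SNPs, 1-based positions).
#' @param barcodes_per_construct barcodes per allele (default 4).
#' @param barcode_length,barcode_min_distance,seed passed to
#'   [generate_barcodes()]; alternatively supply `barcodes` directly.
#' @param barcodes optional pre-generated barcode vector (must be at least
#'   as long as the number of constructs).
#' @return data.table pool manifest, one row per construct, with attribute
#'   `"excluded"` listing variants dropped with a reason code.
#' @export
assemble_pool <- function(regions, variants, barcodes_per_construct = 4L,
                          barcode_length = 12L, barcode_min_distance = 3L,
                          seed = 1L, barcodes = NULL) {
  regions <- as_dt(regions)
  variants <- as_dt(variants)
  if (!"variant_id" %in% names(variants)) {
    variants[, variant_id := paste0(chrom, ":", pos, ref, ">", alt)]
  }
  if (any(nchar(variants$ref) != 1L | nchar(variants$alt) != 1L)) {
    stop("only biallelic SNPs are supported")
  }

  flank_up <- nchar(regions$upstream_flank[1])
  flank_down <- nchar(regions$downstream_flank[1])

  # map each variant onto the region whose test-sequence span contains it
  regions[, span_lo := ifelse(strand == "+", start - flank_up,
                              start - flank_down)]
  regions[, span_hi := ifelse(strand == "+", end + flank_down,
                              end + flank_up)]
  hits <- regions[variants,
                  on = .(chrom, span_lo <= pos, span_hi >= pos),
                  .(region_id, gene_id, transcript_id, exon_rank, strand,
                    rstart = x.start, rend = x.end, test_sequence, exon_seq,
                    chrom, pos = i.pos, ref = i.ref, alt = i.alt,
                    variant_id = i.variant_id),
                  nomatch = NA]
  if (anyNA(hits$region_id)) {
    stop("placement error: variant(s) outside every test sequence: ",
         paste(unique(hits$variant_id[is.na(hits$region_id)]), collapse = ", "))
  }

  # offset of the SNP inside the test sequence, transcript orientation
  hits[, offset := ifelse(strand == "+",
                          pos - (rstart - flank_up) + 1L,
                          (rend + flank_up) - pos + 1L)]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hits[, ref_t := ifelse(strand == "+", ref, comp[ref])]
  hits[, alt_t := ifelse(strand == "+", alt, comp[alt])]
  obs <- substr(hits$test_sequence, hits$offset, hits$offset)
  if (any(obs != hits$ref_t)) {
    bad <- hits$variant_id[obs != hits$ref_t]
    stop("reference-mismatch error: REF allele disagrees with genome for: ",
         paste(unique(bad), collapse = ", "))
  }
  hits[, alt_sequence := {
    s <- test_sequence
    substr(s, offset, offset) <- alt_t
    s
  }]

  # an ALT allele may create a restriction site inside the test sequence
  excl <- has_restriction_site(hits$alt_sequence)
  excluded <- data.table::data.table(
    variant_id = hits$variant_id[excl],
    reason = "restriction_site_created")
  hits <- hits[!excl]

  n_constructs <- nrow(hits) * 2L * barcodes_per_construct
  if (n_constructs == 0L) {
    out <- data.table::data.table(
      construct_id = character(0), barcode = character(0),
      region_id = character(0), gene_id = character(0),
      transcript_id = character(0), exon_rank = integer(0),
      chrom = character(0), pos = integer(0), ref = character(0),
      alt = character(0), variant_id = character(0), allele = character(0),
      strand = character(0), exon_seq = character(0),
      test_sequence = character(0), full_sequence = character(0))
    data.table::setattr(out, "excluded", excluded)
    return(out)
  }
  if (is.null(barcodes)) {
    barcodes <- generate_barcodes(n_constructs, length = barcode_length,
                                  min_distance = barcode_min_distance,
                                  seed = seed)
  }
  if (length(barcodes) < n_constructs) stop("not enough barcodes supplied")
  if (anyDuplicated(barcodes)) stop("barcodes must be unique")

  alleles <- data.table::data.table(
    allele = rep(c("REF", "ALT"), each = barcodes_per_construct),
    bc_idx = rep(seq_len(barcodes_per_construct), 2L))
  pool <- hits[rep(seq_len(nrow(hits)), each = nrow(alleles))]
  pool[, c("allele", "bc_idx") :=
         alleles[rep(seq_len(nrow(alleles)), times = nrow(hits))]]
  pool[, barcode := barcodes[seq_len(.N)]]
  pool[, construct_id := paste(region_id, variant_id, allele, bc_idx,
                               sep = "_")]
  pool[, test_seq_used := ifelse(allele == "REF", test_sequence, alt_sequence)]
  pool[, exon_seq_used := substr(test_seq_used, flank_up + 1L,
                                 nchar(test_seq_used) - flank_down)]
  pool[, full_sequence := paste0(OLIGO_FLANK5, test_seq_used, barcode,
                                 OLIGO_LINKER, OLIGO_FLANK3)]

  # both sites must occur exactly once (in the linker); boundary effects can
  # in principle create extra copies
  bad_full <- count_pattern(pool$full_sequence, SITE_MFEI) != 1L |
              count_pattern(pool$full_sequence, SITE_SPEI) != 1L
  if (any(bad_full)) {
    excluded <- rbind(excluded, data.table::data.table(
      variant_id = unique(pool$variant_id[bad_full]),
      reason = "linker_site_duplicated"))
    pool <- pool[!pool$variant_id %in% pool$variant_id[bad_full]]
  }

  out <- pool[, .(construct_id, barcode, region_id, gene_id, transcript_id,
                  exon_rank, chrom, pos, ref, alt, variant_id, allele,
                  strand, exon_seq = exon_seq_used,
                  test_sequence = test_seq_used, full_sequence)]
  data.table::setattr(out, "excluded", excluded)
  out
}

#' Re-parse a full oligo sequence into its parts
#'
#' Inverse of the assembly in [assemble_pool()]: recovers the test sequence
#' and barcode from a full construct sequence.
#'
#' @param full_sequence character vector of construct sequences.
#' @param barcode_length barcode length used at assembly.
#' @return data.table with columns `test_sequence` and `barcode`.
#' @export
parse_full_sequence <- function(full_sequence, barcode_length = 12L) {
  n5 <- nchar(OLIGO_FLANK5)
  tail_len <- nchar(OLIGO_LINKER) + nchar(OLIGO_FLANK3)
  ok <- startsWith(full_sequence, OLIGO_FLANK5) &
    endsWith(full_sequence, paste0(OLIGO_LINKER, OLIGO_FLANK3))
  if (!all(ok)) stop("sequence does not match the invariant segments")
  core <- substr(full_sequence, n5 + 1L, nchar(full_sequence) - tail_len)
  data.table::data.table(
    test_sequence = substr(core, 1L, nchar(core) - barcode_length),
    barcode = substr(core, nchar(core) - barcode_length + 1L, nchar(core))
  )
}

#' Write a pool manifest TSV
#' @param pool manifest from [assemble_pool()].
#' @param path output TSV path.
#' @export
write_pool_manifest <- function(pool, path) {
  data.table::fwrite(as_dt(pool), path, sep = "\t")
  invisible(path)
}

#' Read a pool manifest TSV
#' @param path manifest TSV path.
#' @export
read_pool_manifest <- function(path) {
  data.table::fread(path, sep = "\t", colClasses = list(character = "chrom"))
}

#' Write the oligo pool as FASTA
#' @param pool manifest from [assemble_pool()].
#' @param path output FASTA path.
#' @export
write_pool_fasta <- function(pool, path) {
  seqs <- Biostrings::DNAStringSet(pool$full_sequence)
  names(seqs) <- pool$construct_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
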