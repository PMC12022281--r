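# Shared fixtures, built in code at test time. Cached per session so several
# test files can reuse the same small experiment without re-simulating.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

tiny_design <- function() {
  fixture("tiny_design", function() {
    models <- sim_gene_models(n_genes = 12, seed = 7)
    regions <- select_test_regions(models$exons, models$genome)
    sim <- sim_variants(regions, models$genome, n_variants = 8,
                        fraction_sdv = 0.5, seed = 3)
    pool <- assemble_pool(regions, sim$variants, seed = 11)
    list(models = models, regions = regions, variants = sim$variants,
         truth = sim$truth, pool = pool)
  })
}

# A random toy multi-exon transcript with a clean CDS (random non-stop
# codons + terminal stop), split into exons at random boundaries.
random_toy_transcript <- function(seed) {
  set.seed(seed)
  codons <- apply(expand.grid(DNA <- c("A", "C", "G", "T"), DNA, DNA), 1,
                  paste, collapse = "")
  sense_codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  n_codons <- sample(20:150, 1)
  cds <- paste(c(sample(sense_codons, n_codons, replace = TRUE),
                 sample(c("TAA", "TAG", "TGA"), 1)), collapse = "")
  utr5 <- paste(sample(DNA, sample(10:60, 1), replace = TRUE), collapse = "")
  utr3 <- paste(sample(DNA, sample(10:120, 1), replace = TRUE), collapse = "")
  mrna <- paste0(utr5, cds, utr3)
  len <- nchar(mrna)
  n_ex <- sample(3:8, 1)
  cuts <- sort(sample(seq_len(len - 1), n_ex - 1))
  bounds <- c(0, cuts, len)
  exons <- data.frame(
    exon_rank = seq_len(n_ex),
    exon_seq = vapply(seq_len(n_ex), function(i) {
      substr(mrna, bounds[i] + 1, bounds[i + 1])
    }, character(1)))
  list(exons = exons, cds_start = nchar(utr5) + 1L,
       cds_end = nchar(utr5) + nchar(cds))
}

# Independent consequence oracle: brute-force translation of the
# concatenated skipped-form sequence with Biostrings.
oracle_splice_consequence <- function(exons, cds_start, cds_end,
                                      skipped_rank) {
  lens <- nchar(exons$exon_seq)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  s <- starts[skipped_rank]; e <- ends[skipped_rank]
  if (s <= cds_start + 2L && e >= cds_start) return(list(consequence = "DEL_ATG"))
  if (s > cds_end) return(list(consequence = "UTR3_DEL"))
  if (e < cds_start) return(list(consequence = "UTR5_DEL"))
  keep <- setdiff(seq_along(lens), skipped_rank)
  skipped <- paste(exons$exon_seq[keep], collapse = "")
  tailseq <- substr(skipped, cds_start, nchar(skipped))
  tailseq <- substr(tailseq, 1, 3 * (nchar(tailseq) %/% 3))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(tailseq),
                                           if.fuzzy.codon = "X"))
  star <- regexpr("*", aa, fixed = TRUE)[1]
  if (star == -1) return(list(consequence = NA_character_, flag = "no_stop"))
  stop_pos <- cds_start + 3L * (star - 1L)
  orig_equiv <- if (e <= cds_end) cds_end - 2L - (e - s + 1L) else NA_integer_
  if (!is.na(orig_equiv) && stop_pos == orig_equiv) {
    return(list(consequence = "IFD"))
  }
  new_ends <- cumsum(lens[keep])
  ptc_exon <- which(stop_pos <= new_ends)[1]
  list(consequence = "PTC", ptc_exon = ptc_exon,
       nmd = ptc_exon < length(keep))
}
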