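test_that("generated barcodes respect distance, motif and homopolymer rules", {
  bcs <- generate_barcodes(8, length = 12, min_distance = 3, seed = 1)
  expect_length(bcs, 8)
  expect_true(all(nchar(bcs) == 12))
  # exhaustive pairwise Hamming check
  dmin <- Inf
  for (i in 1:7) for (j in (i + 1):8) {
    d <- sum(strsplit(bcs[i], "")[[1]] != strsplit(bcs[j], "")[[1]])
    dmin <- min(dmin, d)
  }
  expect_gte(dmin, 3)
  expect_false(any(grepl("CAATTG|ACTAGT", bcs)))
  expect_false(any(grepl("A{5}|C{5}|G{5}|T{5}", bcs)))
  # reproducibility and the trivial single-barcode case
  expect_identical(bcs, generate_barcodes(8, 12, 3, seed = 1))
  expect_length(generate_barcodes(1, 12, 3, seed = 5), 1)
})

test_that("infeasible barcode requests raise a capacity error", {
  expect_error(generate_barcodes(1e6, length = 8, min_distance = 5),
               "capacity")
})

test_that("test-region selection enforces the design constraints", {
  d <- tiny_design()
  reg <- d$regions
  rej <- attr(reg, "rejected")
  expect_true(all(nchar(reg$exon_seq) >= 13 & nchar(reg$exon_seq) <= 98))
  expect_true(all(nchar(reg$upstream_flank) == 50))
  expect_true(all(nchar(reg$downstream_flank) == 20))
  expect_false(any(grepl("CAATTG|ACTAGT", reg$test_sequence)))
  # no terminal exons
  ex <- data.table::as.data.table(d$models$exons)
  ex[, n_exons := max(exon_rank), by = transcript_id]
  m <- merge(reg, ex, by = c("transcript_id", "exon_rank"))
  expect_true(all(m$exon_rank > 1 & m$exon_rank < m$n_exons))
  # every over-length internal exon was rejected with the right code
  expect_true("exon_too_long" %in% rej$reason)
  expect_true(all(c("terminal_exon") %in% rej$reason))
  # deterministic order
  expect_identical(reg$region_id,
                   select_test_regions(d$models$exons, d$models$genome)$region_id)
})

test_that("boundary exon lengths are handled exactly", {
  # one + strand gene: exons of 100 / 98 / 99 / 100 nt; only the 98-nt
  # internal exon qualifies
  set.seed(42)
  lens <- c(100L, 98L, 99L, 100L)
  introns <- c(200L, 200L, 200L)
  pos <- 121L
  starts <- integer(4)
  for (i in 1:4) {
    starts[i] <- pos
    pos <- pos + lens[i] + if (i < 4) introns[i] else 0L
  }
  chrom_len <- pos + 120L
  genome <- c(chrT = paste(sample(c("A", "C", "G", "T"), chrom_len,
                                  replace = TRUE), collapse = ""))
  exons <- data.frame(gene_id = "G", transcript_id = "T",
                      exon_rank = 1:4, chrom = "chrT",
                      start = starts, end = starts + lens - 1L, strand = "+")
  reg <- select_test_regions(exons, genome)
  rej <- attr(reg, "rejected")
  if (nrow(reg) == 1L) {
    expect_equal(nchar(reg$exon_seq), 98)
    expect_equal(reg$exon_rank, 2L)
  } else {
    # the 98-nt exon can only have been lost to a chance restriction site
    expect_true("restriction_site" %in%
                  rej[rej$exon_rank == 2, ]$reason)
  }
  expect_true(any(rej$reason == "exon_too_long" & rej$exon_rank == 3))
})

test_that("a restriction site in the flank rejects the region", {
  genome <- c(chrT = paste0(strrep("A", 120),
                            strrep("CT", 60),            # exon 1
                            strrep("AG", 100),           # intron
                            strrep("GT", 20),            # exon 2 (40 nt)
                            strrep("TC", 100),           # intron
                            strrep("CA", 60),            # exon 3
                            strrep("A", 120)))
  s1 <- 121L
  exons <- data.frame(gene_id = "G", transcript_id = "T", exon_rank = 1:3,
                      chrom = "chrT",
                      start = c(s1, s1 + 120 + 200, s1 + 120 + 200 + 40 + 200),
                      end = c(s1 + 119, s1 + 120 + 200 + 39,
                              s1 + 120 + 200 + 40 + 200 + 119),
                      strand = "+")
  reg0 <- select_test_regions(exons, genome)
  expect_equal(nrow(reg0), 1L)  # clean periodic sequence passes
  # plant a SpeI site in the downstream flank (20 nt after exon 2 end)
  g2 <- genome
  e2_end <- s1 + 120 + 200 + 39
  substr(g2["chrT"], e2_end + 5, e2_end + 10) <- "ACTAGT"
  reg <- select_test_regions(exons, g2)
  expect_equal(nrow(reg), 0L)
  expect_true("restriction_site" %in% attr(reg, "rejected")$reason)
})

test_that("pool assembly emits 2 x 4 valid constructs per variant", {
  d <- tiny_design()
  pool <- d$pool
  n_var <- length(unique(pool$variant_id))
  expect_equal(nrow(pool), n_var * 2L * 4L)
  expect_equal(anyDuplicated(pool$barcode), 0L)
  # invariant segments and single-occurrence restriction sites
  expect_true(all(startsWith(pool$full_sequence, "CTGACTCTCTCTGCCTC")))
  expect_true(all(endsWith(pool$full_sequence,
                           paste0("CAATTGACTACTAGT", "TCTAGAGGGCCCGTTTA"))))
  n_mfe <- vapply(gregexpr("CAATTG", pool$full_sequence), function(m)
    sum(m > 0), numeric(1))
  n_spe <- vapply(gregexpr("ACTAGT", pool$full_sequence), function(m)
    sum(m > 0), numeric(1))
  expect_true(all(n_mfe == 1 & n_spe == 1))
  # REF and ALT differ at exactly one position
  first_bc <- pool[!duplicated(paste(pool$variant_id, pool$allele)), ]
  w <- data.table::dcast(data.table::as.data.table(first_bc),
                         variant_id ~ allele, value.var = "test_sequence")
  diffs <- mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)),
                  w$REF, w$ALT)
  expect_true(all(diffs == 1))
})

test_that("full sequences round-trip through the parser", {
  pool <- tiny_design()$pool
  parsed <- parse_full_sequence(pool$full_sequence)
  expect_identical(parsed$barcode, pool$barcode)
  expect_identical(parsed$test_sequence, pool$test_sequence)
})

test_that("a SNP creating a restriction site is excluded from the pool", {
  d <- tiny_design()
  reg <- d$regions[1]
  # craft an ALT that completes a CAATTG site inside the exon
  seq <- reg$test_sequence
  pos_in_test <- 55L  # inside the exon (flank is 50)
  # place CAATTG-with-one-change at the REF sequence, variant fixes it
  broken <- "CATTTG"
  substr(seq, pos_in_test, pos_in_test + 5) <- broken
  genome <- d$models$genome
  # rebuild a + strand single-region genome for clarity
  g <- c(chrV = paste0(strrep("A", 100), seq, strrep("A", 100)))
  exons <- data.frame(gene_id = "G", transcript_id = "T", exon_rank = 1:3,
                      chrom = "chrV",
                      start = c(20, 151, 100 + nchar(seq) + 50),
                      end = c(40, 150 + nchar(seq) - 70, 100 + nchar(seq) + 80),
                      strand = "+")
  regions <- select_test_regions(exons, g)
  expect_equal(nrow(regions), 1L)
  snp_pos <- 100L + pos_in_test + 2L  # third base of the broken site
  v <- data.frame(chrom = "chrV", pos = snp_pos,
                  ref = substr(g[["chrV"]], snp_pos, snp_pos),
                  alt = "A",  # CATTTG -> CAATTG
                  variant_id = "rsX")
  pool <- assemble_pool(regions, v, seed = 2)
  expect_equal(nrow(pool), 0L)
  expect_true("restriction_site_created" %in% attr(pool, "excluded")$reason)
})

test_that("variants outside any region or mismatching the genome error", {
  d <- tiny_design()
  v_out <- data.frame(chrom = d$regions$chrom[1], pos = 1L, ref = "A",
                      alt = "C", variant_id = "rsOUT")
  expect_error(assemble_pool(d$regions, v_out), "placement")
  v1 <- d$variants[1, ]
  wrong <- setdiff(c("A", "C", "G", "T"), c(v1$ref, v1$alt))[1]
  v1$ref <- wrong
  expect_error(assemble_pool(d$regions, v1), "mismatch")
})

test_that("pool manifest and FASTA writers round-trip", {
  pool <- tiny_design()$pool
  tsv <- tempfile(fileext = ".tsv")
  write_pool_manifest(pool, tsv)
  back <- read_pool_manifest(tsv)
  expect_equal(back$full_sequence, pool$full_sequence)
  fa <- tempfile(fileext = ".fa")
  write_pool_fasta(pool, fa)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(seqs), nrow(pool))
  expect_equal(unname(as.character(seqs)), pool$full_sequence)
})
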