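# a hand-built 4-exon transcript:
#   exon1: 5'UTR (20 nt) + start of CDS
#   CDS assembled from non-stop codons, terminal TAA
make_toy <- function(exon2_len) {
  # CDS: 60 codons + stop; exon2 carries `exon2_len` nt of pure CDS
  codon_pool <- c("GCT", "GAA", "TGG", "CAT", "AAA", "CTG", "TTC", "GGA")
  cds <- paste(c(rep(codon_pool, length.out = 60), "TAA"), collapse = "")
  utr5 <- strrep("CT", 10)
  utr3 <- strrep("GA", 15)
  mrna <- paste0(utr5, cds, utr3)
  # split: exon1 = utr5 + 30 nt CDS; exon2 = next exon2_len; rest split in 2
  b1 <- nchar(utr5) + 30L
  b2 <- b1 + exon2_len
  b3 <- b2 + 60L
  exons <- data.frame(exon_rank = 1:4, exon_seq = c(
    substr(mrna, 1, b1), substr(mrna, b1 + 1, b2),
    substr(mrna, b2 + 1, b3), substr(mrna, b3 + 1, nchar(mrna))))
  list(exons = exons, cds_start = nchar(utr5) + 1L,
       cds_end = nchar(utr5) + nchar(cds))
}

test_that("frame-preserving exon skips are in-frame deletions", {
  toy <- make_toy(84L)  # 84 %% 3 == 0
  res <- splice_consequence(toy$exons, toy$cds_start, toy$cds_end, 2L)
  expect_equal(res$consequence, "IFD")
  expect_true(res$frame_preserved)
  expect_true(is.na(res$ptc_exon))
})

test_that("frameshifting skips create a PTC found by codon scan", {
  toy <- make_toy(83L)
  res <- splice_consequence(toy$exons, toy$cds_start, toy$cds_end, 2L)
  expect_equal(res$consequence, "PTC")
  expect_false(res$frame_preserved)
  expect_true(res$ptc_exon >= 1L && res$ptc_exon <= 3L)
  orc <- oracle_splice_consequence(toy$exons, toy$cds_start, toy$cds_end, 2L)
  expect_equal(res$consequence, orc$consequence)
  expect_equal(res$ptc_exon, orc$ptc_exon)
  expect_equal(res$nmd_predicted, orc$nmd)
})

test_that("start-codon and 3'UTR exons are classified by position", {
  # exon containing the ATG: put the CDS start inside exon 2
  codon_pool <- c("GCT", "GAA", "TGG", "CAT")
  cds <- paste(c(rep(codon_pool, length.out = 40), "TAA"), collapse = "")
  utr5 <- strrep("CT", 30)
  utr3 <- strrep("GATTTT", 20)
  mrna <- paste0(utr5, cds, utr3)
  cds_start <- nchar(utr5) + 1L
  cds_end <- nchar(utr5) + nchar(cds)
  cut1 <- nchar(utr5) - 5L           # exon2 starts 5 nt before the CDS
  cut2 <- nchar(utr5) + 30L
  cut3 <- cds_end + 10L              # exon4 entirely in the 3'UTR... exon3 ends past stop
  exons <- data.frame(exon_rank = 1:4, exon_seq = c(
    substr(mrna, 1, cut1), substr(mrna, cut1 + 1, cut2),
    substr(mrna, cut2 + 1, cut3), substr(mrna, cut3 + 1, nchar(mrna))))
  res <- splice_consequence(exons, cds_start, cds_end, 2L)
  expect_equal(res$consequence, "DEL_ATG")
  # and an internal exon fully 3' of the stop codon
  exons2 <- data.frame(exon_rank = 1:4, exon_seq = c(
    substr(mrna, 1, cds_end - 60L), substr(mrna, cds_end - 59L, cds_end + 2L),
    substr(mrna, cds_end + 3L, cds_end + 40L),
    substr(mrna, cds_end + 41L, nchar(mrna))))
  res2 <- splice_consequence(exons2, cds_start, cds_end, 3L)
  expect_equal(res2$consequence, "UTR3_DEL")
})

test_that("PTC in the last exon does not predict NMD", {
  # craft a skip whose frameshift stop lands in the final exon: tiny exon 3
  codon_pool <- c("GCT", "GAA", "TGG", "CAT")
  cds <- paste(c(rep(codon_pool, length.out = 30), "TAA"), collapse = "")
  utr5 <- strrep("CT", 10)
  # 3'UTR rich in stop codons in shifted frames is fine; keep simple
  utr3 <- strrep("A", 40)
  mrna <- paste0(utr5, cds, utr3)
  cds_start <- nchar(utr5) + 1L
  cds_end <- nchar(utr5) + nchar(cds)
  b1 <- cds_start + 20L
  b2 <- b1 + 82L  # frameshifting skip of exon 2
  exons <- data.frame(exon_rank = 1:3, exon_seq = c(
    substr(mrna, 1, b1), substr(mrna, b1 + 1, b2),
    substr(mrna, b2 + 1, nchar(mrna))))
  res <- splice_consequence(exons, cds_start, cds_end, 2L)
  if (identical(res$consequence, "PTC") && identical(res$ptc_exon, 2L)) {
    expect_false(res$nmd_predicted)
  }
  orc <- oracle_splice_consequence(exons, cds_start, cds_end, 2L)
  expect_equal(res$consequence, orc$consequence)
})

test_that("consequence classification matches brute-force translation", {
  set.seed(99)
  n_ok <- 0L
  for (i in 1:150) {
    toy <- random_toy_transcript(seed = 1000 + i)
    n_ex <- nrow(toy$exons)
    skip <- (2:(n_ex - 1))[sample.int(n_ex - 2L, 1)]
    res <- splice_consequence(toy$exons, toy$cds_start, toy$cds_end, skip)
    orc <- oracle_splice_consequence(toy$exons, toy$cds_start, toy$cds_end,
                                     skip)
    got <- if (res$flag == "no_stop") "no_stop" else res$consequence
    want <- if (!is.null(orc$flag) && identical(orc$flag, "no_stop"))
      "no_stop" else orc$consequence
    expect_identical(got, want)
    if (identical(res$consequence, "PTC")) {
      expect_equal(res$ptc_exon, orc$ptc_exon)
    }
    n_ok <- n_ok + 1L
  }
  expect_equal(n_ok, 150L)
})

test_that("IFD implies a frame-preserving exon length when fully coding", {
  set.seed(17)
  for (i in 1:60) {
    toy <- random_toy_transcript(seed = 2000 + i)
    n_ex <- nrow(toy$exons)
    skip <- (2:(n_ex - 1))[sample.int(n_ex - 2L, 1)]
    res <- splice_consequence(toy$exons, toy$cds_start, toy$cds_end, skip)
    lens <- nchar(toy$exons$exon_seq)
    ends <- cumsum(lens); starts <- ends - lens + 1L
    fully_coding <- starts[skip] >= toy$cds_start && ends[skip] <= toy$cds_end
    if (identical(res$consequence, "IFD") && fully_coding) {
      expect_equal(lens[skip] %% 3L, 0L)
    }
  }
})

test_that("model errors are rejected", {
  toy <- make_toy(84L)
  expect_error(splice_consequence(toy$exons, toy$cds_start,
                                  toy$cds_end - 1L, 2L), "divisible")
  expect_error(splice_consequence(toy$exons, toy$cds_start, toy$cds_end, 1L),
               "internal")
})

test_that("allele functional labels follow the deleterious-skip rule", {
  expect_equal(allele_functional_class("PTC", TRUE, -20),
               list(ref = "GOF", alt = "LOF"))
  expect_equal(allele_functional_class("PTC", TRUE, +20),
               list(ref = "LOF", alt = "GOF"))
  expect_equal(allele_functional_class("DEL_ATG", FALSE, -10),
               list(ref = "GOF", alt = "LOF"))
  expect_equal(allele_functional_class("IFD", FALSE, -30),
               list(ref = "UNKNOWN", alt = "UNKNOWN"))
  expect_equal(allele_functional_class("UTR3_DEL", FALSE, 15),
               list(ref = "UNKNOWN", alt = "UNKNOWN"))
  # PTC in the last exon: no NMD, not predictable
  expect_equal(allele_functional_class("PTC", FALSE, -20),
               list(ref = "UNKNOWN", alt = "UNKNOWN"))
})

test_that("conservation enrichment matches exact hypergeometric arithmetic", {
  category <- c(rep("LOSS", 50), rep("NEUTRAL", 100))
  conserved <- c(rep(TRUE, 40), rep(FALSE, 10),
                 rep(TRUE, 40), rep(FALSE, 60))
  enr <- gerp_enrichment(category, conserved)
  loss <- enr[enr$category == "LOSS", ]
  expect_equal(loss$fold_change, 2)
  tab <- matrix(c(40, 10, 40, 60), nrow = 2)
  expect_equal(loss$p_value, stats::fisher.test(tab)$p.value)
  # identical proportions: fold change 1, p = 1
  cat2 <- c(rep("GAIN", 40), rep("NEUTRAL", 40))
  cons2 <- rep(c(TRUE, FALSE), 40)
  enr2 <- gerp_enrichment(cat2, cons2)
  gain <- enr2[enr2$category == "GAIN", ]
  expect_equal(gain$fold_change, 1)
  expect_equal(gain$p_value, 1)
  # empty category flagged
  expect_true(enr2[enr2$category == "LOSS", ]$flagged)
  # swapping rows inverts the fold change, p unchanged (Fisher symmetry)
  cat3 <- c(rep("LOSS", 100), rep("NEUTRAL", 50))
  cons3 <- c(rep(TRUE, 40), rep(FALSE, 60), rep(TRUE, 40), rep(FALSE, 10))
  enr3 <- gerp_enrichment(cat3, cons3)
  loss3 <- enr3[enr3$category == "LOSS", ]
  expect_equal(loss3$fold_change, 0.5)
  expect_equal(loss3$p_value, loss$p_value)
})

test_that("rsID colocalization flags exact intersections", {
  sdv <- c("rs1", "RS2", "rs3", "bad_id", "rs10")
  qtl <- list(single_eqtl = c("rs2", "rs99"),
              multi_sqtl = c("rs3", "rs10"),
              empty_src = character(0))
  cc <- colocalize_qtl(sdv, qtl)
  expect_equal(cc$summary$n, 4L)         # malformed id skipped
  expect_equal(cc$summary$n_skipped, 1L)
  expect_equal(cc$summary$n_hit, 3L)
  expect_equal(cc$summary$pct_hit, 75)
  expect_true(cc$flags$single_eqtl[cc$flags$rsid == "rs2"])
  expect_false(any(cc$flags$empty_src))
  # printed-style rate arithmetic
  expect_equal(call_rate_pct(27, 38), 71.1)
})
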