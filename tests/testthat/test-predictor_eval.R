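test_that("score harmonisation follows the 4-class and signed conventions", {
  s <- data.frame(variant_id = c("v1", "v2", "v3"), tool = "spliceai",
                  acceptor_gain = c(0.1, 0, 0.3),
                  acceptor_loss = c(0.7, 0, 0.1),
                  donor_gain = c(0.0, 0, 0.2),
                  donor_loss = c(0.2, 0, 0.1))
  h <- harmonize_scores(s)
  expect_equal(h$harmonized_signed, c(-0.7, 0, 0.3))
  expect_equal(h$harmonized_abs, c(0.7, 0, 0.3))
  expect_equal(h$harmonized_abs, abs(h$harmonized_signed))
  # signed-score tool
  s2 <- data.frame(variant_id = "v4", tool = "pangolin",
                   signed_score = -0.44)
  h2 <- harmonize_scores(s2)
  expect_equal(h2$harmonized_abs, 0.44)
  expect_true(score_predicted(h2$harmonized_abs, 0.2))
  expect_false(score_predicted(h2$harmonized_abs, 0.5))
  # all-zero scores are not predicted at any regime
  expect_false(any(score_predicted(h$harmonized_abs[2], c(0.2, 0.5, 0.8))))
  # out-of-range inputs rejected with the variant id
  bad <- s; bad$acceptor_gain[1] <- 1.2
  expect_error(harmonize_scores(bad), "v1")
  bad2 <- s2; bad2$signed_score <- -1.5
  expect_error(harmonize_scores(bad2), "v4")
})

test_that("gene models convert to a predictor annotation table", {
  ex <- data.frame(
    gene_id = rep(c("G1", "G2"), c(3, 4)),
    transcript_id = rep(c("T1", "T2"), c(3, 4)),
    exon_rank = c(1:3, 1:4),
    chrom = c(rep("chr1", 3), rep("chr2", 4)),
    start = c(100, 300, 500, 4000, 3000, 2000, 1000),
    end = c(150, 350, 550, 4100, 3100, 2100, 1100),
    strand = c(rep("+", 3), rep("-", 4)))
  ann <- convert_gtf_to_predictor_annotation(ex)
  g1 <- ann$genes[ann$genes$name == "G1", ]
  expect_equal(g1$exon_starts, "100,300,500")
  expect_equal(g1$exon_ends, "150,350,550")
  # minus-strand gene still reported in ascending genomic order
  g2 <- ann$genes[ann$genes$name == "G2", ]
  expect_equal(g2$strand, "-")
  expect_equal(g2$exon_starts, "1000,2000,3000,4000")
  expect_equal(g2$tx_start, 1000)
  expect_equal(g2$tx_end, 4100)
  # without canonical tags the full table doubles as the canonical one
  expect_equal(ann$canonical, ann$genes)
  # canonical tag restricts the second table
  ex$canonical <- ex$transcript_id == "T1"
  ann2 <- convert_gtf_to_predictor_annotation(ex)
  expect_equal(ann2$canonical$name, "G1")
  # writer round-trip
  f <- tempfile(fileext = ".txt")
  write_predictor_annotation(ann$genes, f)
  lines <- readLines(f)
  expect_match(lines[1], "^#NAME\t")
  expect_equal(length(lines), 3L)
})

test_that("gtf round trip through rtracklayer preserves the annotation", {
  d <- tiny_design()
  gtf <- tempfile(fileext = ".gtf")
  fa <- tempfile(fileext = ".fa")
  write_gene_models(d$models, gtf, fa)
  ann_file <- convert_gtf_to_predictor_annotation(gtf)
  ann_mem <- convert_gtf_to_predictor_annotation(d$models$exons)
  expect_equal(ann_file$genes[order(ann_file$genes$name), ],
               ann_mem$genes[order(ann_mem$genes$name), ])
})

test_that("TP/TN rates by bin match exact counting", {
  score <- c(0.9, 0.85, 0.95, 0.3, 0.25, 0.1, 0.05, 0.5)
  pos <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  tb <- tp_tn_by_bin(score, pos)
  top <- tb[as.character(tb$bin) == "[0.8,1]", ]
  expect_equal(top$n, 3L)
  expect_equal(top$tp_rate, 1)
  low <- tb[grepl("^\\[0,", as.character(tb$bin)), ]
  expect_equal(low$n, 2L)
  expect_equal(low$tn_rate, 1)
  # scores independent of labels: TP rate in each occupied bin close to the
  # base rate (binomial sampling error)
  set.seed(12)
  n <- 4000
  sc <- stats::runif(n)
  lb <- stats::runif(n) < 0.3
  tb2 <- tp_tn_by_bin(sc, lb)
  occ <- tb2[tb2$n > 200, ]
  expect_true(all(abs(occ$tp_rate - 0.3) < 3 * sqrt(0.3 * 0.7 / occ$n) + 0.02))
  # empty bin flagged
  tb3 <- tp_tn_by_bin(c(0.1, 0.15), c(TRUE, FALSE))
  expect_true(any(tb3$empty))
  expect_true(all(is.na(tb3$tp_rate[tb3$empty])))
})

test_that("AUC equals the exhaustive pairwise-concordance oracle", {
  oracle <- function(score, pos) {
    ps <- score[pos]; ns <- score[!pos]
    tot <- 0
    for (p in ps) tot <- tot + sum(p > ns) + 0.5 * sum(p == ns)
    tot / (length(ps) * length(ns))
  }
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  set.seed(31)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    score <- round(stats::runif(n), sample(c(1, 2), 1))  # force ties often
    pos <- stats::runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    expect_equal(roc_auc(score, pos)$auc, oracle(score, pos))
  }
  # cross-check against an established ROC implementation
  set.seed(32)
  score <- stats::runif(200)
  pos <- stats::runif(200) < 0.4
  expect_equal(roc_auc(score, pos)$auc,
               as.numeric(pROC::auc(pROC::roc(
                 pos, score, quiet = TRUE,
                 levels = c(FALSE, TRUE), direction = "<"))))
  # invariance under strictly monotone transforms; null expectation ~ 0.5
  expect_equal(roc_auc(score^3, pos)$auc, roc_auc(score, pos)$auc)
  expect_lt(abs(roc_auc(score, pos)$auc - 0.5), 0.1)
  expect_error(roc_auc(score, rep(TRUE, 200)), "both classes")
})

test_that("ROC points are monotone in both coordinates", {
  set.seed(8)
  r <- roc_auc(sample(seq(0, 1, 0.05), 100, replace = TRUE),
               stats::runif(100) < 0.5)$roc
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
})

test_that("threshold scan counts follow the construction", {
  # engineered set: at t = 0.1 exactly 11 predicted positives, 6 of them
  # false, mirroring a sub-threshold screen
  score <- c(rep(0.15, 5), rep(0.12, 6), rep(0.05, 20))
  pos <- c(rep(TRUE, 5), rep(FALSE, 6), rep(c(TRUE, FALSE), 10))
  sc <- threshold_scan(score, pos, thresholds = c(0, 0.1, 0.2))
  at01 <- sc[sc$threshold == 0.1, ]
  expect_equal(at01$n_predicted, 11L)
  expect_equal(at01$fp, 6L)
  expect_equal(at01$tp, 5L)
  at0 <- sc[sc$threshold == 0, ]
  expect_equal(at0$sensitivity, 1)
  expect_equal(at0$n_predicted, 31L)
  above <- threshold_scan(score, pos, thresholds = 0.16)
  expect_equal(above$sensitivity, 0)
  # monotone predicted-positive count
  full <- threshold_scan(score, pos)
  expect_true(all(diff(full$n_predicted) <= 0))
})

test_that("positive-set summaries reproduce printed-percentage arithmetic", {
  score <- c(rep(0.5, 17), rep(0.05, 7))
  group <- rep("in_vivo", 24)
  ps <- positive_set_summary(score, group, regime = 0.2)
  expect_equal(ps$n, 24L)
  expect_equal(ps$n_predicted, 17L)
  expect_equal(ps$pct_predicted, 70.8)
  zero <- positive_set_summary(rep(0.01, 5), rep("g", 5))
  expect_equal(zero$pct_predicted, 0)
  expect_equal(call_rate_pct(15, 17), 88.2)
  expect_equal(call_rate_pct(2, 7), 28.6)
})

test_that("balanced subset selection fills score bins evenly", {
  set.seed(5)
  # at least 30 candidates in every score bin
  edges <- c(0, 0.02, 0.2, 0.5, 0.8, 1)
  sc <- unlist(lapply(seq_len(5), function(i) {
    stats::runif(120, edges[i] + 1e-6, edges[i + 1] - 1e-6)
  }))
  pool <- data.frame(variant_id = sprintf("v%04d", seq_along(sc)),
                     harmonized_abs = sc)
  sel <- select_balanced_set(pool, 146, seed = 3)
  expect_equal(nrow(sel), 146L)
  q <- attr(sel, "quota")
  expect_true(max(q$selected) - min(q$selected) <= 1)
  # identity when the target covers the pool
  expect_equal(nrow(select_balanced_set(pool, nrow(pool))), nrow(pool))
  # an empty bin redistributes its quota
  pool2 <- pool[pool$harmonized_abs > 0.2, ]
  sel2 <- select_balanced_set(pool2, 100, seed = 3)
  expect_equal(nrow(sel2), 100L)
  q2 <- attr(sel2, "quota")
  expect_true(all(q2$selected[q2$available == 0] == 0L))
  # determinism
  expect_equal(select_balanced_set(pool, 146, seed = 3)$variant_id,
               sel$variant_id)
})
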