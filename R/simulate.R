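# ---------------------------------------------------------------------------
# Synthetic-data generators. Every input the pipeline consumes can be
# simulated with known ground truth: gene models + genome, SNPs with planted
# PSI effects, plasmid-library reads with planted QC failures, reporter
# RNA-seq read pairs with UMI duplication and sequencing error, predictor
# scores with a target rank correlation to the true effect, and GWAS summary
# statistics with planted QTL peaks. All generators are deterministic for a
# given seed.
# ---------------------------------------------------------------------------

#' Simulate gene models and a matching genome
#'
#' One gene per chromosome, 4-7 exons by default; internal exons are drawn
#' mostly in the 13-98 nt band eligible for the reporter design (a minority
#' deliberately exceed it so selection filters are exercised), introns are
#' long enough for the 50/20-nt flanks, and roughly half the genes are on
#' the minus strand.
#'
#' @param n_genes number of genes (default 10).
#' @param exons_per_gene integer range, inclusive (default c(4, 7)).
#' @param internal_exon_range eligible internal exon lengths (default
#'   c(13, 98)).
#' @param p_oversize probability an internal exon is drawn over-length
#'   (default 0.08).
#' @param intron_range intron length range (default c(100, 300)).
#' @param terminal_exon_range terminal exon lengths (default c(60, 200)).
#' @param seed integer seed.
#' @return list with `exons` (gene-model table usable by
#'   [select_test_regions()]) and `genome` (named character vector).
#' @export
sim_gene_models <- function(n_genes = 10L, exons_per_gene = c(4L, 7L),
                            internal_exon_range = c(13L, 98L),
                            p_oversize = 0.08, intron_range = c(100L, 300L),
                            terminal_exon_range = c(60L, 200L), seed = 1L) {
  if (internal_exon_range[1] > internal_exon_range[2] ||
      intron_range[1] < 60L) {
    stop("config error: invalid length configuration")
  }
  set.seed(seed)
  genome <- character(n_genes)
  names(genome) <- paste0("chr", seq_len(n_genes))
  exon_rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    n_ex <- sample(exons_per_gene[1]:exons_per_gene[2], 1L)
    lens <- integer(n_ex)
    lens[c(1L, n_ex)] <- sample(terminal_exon_range[1]:terminal_exon_range[2],
                                2L, replace = TRUE)
    for (i in seq_len(n_ex)[-c(1L, n_ex)]) {
      lens[i] <- if (stats::runif(1) < p_oversize) {
        sample((internal_exon_range[2] + 1L):(internal_exon_range[2] + 60L), 1L)
      } else {
        sample(internal_exon_range[1]:internal_exon_range[2], 1L)
      }
    }
    introns <- sample(intron_range[1]:intron_range[2], n_ex - 1L,
                      replace = TRUE)
    pad <- 120L
    starts <- integer(n_ex)
    pos <- pad + 1L
    for (i in seq_len(n_ex)) {
      starts[i] <- pos
      pos <- pos + lens[i] + if (i < n_ex) introns[i] else 0L
    }
    ends <- starts + lens - 1L
    chr_len <- ends[n_ex] + pad
    genome[g] <- random_dna(1L, chr_len)
    strand <- sample(c("+", "-"), 1L)
    rank <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    exon_rows[[g]] <- data.table::data.table(
      gene_id = sprintf("GENE%03d", g),
      transcript_id = sprintf("TX%03d", g),
      exon_rank = rank, chrom = names(genome)[g],
      start = starts, end = ends, strand = strand)
  }
  list(exons = data.table::rbindlist(exon_rows), genome = genome)
}

#' Write simulated gene models / genome to GTF and FASTA
#'
#' @param models list from [sim_gene_models()].
#' @param gtf,fasta output paths.
#' @export
write_gene_models <- function(models, gtf, fasta) {
  ex <- as_dt(models$exons)
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(ex$start, ex$end),
    strand = ex$strand)
  gr$type <- "exon"
  gr$gene_id <- ex$gene_id
  gr$transcript_id <- ex$transcript_id
  gr$exon_number <- as.character(ex$exon_rank)
  rtracklayer::export(gr, gtf, format = "gtf")
  seqs <- Biostrings::DNAStringSet(models$genome)
  Biostrings::writeXStringSet(seqs, fasta)
  invisible(list(gtf = gtf, fasta = fasta))
}

#' Simulate biallelic SNPs inside test regions, with planted PSI truth
#'
#' Each selected region receives one SNP placed uniformly inside its test
#' sequence. A fraction of variants are true SDV with |delta-PSI| drawn from
#' `effect_range` (random sign, truncated so PSI stays in [0, 100]); the
#' rest have exactly zero true effect. REF-allele PSI is uniform on
#' `psi_ref_range`.
#'
#' @param regions test-region table from [select_test_regions()].
#' @param genome genome used for the regions (for REF alleles).
#' @param fraction_sdv fraction of variants with a true effect (default 0.2).
#' @param effect_range magnitude range of true |delta-PSI| (default
#'   c(10, 50)).
#' @param psi_ref_range range of true REF PSI (default c(30, 90)).
#' @param n_variants optional cap on the number of regions used.
#' @param seed integer seed.
#' @return list with `variants` (chrom, pos, ref, alt, variant_id) and
#'   `truth` (variant_id, region_id, true_psi_ref, true_psi_alt,
#'   true_delta_psi, is_sdv).
#' @export
sim_variants <- function(regions, genome, fraction_sdv = 0.2,
                         effect_range = c(10, 50),
                         psi_ref_range = c(30, 90), n_variants = NULL,
                         seed = 1L) {
  set.seed(seed)
  regions <- as_dt(regions)
  genome <- load_genome(genome)
  if (!is.null(n_variants)) {
    regions <- regions[seq_len(min(n_variants, nrow(regions)))]
  }
  n <- nrow(regions)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    r <- regions[i]
    flank_up <- nchar(r$upstream_flank)
    span_lo <- if (r$strand == "+") r$start - flank_up else
      r$start - nchar(r$downstream_flank)
    span_hi <- span_lo + nchar(r$test_sequence) - 1L
    repeat {
      pos <- sample(span_lo:span_hi, 1L)
      ref <- substr(genome[[r$chrom]], pos, pos)
      alt <- sample(setdiff(DNA_BASES, ref), 1L)
      # keep the ALT test sequence free of new restriction sites
      off <- if (r$strand == "+") pos - span_lo + 1L else span_hi - pos + 1L
      alt_t <- if (r$strand == "+") alt else comp[[alt]]
      s <- r$test_sequence
      substr(s, off, off) <- alt_t
      if (!has_restriction_site(s)) break
    }
    rows[[i]] <- data.table::data.table(
      chrom = r$chrom, pos = pos, ref = ref, alt = alt,
      variant_id = sprintf("rs%07d", i), region_id = r$region_id)
  }
  variants <- data.table::rbindlist(rows)
  truth <- variants[, .(variant_id, region_id)]
  truth[, true_psi_ref := stats::runif(.N, psi_ref_range[1], psi_ref_range[2])]
  sdv <- stats::runif(n) < fraction_sdv
  eff <- stats::runif(n, effect_range[1], effect_range[2]) *
    sample(c(-1, 1), n, replace = TRUE)
  eff[!sdv] <- 0
  alt_psi <- pmin(100, pmax(0, truth$true_psi_ref + eff))
  truth[, true_psi_alt := alt_psi]
  truth[, true_delta_psi := true_psi_alt - true_psi_ref]
  truth[, is_sdv := abs(true_delta_psi) >= 5]
  list(variants = variants[, .(chrom, pos, ref, alt, variant_id)],
       truth = truth)
}

#' Write variants as a minimal VCF
#' @param variants table with `chrom, pos, ref, alt, variant_id`.
#' @param path output path.
#' @export
write_variants_vcf <- function(variants, path) {
  v <- as_dt(variants)
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                  v$chrom, v$pos, v$variant_id, v$ref, v$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF of biallelic SNPs into the variant table used by the package
#' @param path VCF path.
#' @export
read_variants_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  f <- data.table::fread(text = lines, header = FALSE, sep = "\t")
  data.table::data.table(chrom = as.character(f$V1), pos = as.integer(f$V2),
                         ref = as.character(f$V4), alt = as.character(f$V5),
                         variant_id = as.character(f$V3))
}

# error injection: substitute bases i.i.d. at `rate`; returns mutated strings
inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
    }
  }
  seqs
}

#' Simulate reporter RNA-seq read pairs for one replicate
#'
#' Per barcode, the molecule count is Poisson(`depth`); each molecule is an
#' inclusion with probability true PSI / 100, carries a fresh random 10-nt
#' UMI and is sequenced `1 + Geometric(umi_dup_rate)` times. Base-call
#' errors are i.i.d. at `seq_error_rate`. Read 1 is the first 75 nt of the
#' cDNA; read 2 is the UMI followed by the reverse complement of the cDNA
#' 3' end (which ends with the barcode).
#'
#' @param manifest pool manifest (REF and ALT constructs).
#' @param truth truth table from [sim_variants()] (per-variant true PSI).
#' @param depth expected molecules per barcode (default 500).
#' @param umi_dup_rate geometric duplication parameter in [0, 1)
#'   (default 0.1).
#' @param seq_error_rate per-base substitution rate (default 0.001).
#' @param seed integer seed.
#' @return list with `reads` (data.table `r1, r2`) and `molecule_truth`
#'   (per-barcode true molecule and inclusion counts).
#' @export
sim_reporter_reads <- function(manifest, truth, depth = 500,
                               umi_dup_rate = 0.1, seq_error_rate = 0.001,
                               seed = 1L) {
  stopifnot(depth >= 1)
  set.seed(seed)
  manifest <- as_dt(manifest)
  truth <- as_dt(truth)
  m <- truth[, .(variant_id, true_psi_ref, true_psi_alt)][
    manifest, on = "variant_id"]
  m[, true_psi := data.table::fifelse(allele == "REF", true_psi_ref,
                                      true_psi_alt)]
  m[, n_mol := stats::rpois(.N, depth)]
  m[, n_inc := stats::rbinom(.N, n_mol, true_psi / 100)]

  # expand to molecules
  mol <- m[, {
    if (n_mol == 0L) NULL else data.table::data.table(
      included = seq_len(n_mol) <= n_inc)
  }, by = .(barcode, exon_seq)]
  mol[, umi := random_dna(.N, UMI_LENGTH)]
  # duplicate reads per molecule
  dup <- 1L + stats::rgeom(nrow(mol), prob = 1 - umi_dup_rate)
  reads <- mol[rep(seq_len(nrow(mol)), dup)]

  cdna <- paste0(REPORTER_EXON1,
                 data.table::fifelse(reads$included, reads$exon_seq, ""),
                 REPORTER_EXON3, reads$barcode)
  len <- nchar(cdna)
  r1 <- substr(cdna, 1L, pmin(R1_LENGTH, len))
  tail_len <- pmin(R2_LENGTH - UMI_LENGTH, len)
  r2_body <- revcomp(substr(cdna, len - tail_len + 1L, len))
  r1 <- inject_errors(r1, seq_error_rate)
  r2_body <- inject_errors(r2_body, seq_error_rate)
  out <- data.table::data.table(r1 = r1, r2 = paste0(reads$umi, r2_body))
  mt <- mol[, .(n_molecules = .N, n_included = sum(included)), by = barcode]
  list(reads = out, molecule_truth = mt)
}

#' Simulate per-barcode molecule counts without read sequences
#'
#' Count-level shortcut emulating the deduplicated output of the read path:
#' inclusion/exclusion molecule tallies per barcode drawn from the same
#' Poisson-binomial model as [sim_reporter_reads()]. Used for large
#' simulation studies (e.g. null calibrations) where the nucleotide-level
#' path would add nothing but runtime.
#'
#' @inheritParams sim_reporter_reads
#' @return data.table `barcode, inclusion, exclusion` per barcode.
#' @export
sim_molecule_counts <- function(manifest, truth, depth = 500, seed = 1L) {
  set.seed(seed)
  manifest <- as_dt(manifest)
  truth <- as_dt(truth)
  m <- truth[, .(variant_id, true_psi_ref, true_psi_alt)][
    manifest, on = "variant_id"]
  m[, true_psi := data.table::fifelse(allele == "REF", true_psi_ref,
                                      true_psi_alt)]
  m[, n_mol := stats::rpois(.N, depth)]
  m[, inclusion := stats::rbinom(.N, n_mol, true_psi / 100)]
  m[, .(barcode, inclusion, exclusion = n_mol - inclusion)]
}

#' Simulate plasmid-library reads with planted QC failure modes
#'
#' Each construct is assigned a planted status: a fraction are absent from
#' PL1, a fraction carry a synthesised barcode mutation (every PL1/PL2 read
#' shows the mutated barcode), a fraction have low-fidelity inserts (a
#' per-read probability of insert error chosen to push the correct-read
#' fraction below the QC cutoff), and a fraction are absent from PL2; the
#' rest are clean. Reads are 150-nt pairs from the construct ends.
#'
#' @param pool manifest from [assemble_pool()].
#' @param reads_per_bc PL1/PL2 read pairs per construct (default 50).
#' @param p_absent_pl1,p_bc_mutated,p_low_fidelity,p_absent_pl2 planted
#'   failure fractions (defaults 0.02 each).
#' @param low_fidelity_error_frac per-read probability of a (single-base)
#'   insert error for low-fidelity constructs (default 0.5, well below the
#'   0.85 correct-read cutoff).
#' @param seed integer seed.
#' @return list with `pl1`, `pl2` read tables (`r1, r2`) and `truth`
#'   (barcode, planted status).
#' @export
sim_library_reads <- function(pool, reads_per_bc = 50L,
                              p_absent_pl1 = 0.02, p_bc_mutated = 0.02,
                              p_low_fidelity = 0.02, p_absent_pl2 = 0.02,
                              low_fidelity_error_frac = 0.5, seed = 1L) {
  set.seed(seed)
  pool <- as_dt(pool)
  n <- nrow(pool)
  status <- sample(
    c("ABSENT_PL1", "BC_MUTATED", "LOW_FIDELITY", "ABSENT_PL2", "VALID"),
    n, replace = TRUE,
    prob = c(p_absent_pl1, p_bc_mutated, p_low_fidelity, p_absent_pl2,
             1 - p_absent_pl1 - p_bc_mutated - p_low_fidelity - p_absent_pl2))
  truth <- data.table::data.table(barcode = pool$barcode,
                                  construct_id = pool$construct_id,
                                  status = status)

  span <- barcode_span_from_end(nchar(pool$barcode[1]))
  make_reads <- function(i, run) {
    st <- status[i]
    if (st == "ABSENT_PL1" && run == "PL1") return(NULL)
    if (st == "ABSENT_PL2" && run == "PL2") return(NULL)
    full <- pool$full_sequence[i]
    len <- nchar(full)
    if (st == "BC_MUTATED") {
      # a synthesis error: one fixed substitution inside the barcode,
      # carried by every copy of the construct
      p <- len - sample(span[1]:span[2], 1L) + 1L
      old <- substr(full, p, p)
      substr(full, p, p) <- sample(setdiff(DNA_BASES, old), 1L)
    }
    k <- reads_per_bc
    seqs <- rep(full, k)
    if (st == "LOW_FIDELITY" && run == "PL1") {
      hit <- stats::runif(k) < low_fidelity_error_frac
      for (j in which(hit)) {
        # error inside the test sequence (outside barcode and flanks)
        p <- sample((nchar(OLIGO_FLANK5) + 1L):(len - span[2] - 1L), 1L)
        old <- substr(seqs[j], p, p)
        substr(seqs[j], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
      }
    }
    lens <- nchar(seqs)
    data.table::data.table(
      r1 = substr(seqs, 1L, pmin(PL_READ_LENGTH, lens)),
      r2 = revcomp(substr(seqs, pmax(1L, lens - PL_READ_LENGTH + 1L), lens)))
  }

  pl1 <- data.table::rbindlist(lapply(seq_len(n), make_reads, run = "PL1"))
  pl2 <- data.table::rbindlist(lapply(seq_len(n), make_reads, run = "PL2"))
  list(pl1 = pl1, pl2 = pl2, truth = truth)
}

#' Simulate predictor scores with a target rank correlation to the truth
#'
#' Generates a harmonised absolute score in [0, 1] whose Spearman
#' correlation with |true delta-PSI| is approximately `rho` (Gaussian copula
#' construction), and decomposes it into the four-class representation:
#' variants whose true effect decreases inclusion load the loss classes,
#' gains load the gain classes.
#'
#' @param truth truth table from [sim_variants()].
#' @param rho target Spearman correlation (default 0.7).
#' @param tool tool label (default "simtool").
#' @param seed integer seed.
#' @return data.table of raw scores: `variant_id, tool, acceptor_gain,
#'   acceptor_loss, donor_gain, donor_loss, signed_score`.
#' @export
sim_predictor_scores <- function(truth, rho = 0.7, tool = "simtool",
                                 seed = 1L) {
  set.seed(seed)
  truth <- as_dt(truth)
  n <- nrow(truth)
  target <- abs(truth$true_delta_psi)
  # Gaussian copula on mid-ranks, with the mixing weight calibrated
  # numerically so the realised Spearman correlation hits the target even
  # when many variants are tied at zero effect
  r_mid <- rank(target)  # average ranks for ties
  z1 <- stats::qnorm((r_mid - 0.5) / n)
  eps <- matrix(stats::rnorm(n * 9L), n, 9L)
  if (stats::sd(z1) == 0 || rho <= 0) {
    z2 <- eps[, 1L]
  } else {
    spearman_at <- function(w) {
      mean(vapply(2:9, function(j) {
        stats::cor(rank(w * z1 + sqrt(1 - w^2) * eps[, j]), r_mid)
      }, numeric(1)))
    }
    w <- tryCatch(
      stats::uniroot(function(w) spearman_at(w) - rho,
                     lower = 0.01, upper = 0.999, tol = 1e-3)$root,
      error = function(e) 2 * sin(pi * rho / 6))
    z2 <- w * z1 + sqrt(1 - w^2) * eps[, 1L]
  }
  score_abs <- (rank(z2, ties.method = "first") - 0.5) / n
  sign <- ifelse(truth$true_delta_psi < 0, -1, 1)
  sign[truth$true_delta_psi == 0] <- sample(c(-1, 1), sum(truth$true_delta_psi == 0),
                                            replace = TRUE)
  out <- data.table::data.table(
    variant_id = truth$variant_id, tool = tool,
    acceptor_gain = 0, acceptor_loss = 0, donor_gain = 0, donor_loss = 0,
    signed_score = sign * score_abs)
  loss <- sign < 0
  donor <- stats::runif(n) < 0.5
  out[loss & donor, donor_loss := score_abs[loss & donor]]
  out[loss & !donor, acceptor_loss := score_abs[loss & !donor]]
  out[!loss & donor, donor_gain := score_abs[!loss & donor]]
  out[!loss & !donor, acceptor_gain := score_abs[!loss & !donor]]
  out
}

#' Simulate GWAS summary statistics with planted QTL peaks
#'
#' Background variants receive -log10 p-values from the uniform null; each
#' planted QTL has a lead variant with a large -log10 p and neighbours whose
#' significance decays with distance from the lead (exponential kernel),
#' emulating local LD structure. Peaks are compact by construction: member
#' significance stays in the upper third of the peak and above the
#' genome-wide floor, so the planted interval is well defined.
#'
#' @param n_variants background variants per chromosome (default 2000).
#' @param n_chrom chromosomes (default 5).
#' @param n_qtl planted QTL (default 4; at most one per chromosome).
#' @param chrom_length chromosome length in bp (default 10 Mb).
#' @param lead_neglogp_range -log10 p of planted leads (default c(9.5, 15)).
#' @param ld_scale decay scale of the peak in bp (default 3e5).
#' @param n_peak_members variants per planted peak (default 30).
#' @param seed integer seed.
#' @return list with `summary` (GWAS summary table: chrom, pos, ref, alt,
#'   rsid, maf, neg_log10_p, imputation_r2, trait, breed) and `truth`
#'   (per planted QTL: chrom, lead position, truth interval spanned by
#'   members in the upper third of the peak).
#' @export
sim_gwas_summary <- function(n_variants = 2000L, n_chrom = 5L, n_qtl = 4L,
                             chrom_length = 1e7,
                             lead_neglogp_range = c(9.5, 15),
                             ld_scale = 3e5, n_peak_members = 30L, seed = 1L) {
  stopifnot(n_qtl <= n_chrom)
  set.seed(seed)
  rows <- vector("list", n_chrom)
  truth <- vector("list", n_qtl)
  qtl_chroms <- sample(seq_len(n_chrom), n_qtl)
  for (ch in seq_len(n_chrom)) {
    chrom <- paste0("chr", ch)
    pos <- sort(sample.int(chrom_length, n_variants))
    nlp <- -log10(stats::runif(n_variants))
    dt <- data.table::data.table(chrom = chrom, pos = pos, neg_log10_p = nlp)
    if (ch %in% qtl_chroms) {
      lead_pos <- sample.int(chrom_length - 2e6, 1L) + 1e6
      lead_nlp <- stats::runif(1, lead_neglogp_range[1], lead_neglogp_range[2])
      # members confined to the distance at which the exponential decay
      # (with a little jitter) still keeps them in the upper third
      off <- round(stats::runif(n_peak_members, -0.9, 0.9) *
                     ld_scale * log(1.5))
      mem_pos <- pmax(1, pmin(chrom_length, lead_pos + off))
      mem_nlp <- lead_nlp * exp(-abs(mem_pos - lead_pos) / ld_scale) *
        stats::runif(length(mem_pos), 0.97, 1)
      peak <- data.table::data.table(chrom = chrom,
                                     pos = c(lead_pos, mem_pos),
                                     neg_log10_p = c(lead_nlp, mem_nlp))
      dt <- rbind(dt, peak)
      # truth interval: members in the upper third of the peak above the
      # genome-wide floor (by construction, all of them)
      in_third <- peak$neg_log10_p >= (2 / 3) * lead_nlp &
        peak$neg_log10_p > 6 & abs(peak$pos - lead_pos) <= 2e6
      truth[[which(qtl_chroms == ch)]] <- data.table::data.table(
        chrom = chrom, lead_pos = lead_pos, lead_neg_log10_p = lead_nlp,
        ci_start = min(peak$pos[in_third]), ci_end = max(peak$pos[in_third]))
    }
    rows[[ch]] <- dt
  }
  summ <- data.table::rbindlist(rows)
  data.table::setorder(summ, chrom, pos)
  n <- nrow(summ)
  summ[, `:=`(ref = sample(DNA_BASES, n, replace = TRUE))]
  summ[, alt := vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L),
                       character(1))]
  summ[, rsid := sprintf("rs%08d", sample.int(9e7, n))]
  summ[, maf := stats::runif(n, 0.005, 0.5)]
  summ[, imputation_r2 := stats::rbeta(n, 8, 2)]
  summ[, trait := "trait1"]
  summ[, breed := "breedA"]
  list(summary = summ[], truth = data.table::rbindlist(truth))
}

#' Write reporter reads as paired FASTQ files
#'
#' @param reads data.table with `r1, r2`.
#' @param r1_path,r2_path output FASTQ paths.
#' @param quality_char constant base quality (default "I").
#' @export
write_fastq_pair <- function(reads, r1_path, r2_path, quality_char = "I") {
  wr <- function(seqs, path) {
    ids <- sprintf("read%07d", seq_along(seqs))
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    q <- Biostrings::BStringSet(strrep(quality_char, nchar(seqs)))
    qs <- Biostrings::QualityScaledDNAStringSet(
      x, Biostrings::PhredQuality(q))
    Biostrings::writeQualityScaledXStringSet(qs, path)
  }
  wr(reads$r1, r1_path)
  wr(reads$r2, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ files into the read table used by the quantifier
#' @param r1_path,r2_path FASTQ paths.
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  data.table::data.table(r1 = as.character(r1), r2 = as.character(r2))
}
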