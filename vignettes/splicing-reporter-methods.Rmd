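---
title: "Models and methods behind spliceMPRA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spliceMPRA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceMPRA)
```

# The assay model

A splicing reporter pool interrogates one internal exon per construct. The
test sequence is the exon (13–98 nt) plus 50 nt of its upstream intron and
20 nt of its downstream intron, cloned between two constant reporter exons.
The synthesized oligo is

```
5'-CTGACTCTCTCTGCCTC | upstream(50) exon downstream(20) | barcode |
   CAATTGACTACTAGT | TCTAGAGGGCCCGTTTA-3'
```

The middle linker carries the MfeI (`CAATTG`) and SpeI (`ACTAGT`) cloning
sites; consequently no other copy of either site may occur anywhere in a
construct, which excludes both test regions that contain one and variants
whose ALT allele creates one. First and last exons cannot be assayed (they
lack one splice site), and fixed-length flanks mean a region is skipped —
not truncated — when a flank would run into a neighbouring exon.

Each variant is represented by REF and ALT constructs carrying the same
test region, differing at exactly one base, each with 4 unique barcodes.
Barcodes (default 12 nt, pairwise Hamming distance ≥ 3, no cloning-site
motif, no homopolymer ≥ 5) are placed 3′ of the downstream intronic flank,
adjacent to the linker, so the splicing signals of the exon and its
proximal flanks are untouched; the exact barcode position and length are a
package choice recorded in the design configuration, since only the
invariant segments are fixed by the assay chemistry.

## Quantification

Sequencing reads are structured as in the assay: read 1 (75 nt) covers the
5′ reporter junction; read 2 (225 nt) starts with a 10-nt UMI and reads the
reverse strand across the barcode and the 3′ junction. A read pair is
assigned to a barcode exactly or by unique 1-mismatch rescue (ambiguous
rescues are discarded). Junction classification compares `k = 8` bases on
each side of each junction with the exon-included and exon-skipped
reference forms; single-sided support suffices, conflicting or absent
support is AMBIGUOUS. Reads sharing a barcode and UMI collapse to one
molecule whose class is the majority vote (ties → AMBIGUOUS). Per barcode,

$$\mathrm{PSI} = 100 \cdot \frac{I}{I + E},$$

with AMBIGUOUS molecules excluded from the denominator; barcodes with fewer
than 10 informative molecules are dropped rather than reported as PSI 0.
The 10-molecule floor is applied after UMI deduplication — molecules, not
raw reads, are the robust unit (a `min_reads` argument exposes the knob).

A variant is evaluable when each allele keeps ≥ 2 expressed barcodes in
every replicate and at least one allele has PSI > 0; otherwise it is
flagged NOT_EVALUABLE with a reason, never silently dropped. The reported
PSI per allele is the mean over surviving barcodes pooled across
replicates, and ΔPSI = PSI(ALT) − PSI(REF).

## SDV calling

Per-barcode PSI values, pooled across the transfection replicates (up to 12
observations per allele), are compared between alleles with a two-tailed
Welch t-test: barcodes are the biological replication unit, and Welch's
form tolerates the unequal barcode counts left after QC. P-values from all
evaluable variants of one cell line are adjusted jointly by
Benjamini–Hochberg. A variant is a splicing LOSS when ΔPSI ≤ −5 and
FDR < regime (0.05 or 0.01), a GAIN when ΔPSI ≥ +5, otherwise NEUTRAL.
Degenerate t-tests are handled explicitly: two zero-variance samples with
equal means give p = 1; with unequal means the smallest representable
double, flagged.

## Library QC

Plasmid-library read pairs (150 nt from each construct end) are matched to
the design by deterministic string comparison — the inserts are short and
fully known, so alignment would only add version-dependent
nondeterminism. A "correct" read pair reconstructs the designed insert
exactly (barcode positions masked; a `max_mismatches` budget, default 0,
allows relaxation), and pairs disagreeing in their mate overlap are
counted separately as conflicting. Barcode statuses are assigned in a
fixed filter order, first failure winning: absent from the first library
(PL1); never observed without mutation (a barcode seen only via mismatched
copies is treated as synthesized wrong); < 85 % correct PL1 reads; absent
from the final library (PL2). Survivors form the whitelist.

# Predictor benchmarking

Four-class splice scores (acceptor/donor × gain/loss, each in [0, 1])
collapse to a single per-variant score: the maximum class score, negated
when the maximum is a loss class (loss wins ties — the conservative
direction). Signed single-score tools pass through; `harmonized_abs` is
always the absolute value. Benchmark labels are *spliceogenic vs not*,
ignoring direction, because a predicted gain (e.g. a cryptic-site
creation) can manifest as exon exclusion in the reporter.

ROC curves group tied scores into single steps and the trapezoid AUC then
equals the Mann–Whitney pairwise-concordance statistic — an identity the
test-suite verifies exhaustively against brute-force pair counting on
instances of n ≤ 30. Threshold scans below the 0.2 high-recall cutoff
report confusion counts, sensitivity, specificity and accuracy per
threshold, with the predicted-positive count non-increasing in the
threshold. Group summaries report predicted-positive percentages at one
decimal. The balanced-subset selector stratifies a candidate pool over
absolute-score bins (default edges 0, 0.02, 0.2, 0.5, 0.8, 1) by
water-filling, so shortfalls in sparse bins flow to the others.

# Consequence classification

Skipping the test exon from its transcript is classified on the spliced
mRNA: loss of the initiation codon (DEL_ATG) when the exon carries any of
the start codon's bases; 3′UTR deletion when the exon lies entirely past
the stop codon; otherwise the skipped form is translated from the original
start. A stop met before the original terminus is a premature termination
codon (PTC), with the skipped-form exon containing it recorded; reaching
the original stop in frame is an in-frame deletion (IFD, which provably
requires a frame-preserving removal). A frameshift whose first stop falls
beyond the original terminus lands in the last exon and is reported there;
no stop at all is flagged. NMD is predicted for a PTC anywhere before the
last exon — the package follows this last-exon rule by default because it
is the rule the consequence table is built on, with the canonical
50-nt-junction rule available via `nmd_rule = "junction_50nt"`. When
skipping is deleterious (PTC + NMD, or DEL_ATG), the allele decreasing
inclusion is loss-of-function and the other gain-of-function; PTC in the
last exon, IFD and 3′UTR deletions are non-predictable. Exons entirely in
the 5′UTR fall outside the four printed classes and are reported as
`UTR5_DEL`. Conservation enrichment uses a two-tailed Fisher exact test on
the 2×2 table of conservation-positive status (GERP > 0 by default; the
cutoff is configurable because "GERP-positive" has no canonical numeric
definition) against LOSS-vs-NEUTRAL and GAIN-vs-NEUTRAL.

# GWAS post-processing

Candidates require MAF > 0.005 and −log10 p > 6 (the 5 % genome-wide
Bonferroni level for 50,000 independent tests); the assay-bound subset
additionally needs an rsID, imputation r² > 0.4 and a position inside an
eligible region. QTL intervals are extracted greedily per chromosome: the
strongest remaining candidate leads; members lie within ±2 Mb and in the
upper third of the peak — interpreted as −log10 p ≥ (2/3) of the lead's
value, with the alternative reading (top third of the range above the
floor) selectable via `peak_rule`, since "upper third of the peak" is
ambiguous; the interval spans the members, extraction repeats on the
remainder, and overlapping intervals merge into the earlier one. The
genome-wide share of SDV-containing QTL extrapolates the observed share by
the assayable-region coverage and the QC survival ratio, capped at 100 %
with a flag.

# The synthetic-data generator

The generator emulates the statistical structure of the experiment, not
its biochemistry:

* **Gene models**: one gene per chromosome, 4–7 exons, internal exons
  mostly 13–98 nt (8 % deliberately over-length so selection filters are
  exercised), introns 100–300 nt, both strands.
* **Variants and truth**: one SNP per region, uniform in the test
  sequence; 20 % of variants are true SDV with |ΔPSI| uniform on 10–50
  (random sign, truncated to keep PSI in [0, 100]); the rest have exactly
  zero effect, making null calibration well defined. REF PSI is uniform on
  30–90, spanning the broad inclusion range reporter exons show in
  practice.
* **Reporter reads**: molecules per barcode ~ Poisson(depth); inclusion ~
  Bernoulli(PSI/100); each molecule gets a fresh random 10-nt UMI and
  1 + Geometric(dup rate) copies; base errors i.i.d. (default 10⁻³).
  Two "cell lines" are re-samplings from shared true PSI with independent
  noise — concordance between them reflects sampling error only, not cell
  biology.
* **Predictor scores**: a Gaussian copula on the mid-ranks of |true ΔPSI|,
  with the mixing weight calibrated by a deterministic root-finder against
  a fixed noise matrix so the realised Spearman correlation hits the
  target (default 0.7) despite the large tie mass of zero-effect variants.
* **GWAS summaries**: uniform-null background plus planted peaks whose
  members stay, by construction, in the upper third of the peak and above
  the significance floor (leads 9.5–15). Diffuse shoulders were
  deliberately avoided: members between the floor and two-thirds of the
  lead make the "true" interval ill-defined under the greedy extraction
  rule, which either absorbs them by merging or leaves straggler
  intervals.
* **Library reads**: constructs receive planted failure modes (absent
  from PL1, barcode synthesis error carried by every copy, low-fidelity
  inserts at a 50 % per-read error probability, absent from PL2) that the
  QC filters must recover exactly.

What passing tests on these data do **not** show: robustness to
overdispersion beyond binomial-Poisson noise (no extra dispersion term by
default; real barcodes show more spread), to cryptic splice sites or
partial intron retention (classification is binary over the two expected
forms), to non-uniform Illumina error profiles, or to LD structures more
complex than an exponential peak.

# Numerical choices and problem sizes

Junction calls need k = 8 exact bases each side — long enough that a
random match is ~10⁻⁵, short enough that a 0.1 % per-base error rate
rarely voids both junctions of a molecule. UMI collapse is exact-match
within barcode (10-nt UMI space vastly exceeds per-barcode molecule
counts; occasional collisions merge two molecules and are tolerated, not
"fixed"). BH is computed per cell line over all evaluable variants
jointly. Score ties in ROC construction are grouped; score bins are
left-closed with the top bin closed on both ends.

The shipped test-suite and acceptance script use the default study
conditions — 200 variants, 20 % SDV, 4 barcodes × 3 replicates, ~500
molecules per barcode at the read level, and 200 null simulations of 200
variants at the molecule-count level for FDR calibration (the count level
is the same Poisson-binomial model without nucleotide strings). At these
sizes the whole suite runs in a few minutes on one CPU; the end-to-end
recovery criteria (ΔPSI truth correlation ≥ 0.95, SDV sensitivity ≥ 0.85,
false discovery proportion ≤ 0.05 at FDR < 0.01) are comfortably met, as
computed by `scripts/acceptance.R`.

# Known limitations

Only biallelic SNPs are designed (no indels); PSI is binary
inclusion/exclusion; the NMD rule is positional, not mechanistic; the
consequence classifier assumes a clean reference CDS (internal stops are a
model error, not data); and predictor scores are inputs — the package
benchmarks predictors but never runs them.
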