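# Invariant segments of the reporter insert. The two restriction sites used
# for cloning (MfeI = CAATTG, SpeI = ACTAGT) live in the middle linker and
# must occur nowhere else in a construct.
OLIGO_FLANK5 <- "CTGACTCTCTCTGCCTC"
OLIGO_LINKER <- "CAATTGACTACTAGT"
OLIGO_FLANK3 <- "TCTAGAGGGCCCGTTTA"
SITE_MFEI <- "CAATTG"
SITE_SPEI <- "ACTAGT"

# Constant reporter exons flanking the test exon in the minigene transcript.
# 60 nt each, free of MfeI/SpeI sites and of long homopolymers; chosen once
# and fixed so junction windows are deterministic.
REPORTER_EXON1 <- "ATGGCACTGTGGATCCGAGAAGTCCTGCATACGGTTCAAGCGATTCTCCTGCCTCAGCC"
REPORTER_EXON3 <- "GATCGGAAGAGCACACGTCTGAACTCCAGTCACTTAGGCATCTCGTATGCCGTCTTCTG"

UMI_LENGTH <- 10L

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' Thin vectorised wrapper used throughout the package.
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Count non-overlapping-agnostic occurrences of a fixed pattern (all start
# positions, overlaps allowed).
count_pattern <- function(seqs, pattern) {
  vapply(
    Biostrings::vmatchPattern(pattern, Biostrings::DNAStringSet(seqs)),
    length, integer(1)
  )
}

has_restriction_site <- function(seqs) {
  count_pattern(seqs, SITE_MFEI) + count_pattern(seqs, SITE_SPEI) > 0L
}

# Longest homopolymer run in each sequence.
max_homopolymer <- function(x) {
  vapply(strsplit(x, ""), function(ch) {
    if (length(ch) == 0L) return(0L)
    max(rle(ch)$lengths)
  }, integer(1))
}

# Random DNA strings, vectorised: n sequences of length len.
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Normalise rsID identifiers
#'
#' Lower-cases the "rs" prefix and strips whitespace; entries that are not of
#' the form rs<digits> are returned as NA.
#'
#' @param x character vector of variant identifiers.
#' @return character vector of normalised rsIDs (NA where malformed).
#' @export
normalize_rsid <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[!grepl("^rs[0-9]+$", x)] <- NA_character_
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_dt <- function(x) {
  data.table::as.data.table(x)
}
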