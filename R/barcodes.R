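#' Generate a set of mutually distant DNA barcodes
#'
#' Draws random barcodes and keeps those that (i) contain neither the MfeI
#' (CAATTG) nor the SpeI (ACTAGT) site, (ii) contain no homopolymer run of 5
#' or more, and (iii) lie at Hamming distance at least `min_distance` from
#' every barcode already accepted (greedy filtering). Reproducible for a
#' given seed.
#'
#' @param n number of barcodes required.
#' @param length barcode length in nucleotides (default 12).
#' @param min_distance minimum pairwise Hamming distance (default 3).
#' @param seed integer seed for reproducibility.
#' @param max_tries sampling budget multiplier; generation aborts with a
#'   capacity error once `max_tries * n` candidates have been examined.
#' @return character vector of `n` barcodes.
#' @export
generate_barcodes <- function(n, length = 12L, min_distance = 3L, seed = 1L,
                              max_tries = 2000L) {
  stopifnot(n >= 1L, length >= 8L, min_distance >= 1L)
  # Singleton-bound sanity check (Hamming sphere packing): the space cannot
  # hold n codes if n * V(r) > 4^length with r = floor((d-1)/2).
  r <- (min_distance - 1L) %/% 2L
  vol <- sum(vapply(0:r, function(k) choose(length, k) * 3^k, numeric(1)))
  if (log(n) + log(vol) > length * log(4)) {
    stop("capacity error: cannot fit ", n, " barcodes of length ", length,
         " at Hamming distance >= ", min_distance, call. = FALSE)
  }
  set.seed(seed)
  accepted <- character(0)
  accepted_mat <- NULL  # integer matrix, one row per accepted barcode
  tried <- 0L
  budget <- max_tries * n
  while (length(accepted) < n) {
    batch <- max(64L, n - length(accepted))
    cand <- random_dna(batch, length)
    tried <- tried + batch
    ok <- !has_restriction_site(cand) & max_homopolymer(cand) < 5L
    for (bc in cand[ok]) {
      v <- utf8ToInt(bc)
      if (!is.null(accepted_mat)) {
        d <- rowSums(accepted_mat != matrix(v, nrow(accepted_mat), length,
                                            byrow = TRUE))
        if (any(d < min_distance)) next
      }
      accepted <- c(accepted, bc)
      accepted_mat <- rbind(accepted_mat, v)
      if (length(accepted) == n) break
    }
    if (tried > budget && length(accepted) < n) {
      stop("capacity error: exhausted sampling budget after ", tried,
           " candidates (", length(accepted), "/", n, " barcodes found)",
           call. = FALSE)
    }
  }
  accepted
}
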