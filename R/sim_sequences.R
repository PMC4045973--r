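BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Mutate a sequence by uniform random substitution
#'
#' Jukes-Cantor-style neutral divergence: the number of substituted sites is
#' Binomial(length, divergence) and each chosen site receives a uniformly
#' drawn *different* base, so the expected mismatch fraction against the
#' input equals `divergence`. Indels are off by default (`indel_rate = 0`)
#' because the downstream variant analysis counts substitutions; a positive
#' `indel_rate` adds that many single-base deletions per site.
#'
#' @param sequence A DNA string (A/C/G/T).
#' @param divergence Expected substitutions/site, in `[0, 0.75)`.
#' @param seed Integer seed.
#' @param indel_rate Per-site single-base deletion rate (default 0).
#' @return The mutated sequence (same length when `indel_rate = 0`).
#' @examples
#' diverge_sequence("ACGTACGT", 0, seed = 1)
#' @export
diverge_sequence <- function(sequence, divergence, seed, indel_rate = 0) {
  if (divergence < 0 || divergence >= 0.75) {
    stop("divergence must lie in [0, 0.75)")
  }
  set.seed(seed)
  x <- seq_chars(sequence)
  n <- length(x)
  nsub <- rbinom(1L, n, divergence)
  if (nsub > 0) {
    pos <- sample.int(n, nsub)
    # draw replacement uniformly from the three other bases
    idx <- match(x[pos], BASES)
    shift <- sample.int(3L, nsub, replace = TRUE)
    x[pos] <- BASES[((idx - 1L + shift) %% 4L) + 1L]
  }
  if (indel_rate > 0) {
    ndel <- rbinom(1L, length(x), indel_rate)
    if (ndel > 0) x <- x[-sample.int(length(x), ndel)]
  }
  paste(x, collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
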