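#' Fragment transcripts into partial-length contigs with read depths
#'
#' Emulates an incompletely assembled transcriptome: each transcript yields one
#' or two contiguous sub-sequences whose total covered fraction is drawn from a
#' Beta distribution with mean `coverage_mean`, and each contig carries a mean
#' read depth drawn from Poisson(`depth_mean`), floored at 1.
#'
#' @param transcripts Named character vector (names are transcript IDs).
#' @param coverage_mean Mean covered fraction, in (0, 1].
#' @param depth_mean Mean per-contig depth.
#' @param seed Integer seed.
#' @param min_len Minimum contig length in bases (default 120, so that real
#'   contigs can clear a >100 bp alignment-length filter).
#' @return data.frame: `contig_id`, `transcript_id`, `start`, `end`
#'   (1-based, on the transcript), `sequence`, `depth`.
#' @export
fragment_to_contigs <- function(transcripts, coverage_mean, depth_mean, seed,
                                min_len = 120) {
  if (length(transcripts) == 0) stop("empty transcript set")
  if (coverage_mean <= 0 || coverage_mean > 1) {
    stop("coverage_mean must be in (0, 1]")
  }
  set.seed(seed)
  shape <- 12
  rows <- vector("list", length(transcripts))
  ids <- names(transcripts)
  for (i in seq_along(transcripts)) {
    L <- nchar(transcripts[[i]])
    f <- if (coverage_mean >= 1) 1 else
      stats::rbeta(1, shape * coverage_mean, shape * (1 - coverage_mean))
    cov_len <- max(min(L, min_len), round(f * L))
    two <- cov_len >= 2 * min_len && cov_len < L && stats::runif(1) < 0.4
    if (!two) {
      start <- if (cov_len >= L) 1L else sample.int(L - cov_len + 1L, 1L)
      spans <- data.frame(start = start, end = start + cov_len - 1L)
    } else {
      l1 <- sample(seq(min_len, cov_len - min_len), 1L)
      l2 <- cov_len - l1
      # place the two contigs disjointly: split the transcript at a point
      # leaving room for each piece on its side
      cut <- sample(seq(l1, L - l2), 1L)
      s1 <- sample.int(cut - l1 + 1L, 1L)
      s2 <- cut + sample.int(L - l2 - cut + 1L, 1L)
      spans <- data.frame(start = c(s1, s2), end = c(s1 + l1 - 1L, s2 + l2 - 1L))
    }
    spans$contig_id <- sprintf("%s_c%d", ids[i], seq_len(nrow(spans)))
    spans$transcript_id <- ids[i]
    rows[[i]] <- spans
  }
  out <- do.call(rbind, rows)
  out$sequence <- substring(transcripts[out$transcript_id], out$start, out$end)
  out$depth <- pmax(1L, stats::rpois(nrow(out), depth_mean))
  out <- out[, c("contig_id", "transcript_id", "start", "end",
                 "sequence", "depth")]
  rownames(out) <- NULL
  out
}
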