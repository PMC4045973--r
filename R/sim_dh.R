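#' Simulate doubled-haploid genotypes on a genetic map
#'
#' Each individual inherits one recombinant gamete per linkage group. The
#' crossover process is a stationary Markov walk along the marker order whose
#' adjacent-interval recombination fraction equals the inverse Kosambi
#' transform of the cM gap, r = 0.5 * tanh(gap_cM / 50) -- i.e. observed
#' adjacent rf, once mapped back through the Kosambi function, recovers the
#' simulated distances. No explicit interference model is imposed beyond the
#' Kosambi relation between distance and rf.
#'
#' @param true_map data.frame `lg`, `marker_id`, `pos_cm` (sorted within LG).
#' @param n_dh Number of individuals (`>= 1`).
#' @param seed Integer seed.
#' @param missing_rate Fraction of calls replaced by `"-"` (missing).
#' @return Character matrix markers x individuals with entries `"a"`, `"b"`
#'   or `"-"`; rownames are marker IDs, colnames `DH_###`.
#' @export
simulate_dh_genotypes <- function(true_map, n_dh, seed, missing_rate = 0) {
  if (n_dh < 1) stop("n_dh must be >= 1")
  stopifnot(all(c("lg", "marker_id", "pos_cm") %in% names(true_map)))
  by_lg <- split(true_map, true_map$lg)
  for (m in by_lg) {
    if (is.unsorted(m$pos_cm)) stop("map positions must be sorted within LG")
  }
  set.seed(seed)
  mats <- lapply(by_lg, function(m) {
    n_mk <- nrow(m)
    r <- kosambi_r(diff(m$pos_cm))
    g <- matrix(NA_integer_, n_mk, n_dh)
    g[1, ] <- stats::rbinom(n_dh, 1L, 0.5)
    if (n_mk > 1) {
      for (j in 2:n_mk) {
        sw <- stats::rbinom(n_dh, 1L, r[j - 1])
        g[j, ] <- (g[j - 1, ] + sw) %% 2L
      }
    }
    rownames(g) <- m$marker_id
    g
  })
  g <- do.call(rbind, mats)
  out <- matrix(c("a", "b")[g + 1L], nrow(g), ncol(g))
  if (missing_rate > 0) {
    miss <- stats::runif(length(out)) < missing_rate
    out[miss] <- "-"
  }
  rownames(out) <- rownames(g)
  colnames(out) <- sprintf("DH_%03d", seq_len(n_dh))
  # restore input marker order
  out[true_map$marker_id, , drop = FALSE]
}

#' Build a simple multi-LG true map for linkage simulations
#'
#' @param n_lg Number of linkage groups.
#' @param markers_per_lg Markers on each LG.
#' @param spacing_cm Distance between adjacent markers, cM.
#' @param lg_prefix Prefix for LG names.
#' @return data.frame `lg`, `marker_id`, `pos_cm`.
#' @export
simulate_genetic_map <- function(n_lg, markers_per_lg, spacing_cm = 10,
                                 lg_prefix = "LG") {
  do.call(rbind, lapply(seq_len(n_lg), function(i) {
    data.frame(
      lg = sprintf("%s%d", lg_prefix, i),
      marker_id = sprintf("%s%d_m%02d", lg_prefix, i, seq_len(markers_per_lg)),
      pos_cm = (seq_len(markers_per_lg) - 1) * spacing_cm,
      stringsAsFactors = FALSE
    )
  }))
}
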