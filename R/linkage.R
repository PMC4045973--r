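# Doubled-haploid linkage mapping: segregation screening, two-point
# rf/LOD, LOD-threshold grouping, heuristic ordering, Kosambi distances.

#' Chi-square segregation test for a DH marker
#'
#' DH genotypes segregate 1:1; the test is a 1-df chi-square on the
#' non-missing a/b counts.
#'
#' @param genotypes Character vector of `"a"`/`"b"`/`"-"` calls.
#' @param alpha Significance level (default 0.05, no multiplicity
#'   correction).
#' @return list: `status` (`"ok"`/`"distorted"`), `chisq`, `p_value`,
#'   `n_a`, `n_b`.
#' @export
segregation_test <- function(genotypes, alpha = 0.05) {
  n_a <- sum(genotypes == "a")
  n_b <- sum(genotypes == "b")
  n <- n_a + n_b
  if (n == 0) stop("all genotype calls are missing")
  e <- n / 2
  chisq <- (n_a - e)^2 / e + (n_b - e)^2 / e
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  list(status = if (p < alpha) "distorted" else "ok",
       chisq = chisq, p_value = p, n_a = n_a, n_b = n_b)
}

#' Two-point recombination fraction and LOD for a DH marker pair
#'
#' `r` is the recombinant fraction over individuals non-missing in both
#' markers, capped at 0.5; LOD is the base-10 likelihood ratio of the
#' binomial DH model at `r` against independence (r = 0.5).
#'
#' @param g1,g2 Character vectors of `"a"`/`"b"`/`"-"` calls.
#' @return list `r`, `lod`, `n` (informative pairs); `r` is `NA` with `n`
#'   reported when fewer than 2 informative individuals exist.
#' @export
estimate_rf_dh <- function(g1, g2) {
  ok <- g1 %in% c("a", "b") & g2 %in% c("a", "b")
  n <- sum(ok)
  if (n < 2) return(list(r = NA_real_, lod = NA_real_, n = n))
  R <- sum(g1[ok] != g2[ok])
  r <- min(R / n, 0.5)
  lod <- if (r >= 0.5) 0 else {
    R * log10(2 * r + (r == 0)) + (n - R) * log10(2 * (1 - r))
  }
  # R == 0 makes the first term 0 * log10(0); the (r == 0) guard renders it 0
  list(r = r, lod = lod, n = n)
}

#' Kosambi map distance
#'
#' `d = 25 * ln((1 + 2r) / (1 - 2r))` centimorgans, the Kosambi transform
#' accounting for partial crossover interference.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Map distance(s) in cM.
#' @export
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("Kosambi distance requires 0 <= r < 0.5")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @param d Map distance(s) in cM.
#' @return `kosambi_r()` returns the recombination fraction
#'   r = tanh(d / 50) / 2.
#' @export
kosambi_r <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  tanh(d / 50) / 2
}

# all pairwise rf/LOD values for a genotype matrix (markers x individuals)
pairwise_rf <- function(g) {
  m <- nrow(g)
  num <- matrix(0L, m, ncol(g))
  num[g == "b"] <- 1L
  miss <- !(g %in% c("a", "b"))
  dim(miss) <- dim(g)
  X <- num; X[miss] <- 0L
  OK <- 1L - miss
  n_ab <- OK %*% t(OK)                    # informative pairs
  # recombinants = sum over ok pairs of xor(g1, g2)
  S11 <- (X * OK) %*% t(X * OK)           # both "b"
  ones <- (1L - X) * OK
  S00 <- ones %*% t(ones)                 # both "a"
  R <- n_ab - S11 - S00
  r <- ifelse(n_ab > 0, pmin(R / n_ab, 0.5), NA_real_)
  lod <- matrix(0, m, m)
  pos <- n_ab > 1 & !is.na(r) & r < 0.5
  lod[pos] <- R[pos] * log10(2 * r[pos] + (r[pos] == 0)) +
    (n_ab[pos] - R[pos]) * log10(2 * (1 - r[pos]))
  lod[n_ab < 2] <- NA_real_
  dimnames(r) <- dimnames(lod) <- list(rownames(g), rownames(g))
  list(r = r, lod = lod, n = n_ab)
}

#' Group markers into linkage groups by a LOD threshold
#'
#' Connected components of the graph whose edges are marker pairs with
#' pairwise LOD at or above the threshold. Pairs with undefined rf
#' (insufficient shared data) contribute no edge.
#'
#' @param lod Symmetric matrix of pairwise LOD scores (marker names on
#'   dimnames).
#' @param lod_threshold Minimum LOD for an edge (default 4.0, the published
#'   grouping threshold).
#' @return list of character vectors, one per group, largest first.
#' @export
group_markers <- function(lod, lod_threshold = 4.0) {
  stopifnot(is.matrix(lod), nrow(lod) == ncol(lod))
  ids <- rownames(lod)
  adj <- which(upper.tri(lod) & !is.na(lod) & lod >= lod_threshold,
               arr.ind = TRUE)
  gr <- igraph::graph_from_data_frame(
    data.frame(from = ids[adj[, 1]], to = ids[adj[, 2]]),
    directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(gr)
  groups <- split(ids, comp$membership)
  groups[order(-lengths(groups), vapply(groups, min, character(1)))]
}

# greedy nearest-neighbour path seeded at the most distal pair, improved by
# 2-opt on the sum of adjacent rf
order_heuristic <- function(rf) {
  m <- nrow(rf)
  if (m <= 2) return(seq_len(m))
  d <- rf
  diag(d) <- Inf
  d[is.na(d)] <- 0.5                      # unknown pairs treated as unlinked
  far <- which(d == max(d[is.finite(d)]), arr.ind = TRUE)[1, ]
  path <- far[1]
  left <- setdiff(seq_len(m), path)
  while (length(left) > 0) {
    nxt <- left[which.min(d[path[length(path)], left])]
    path <- c(path, nxt)
    left <- setdiff(left, nxt)
  }
  cost <- function(p) sum(d[cbind(p[-length(p)], p[-1])])
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        cand <- path
        cand[i:j] <- rev(cand[i:j])
        if (cost(cand) < cost(path) - 1e-12) {
          path <- cand
          improved <- TRUE
        }
      }
    }
  }
  path
}

#' Order a linkage group and assign Kosambi positions
#'
#' Marker order comes from a greedy nearest-neighbour chain seeded at the
#' most distal pair and refined by 2-opt on the sum of adjacent rf (a
#' documented heuristic, not a reimplementation of any regression-mapping
#' engine). Positions are cumulative Kosambi distances over adjacent rf.
#' Orientation is canonical: the lexicographically smaller end marker comes
#' first.
#'
#' @param members Character vector of marker IDs in the group.
#' @param rf Full pairwise rf matrix (dimnames = marker IDs).
#' @param lg_id Linkage-group label.
#' @return data.frame `lg`, `marker_id`, `pos_cm` (first position 0).
#' @export
order_and_space <- function(members, rf, lg_id = "LG1") {
  if (length(members) == 1) {
    return(data.frame(lg = lg_id, marker_id = members, pos_cm = 0,
                      stringsAsFactors = FALSE))
  }
  sub <- rf[members, members, drop = FALSE]
  ord <- order_heuristic(sub)
  ids <- members[ord]
  if (ids[1] > ids[length(ids)]) ids <- rev(ids)
  adj <- sub[cbind(match(ids[-length(ids)], members),
                   match(ids[-1], members))]
  adj[is.na(adj)] <- 0.49
  adj <- pmin(adj, 0.49)                  # guard against r ~ 0.5 blowing up
  data.frame(lg = lg_id, marker_id = ids,
             pos_cm = cumsum(c(0, kosambi_cm(adj))),
             stringsAsFactors = FALSE)
}

#' Build a DH linkage map from a genotype matrix
#'
#' Screens distorted markers (1:1 chi-square at `alpha`), drops markers with
#' more than `max_missing` missing calls, computes pairwise rf/LOD, groups at
#' `lod_threshold` and orders each group with Kosambi spacing. Groups are
#' named `LG01`, `LG02`, ... in decreasing size order.
#'
#' @param genotypes Character matrix markers x individuals (`"a"/"b"/"-"`).
#' @param lod_threshold Grouping LOD (default 4.0).
#' @param alpha Segregation-distortion level (default 0.05).
#' @param max_missing Maximum tolerated fraction of missing calls per marker
#'   (default 0.5).
#' @param min_group_size Groups smaller than this are reported but unordered
#'   singleton maps.
#' @return list: `map` (data.frame `lg`, `marker_id`, `pos_cm`), `groups`,
#'   `distorted` (excluded marker IDs), `dropped_missing`, `rf`, `lod`.
#' @export
build_linkage_map <- function(genotypes, lod_threshold = 4.0, alpha = 0.05,
                              max_missing = 0.5, min_group_size = 2) {
  miss_frac <- rowMeans(!(genotypes %in% c("a", "b")) |
                          is.na(genotypes))
  dim(miss_frac) <- NULL
  names(miss_frac) <- rownames(genotypes)
  dropped <- names(miss_frac)[miss_frac > max_missing]
  if (length(dropped)) {
    warning(length(dropped), " marker(s) dropped for >",
            round(100 * max_missing), "% missing calls")
  }
  g <- genotypes[setdiff(rownames(genotypes), dropped), , drop = FALSE]
  seg <- apply(g, 1, function(x) segregation_test(x, alpha)$status)
  distorted <- rownames(g)[seg == "distorted"]
  g <- g[seg == "ok", , drop = FALSE]
  pw <- pairwise_rf(g)
  groups <- group_markers(pw$lod, lod_threshold)
  maps <- lapply(seq_along(groups), function(i) {
    order_and_space(groups[[i]], pw$r, sprintf("LG%02d", i))
  })
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  list(map = map, groups = groups, distorted = distorted,
       dropped_missing = dropped, rf = pw$r, lod = pw$lod)
}

#' Total and per-LG map length
#'
#' @param map data.frame `lg`, `marker_id`, `pos_cm`.
#' @return list `per_lg` (named vector of LG spans, cM) and `total_cm`.
#' @export
map_length <- function(map) {
  per <- vapply(split(map$pos_cm, map$lg), function(p) max(p) - min(p),
                numeric(1))
  list(per_lg = per, total_cm = sum(per))
}
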