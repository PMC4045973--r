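# Internal k-mer seeding used to shortlist alignment candidates and anchor
# fast identity estimates, in the spirit of BLAST word seeding / MUMmer
# exact-match anchoring. Borderline identities are always refined by true
# local alignment.

all_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

# named character vector -> data.table(kmer, ref_id, rpos), keyed by kmer
kmer_index <- function(seqs, k) {
  dt <- data.table::rbindlist(lapply(names(seqs), function(id) {
    km <- all_kmers(seqs[[id]], k)
    if (length(km) == 0) return(NULL)
    data.table::data.table(kmer = km, ref_id = id, rpos = seq_along(km))
  }))
  if (is.null(dt) || nrow(dt) == 0) {
    dt <- data.table::data.table(kmer = character(), ref_id = character(),
                                 rpos = integer())
  }
  data.table::setkey(dt, kmer)
  attr(dt, "k") <- k
  dt
}

# shared-k-mer counts per (ref_id, query index) for a list of query strings
kmer_hit_counts <- function(index, queries) {
  k <- attr(index, "k")
  qdt <- data.table::rbindlist(lapply(seq_along(queries), function(i) {
    km <- unique(all_kmers(queries[[i]], k))
    if (length(km) == 0) return(NULL)
    data.table::data.table(kmer = km, qpos = i)
  }))
  if (is.null(qdt) || nrow(qdt) == 0 || nrow(index) == 0) {
    return(data.table::data.table(ref_id = character(), qpos = integer(),
                                  n_shared = integer()))
  }
  hits <- index[qdt, nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0) {
    return(data.table::data.table(ref_id = character(), qpos = integer(),
                                  n_shared = integer()))
  }
  counts <- hits[, list(n_shared = length(unique(kmer))),
                 by = c("ref_id", "qpos")]
  data.table::setorder(counts, -n_shared)
  counts
}

# top-n reference ids sharing the most k-mers with any of the query strings
kmer_candidates <- function(index, queries, n_top) {
  counts <- kmer_hit_counts(index, queries)
  if (nrow(counts) == 0) return(character(0))
  tot <- counts[, list(n_shared = sum(n_shared)), by = "ref_id"]
  data.table::setorder(tot, -n_shared)
  utils::head(tot$ref_id, n_top)
}

# top-n (ref_id, best query index) pairs -- used to pick the best frame or
# strand per candidate before aligning
kmer_candidates_by_query <- function(index, queries, n_top) {
  counts <- kmer_hit_counts(index, queries)
  if (nrow(counts) == 0) {
    return(data.frame(ref_id = character(), qpos = integer(),
                      stringsAsFactors = FALSE))
  }
  best <- counts[!duplicated(counts$ref_id), ]
  utils::head(as.data.frame(best[, c("ref_id", "qpos")]), n_top)
}

# Batched candidate search for many queries at once. `views` is a list of
# equal-length character vectors (alternative representations of each query:
# reading frames, strands). Returns a data.table(qid, ref_id, view,
# n_shared, diag, diag_n): for each query, the top `n_top` references by
# shared k-mers, each with its best view, the modal alignment diagonal
# (reference position minus query position) and the number of k-mer matches
# supporting that diagonal. With `positional = FALSE` the diagonal columns
# are skipped (cheaper; enough when candidates feed a full alignment anyway).
# `stride` subsamples query k-mers (every `stride`-th position) to shrink
# the join; anchor counts scale down accordingly.
batch_kmer_candidates <- function(index, views, n_top, positional = TRUE,
                                  stride = 1L, min_shared = 0L) {
  k <- attr(index, "k")
  qdt <- data.table::rbindlist(lapply(seq_along(views), function(v) {
    s <- views[[v]]
    nk <- pmax(nchar(s) - k + 1L, 0L)
    if (sum(nk) == 0) return(NULL)
    dt <- data.table::data.table(
      kmer = unlist(lapply(s, all_kmers, k = k), use.names = FALSE),
      qid = rep(seq_along(s), times = nk),
      view = v,
      qpos = unlist(lapply(nk, seq_len), use.names = FALSE))
    if (stride > 1L) dt <- dt[dt$qpos %% stride == 1L, ]
    dt
  }))
  empty <- data.table::data.table(qid = integer(), ref_id = character(),
                                  view = integer(), n_shared = integer(),
                                  diag = integer(), diag_n = integer())
  if (is.null(qdt) || nrow(qdt) == 0 || nrow(index) == 0) return(empty)
  if (!positional) qdt <- unique(qdt[, c("kmer", "qid", "view")])
  data.table::setkey(qdt, kmer)
  hits <- index[qdt, nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0) return(empty)
  if (positional) {
    hits[, diag := rpos - qpos]
    per_diag <- hits[, list(dn = .N), by = c("qid", "ref_id", "view", "diag")]
    data.table::setorder(per_diag, qid, ref_id, view, -dn)
    mode_diag <- per_diag[!duplicated(per_diag[, c("qid", "ref_id", "view")]), ]
    counts <- hits[, list(n_shared = .N), by = c("qid", "ref_id", "view")]
    counts <- merge(counts, mode_diag, by = c("qid", "ref_id", "view"))
  } else {
    hits <- unique(hits[, c("kmer", "ref_id", "qid", "view")])
    counts <- hits[, list(n_shared = .N), by = c("qid", "ref_id", "view")]
    counts$diag <- NA_integer_
    counts$dn <- NA_integer_
  }
  if (min_shared > 0L) counts <- counts[counts$n_shared >= min_shared, ]
  data.table::setorder(counts, qid, -n_shared)
  counts <- counts[!duplicated(counts[, c("qid", "ref_id")]), ]
  out <- counts[, utils::head(.SD, n_top), by = "qid"]
  data.table::setnames(out, "dn", "diag_n")
  out
}
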