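# Ancestral gene-block painting: ortholog-ID parsing, marker-to-block
# assignment, per-LG block calling, A<->B homoeology, fragmentation and
# block-association motifs.

#' Parse a model-crucifer ortholog gene ID
#'
#' IDs have the form `At<chr>g<5 digits>` with chromosome 1-5,
#' case-insensitive. Total order is (chromosome, number).
#'
#' @param text Character vector of IDs.
#' @return data.frame `at_id` (normalised), `chromosome`, `number`.
#' @export
parse_at_id <- function(text) {
  m <- regmatches(text, regexec("^[Aa][Tt]([1-5])[Gg]([0-9]{5})$", text))
  bad <- lengths(m) != 3
  if (any(bad)) stop("malformed ortholog id: ", paste(text[bad], collapse = ", "))
  chr <- as.integer(vapply(m, `[`, character(1), 2))
  num <- as.integer(vapply(m, `[`, character(1), 3))
  data.frame(at_id = sprintf("At%dg%05d", chr, num),
             chromosome = chr, number = num, stringsAsFactors = FALSE)
}

# single sortable key: chromosome * 1e5 + number
at_key <- function(text) {
  p <- parse_at_id(text)
  p$chromosome * 100000L + p$number
}

validate_block_table <- function(tbl) {
  cols <- c("block_id", "sub_label", "subgenome_class", "reference_lg",
            "at_start", "at_end")
  if (!all(cols %in% names(tbl))) {
    stop("block table must have columns: ", paste(cols, collapse = ", "))
  }
  s <- parse_at_id(tbl$at_start)
  e <- parse_at_id(tbl$at_end)
  if (any(s$chromosome != e$chromosome)) {
    stop("block interval endpoints must lie on one chromosome")
  }
  if (any(s$number > e$number)) stop("block interval start must be <= end")
  if (!all(tbl$subgenome_class %in% c("LF", "MF1", "MF2"))) {
    stop("subgenome_class must be LF, MF1 or MF2")
  }
  invisible(tbl)
}

#' Candidate block assignments for a marker's ortholog ID
#'
#' Returns every block definition whose closed ortholog-ID interval contains
#' the marker's ID -- possibly several rows across subgenome classes; run
#' structure downstream disambiguates.
#'
#' @param at_id One ortholog gene ID.
#' @param block_table Validated block definition table.
#' @return The matching rows of `block_table` (zero rows when none).
#' @export
assign_marker_block <- function(at_id, block_table) {
  validate_block_table(block_table)
  k <- at_key(at_id)
  hit <- at_key(block_table$at_start) <= k & k <= at_key(block_table$at_end)
  out <- block_table[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call gene blocks along mapped linkage groups
#'
#' Markers on each LG (ordered by cM) are scanned for maximal runs of
#' consecutive markers from the same (block, subgenome-class); a single
#' intervening marker of another block breaks a run. A run becomes a call
#' when its marker count reaches the genome's evidence rule: 1 for the
#' well-annotated A genome, 2 for the B genome. Orientation is the sign of
#' the correlation between ortholog order and cM order (undetermined on
#' ties or single-marker calls).
#'
#' @param markers data.frame with `marker_id`, `lg`, `pos_cm`, `block_id`,
#'   `subgenome_class`, `at_id`.
#' @param genome `"A"` or `"B"`.
#' @param min_markers Override of the evidence rule (default: 1 for A, 2
#'   for B).
#' @return data.frame of block calls: `lg`, `genome`, `block_id`,
#'   `subgenome_class`, `n_markers`, `cm_start`, `cm_end`, `at_min`,
#'   `at_max`, `orientation`, plus list-column `supporting_markers`.
#' @export
call_blocks <- function(markers, genome, min_markers = NULL) {
  stopifnot(genome %in% c("A", "B"))
  if (is.null(min_markers)) min_markers <- if (genome == "A") 1L else 2L
  need <- c("marker_id", "lg", "pos_cm", "block_id", "subgenome_class", "at_id")
  stopifnot(all(need %in% names(markers)))
  mk <- markers[!is.na(markers$block_id), , drop = FALSE]
  mk <- mk[order(mk$lg, mk$pos_cm), ]
  calls <- list()
  for (lg_df in split(mk, mk$lg)) {
    key <- paste(lg_df$block_id, lg_df$subgenome_class)
    run_id <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
    for (ix in split(seq_len(nrow(lg_df)), run_id)) {
      if (length(ix) < min_markers) next
      sub <- lg_df[ix, ]
      keys <- at_key(sub$at_id)
      orientation <- "undetermined"
      if (nrow(sub) >= 2 && length(unique(keys)) > 1 &&
          length(unique(sub$pos_cm)) > 1) {
        tau <- stats::cor(keys, sub$pos_cm, method = "kendall")
        if (!is.na(tau) && tau > 0) orientation <- "+"
        if (!is.na(tau) && tau < 0) orientation <- "-"
      }
      calls[[length(calls) + 1L]] <- data.frame(
        lg = sub$lg[1], genome = genome, block_id = sub$block_id[1],
        subgenome_class = sub$subgenome_class[1], n_markers = nrow(sub),
        cm_start = min(sub$pos_cm), cm_end = max(sub$pos_cm),
        at_min = sub$at_id[which.min(keys)],
        at_max = sub$at_id[which.max(keys)],
        orientation = orientation, stringsAsFactors = FALSE)
      calls[[length(calls)]]$supporting_markers <- I(list(sub$marker_id))
    }
  }
  if (length(calls) == 0) {
    return(data.frame(lg = character(), genome = character(),
                      block_id = character(), subgenome_class = character(),
                      n_markers = integer(), cm_start = numeric(),
                      cm_end = numeric(), at_min = character(),
                      at_max = character(), orientation = character()))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

at_spans_overlap <- function(a_min, a_max, b_min, b_max) {
  at_key(a_min) <= at_key(b_max) & at_key(b_min) <= at_key(a_max)
}

#' Infer homoeologous blocks between the A and B genomes
#'
#' Two calls of the same block (and subgenome class) with overlapping
#' ortholog-ID spans are linked when they share at least `min_shared`
#' single-copy (category-ii) markers -- markers whose gene model has exactly
#' one copy in each genome, identified by a shared ortholog ID mapped in
#' both genomes.
#'
#' @param calls_A,calls_B Block calls from [call_blocks()].
#' @param category_ii data.frame of single-copy marker loci: `at_id` plus
#'   `marker_id_A`, `marker_id_B` (the mapped marker of each genome).
#' @param min_shared Minimum shared single-copy markers (default 2).
#' @return data.frame of links: `block_id`, `subgenome_class`, `lg_A`,
#'   `lg_B`, `n_shared`, list-column `shared_at_ids`.
#' @export
infer_homoeology <- function(calls_A, calls_B, category_ii, min_shared = 2) {
  links <- list()
  for (i in seq_len(nrow(calls_A))) {
    for (j in seq_len(nrow(calls_B))) {
      if (calls_A$block_id[i] != calls_B$block_id[j]) next
      if (calls_A$subgenome_class[i] != calls_B$subgenome_class[j]) next
      if (!at_spans_overlap(calls_A$at_min[i], calls_A$at_max[i],
                            calls_B$at_min[j], calls_B$at_max[j])) next
      mk_A <- calls_A$supporting_markers[[i]]
      mk_B <- calls_B$supporting_markers[[j]]
      ii <- category_ii[category_ii$marker_id_A %in% mk_A &
                          category_ii$marker_id_B %in% mk_B, , drop = FALSE]
      if (nrow(ii) < min_shared) next
      links[[length(links) + 1L]] <- data.frame(
        block_id = calls_A$block_id[i],
        subgenome_class = calls_A$subgenome_class[i],
        lg_A = calls_A$lg[i], lg_B = calls_B$lg[j],
        n_shared = nrow(ii), stringsAsFactors = FALSE)
      links[[length(links)]]$shared_at_ids <- I(list(ii$at_id))
    }
  }
  if (length(links) == 0) {
    return(data.frame(block_id = character(), subgenome_class = character(),
                      lg_A = character(), lg_B = character(),
                      n_shared = integer()))
  }
  out <- do.call(rbind, links)
  rownames(out) <- NULL
  out
}

#' Compare block fragmentation between the two genomes
#'
#' For one (block, subgenome-class), the calls of each genome are merged into
#' segments (per LG, with observed ortholog-ID spans) and the pair is
#' classified: `intact_both`; `split_in_A` / `split_in_B` when one genome
#' holds two or more disjoint segments jointly covered by fewer segments in
#' the other; `split_both`; `duplicated` when two segments within one genome
#' overlap by at least half their ortholog span; `absent_in_one` when a
#' genome has no call.
#'
#' @param block_id,subgenome_class Block identity to compare.
#' @param calls_A,calls_B Block calls from [call_blocks()].
#' @param dup_overlap Minimum fractional ortholog-span overlap for the
#'   `duplicated` classification (default 0.5).
#' @return list: `block_id`, `subgenome_class`, `segments` (data.frame with
#'   `genome`, `lg`, `at_min`, `at_max`, `n_markers`), `classification`.
#' @export
fragmentation_compare <- function(block_id, subgenome_class, calls_A, calls_B,
                                  dup_overlap = 0.5) {
  pick <- function(calls) {
    calls[calls$block_id == block_id &
            calls$subgenome_class == subgenome_class, , drop = FALSE]
  }
  sA <- pick(calls_A); sB <- pick(calls_B)
  seg_df <- function(s, genome) {
    if (nrow(s) == 0) {
      return(data.frame(genome = character(), lg = character(),
                        at_min = character(), at_max = character(),
                        n_markers = integer()))
    }
    data.frame(genome = genome, lg = s$lg, at_min = s$at_min,
               at_max = s$at_max, n_markers = s$n_markers,
               stringsAsFactors = FALSE)
  }
  segments <- rbind(seg_df(sA, "A"), seg_df(sB, "B"))
  dup_in <- function(s) {
    if (nrow(s) < 2) return(FALSE)
    for (i in 1:(nrow(s) - 1)) {
      for (j in (i + 1):nrow(s)) {
        lo <- max(at_key(s$at_min[i]), at_key(s$at_min[j]))
        hi <- min(at_key(s$at_max[i]), at_key(s$at_max[j]))
        if (hi < lo) next
        span <- min(at_key(s$at_max[i]) - at_key(s$at_min[i]),
                    at_key(s$at_max[j]) - at_key(s$at_min[j]))
        if (span == 0 || (hi - lo) / span >= dup_overlap) return(TRUE)
      }
    }
    FALSE
  }
  n_disjoint <- function(s) {
    if (nrow(s) == 0) return(0L)
    ir <- IRanges::reduce(IRanges::IRanges(at_key(s$at_min), at_key(s$at_max)))
    length(ir)
  }
  classification <- if (nrow(sA) == 0 || nrow(sB) == 0) {
    "absent_in_one"
  } else if (dup_in(segments[segments$genome == "A", ]) ||
             dup_in(segments[segments$genome == "B", ])) {
    "duplicated"
  } else {
    dA <- n_disjoint(segments[segments$genome == "A", ])
    dB <- n_disjoint(segments[segments$genome == "B", ])
    if (dA >= 2 && dB >= 2) "split_both"
    else if (dA >= 2 && dB < dA) "split_in_A"
    else if (dB >= 2 && dA < dB) "split_in_B"
    else "intact_both"
  }
  list(block_id = block_id, subgenome_class = subgenome_class,
       segments = segments, classification = classification)
}

#' Block-association motifs per LG and shared motifs across genomes
#'
#' A motif is the maximal ordered tuple of adjacent block IDs along one LG
#' (consecutive duplicate IDs collapsed). A shared motif is a contiguous
#' sub-run of length at least `min_len` occurring (forwards or reversed --
#' orientation-invariant) in one LG of each genome.
#'
#' @param calls_A,calls_B Block calls from [call_blocks()].
#' @param min_len Minimum shared-motif length in blocks (default 2).
#' @return list: `motifs_A`, `motifs_B` (named list of block-ID vectors per
#'   LG) and `shared` (data.frame `lg_A`, `lg_B`, `motif`, `length`).
#' @export
association_motifs <- function(calls_A, calls_B, min_len = 2) {
  lg_motifs <- function(calls) {
    calls <- calls[order(calls$lg, calls$cm_start), ]
    lapply(split(calls$block_id, calls$lg), function(b) {
      b[c(TRUE, b[-1] != b[-length(b)])]
    })
  }
  mA <- lg_motifs(calls_A)
  mB <- lg_motifs(calls_B)
  subruns <- function(x, len) {
    if (length(x) < len) return(character(0))
    vapply(seq_len(length(x) - len + 1),
           function(i) paste(x[i:(i + len - 1)], collapse = "-"),
           character(1))
  }
  shared <- list()
  for (la in names(mA)) {
    for (lb in names(mB)) {
      best <- NULL
      for (len in seq(min(length(mA[[la]]), length(mB[[lb]])), min_len)) {
        sa <- subruns(mA[[la]], len)
        sb <- c(subruns(mB[[lb]], len), subruns(rev(mB[[lb]]), len))
        hit <- intersect(sa, sb)
        if (length(hit) > 0) {
          best <- data.frame(lg_A = la, lg_B = lb, motif = hit,
                             length = len, stringsAsFactors = FALSE)
          break
        }
      }
      if (!is.null(best)) shared[[length(shared) + 1L]] <- best
    }
  }
  shared <- if (length(shared)) do.call(rbind, shared) else
    data.frame(lg_A = character(), lg_B = character(), motif = character(),
               length = integer(), stringsAsFactors = FALSE)
  rownames(shared) <- NULL
  list(motifs_A = mA, motifs_B = mB, shared = shared)
}
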