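#' Build an ordered ancestral gene set
#'
#' Lays out `n_blocks` ancestral blocks (labelled `A`..`X`) on the five
#' model-crucifer chromosomes and gives every gene an ortholog gene ID of the
#' form `At<chr>g<5 digits>`, with numbers increasing along the chromosome so
#' that each block occupies a contiguous, non-overlapping ID interval.
#'
#' @param cfg A [sim_config()].
#' @return data.frame with one row per ancestral gene: `gene_id`, `block_id`,
#'   `pos_in_block`, `at_chr`, `at_num`, `at_id`, `sequence`.
#' @export
make_ancestor <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 1L))
  blocks <- LETTERS[seq_len(cfg$n_blocks)]
  chr <- rep(1:5, length.out = cfg$n_blocks)
  slot <- stats::ave(seq_along(blocks), chr, FUN = seq_along)
  rows <- lapply(seq_along(blocks), function(i) {
    pos <- seq_len(cfg$genes_per_block)
    at_num <- (slot[i] - 1L) * 15000L + 100L + 10L * pos
    data.frame(
      gene_id = sprintf("anc_%s_%03d", blocks[i], pos),
      block_id = blocks[i],
      pos_in_block = pos,
      at_chr = chr[i],
      at_num = at_num,
      at_id = sprintf("At%dg%05d", chr[i], at_num),
      stringsAsFactors = FALSE
    )
  })
  anc <- do.call(rbind, rows)
  anc$sequence <- vapply(seq_len(nrow(anc)),
                         function(i) random_dna(cfg$gene_length),
                         character(1))
  anc
}

#' Triplicate an ancestral gene set and fractionate it
#'
#' Each ancestral gene is copied into the three subgenome classes LF, MF1 and
#' MF2 and each copy is independently retained with the class's retention
#' probability, reproducing the observed mixture of single-copy, two-copy and
#' three-copy gene families.
#'
#' @param ancestor_genes data.frame from [make_ancestor()] (ordered within
#'   labelled blocks).
#' @param retention_probs Named `c(LF=, MF1=, MF2=)` probabilities in `[0,1]`.
#' @param seed Integer seed.
#' @return data.frame of retained copies: ancestor columns plus `class` and
#'   `copy_id`.
#' @export
triplicate_and_fractionate <- function(ancestor_genes, retention_probs, seed) {
  if (!all(c("LF", "MF1", "MF2") %in% names(retention_probs)) ||
      any(retention_probs < 0 | retention_probs > 1)) {
    stop("retention_probs must be named LF/MF1/MF2 probabilities in [0, 1]")
  }
  set.seed(seed)
  out <- lapply(c("LF", "MF1", "MF2"), function(cl) {
    keep <- stats::runif(nrow(ancestor_genes)) < retention_probs[[cl]]
    cp <- ancestor_genes[keep, , drop = FALSE]
    if (nrow(cp) == 0) return(NULL)
    cp$class <- cl
    cp$copy_id <- paste(cp$gene_id, cl, sep = "_")
    cp
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Distribute (block, class) segments over linkage groups
#'
#' @param copies data.frame from [triplicate_and_fractionate()].
#' @param n_lg Number of linkage groups.
#' @param lg_prefix Prefix for LG names (e.g. `"A"`).
#' @param seed Integer seed.
#' @return A layout data.frame: `segment_id`, `lg`, `seg_order`, `block_id`,
#'   `class` and a list-column `genes` of copy IDs ordered along the ancestral
#'   chromosome.
#' @export
build_layout <- function(copies, n_lg, lg_prefix, seed) {
  set.seed(seed)
  key <- paste(copies$block_id, copies$class, sep = "_")
  segs <- split(copies[order(copies$at_num), ], key[order(copies$at_num)])
  segs <- segs[lengths(lapply(segs, nrow)) > 0]
  ids <- names(segs)
  perm <- sample(length(ids))
  lg <- paste0(lg_prefix, ((seq_along(ids) - 1L) %% n_lg) + 1L)
  layout <- data.frame(
    segment_id = ids[perm],
    lg = lg,
    block_id = vapply(segs[perm], function(s) s$block_id[1], character(1)),
    class = vapply(segs[perm], function(s) s$class[1], character(1)),
    stringsAsFactors = FALSE
  )
  layout$genes <- I(lapply(segs[perm], function(s) s$copy_id))
  layout$seg_order <- stats::ave(seq_len(nrow(layout)), layout$lg, FUN = seq_along)
  layout <- layout[order(layout$lg, layout$seg_order), ]
  rownames(layout) <- NULL
  layout
}

apply_one_event <- function(layout, ev) {
  i <- which(layout$segment_id == ev$segment_id)
  if (length(i) != 1) stop("event refers to unknown segment: ", ev$segment_id)
  if (ev$type == "split") {
    genes <- layout$genes[[i]]
    k <- ev$cut_after
    if (k < 1 || k >= length(genes)) stop("invalid split point")
    new_row <- layout[i, ]
    new_row$segment_id <- ev$new_segment_id
    new_row$genes <- I(list(genes[(k + 1):length(genes)]))
    layout$genes[[i]] <- genes[1:k]
    moved <- new_row
  } else if (ev$type == "translocation") {
    moved <- layout[i, ]
    layout <- layout[-i, ]
  } else {
    stop("unknown event type: ", ev$type)
  }
  if (isTRUE(ev$flip)) moved$genes <- I(list(rev(moved$genes[[1]])))
  tgt <- which(layout$lg == ev$target_lg)
  pos <- min(ev$target_pos, length(tgt) + 1L)
  moved$lg <- ev$target_lg
  layout <- rbind(layout, moved)
  # recompute segment order: target segment inserted at position `pos`
  ord <- order(layout$lg, ifelse(layout$segment_id == moved$segment_id,
                                 pos - 0.5, layout$seg_order))
  layout <- layout[ord, ]
  layout$seg_order <- stats::ave(seq_len(nrow(layout)), layout$lg, FUN = seq_along)
  rownames(layout) <- NULL
  layout
}

#' Apply random block-level rearrangements to a genome layout
#'
#' Events are whole-segment translocations and block splits (a split cuts a
#' segment's gene run into two contiguous sub-runs, moving the distal part to
#' another LG). The returned event log replays deterministically with
#' [replay_rearrangements()], which is how the simulator's fragmentation truth
#' is defined.
#'
#' @param layout Layout from [build_layout()].
#' @param n_events Number of events (`>= 0`).
#' @param seed Integer seed.
#' @param min_split_genes Minimum genes on each side of a split (default 2,
#'   so every simulated split is detectable by two-marker evidence rules).
#' @return `list(layout = <rearranged layout>, events = <event data.frame>)`.
#' @export
apply_rearrangements <- function(layout, n_events, seed, min_split_genes = 2) {
  if (n_events < 0) stop("n_events must be >= 0")
  set.seed(seed)
  events <- list()
  lgs <- unique(layout$lg)
  cur <- layout
  for (e in seq_len(n_events)) {
    sizes <- lengths(cur$genes)
    splittable <- which(sizes >= 2 * min_split_genes)
    do_split <- length(splittable) > 0 && stats::runif(1) < 0.5
    if (do_split) {
      i <- splittable[sample.int(length(splittable), 1L)]
      k <- sample(seq(min_split_genes, sizes[i] - min_split_genes), 1L)
      ev <- data.frame(
        event_no = e, type = "split", segment_id = cur$segment_id[i],
        cut_after = k,
        new_segment_id = paste0(cur$segment_id[i], ".s", e),
        target_lg = sample(setdiff(lgs, cur$lg[i]), 1L),
        target_pos = NA_integer_, flip = stats::runif(1) < 0.5,
        stringsAsFactors = FALSE
      )
    } else {
      i <- sample.int(nrow(cur), 1L)
      ev <- data.frame(
        event_no = e, type = "translocation", segment_id = cur$segment_id[i],
        cut_after = NA_integer_, new_segment_id = NA_character_,
        target_lg = sample(setdiff(lgs, cur$lg[i]), 1L),
        target_pos = NA_integer_, flip = stats::runif(1) < 0.5,
        stringsAsFactors = FALSE
      )
    }
    n_tgt <- sum(cur$lg == ev$target_lg)
    ev$target_pos <- sample.int(n_tgt + 1L, 1L)
    cur <- apply_one_event(cur, ev)
    events[[e]] <- ev
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(event_no = integer(), type = character(),
               segment_id = character(), cut_after = integer(),
               new_segment_id = character(), target_lg = character(),
               target_pos = integer(), flip = logical(),
               stringsAsFactors = FALSE)
  list(layout = cur, events = events)
}

#' @rdname apply_rearrangements
#' @param events Event log from [apply_rearrangements()].
#' @export
replay_rearrangements <- function(layout, events) {
  cur <- layout
  for (e in seq_len(nrow(events))) {
    cur <- apply_one_event(cur, events[e, ])
  }
  cur
}

#' Genetic map implied by a layout
#'
#' Genes on each LG (segments in order, genes in stored segment order) are
#' spaced `gene_spacing_cm` apart.
#'
#' @param layout A layout data.frame.
#' @param gene_spacing_cm Spacing between adjacent genes, cM.
#' @return data.frame `lg`, `marker_id` (copy ID), `pos_cm`.
#' @export
layout_to_map <- function(layout, gene_spacing_cm = 1) {
  layout <- layout[order(layout$lg, layout$seg_order), ]
  out <- lapply(split(layout, layout$lg), function(lg_df) {
    genes <- unlist(lg_df$genes, use.names = FALSE)
    data.frame(lg = lg_df$lg[1], marker_id = genes,
               pos_cm = (seq_along(genes) - 1) * gene_spacing_cm,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
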