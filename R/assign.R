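#' Configuration for contig-to-subgenome assignment
#'
#' Thresholds of the two-step classification: a protein-level similarity
#' search at `evalue_max`, then nucleotide-level grouping by maximum identity,
#' keeping only contigs with more than `min_identity_pct` identity over more
#' than `min_aligned_len` aligned bases.
#'
#' @param evalue_max Maximum E-value for a protein hit (default `1e-5`).
#' @param min_identity_pct Identity threshold in percent (default 80,
#'   exclusive: a contig must exceed it).
#' @param min_aligned_len Aligned-length threshold in bases (default 100,
#'   exclusive).
#' @param n_candidates Alignment candidates shortlisted per reference set by
#'   k-mer seeding.
#' @param kmer_protein,kmer_nucleotide Seeding word sizes.
#' @return A list of class `assign_config`.
#' @export
assign_config <- function(evalue_max = 1e-5, min_identity_pct = 80,
                          min_aligned_len = 100, n_candidates = 3,
                          kmer_protein = 4, kmer_nucleotide = 12) {
  stopifnot(evalue_max > 0, min_identity_pct > 0, min_aligned_len > 0)
  structure(list(evalue_max = evalue_max,
                 min_identity_pct = min_identity_pct,
                 min_aligned_len = min_aligned_len,
                 n_candidates = n_candidates,
                 kmer_protein = kmer_protein,
                 kmer_nucleotide = kmer_nucleotide),
            class = "assign_config")
}

# six-frame translation of a nucleotide string; frames 1:3 forward, 4:6 on
# the reverse complement. Ambiguity codes are replaced by A before
# translation (they could only yield X residues, which carry no signal for
# candidate scoring or local alignment).
six_frame_translate <- function(x) {
  x <- gsub("[^ACGT]", "A", toupper(x))
  rc <- revcomp_chr(x)
  pieces <- character(6)
  for (i in 1:3) {
    for (s in c(0L, 3L)) {
      src <- if (s == 0L) x else rc
      n <- nchar(src) - i + 1L
      n <- n - (n %% 3L)
      pieces[i + s] <- if (n >= 3) substr(src, i, i + n - 1L) else "AAA"
    }
  }
  as.character(Biostrings::translate(Biostrings::DNAStringSet(pieces)))
}

# Karlin-Altschul E-value for a gapped BLOSUM62 local alignment score
# (standard gapped parameters lambda = 0.267, K = 0.041)
ka_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  K * m * n * exp(-lambda * score)
}

#' Protein-level best hits of a contig by six-frame translated search
#'
#' Translates the contig in all six frames, shortlists database proteins by
#' shared amino-acid words, aligns locally (BLOSUM62, gap open 11 / extend 1)
#' and converts scores to Karlin-Altschul E-values against the database size.
#'
#' @param contig A nucleotide string.
#' @param protein_set Named character vector of database proteins.
#' @param evalue_max Report hits with E-value at or below this.
#' @param n_candidates Shortlist size.
#' @param index Optional precomputed [kmer_index()] of `protein_set`.
#' @return data.frame `protein_id`, `score`, `evalue`, `frame`, sorted by
#'   decreasing score. Zero rows when nothing reaches `evalue_max`.
#' @export
translated_best_hits <- function(contig, protein_set, evalue_max = 1e-5,
                                 n_candidates = 5, index = NULL) {
  if (length(protein_set) == 0) stop("protein set is empty")
  if (is.na(contig) || nchar(contig) == 0) stop("empty contig")
  empty <- data.frame(protein_id = character(), score = numeric(),
                      evalue = numeric(), frame = integer(),
                      stringsAsFactors = FALSE)
  if (nchar(contig) < 3) return(empty)
  frames <- six_frame_translate(contig)
  if (is.null(index)) index <- kmer_index(as.list(protein_set), k = 4)
  cand <- kmer_candidates_by_query(index, as.list(frames), n_candidates)
  if (nrow(cand) == 0) return(empty)
  db_size <- sum(nchar(protein_set))
  m <- max(nchar(frames))
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    pid <- cand$ref_id[i]
    f <- cand$qpos[i]         # frame sharing the most words with this protein
    sc <- Biostrings::pairwiseAlignment(
      frames[f], protein_set[[pid]],
      type = "local", substitutionMatrix = blosum62(),
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    data.frame(protein_id = pid, score = sc,
               evalue = ka_evalue(sc, m, db_size), frame = f,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  hits <- hits[order(-hits$score), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Nucleotide identity of a contig against one reference sequence
#'
#' Best local alignment on either strand (match +1 / mismatch -1, gap open 4 /
#' extend 2). Identity is matches over alignment columns; `aligned_length` is
#' the number of alignment columns. Reference coordinates are 1-based closed
#' and strand-normalised (always on the forward reference).
#'
#' @param contig,reference_cds Nucleotide strings.
#' @param reference_id Identifier copied into the result.
#' @param strand `"both"` (default), `"+"` or `"-"`: orientations to try.
#' @return One-row data.frame: `reference_id`, `identity_pct`,
#'   `aligned_length`, `strand`, `ref_start`, `ref_end`, `score`.
#' @export
nucleotide_identity <- function(contig, reference_cds, reference_id = NA_character_,
                                strand = "both") {
  stopifnot(nchar(contig) > 0, nchar(reference_cds) > 0)
  mat <- nuc_matrix()
  align_one <- function(query) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), Biostrings::DNAString(reference_cds),
      type = "local", substitutionMatrix = mat,
      gapOpening = 4, gapExtension = 2)
  }
  pa_f <- if (strand %in% c("both", "+")) align_one(contig) else NULL
  pa_r <- if (strand %in% c("both", "-")) align_one(revcomp_chr(contig)) else NULL
  use_rev <- is.null(pa_f) ||
    (!is.null(pa_r) && BiocGenerics::score(pa_r) > BiocGenerics::score(pa_f))
  pa <- if (use_rev) pa_r else pa_f
  ncols <- nchar(pa)
  if (BiocGenerics::score(pa) <= 0 || ncols == 0) {
    return(data.frame(reference_id = reference_id, identity_pct = 0,
                      aligned_length = 0L, strand = "+",
                      ref_start = NA_integer_, ref_end = NA_integer_,
                      score = BiocGenerics::score(pa),
                      stringsAsFactors = FALSE))
  }
  sbj <- Biostrings::subject(pa)
  data.frame(
    reference_id = reference_id,
    identity_pct = 100 * Biostrings::nmatch(pa) / ncols,
    aligned_length = ncols,
    strand = if (use_rev) "-" else "+",
    ref_start = BiocGenerics::start(sbj),
    ref_end = BiocGenerics::end(sbj),
    score = BiocGenerics::score(pa),
    stringsAsFactors = FALSE
  )
}

#' Assign one contig to a subgenome from its identity hits
#'
#' The keep rule retains a contig only if some hit exceeds
#' `min_identity_pct` identity over more than `min_aligned_len` aligned bases
#' (the contrapositive of the published removal rule); a kept contig goes to
#' the genome of its maximum-identity hit, with exact ties declared
#' `ambiguous` and excluded downstream.
#'
#' @param contig_id Contig identifier.
#' @param hits_A,hits_B data.frames of [nucleotide_identity()] rows against
#'   the A and B reference sets.
#' @param config An [assign_config()].
#' @return One-row data.frame: `contig_id`, `verdict` (`A`, `B`, `ambiguous`,
#'   `removed`), `gene_model_id`, `identity_pct`, `aligned_length`, `step`,
#'   `reason`.
#' @export
assign_contig <- function(contig_id, hits_A, hits_B, config = assign_config()) {
  keep <- function(h) {
    if (is.null(h) || nrow(h) == 0) {
      return(data.frame(reference_id = character(), identity_pct = numeric(),
                        aligned_length = integer(), stringsAsFactors = FALSE))
    }
    h[h$identity_pct > config$min_identity_pct &
        h$aligned_length > config$min_aligned_len, , drop = FALSE]
  }
  kA <- keep(hits_A); kB <- keep(hits_B)
  res <- function(verdict, gene = NA_character_, id_pct = NA_real_,
                  alen = NA_integer_, reason = NA_character_) {
    data.frame(contig_id = contig_id, verdict = verdict, gene_model_id = gene,
               identity_pct = id_pct, aligned_length = alen,
               step = "nucleotide", reason = reason, stringsAsFactors = FALSE)
  }
  if (nrow(kA) == 0 && nrow(kB) == 0) {
    return(res("removed", reason = "below_identity_threshold"))
  }
  bA <- if (nrow(kA)) kA[which.max(kA$identity_pct), ] else NULL
  bB <- if (nrow(kB)) kB[which.max(kB$identity_pct), ] else NULL
  if (is.null(bB) || (!is.null(bA) && bA$identity_pct > bB$identity_pct)) {
    return(res("A", bA$reference_id, bA$identity_pct, bA$aligned_length))
  }
  if (is.null(bA) || bB$identity_pct > bA$identity_pct) {
    return(res("B", bB$reference_id, bB$identity_pct, bB$aligned_length))
  }
  res("ambiguous", reason = "tie_A_B")
}

#' Classify contigs lacking protein hits
#'
#' Orphan contigs are screened against the A-genome genomic sequence first:
#' matches above the identity/length thresholds are removed (they are genomic,
#' e.g. intron-bearing, not informative transcripts). Remaining contigs that
#' match the B transcriptome become `B_specific`; everything else is removed
#' as unclassified.
#'
#' @param orphans data.frame with `contig_id` and `sequence`.
#' @param genome_reference Named character vector of A-genome genomic
#'   sequences.
#' @param b_transcriptome Named character vector of B transcripts.
#' @param config An [assign_config()].
#' @return data.frame of assignments (columns as [assign_contig()]).
#' @export
classify_orphans <- function(orphans, genome_reference, b_transcriptome,
                             config = assign_config()) {
  idx_g <- kmer_index(as.list(genome_reference), config$kmer_nucleotide)
  idx_b <- kmer_index(as.list(b_transcriptome), config$kmer_nucleotide)
  rows <- lapply(seq_len(nrow(orphans)), function(i) {
    ct <- orphans$sequence[i]
    cid <- orphans$contig_id[i]
    best_of <- function(index, seqs) {
      cand <- kmer_candidates_by_query(index, list(ct, revcomp_chr(ct)),
                                       config$n_candidates)
      if (nrow(cand) == 0) return(NULL)
      hits <- do.call(rbind, lapply(seq_len(nrow(cand)), function(j) {
        nucleotide_identity(ct, seqs[[cand$ref_id[j]]], cand$ref_id[j],
                            strand = if (cand$qpos[j] == 1L) "+" else "-")
      }))
      hits[hits$identity_pct > config$min_identity_pct &
             hits$aligned_length > config$min_aligned_len, , drop = FALSE]
    }
    g <- best_of(idx_g, genome_reference)
    if (!is.null(g) && nrow(g) > 0) {
      return(data.frame(contig_id = cid, verdict = "removed",
                        gene_model_id = NA_character_,
                        identity_pct = max(g$identity_pct),
                        aligned_length = g$aligned_length[which.max(g$identity_pct)],
                        step = "orphan", reason = "matches_genome",
                        stringsAsFactors = FALSE))
    }
    b <- best_of(idx_b, b_transcriptome)
    if (!is.null(b) && nrow(b) > 0) {
      bb <- b[which.max(b$identity_pct), ]
      return(data.frame(contig_id = cid, verdict = "B_specific",
                        gene_model_id = bb$reference_id,
                        identity_pct = bb$identity_pct,
                        aligned_length = bb$aligned_length,
                        step = "orphan", reason = NA_character_,
                        stringsAsFactors = FALSE))
    }
    data.frame(contig_id = cid, verdict = "removed",
               gene_model_id = NA_character_, identity_pct = NA_real_,
               aligned_length = NA_integer_, step = "orphan",
               reason = "unclassified", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group assigned contigs into per-accession gene models
#'
#' @param assignments Assignment data.frame (must include `accession`).
#' @return data.frame with one row per (accession, genome, gene model):
#'   `accession`, `genome`, `gene_model_id`, `n_contigs` and a list-column
#'   `contigs`.
#' @export
group_gene_models <- function(assignments) {
  a <- assignments[assignments$verdict %in% c("A", "B"), , drop = FALSE]
  if (nrow(a) == 0) {
    return(data.frame(accession = character(), genome = character(),
                      gene_model_id = character(), n_contigs = integer()))
  }
  key <- paste(a$accession, a$verdict, a$gene_model_id, sep = "\r")
  groups <- split(a$contig_id, key)
  parts <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  out <- data.frame(accession = parts[, 1], genome = parts[, 2],
                    gene_model_id = parts[, 3],
                    n_contigs = lengths(groups), stringsAsFactors = FALSE)
  out$contigs <- I(unname(groups))
  rownames(out) <- NULL
  out[order(out$accession, out$genome, out$gene_model_id), ]
}

#' Gene-model coverage report
#'
#' Coverage of a gene model is the union of its contigs' aligned reference
#' spans divided by the reference length (strand-normalised, 1-based closed).
#'
#' @param assignments Assignment data.frame including `accession`, `ref_start`,
#'   `ref_end`.
#' @param reference_lengths Named integer vector of reference gene lengths.
#' @param bin_edges Ascending histogram bin edges in `[0, 1]`.
#' @return list with `coverage` (per gene model) and `histogram` (counts per
#'   bin, summing to the number of gene models).
#' @export
coverage_report <- function(assignments, reference_lengths,
                            bin_edges = seq(0, 1, 0.1)) {
  if (is.unsorted(bin_edges, strictly = TRUE) ||
      min(bin_edges) < 0 || max(bin_edges) > 1) {
    stop("bin_edges must be strictly ascending within [0, 1]")
  }
  a <- assignments[assignments$verdict %in% c("A", "B") &
                     !is.na(assignments$ref_start), , drop = FALSE]
  key <- paste(a$accession, a$verdict, a$gene_model_id, sep = "\r")
  cov <- vapply(split(seq_len(nrow(a)), key), function(ix) {
    gid <- a$gene_model_id[ix[1]]
    len <- reference_lengths[[gid]]
    if (is.null(len) || len == 0) stop("zero-length reference: ", gid)
    ir <- IRanges::reduce(IRanges::IRanges(a$ref_start[ix], a$ref_end[ix]))
    min(1, sum(BiocGenerics::width(ir)) / len)
  }, numeric(1))
  parts <- do.call(rbind, strsplit(names(cov), "\r", fixed = TRUE))
  cov_df <- data.frame(accession = parts[, 1], genome = parts[, 2],
                       gene_model_id = parts[, 3], coverage = unname(cov),
                       stringsAsFactors = FALSE)
  h <- graphics::hist(pmin(cov_df$coverage, max(bin_edges)),
                      breaks = bin_edges, plot = FALSE, right = TRUE,
                      include.lowest = TRUE)
  hist_df <- data.frame(bin_low = utils::head(bin_edges, -1),
                        bin_high = bin_edges[-1], count = h$counts)
  list(coverage = cov_df, histogram = hist_df)
}

#' Run the full two-step contig classification
#'
#' Step 1: translated search of every contig against the A-genome protein set.
#' Step 2: contigs with a protein hit are compared at the nucleotide level
#' against both reference sets and assigned by maximum identity; contigs
#' without a protein hit go through the orphan branch (genomic screen, then
#' B-transcriptome screen). Internally the search is batched: candidates come
#' from one k-mer join per reference set and alignments are grouped by
#' reference sequence, which keeps large contig sets fast without changing
#' any per-contig contract.
#'
#' @param contigs data.frame with `contig_id`, `accession`, `sequence`,
#'   `depth`.
#' @param proteins_A Named character vector: A-genome reference proteins.
#' @param cds_A Named character vector: A-genome reference CDS.
#' @param transcriptome_B Named character vector: B reference transcripts.
#' @param genome_A Named character vector: A genomic sequences (orphan screen).
#' @param config An [assign_config()].
#' @param gene_model_key `"protein"` to key A-verdict gene models by the
#'   protein-step best hit when present (default), `"nucleotide"` to always
#'   use the nucleotide-step best hit.
#' @return Assignment data.frame, one row per input contig.
#' @export
assign_contigs <- function(contigs, proteins_A, cds_A, transcriptome_B,
                           genome_A, config = assign_config(),
                           gene_model_key = c("protein", "nucleotide")) {
  gene_model_key <- match.arg(gene_model_key)
  stopifnot(all(c("contig_id", "accession", "sequence") %in% names(contigs)))
  n <- nrow(contigs)
  seqs <- toupper(contigs$sequence)
  rcs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))

  # --- step 1: translated search -------------------------------------------
  frames <- batch_six_frames(seqs, rcs)
  idx_pep <- kmer_index(as.list(proteins_A), config$kmer_protein)
  cand_pep <- batch_kmer_candidates(idx_pep, frames, config$n_candidates,
                                    positional = FALSE)
  db_size <- sum(nchar(proteins_A))
  best_protein <- rep(NA_character_, n)
  if (nrow(cand_pep) > 0) {
    cand_pep$score <- batch_align_scores(
      cand_pep, views = frames, subjects = proteins_A,
      aa = TRUE)
    m_len <- vapply(seq_len(n), function(i) max(nchar(vapply(frames, `[`,
      character(1), i))), numeric(1))
    cand_pep$evalue <- ka_evalue(cand_pep$score, m_len[cand_pep$qid], db_size)
    sig <- cand_pep[cand_pep$evalue <= config$evalue_max, ]
    if (nrow(sig) > 0) {
      data.table::setorder(sig, qid, -score)
      top <- sig[!duplicated(sig$qid), ]
      best_protein[top$qid] <- top$ref_id
    }
  }
  has_pep <- !is.na(best_protein)

  # --- step 2: nucleotide grouping by maximum identity ---------------------
  strands <- list(seqs, rcs)
  idx_A <- kmer_index(as.list(cds_A), config$kmer_nucleotide)
  idx_B <- kmer_index(as.list(transcriptome_B), config$kmer_nucleotide)
  sub2 <- which(has_pep)
  hits_A <- batch_nucleotide_hits(idx_A, cds_A, strands, sub2,
                                  config$n_candidates, refine = FALSE)
  hits_B <- batch_nucleotide_hits(idx_B, transcriptome_B, strands, sub2,
                                  config$n_candidates, refine = FALSE)
  # Cross-side refinement: anchored identity estimates are only recomputed
  # by true local alignment where they could change the outcome -- a weakly
  # anchored hit, an overall best identity near the keep/remove threshold,
  # or a near-tie between the two genomes' best identities.
  refined <- refine_two_sided(hits_A, hits_B, cds_A, transcriptome_B,
                              strands, sub2)
  hits_A <- refined$A
  hits_B <- refined$B
  out <- vector("list", n)
  for (i in sub2) {
    hA <- hits_A[[i]]
    hB <- hits_B[[i]]
    asg <- assign_contig(contigs$contig_id[i], hA, hB, config)
    if (asg$verdict == "A" && gene_model_key == "protein" &&
        best_protein[i] %in% names(cds_A)) {
      asg$gene_model_id <- best_protein[i]
      asg$step <- "protein"
    }
    best <- switch(asg$verdict,
                   A = hA[which.max(hA$identity_pct), ],
                   B = hB[which.max(hB$identity_pct), ],
                   NULL)
    asg$ref_start <- if (is.null(best)) NA_integer_ else best$ref_start
    asg$ref_end <- if (is.null(best)) NA_integer_ else best$ref_end
    asg$strand <- if (is.null(best)) NA_character_ else best$strand
    out[[i]] <- asg
  }

  # --- orphan branch -------------------------------------------------------
  orphan <- which(!has_pep)
  if (length(orphan) > 0) {
    idx_g <- kmer_index(as.list(genome_A), config$kmer_nucleotide)
    hits_g <- batch_nucleotide_hits(idx_g, genome_A, strands, orphan,
                                    config$n_candidates)
    hits_b <- batch_nucleotide_hits(idx_B, transcriptome_B, strands, orphan,
                                    config$n_candidates)
    pass <- function(h) {
      if (is.null(h)) return(h)
      h[h$identity_pct > config$min_identity_pct &
          h$aligned_length > config$min_aligned_len, , drop = FALSE]
    }
    for (i in orphan) {
      g <- pass(hits_g[[i]])
      b <- pass(hits_b[[i]])
      row <- if (!is.null(g) && nrow(g) > 0) {
        data.frame(contig_id = contigs$contig_id[i], verdict = "removed",
                   gene_model_id = NA_character_,
                   identity_pct = max(g$identity_pct),
                   aligned_length = g$aligned_length[which.max(g$identity_pct)],
                   step = "orphan", reason = "matches_genome",
                   stringsAsFactors = FALSE)
      } else if (!is.null(b) && nrow(b) > 0) {
        bb <- b[which.max(b$identity_pct), ]
        data.frame(contig_id = contigs$contig_id[i], verdict = "B_specific",
                   gene_model_id = bb$reference_id,
                   identity_pct = bb$identity_pct,
                   aligned_length = bb$aligned_length,
                   step = "orphan", reason = NA_character_,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(contig_id = contigs$contig_id[i], verdict = "removed",
                   gene_model_id = NA_character_, identity_pct = NA_real_,
                   aligned_length = NA_integer_, step = "orphan",
                   reason = "unclassified", stringsAsFactors = FALSE)
      }
      row$ref_start <- NA_integer_
      row$ref_end <- NA_integer_
      row$strand <- NA_character_
      out[[i]] <- row
    }
  }
  res <- do.call(rbind, out)
  res$accession <- contigs$accession[match(res$contig_id, contigs$contig_id)]
  res$depth <- contigs$depth[match(res$contig_id, contigs$contig_id)]
  rownames(res) <- NULL
  res
}

# vectorised six-frame translation for a set of sequences: a list of 6
# character vectors (frames 1-3 forward, 4-6 reverse complement)
batch_six_frames <- function(seqs, rcs = NULL) {
  seqs <- gsub("[^ACGT]", "A", toupper(seqs))
  if (is.null(rcs)) {
    rcs <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs)))
  } else {
    rcs <- gsub("[^ACGT]", "A", toupper(rcs))
  }
  one <- function(src, offset) {
    len <- nchar(src) - offset + 1L
    len <- pmax(len - (len %% 3L), 0L)
    piece <- substr(src, offset, offset + len - 1L)
    piece[len < 3] <- "AAA"
    as.character(Biostrings::translate(Biostrings::DNAStringSet(piece)))
  }
  c(lapply(1:3, function(f) one(seqs, f)),
    lapply(1:3, function(f) one(rcs, f)))
}

# align shortlisted (query, reference) pairs grouped by reference;
# score-only, used for the translated protein step
batch_align_scores <- function(cand, views, subjects, aa = TRUE) {
  scores <- numeric(nrow(cand))
  pat_of <- function(rows) {
    vapply(rows, function(r) views[[cand$view[r]]][cand$qid[r]], character(1))
  }
  for (rid in unique(cand$ref_id)) {
    rows <- which(cand$ref_id == rid)
    pats <- pat_of(rows)
    scores[rows] <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(pats), Biostrings::AAString(subjects[[rid]]),
      type = "local", substitutionMatrix = blosum62(),
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
  }
  scores
}

# Batched nucleotide identity: candidates for the given query subset via one
# k-mer join (strand picked per candidate). Identity is first estimated by
# anchoring on the modal shared-k-mer diagonal and comparing the ungapped
# overlap (exact-match anchoring, as MUMmer-style engines do); any hit that
# is the best for its query and falls in an uncertainty band around the
# keep/remove threshold -- or has too little anchor support -- is refined by
# true local alignment. Returns a list indexed by query position; NULL where
# no candidates.
batch_nucleotide_hits <- function(index, ref_seqs, strands, subset, n_top,
                                  min_anchor = 2, refine_band = c(40, 90),
                                  refine = TRUE, stride = 2L) {
  out <- vector("list", length(strands[[1]]))
  if (length(subset) == 0) return(out)
  views_sub <- lapply(strands, `[`, subset)
  cand <- batch_kmer_candidates(index, views_sub, n_top, stride = stride,
                                min_shared = 3L)
  if (nrow(cand) == 0) return(out)
  cand <- as.data.frame(cand)
  cand$qid <- subset[cand$qid]            # back to full indexing
  n_pair <- nrow(cand)
  qseq <- vapply(seq_len(n_pair), function(r) {
    strands[[cand$view[r]]][cand$qid[r]]
  }, character(1))
  ref_len <- nchar(ref_seqs)[cand$ref_id]
  q_len <- nchar(qseq)

  # ungapped overlap on the anchored diagonal: rpos = qpos + diag
  o <- cand$diag
  qs <- pmax(1L, 1L - o)
  qe <- pmin(q_len, ref_len - o)
  identity <- numeric(n_pair)
  alen <- integer(n_pair)
  for (r in seq_len(n_pair)) {
    if (qe[r] < qs[r]) next
    a <- charToRaw(substr(qseq[r], qs[r], qe[r]))
    b <- charToRaw(substr(ref_seqs[[cand$ref_id[r]]], qs[r] + o[r],
                          qe[r] + o[r]))
    alen[r] <- length(a)
    identity[r] <- 100 * sum(a == b) / length(a)
  }
  hit <- data.frame(
    qid = cand$qid, reference_id = cand$ref_id,
    identity_pct = identity, aligned_length = alen,
    strand = ifelse(cand$view == 1L, "+", "-"),
    ref_start = qs + o, ref_end = qe + o,
    score = NA_real_, view = cand$view, diag_n = cand$diag_n,
    stringsAsFactors = FALSE)

  if (refine) {
    # refine by local alignment where the estimate cannot be trusted
    ord <- order(hit$qid, -hit$identity_pct)
    best <- logical(n_pair)
    best[ord] <- !duplicated(hit$qid[ord])
    need_dp <- (cand$diag_n < min_anchor &
                  hit$identity_pct > refine_band[1]) |
      (best & hit$identity_pct > refine_band[1] &
         hit$identity_pct < refine_band[2])
    hit <- dp_refine(hit, which(need_dp), ref_seqs, strands)
  }
  sp <- split(hit, hit$qid)
  out[as.integer(names(sp))] <- sp
  out
}

# Cross-side refinement of unrefined hit lists (see assign_contigs): rebuild
# both tables, refine weakly anchored rows plus side-best rows of queries
# whose outcome is uncertain, and re-split per query.
refine_two_sided <- function(hits_A, hits_B, seqs_A, seqs_B, strands, subset,
                             band = c(40, 90), margin = 3, min_anchor = 2) {
  n <- length(strands[[1]])
  tabA <- do.call(rbind, hits_A[subset])
  tabB <- do.call(rbind, hits_B[subset])
  side_best <- function(tab) {
    out <- rep(NA_real_, n)
    if (!is.null(tab) && nrow(tab)) {
      agg <- tapply(tab$identity_pct, tab$qid, max)
      out[as.integer(names(agg))] <- agg
    }
    out
  }
  bA <- side_best(tabA)
  bB <- side_best(tabB)
  overall <- pmax(bA, bB, na.rm = TRUE)
  needq <- (!is.na(bA) & !is.na(bB) & abs(bA - bB) < margin) |
    (!is.na(overall) & overall > band[1] & overall < band[2])
  refine_tab <- function(tab, seqs) {
    if (is.null(tab) || nrow(tab) == 0) return(tab)
    ord <- order(tab$qid, -tab$identity_pct)
    sb <- logical(nrow(tab))
    sb[ord] <- !duplicated(tab$qid[ord])
    rows <- which((tab$diag_n < min_anchor & tab$identity_pct > band[1]) |
                    (sb & needq[tab$qid]))
    dp_refine(tab, rows, seqs, strands)
  }
  resplit <- function(tab) {
    out <- vector("list", n)
    if (is.null(tab) || nrow(tab) == 0) return(out)
    sp <- split(tab, tab$qid)
    out[as.integer(names(sp))] <- sp
    out
  }
  list(A = resplit(refine_tab(tabA, seqs_A)),
       B = resplit(refine_tab(tabB, seqs_B)))
}

# recompute the given rows of a hit table by true local alignment, batched
# per reference sequence
dp_refine <- function(hit, rows_dp, ref_seqs, strands) {
  if (length(rows_dp) == 0) return(hit)
  for (rid in unique(hit$reference_id[rows_dp])) {
    rows <- rows_dp[hit$reference_id[rows_dp] == rid]
    pats <- vapply(rows, function(r) strands[[hit$view[r]]][hit$qid[r]],
                   character(1))
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(pats),
      Biostrings::DNAString(ref_seqs[[rid]]),
      type = "local", substitutionMatrix = nuc_matrix(),
      gapOpening = 4, gapExtension = 2)
    ncols <- Biostrings::nchar(pa)
    sc <- BiocGenerics::score(pa)
    nm <- Biostrings::nmatch(pa)
    sbj <- Biostrings::subject(pa)
    ok <- sc > 0 & ncols > 0
    hit$identity_pct[rows] <- ifelse(ok, 100 * nm / pmax(ncols, 1L), 0)
    hit$aligned_length[rows] <- ifelse(ok, ncols, 0L)
    hit$ref_start[rows] <- ifelse(ok, BiocGenerics::start(sbj), NA_integer_)
    hit$ref_end[rows] <- ifelse(ok, BiocGenerics::end(sbj), NA_integer_)
    hit$score[rows] <- sc
  }
  hit
}
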