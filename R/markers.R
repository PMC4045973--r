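# Pipeline layer between contig assignment and mapping: reference-projected
# gene-model consensus per accession, allelic SNP calling, HSV/PSV site
# discovery via homoeologue/paralogue projection, KASP filtering and marker
# formatting.

# Project contigs onto their reference gene with one batched local
# alignment call; returns a list of data.frames (ref_pos, base) per contig.
# Gapless alignments (the overwhelming case) use a direct substring fast
# path; gapped ones walk the alignment columns.
project_contigs <- function(contig_seqs, ref_seq) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(contig_seqs), Biostrings::DNAString(ref_seq),
    type = "local", substitutionMatrix = nuc_matrix(),
    gapOpening = 4, gapExtension = 2)
  sbj <- Biostrings::subject(pa)
  pat <- Biostrings::pattern(pa)
  st_s <- BiocGenerics::start(sbj); en_s <- BiocGenerics::end(sbj)
  st_p <- BiocGenerics::start(pat)
  ind <- Biostrings::nindel(pa)
  n_ind <- rowSums(Biostrings::insertion(ind)) +
    rowSums(Biostrings::deletion(ind))
  gapped <- which(n_ind > 0)
  ap <- if (length(gapped)) {
    as.character(Biostrings::alignedPattern(pa[gapped]))
  } else character(0)
  as_ <- if (length(gapped)) {
    as.character(Biostrings::alignedSubject(pa[gapped]))
  } else character(0)
  lapply(seq_along(contig_seqs), function(i) {
    if (n_ind[i] == 0) {
      span <- en_s[i] - st_s[i]
      data.frame(
        ref_pos = st_s[i]:en_s[i],
        base = seq_chars(substr(contig_seqs[[i]], st_p[i], st_p[i] + span)),
        stringsAsFactors = FALSE)
    } else {
      g <- match(i, gapped)
      p <- seq_chars(ap[g])
      s <- seq_chars(as_[g])
      ref_pos <- st_s[i] - 1L + cumsum(s != "-")
      keep <- s != "-" & p != "-"
      data.frame(ref_pos = ref_pos[keep], base = p[keep],
                 stringsAsFactors = FALSE)
    }
  })
}

# single-contig convenience wrapper
project_contig <- function(contig_seq, ref_seq) {
  project_contigs(list(contig_seq), ref_seq)[[1]]
}

# Reference-projected consensus of one accession's contigs for one gene
# model. Disagreeing overlaps become "N"; depth at a position is the maximum
# contig depth covering it (per-contig mean depth stands in for site depth).
consensus_gene_model <- function(contig_seqs, contig_depths, ref_seq,
                                 projections = NULL) {
  L <- nchar(ref_seq)
  base <- rep(NA_character_, L)
  depth <- rep(NA_real_, L)
  if (is.null(projections)) projections <- project_contigs(contig_seqs, ref_seq)
  for (i in seq_along(projections)) {
    pr <- projections[[i]]
    pos <- pr$ref_pos
    fresh <- is.na(base[pos])
    conflict <- !fresh & base[pos] != pr$base
    agree <- !fresh & !conflict
    base[pos[fresh]] <- pr$base[fresh]
    depth[pos[fresh]] <- contig_depths[i]
    base[pos[conflict]] <- "N"
    depth[pos[agree]] <- pmax(depth[pos[agree]], contig_depths[i])
  }
  list(base = base, depth = depth)
}

# Column-wise projection between two reference CDS (global alignment):
# data.frame(posA, posB, baseA, baseB) over aligned (non-gap) columns.
# Equal-length gapless pairs skip the dynamic programme entirely.
pair_projection <- function(seqA, seqB) {
  if (nchar(seqA) == nchar(seqB)) {
    a <- seq_chars(seqA); b <- seq_chars(seqB)
    n_mismatch <- sum(a != b)
    # identical-length sequences with plausible divergence: treat as
    # collinear unless they look unrelated
    if (n_mismatch / length(a) < 0.45) {
      pos <- seq_along(a)
      return(data.frame(posA = pos, posB = pos, baseA = a, baseB = b,
                        stringsAsFactors = FALSE))
    }
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seqA), Biostrings::DNAString(seqB),
    type = "global", substitutionMatrix = nuc_matrix(),
    gapOpening = 4, gapExtension = 2)
  p <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  s <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  posA <- cumsum(p != "-")
  posB <- cumsum(s != "-")
  keep <- p != "-" & s != "-"
  data.frame(posA = posA[keep], posB = posB[keep],
             baseA = p[keep], baseB = s[keep], stringsAsFactors = FALSE)
}

# Pair each reference gene with its homoeologue in the other reference set
# (same ortholog family, maximum nucleotide identity) and list its
# within-genome paralogues. Annotation = data.frame(ref_id, at_id).
reference_families <- function(ann_A, ann_B) {
  fam <- list()
  for (at in unique(c(ann_A$at_id, ann_B$at_id))) {
    fam[[at]] <- list(A = ann_A$ref_id[ann_A$at_id == at],
                      B = ann_B$ref_id[ann_B$at_id == at])
  }
  fam
}

best_homoeologue <- function(ref_seq, candidates, cand_seqs) {
  if (length(candidates) == 0) return(NA_character_)
  if (length(candidates) == 1) return(candidates)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(unname(cand_seqs[candidates])),
    Biostrings::DNAString(ref_seq),
    type = "local", substitutionMatrix = nuc_matrix(),
    gapOpening = 4, gapExtension = 2)
  ids <- Biostrings::nmatch(pa) / pmax(Biostrings::nchar(pa), 1L)
  candidates[which.max(ids)]
}

#' Discover, classify and filter co-dominant SNP markers
#'
#' End-to-end marker development from assigned contigs: per-accession gene
#' models are rebuilt as reference-projected consensus sequences; allelic
#' SNPs are called between the two accessions' models of each gene;
#' HSV/PSV sites are found by projecting each gene onto its homoeologue in
#' the other genome (maximum-identity member of the same ortholog family)
#' and onto its within-genome paralogues; each SNP is then screened with the
#' KASP suitability rules and passing SNPs are formatted as marker sequences
#' with bracketed variable base and lower-case HSV/PSV degeneracy.
#'
#' @param assignments Assignment data.frame from [assign_contigs()].
#' @param contigs Contig data.frame (`contig_id`, `sequence`, `depth`).
#' @param cds_A,transcriptome_B Named reference sequence vectors.
#' @param annotation_A,annotation_B data.frames `ref_id`, `at_id` (reference
#'   metadata: ortholog family of every reference gene).
#' @param exons_A Exon structure data.frame (`ref_id`, `start`, `end`) for
#'   the A reference; used for the junction screen (A-genome markers; B
#'   markers carry no structure and junctions are unevaluable unless
#'   provided).
#' @param exons_B Optional exon structure for B reference genes.
#' @param config A [filter_config()].
#' @param marker_prefix Marker ID prefix (default `"BJ_VH_"`).
#' @return list: `variants` (every called SNP with class, filter verdict and
#'   reasons), `markers` (passing markers with category and formatted
#'   sequence), `funnel` (stage counts), `gene_models` (per-genome counts).
#' @export
discover_markers <- function(assignments, contigs, cds_A, transcriptome_B,
                             annotation_A, annotation_B, exons_A,
                             exons_B = NULL, config = filter_config(),
                             marker_prefix = "BJ_VH_") {
  refs <- c(cds_A, transcriptome_B)
  seq_of <- setNames(contigs$sequence, contigs$contig_id)
  depth_of <- setNames(contigs$depth, contigs$contig_id)
  groups <- group_gene_models(assignments)

  # consensus per (accession, genome, gene model)
  cons <- list()
  for (i in seq_len(nrow(groups))) {
    gid <- groups$gene_model_id[i]
    key <- paste(groups$accession[i], gid, sep = "\r")
    cids <- groups$contigs[[i]]
    cons[[key]] <- consensus_gene_model(seq_of[cids], depth_of[cids],
                                        refs[[gid]])
  }

  accs <- sort(unique(groups$accession))
  if (length(accs) != 2) stop("marker discovery needs exactly two accessions")
  shared <- intersect(
    groups$gene_model_id[groups$accession == accs[1]],
    groups$gene_model_id[groups$accession == accs[2]])
  n_models <- table(factor(groups$genome[match(shared, groups$gene_model_id)],
                           levels = c("A", "B")))

  ann <- rbind(cbind(annotation_A, genome = "A"),
               cbind(annotation_B, genome = "B"))
  junctions_of <- function(gid) {
    ex <- if (gid %in% exons_A$ref_id) {
      exons_A[exons_A$ref_id == gid, ]
    } else if (!is.null(exons_B) && gid %in% exons_B$ref_id) {
      exons_B[exons_B$ref_id == gid, ]
    } else return(NULL)
    ends <- sort(ex$end)
    utils::head(ends, -1)
  }

  variants <- list()
  markers <- list()
  mk_n <- 0L
  for (gid in sort(shared)) {
    genome <- ann$genome[match(gid, ann$ref_id)]
    at <- ann$at_id[match(gid, ann$ref_id)]
    c1 <- cons[[paste(accs[1], gid, sep = "\r")]]
    c2 <- cons[[paste(accs[2], gid, sep = "\r")]]
    aln <- allelic_alignment_from_consensus(gid, c1, c2)
    if (nrow(aln$columns) < config$window_len) next
    snps <- call_snps(aln)
    # homoeologue / paralogue projections for this gene
    same_fam <- ann$ref_id[ann$at_id == at & ann$ref_id != gid]
    homo_ids <- same_fam[ann$genome[match(same_fam, ann$ref_id)] != genome]
    para_ids <- same_fam[ann$genome[match(same_fam, ann$ref_id)] == genome]
    homo <- best_homoeologue(refs[[gid]], homo_ids, refs)
    pr_homo <- if (!is.na(homo)) pair_projection(refs[[gid]], refs[[homo]])
               else NULL
    n_A <- sum(ann$at_id == at & ann$genome == "A")
    n_B <- sum(ann$at_id == at & ann$genome == "B")
    category <- classify_copy_category(n_A, n_B)
    secondary <- data.frame(pos = integer(), base_self = character(),
                            base_other = character(), type = character(),
                            stringsAsFactors = FALSE)
    add_secondary <- function(other_id, type, pr = NULL) {
      if (is.null(pr)) pr <- pair_projection(refs[[gid]], refs[[other_id]])
      diffc <- pr[pr$baseA != pr$baseB, , drop = FALSE]
      if (nrow(diffc) == 0) return(NULL)
      # accession concordance on the focal side: both accessions' consensus
      # (where covered) must agree with the focal reference base
      conc <- vapply(diffc$posA, function(p) {
        b1 <- c1$base[p]; b2 <- c2$base[p]
        all(is.na(c(b1, b2)) | c(b1, b2) == diffc$baseA[match(p, diffc$posA)])
      }, logical(1))
      d <- diffc[conc, , drop = FALSE]
      if (nrow(d) == 0) return(NULL)
      data.frame(pos = d$posA, base_self = d$baseA, base_other = d$baseB,
                 type = type, stringsAsFactors = FALSE)
    }
    if (!is.na(homo)) {
      hv <- add_secondary(homo, "HSV", pr_homo)
      if (!is.null(hv)) secondary <- rbind(secondary, hv)
    }
    for (pid in para_ids) {
      pv <- add_secondary(pid, "PSV")
      if (!is.null(pv)) secondary <- rbind(secondary, pv)
    }
    secondary <- secondary[!duplicated(secondary$pos), , drop = FALSE]
    if (nrow(snps) == 0) next
    jx <- junctions_of(gid)
    if (is.null(jx) && !is.na(homo) && !is.null(pr_homo)) {
      # no own exon structure: project the homoeologue's junctions onto the
      # focal gene (junctions falling in alignment gaps are dropped)
      jx_other <- junctions_of(homo)
      if (!is.null(jx_other)) {
        jx <- pr_homo$posA[match(jx_other, pr_homo$posB)]
        jx <- jx[!is.na(jx)]
      }
    }
    for (v in seq_len(nrow(snps))) {
      var <- snps[v, ]
      verdict <- kaspar_filter(var, aln, jx, config)
      row <- data.frame(
        gene_model_id = gid, genome = genome, at_id = at,
        position = var$position, allele_1 = var$allele_1,
        allele_2 = var$allele_2, depth_1 = var$depth_1,
        depth_2 = var$depth_2, var_class = "allelic_SNP",
        category = category, pass = verdict$pass,
        reasons = paste(verdict$reasons, collapse = ";"),
        stringsAsFactors = FALSE)
      variants[[length(variants) + 1L]] <- row
      if (verdict$pass) {
        mk_n <- mk_n + 1L
        seq_mk <- design_marker_sequence(var, c1$base, secondary, config)
        markers[[length(markers) + 1L]] <- data.frame(
          marker_id = sprintf("%s%04d", marker_prefix, mk_n),
          gene_model_id = gid, genome = genome, at_id = at,
          position = var$position, category = category,
          marker_sequence = seq_mk, stringsAsFactors = FALSE)
      }
    }
  }
  variants <- if (length(variants)) do.call(rbind, variants) else
    data.frame(gene_model_id = character(), genome = character(),
               at_id = character(), position = integer(),
               allele_1 = character(), allele_2 = character(),
               depth_1 = numeric(), depth_2 = numeric(),
               var_class = character(), category = character(),
               pass = logical(), reasons = character(),
               stringsAsFactors = FALSE)
  markers <- if (length(markers)) do.call(rbind, markers) else
    data.frame(marker_id = character(), gene_model_id = character(),
               genome = character(), at_id = character(),
               position = integer(), category = character(),
               marker_sequence = character(), stringsAsFactors = FALSE)
  rownames(variants) <- rownames(markers) <- NULL
  funnel <- c(
    gene_models_overlapping = length(shared),
    gene_models_with_snps = length(unique(variants$gene_model_id)),
    snps_called = nrow(variants),
    snps_passing = sum(variants$pass)
  )
  list(variants = variants, markers = markers, funnel = funnel,
       gene_models = as.data.frame(n_models, stringsAsFactors = FALSE))
}
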