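#' Simulate a complete allopolyploid study with known truth
#'
#' Generates everything the analysis pipeline consumes, with the generating
#' truth attached: dual diploid references (A: CDS + protein + exon structure
#' + genomic sequence with introns; B: transcriptome), two accessions'
#' fragmented contigs with read depths, the true contig-to-subgenome
#' assignment, true allelic SNPs and HSV sites, rearranged linkage-group
#' layouts with replayable event logs, a block definition table derived from
#' the (rearranged) A-genome reference layout, the true genetic map and a
#' simulated DH genotype matrix.
#'
#' History of a gene: ancestral sequence -> triplicated progenitor copies
#' (LF/MF1/MF2, paralogue divergence) -> A and B lineage copies (homoeologue
#' divergence, independent fractionation per lineage) -> two accession
#' haplotypes per retained copy (allelic divergence, A rate > B rate).
#'
#' @param cfg A [sim_config()].
#' @return A list of class `truth_set`; see Details for components.
#' @export
simulate_allopolyploid <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  anc <- make_ancestor(cfg)

  copies_A <- triplicate_and_fractionate(anc, cfg$retention_probs,
                                         derive_seed(cfg$seed, 2L))
  copies_B <- triplicate_and_fractionate(anc, cfg$retention_probs,
                                         derive_seed(cfg$seed, 3L))

  ctr <- 0L
  nxt <- function() {
    ctr <<- ctr + 1L
    derive_seed(cfg$seed, 1000L + ctr)
  }

  # progenitor (post-triplication, pre-split) copies for every gene x class
  # retained in at least one lineage
  anc_seq <- setNames(anc$sequence, anc$gene_id)
  all_copies <- unique(rbind(copies_A[, c("gene_id", "class", "copy_id")],
                             copies_B[, c("gene_id", "class", "copy_id")]))
  all_copies <- all_copies[order(all_copies$copy_id), ]
  progenitor <- setNames(
    vapply(seq_len(nrow(all_copies)), function(i) {
      diverge_sequence(anc_seq[[all_copies$gene_id[i]]],
                       cfg$paralogue_divergence / 2, nxt())
    }, character(1)),
    all_copies$copy_id
  )

  build_reference <- function(copies, genome) {
    ref <- copies
    ref$genome <- genome
    ref$ref_id <- sprintf("ref%s_%s_%s_%03d", genome, ref$block_id,
                          ref$class, ref$pos_in_block)
    ref$sequence <- vapply(ref$copy_id, function(cid) {
      diverge_sequence(progenitor[[cid]], cfg$homoeologue_divergence / 2, nxt())
    }, character(1))
    ref[order(ref$ref_id), ]
  }
  reference_A <- build_reference(copies_A, "A")
  reference_B <- build_reference(copies_B, "B")
  reference_A$protein <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(reference_A$sequence), if.fuzzy.codon = "solve"))

  # accession haplotypes
  hap <- function(ref, rate) {
    lapply(c(acc1 = "acc1", acc2 = "acc2"), function(a) {
      setNames(vapply(ref$sequence, function(s) {
        diverge_sequence(s, rate / 2, nxt())
      }, character(1), USE.NAMES = FALSE), ref$ref_id)
    })
  }
  hap_A <- hap(reference_A, cfg$allelic_snp_rate_A)
  hap_B <- hap(reference_B, cfg$allelic_snp_rate_B)

  # exon structure and intron-containing genomic sequence for reference A
  set.seed(derive_seed(cfg$seed, 4L))
  exon_rows <- vector("list", nrow(reference_A))
  genome_A <- character(nrow(reference_A))
  for (i in seq_len(nrow(reference_A))) {
    L <- nchar(reference_A$sequence[i])
    n_ex <- sample(1:5, 1L)
    cand <- seq(50L, L - 50L, by = 25L)
    n_ex <- min(n_ex, length(cand) + 1L)
    cuts <- if (n_ex > 1) sort(sample(cand, n_ex - 1L)) else integer(0)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, L)
    exon_rows[[i]] <- data.frame(ref_id = reference_A$ref_id[i],
                                 start = starts, end = ends,
                                 stringsAsFactors = FALSE)
    pieces <- substring(reference_A$sequence[i], starts, ends)
    introns <- c(vapply(seq_len(n_ex - 1L),
                        function(k) random_dna(sample(60:120, 1L)),
                        character(1)), "")
    genome_A[i] <- paste0(paste0(pieces, introns), collapse = "")
  }
  exons_A <- do.call(rbind, exon_rows)
  names(genome_A) <- reference_A$ref_id

  # linkage-group layouts with rearrangements
  lay0_A <- build_layout(copies_A, cfg$n_lg_A, "A", derive_seed(cfg$seed, 5L))
  lay0_B <- build_layout(copies_B, cfg$n_lg_B, "B", derive_seed(cfg$seed, 6L))
  rea_A <- apply_rearrangements(lay0_A, cfg$n_rearrangements,
                                derive_seed(cfg$seed, 7L))
  rea_B <- apply_rearrangements(lay0_B, cfg$n_rearrangements,
                                derive_seed(cfg$seed, 8L))

  block_table <- layout_block_table(rea_A$layout, copies_A, anc)

  # true genetic map (loci are reference gene IDs) and DH genotypes
  map_A <- layout_to_map(rea_A$layout, cfg$gene_spacing_cm)
  map_B <- layout_to_map(rea_B$layout, cfg$gene_spacing_cm)
  map_A$marker_id <- reference_A$ref_id[match(map_A$marker_id, reference_A$copy_id)]
  map_B$marker_id <- reference_B$ref_id[match(map_B$marker_id, reference_B$copy_id)]
  true_map <- rbind(map_A, map_B)
  dh <- simulate_dh_genotypes(true_map, cfg$n_dh, derive_seed(cfg$seed, 9L),
                              missing_rate = cfg$missing_rate)

  # accession transcriptomes and fragmented contigs
  contig_sets <- lapply(c(acc1 = "acc1", acc2 = "acc2"), function(a) {
    tr <- c(setNames(hap_A[[a]], paste0(a, ".", names(hap_A[[a]]))),
            setNames(hap_B[[a]], paste0(a, ".", names(hap_B[[a]]))))
    ct <- fragment_to_contigs(tr, cfg$contig_coverage_mean, cfg$depth_mean,
                              derive_seed(cfg$seed, if (a == "acc1") 10L else 11L))
    ct$accession <- a
    ct$ref_id <- sub("^acc[12]\\.", "", ct$transcript_id)
    ct$genome <- ifelse(grepl("^refA_", ct$ref_id), "A", "B")
    ct
  })
  contigs <- do.call(rbind, contig_sets)
  rownames(contigs) <- NULL

  truth_variants <- truth_allelic_variants(reference_A, reference_B,
                                           hap_A, hap_B)
  truth_hsv <- truth_hsv_sites(reference_A, reference_B, hap_A, hap_B)

  structure(list(
    config = cfg,
    ancestor = anc,
    reference_A = reference_A,
    reference_B = reference_B,
    exons_A = exons_A,
    genome_A = genome_A,
    haplotypes_A = hap_A,
    haplotypes_B = hap_B,
    block_table = block_table,
    layout_A = rea_A$layout, layout_B = rea_B$layout,
    layout_A0 = lay0_A, layout_B0 = lay0_B,
    events_A = rea_A$events, events_B = rea_B$events,
    true_map = true_map,
    dh_genotypes = dh,
    contigs = contigs,
    truth_variants = truth_variants,
    truth_hsv = truth_hsv
  ), class = "truth_set")
}

# Block definition table from the (rearranged) reference-A layout: one row per
# segment of a (block, class) pair; multi-segment pairs get sub-labels a/b/c
# in ancestral-chromosome order, mirroring how reference sub-blocks are named.
layout_block_table <- function(layout_A, copies_A, anc) {
  at_of <- setNames(copies_A$at_num, copies_A$copy_id)
  id_of <- setNames(copies_A$at_id, copies_A$copy_id)
  rows <- lapply(seq_len(nrow(layout_A)), function(i) {
    genes <- layout_A$genes[[i]]
    nums <- at_of[genes]
    data.frame(
      block_id = layout_A$block_id[i],
      subgenome_class = layout_A$class[i],
      reference_lg = layout_A$lg[i],
      at_start = id_of[genes[which.min(nums)]],
      at_end = id_of[genes[which.max(nums)]],
      .min = min(nums),
      stringsAsFactors = FALSE
    )
  })
  tbl <- do.call(rbind, rows)
  key <- paste(tbl$block_id, tbl$subgenome_class)
  n_seg <- stats::ave(seq_len(nrow(tbl)), key, FUN = length)
  rank_seg <- stats::ave(tbl$.min, key, FUN = rank)
  tbl$sub_label <- ifelse(n_seg > 1, letters[rank_seg], "")
  tbl$.min <- NULL
  rownames(tbl) <- NULL
  tbl[, c("block_id", "sub_label", "subgenome_class", "reference_lg",
          "at_start", "at_end")]
}

mismatch_positions <- function(a, b) {
  which(charToRaw(a) != charToRaw(b))
}

truth_allelic_variants <- function(reference_A, reference_B, hap_A, hap_B) {
  one_genome <- function(ref, hp, genome) {
    rows <- lapply(ref$ref_id, function(rid) {
      p <- mismatch_positions(hp$acc1[[rid]], hp$acc2[[rid]])
      if (length(p) == 0) return(NULL)
      data.frame(genome = genome, ref_id = rid, pos = p,
                 base_acc1 = substring(hp$acc1[[rid]], p, p),
                 base_acc2 = substring(hp$acc2[[rid]], p, p),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  out <- rbind(one_genome(reference_A, hap_A, "A"),
               one_genome(reference_B, hap_B, "B"))
  if (is.null(out)) out <- data.frame(genome = character(), ref_id = character(),
                                      pos = integer(), base_acc1 = character(),
                                      base_acc2 = character())
  rownames(out) <- NULL
  out
}

# HSV truth: sites where both accessions agree within each genome but the A
# and B homoeologues (same gene, same subgenome class) differ.
truth_hsv_sites <- function(reference_A, reference_B, hap_A, hap_B) {
  key_A <- paste(reference_A$gene_id, reference_A$class)
  key_B <- paste(reference_B$gene_id, reference_B$class)
  shared <- intersect(key_A, key_B)
  rows <- lapply(shared, function(k) {
    ra <- reference_A$ref_id[match(k, key_A)]
    rb <- reference_B$ref_id[match(k, key_B)]
    a1 <- hap_A$acc1[[ra]]; a2 <- hap_A$acc2[[ra]]
    b1 <- hap_B$acc1[[rb]]; b2 <- hap_B$acc2[[rb]]
    p <- mismatch_positions(a1, b1)
    if (length(p)) {
      ok <- substring(a1, p, p) == substring(a2, p, p) &
        substring(b1, p, p) == substring(b2, p, p)
      p <- p[ok]
    }
    if (length(p) == 0) return(NULL)
    data.frame(ref_id_A = ra, ref_id_B = rb, pos = p,
               base_A = substring(a1, p, p), base_B = substring(b1, p, p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(ref_id_A = character(),
                                      ref_id_B = character(), pos = integer(),
                                      base_A = character(), base_B = character())
  rownames(out) <- NULL
  out
}

#' Write a truth set's pipeline inputs to a directory
#'
#' Emits the files a real study would start from: per-accession contig FASTA +
#' depth TSV, reference A protein/CDS FASTA + exon GFF3 + genomic FASTA,
#' reference B transcriptome FASTA, block table TSV, DH genotype TSV and the
#' simulator configuration JSON. All outputs are plain text and byte-stable
#' for a fixed seed.
#'
#' @param ts A `truth_set`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the written paths.
#' @export
write_truth_set <- function(ts, dir) {
  stopifnot(inherits(ts, "truth_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  paths <- list(
    config = p("sim_config.json"),
    ref_A_cds = p("reference_A_cds.fasta"),
    ref_A_pep = p("reference_A_pep.fasta"),
    ref_A_exons = p("reference_A_exons.gff3"),
    ref_A_genome = p("reference_A_genomic.fasta"),
    ref_B = p("reference_B_transcriptome.fasta"),
    block_table = p("block_table.tsv"),
    genotypes = p("dh_genotypes.tsv"),
    true_map = p("true_map.tsv"),
    truth_assignment = p("truth_assignment.tsv")
  )
  write_sim_config(ts$config, paths$config)
  write_fasta(setNames(ts$reference_A$sequence, ts$reference_A$ref_id),
              paths$ref_A_cds)
  write_protein_fasta(setNames(ts$reference_A$protein, ts$reference_A$ref_id),
                      paths$ref_A_pep)
  write_exon_gff3(ts$exons_A, paths$ref_A_exons)
  write_fasta(ts$genome_A, paths$ref_A_genome)
  write_fasta(setNames(ts$reference_B$sequence, ts$reference_B$ref_id),
              paths$ref_B)
  write_block_table(ts$block_table, paths$block_table)
  write_genotype_tsv(ts$dh_genotypes, paths$genotypes)
  write_tsv(ts$true_map, paths$true_map)
  write_tsv(ts$contigs[, c("contig_id", "accession", "genome", "ref_id")],
            paths$truth_assignment)
  for (a in unique(ts$contigs$accession)) {
    ct <- ts$contigs[ts$contigs$accession == a, ]
    paths[[paste0("contigs_", a)]] <- p(sprintf("contigs_%s.fasta", a))
    paths[[paste0("depth_", a)]] <- p(sprintf("depth_%s.tsv", a))
    write_fasta(setNames(ct$sequence, ct$contig_id),
                paths[[paste0("contigs_", a)]])
    write_depth_tsv(data.frame(contig_id = ct$contig_id, mean_depth = ct$depth),
                    paths[[paste0("depth_", a)]])
  }
  invisible(paths)
}
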