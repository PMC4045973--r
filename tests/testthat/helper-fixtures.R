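# Shared fixtures: one small simulated study reused across test files, with
# the assignment and marker stages computed lazily and cached for the run.

.fixture_cache <- new.env(parent = emptyenv())

small_config <- function() {
  sim_config(n_blocks = 6, genes_per_block = 4, seed = 7,
             n_lg_A = 4, n_lg_B = 3, n_rearrangements = 2)
}

small_truth <- function() {
  if (is.null(.fixture_cache$ts)) {
    .fixture_cache$ts <- simulate_allopolyploid(small_config())
  }
  .fixture_cache$ts
}

ref_sets <- function(ts) {
  list(pep = setNames(ts$reference_A$protein, ts$reference_A$ref_id),
       cds_A = setNames(ts$reference_A$sequence, ts$reference_A$ref_id),
       trB = setNames(ts$reference_B$sequence, ts$reference_B$ref_id))
}

small_assignments <- function() {
  if (is.null(.fixture_cache$asg)) {
    ts <- small_truth()
    rs <- ref_sets(ts)
    .fixture_cache$asg <- assign_contigs(
      ts$contigs, proteins_A = rs$pep, cds_A = rs$cds_A,
      transcriptome_B = rs$trB, genome_A = ts$genome_A)
  }
  .fixture_cache$asg
}

small_markers <- function() {
  if (is.null(.fixture_cache$mk)) {
    ts <- small_truth()
    rs <- ref_sets(ts)
    .fixture_cache$mk <- discover_markers(
      small_assignments(), ts$contigs, cds_A = rs$cds_A,
      transcriptome_B = rs$trB,
      annotation_A = ts$reference_A[, c("ref_id", "at_id")],
      annotation_B = ts$reference_B[, c("ref_id", "at_id")],
      exons_A = ts$exons_A)
  }
  .fixture_cache$mk
}

# non-overlapping dinucleotide shuffle (preserves dinucleotide content)
dinucleotide_shuffle <- function(s) {
  n <- nchar(s) - nchar(s) %% 2
  pairs <- substring(s, seq(1, n, 2), seq(2, n, 2))
  paste(sample(pairs), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# allelic alignment built directly from explicit column vectors
make_alignment <- function(pos, base1, base2, depth1, depth2,
                           gap = rep(FALSE, length(pos)), id = "g1") {
  structure(list(gene_model_id = id,
                 columns = data.frame(pos = pos, base1 = base1, base2 = base2,
                                      depth1 = depth1, depth2 = depth2,
                                      gap = gap, stringsAsFactors = FALSE)),
            class = "allelic_alignment")
}
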