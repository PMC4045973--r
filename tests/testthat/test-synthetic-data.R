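# Synthetic-data generator: fractionation, divergence, rearrangements,
# contig fragmentation, DH genotypes, determinism and file round-trips.

test_that("config validation enforces the divergence hierarchy and probabilities", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(retention_probs = c(LF = 1.2, MF1 = 0.5, MF2 = 0.3)),
               "probabilities")
  expect_error(sim_config(paralogue_divergence = 0.05,
                          homoeologue_divergence = 0.07),
               "paralogue_divergence")
  expect_error(sim_config(homoeologue_divergence = 0.004,
                          allelic_snp_rate_A = 0.005),
               "paralogue_divergence")
  expect_error(sim_config(n_rearrangements = -1), "n_rearrangements")
})

test_that("triplication and fractionation follow per-class Bernoulli retention", {
  anc <- make_ancestor(sim_config(n_blocks = 4, genes_per_block = 5, seed = 1))
  all3 <- triplicate_and_fractionate(anc, c(LF = 1, MF1 = 1, MF2 = 1), seed = 1)
  expect_equal(nrow(all3), 3 * nrow(anc))
  expect_equal(as.integer(table(all3$class)), rep(nrow(anc), 3L))

  only_lf <- triplicate_and_fractionate(anc, c(LF = 1, MF1 = 0, MF2 = 0),
                                        seed = 1)
  expect_equal(sort(only_lf$gene_id), sort(anc$gene_id))
  expect_true(all(only_lf$class == "LF"))

  expect_error(triplicate_and_fractionate(anc, c(LF = 1.5, MF1 = 0, MF2 = 0),
                                          seed = 1), "probabilities")

  # binomial expectation at 1000 genes, within 3 sigma per class
  big <- make_ancestor(sim_config(n_blocks = 20, genes_per_block = 50, seed = 2))
  probs <- c(LF = 0.7, MF1 = 0.5, MF2 = 0.3)
  copies <- triplicate_and_fractionate(big, probs, seed = 3)
  n <- nrow(big)
  for (cl in names(probs)) {
    got <- sum(copies$class == cl)
    expect_lt(abs(got - n * probs[[cl]]),
              3 * sqrt(n * probs[[cl]] * (1 - probs[[cl]])))
  }
})

test_that("sequence divergence matches its binomial substitution model", {
  s <- random_dna_str(300)
  expect_identical(diverge_sequence(s, 0, seed = 1), s)
  expect_error(diverge_sequence(s, 0.75, seed = 1), "divergence")
  expect_error(diverge_sequence(s, -0.01, seed = 1), "divergence")

  long <- random_dna_str(10000)
  mut <- diverge_sequence(long, 0.07, seed = 5)
  expect_equal(nchar(mut), nchar(long))
  mism <- sum(charToRaw(long) != charToRaw(mut))
  # every drawn substitution changes the base, so E[mismatches] = n * d
  expect_lt(abs(mism - 700), 3 * sqrt(10000 * 0.07 * 0.93))

  del <- diverge_sequence(long, 0.01, seed = 6, indel_rate = 0.01)
  expect_lt(nchar(del), nchar(long))
})

test_that("rearrangements conserve genes, log replayably, and split as asked", {
  cfg <- small_config()
  anc <- make_ancestor(cfg)
  copies <- triplicate_and_fractionate(anc, cfg$retention_probs, seed = 4)
  lay <- build_layout(copies, 4, "A", seed = 5)

  same <- apply_rearrangements(lay, 0, seed = 1)
  expect_identical(same$layout, lay)
  expect_equal(nrow(same$events), 0)

  rea <- apply_rearrangements(lay, 5, seed = 9)
  expect_setequal(unname(unlist(rea$layout$genes)),
                  unname(unlist(lay$genes)))
  expect_identical(replay_rearrangements(lay, rea$events), rea$layout)
  expect_error(apply_rearrangements(lay, -1, seed = 1), "n_events")

  # an explicit split at gene 37 of a 100-gene segment
  seg <- data.frame(segment_id = c("big", "other"), lg = c("L1", "L2"),
                    block_id = c("A", "B"), class = c("LF", "LF"),
                    seg_order = c(1L, 1L), stringsAsFactors = FALSE)
  seg$genes <- I(list(sprintf("g%03d", 1:100), "x1"))
  ev <- data.frame(event_no = 1, type = "split", segment_id = "big",
                   cut_after = 37, new_segment_id = "big.s1",
                   target_lg = "L2", target_pos = 1L, flip = FALSE,
                   stringsAsFactors = FALSE)
  out <- replay_rearrangements(seg, ev)
  expect_equal(out$genes[[which(out$segment_id == "big")]],
               sprintf("g%03d", 1:37))
  moved <- out[out$segment_id == "big.s1", ]
  expect_equal(moved$lg, "L2")
  expect_equal(moved$genes[[1]], sprintf("g%03d", 38:100))
})

test_that("contig fragmentation covers substrings with Poisson depths", {
  tr <- setNames(vapply(1:40, function(i) random_dna_str(500), character(1)),
                 sprintf("t%02d", 1:40))
  expect_error(fragment_to_contigs(character(0), 0.8, 20, seed = 1), "empty")
  expect_error(fragment_to_contigs(tr, 0, 20, seed = 1), "coverage_mean")

  full <- fragment_to_contigs(tr, 1, 20, seed = 2)
  expect_equal(nrow(full), length(tr))
  expect_identical(unname(full$sequence), unname(tr[full$transcript_id]))

  part <- fragment_to_contigs(tr, 0.7, 20, seed = 3)
  expect_true(all(part$sequence ==
                    substring(tr[part$transcript_id], part$start, part$end)))
  # per-transcript covered span never exceeds the transcript
  for (id in names(tr)) {
    sp <- part[part$transcript_id == id, ]
    expect_lte(sum(sp$end - sp$start + 1), nchar(tr[[id]]))
  }

  many <- fragment_to_contigs(
    setNames(replicate(1000, random_dna_str(300)), sprintf("u%04d", 1:1000)),
    0.9, 20, seed = 4)
  expect_lt(abs(mean(many$depth) - 20), 3 * sqrt(20 / nrow(many)))
})

test_that("DH genotypes realise inverse-Kosambi recombination fractions", {
  map0 <- data.frame(lg = "L1", marker_id = c("m1", "m2"), pos_cm = c(0, 0))
  g0 <- simulate_dh_genotypes(map0, 500, seed = 1)
  expect_true(all(g0["m1", ] == g0["m2", ]))

  map10 <- data.frame(lg = "L1", marker_id = c("m1", "m2"), pos_cm = c(0, 10))
  g10 <- simulate_dh_genotypes(map10, 2000, seed = 2)
  rf <- mean(g10["m1", ] != g10["m2", ])
  r_exp <- 0.5 * tanh(0.2)
  expect_lt(abs(rf - r_exp), 3 * sqrt(r_exp * (1 - r_exp) / 2000))

  map2 <- data.frame(lg = c("L1", "L2"), marker_id = c("m1", "m2"),
                     pos_cm = c(0, 0))
  gx <- simulate_dh_genotypes(map2, 2000, seed = 3)
  rf_x <- mean(gx["m1", ] != gx["m2", ])
  expect_lt(abs(rf_x - 0.5), 3 * sqrt(0.25 / 2000))

  bad <- data.frame(lg = "L1", marker_id = c("m1", "m2"), pos_cm = c(10, 0))
  expect_error(simulate_dh_genotypes(bad, 10, seed = 1), "sorted")
  expect_error(simulate_dh_genotypes(map10, 0, seed = 1), "n_dh")

  miss <- simulate_dh_genotypes(map10, 200, seed = 4, missing_rate = 0.1)
  expect_true(all(miss %in% c("a", "b", "-")))
})

test_that("simulated divergence ordering holds: allelic > homoeologue > paralogue identity", {
  ts <- small_truth()
  ident <- function(a, b) mean(charToRaw(a) == charToRaw(b))
  all_id <- mean(vapply(ts$reference_A$ref_id[1:20], function(r) {
    ident(ts$haplotypes_A$acc1[[r]], ts$haplotypes_A$acc2[[r]])
  }, numeric(1)))
  hsv_pairs <- merge(ts$reference_A, ts$reference_B,
                     by = c("gene_id", "class"))[1:20, ]
  hom_id <- mean(vapply(seq_len(nrow(hsv_pairs)), function(i) {
    ident(hsv_pairs$sequence.x[i], hsv_pairs$sequence.y[i])
  }, numeric(1)))
  para_pairs <- merge(ts$reference_A, ts$reference_A, by = "gene_id")
  para_pairs <- para_pairs[para_pairs$class.x < para_pairs$class.y, ][1:20, ]
  par_id <- mean(vapply(seq_len(nrow(para_pairs)), function(i) {
    ident(para_pairs$sequence.x[i], para_pairs$sequence.y[i])
  }, numeric(1)))
  expect_gt(all_id, hom_id)
  expect_gt(hom_id, par_id)
})

test_that("a fixed seed yields byte-identical emitted files", {
  cfg <- sim_config(n_blocks = 3, genes_per_block = 3, seed = 31,
                    n_lg_A = 2, n_lg_B = 2, n_rearrangements = 1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_truth_set(simulate_allopolyploid(cfg), d1)
  write_truth_set(simulate_allopolyploid(cfg), d2)
  files <- list.files(d1)
  expect_identical(files, list.files(d2))
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6),
                     info = f)
  }
})

test_that("emitted files round-trip through the package readers", {
  ts <- small_truth()
  d <- withr::local_tempdir()
  paths <- write_truth_set(ts, d)

  cds <- read_fasta(paths$ref_A_cds)
  expect_identical(unname(cds[ts$reference_A$ref_id]), ts$reference_A$sequence)

  exons <- read_exon_gff3(paths$ref_A_exons)
  orig <- ts$exons_A[order(ts$exons_A$ref_id, ts$exons_A$start), ]
  rownames(orig) <- rownames(exons) <- NULL
  expect_equal(exons, orig)

  g <- read_genotype_tsv(paths$genotypes)
  expect_identical(g, ts$dh_genotypes)

  bt <- read_block_table(paths$block_table)
  expect_identical(bt$block_id, ts$block_table$block_id)
  expect_identical(bt$at_start, ts$block_table$at_start)

  dep <- read_depth_tsv(paths$depth_acc1)
  ct1 <- ts$contigs[ts$contigs$accession == "acc1", ]
  expect_identical(dep$contig_id, ct1$contig_id)
  expect_identical(dep$mean_depth, ct1$depth)

  cfg2 <- read_sim_config(paths$config)
  expect_equal(unclass(cfg2), unclass(ts$config))
})
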