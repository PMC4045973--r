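# Variant calling between accessions, SNP/HSV/PSV classification, KASP
# suitability filters, copy categories, marker formatting, funnel arithmetic.

test_that("allelic alignment reports mismatch columns on accession-1 coordinates", {
  s <- random_dna_str(300)
  same <- align_alleles(s, s)
  expect_equal(sum(same$columns$base1 != same$columns$base2), 0)

  x <- strsplit(s, "")[[1]]
  x[120] <- setdiff(c("A", "C", "G", "T"), x[120])[1]
  one <- align_alleles(s, paste(x, collapse = ""))
  snps <- call_snps(one)
  expect_equal(nrow(snps), 1)
  expect_equal(snps$position, 120)

  # overlap shorter than the marker window is unusable
  short <- align_alleles(substr(s, 1, 80), substr(s, 1, 80), window_len = 101)
  expect_equal(nrow(short$columns), 0)
  expect_equal(nrow(call_snps(short)), 0)
})

test_that("substitutions are called, indel and N columns are not", {
  s <- random_dna_str(400)
  x <- strsplit(s, "")[[1]]
  for (p in c(100, 200, 300)) x[p] <- setdiff(c("A", "C", "G", "T"), x[p])[1]
  x <- x[-350]                             # one deletion
  res <- call_snps(align_alleles(s, paste(x, collapse = "")))
  expect_equal(res$position, c(100, 200, 300))

  aln <- make_alignment(1:3, c("A", "N", "G"), c("C", "T", "G"), 10, 10)
  expect_equal(call_snps(aln)$position, 1L)
})

test_that("calls equal a brute-force haplotype column scan on simulated genes", {
  ts <- small_truth()
  ids <- ts$reference_A$ref_id[1:10]
  for (rid in ids) {
    h1 <- ts$haplotypes_A$acc1[[rid]]
    h2 <- ts$haplotypes_A$acc2[[rid]]
    got <- call_snps(align_alleles(h1, h2, gene_model_id = rid))
    want <- which(charToRaw(h1) != charToRaw(h2))
    expect_equal(got$position, want, info = rid)
    expect_identical(got$allele_1, substring(h1, want, want))
    expect_identical(got$allele_2, substring(h2, want, want))
  }
})

test_that("sites classify as allelic SNP, HSV, PSV or undetermined by definition", {
  expect_identical(classify_variant("G", "A", homoeologue = c("A", "A")),
                   "allelic_SNP")
  expect_identical(classify_variant("G", "G", homoeologue = c("A", "A")),
                   "HSV")
  expect_identical(classify_variant("G", "G", homoeologue = c("G", "G"),
                                    paralogue = c("T", "T")), "PSV")
  expect_identical(classify_variant("G", "G", homoeologue = c("G", "G")),
                   "none")
  expect_identical(classify_variant("G", "G", homoeologue = c("-", "A")),
                   "undetermined")
  expect_identical(classify_variant(NA, "A"), "undetermined")
  # HSV takes precedence when both contrasts differ
  expect_identical(classify_variant("G", "G", homoeologue = c("A", "A"),
                                    paralogue = c("T", "T")), "HSV")
})

test_that("the KASP filter enforces depth, conserved flanks and junction screens", {
  n <- 300
  base <- strsplit(random_dna_str(n), "")[[1]]
  aln <- make_alignment(1:n, base, base, 20, 20)
  aln$columns$base2[150] <- setdiff(c("A", "C", "G", "T"), base[150])[1]
  v <- call_snps(aln)
  expect_equal(nrow(v), 1)

  ok <- kaspar_filter(v, aln, exon_junctions = integer(0))
  expect_true(ok$pass)

  v_low <- v; v_low$depth_1 <- 6
  expect_identical(kaspar_filter(v_low, aln, integer(0))$reasons, "depth")

  # a second mismatch inside the left flank breaks conservation
  aln2 <- aln
  aln2$columns$base2[120] <- setdiff(c("A", "C", "G", "T"), base[120])[1]
  v2 <- call_snps(aln2)
  f <- kaspar_filter(v2[v2$position == 150, ], aln2, integer(0))
  expect_false(f$pass)
  expect_true("flank" %in% f$reasons)

  # variant 39 bases from the start cannot carry a 50-base flank
  aln3 <- make_alignment(1:n, base, base, 20, 20)
  aln3$columns$base2[40] <- setdiff(c("A", "C", "G", "T"), base[40])[1]
  v3 <- call_snps(aln3)
  expect_true("flank" %in% kaspar_filter(v3, aln3, integer(0))$reasons)

  # junction 20 bases right of the variant falls inside the window
  expect_true("junction" %in% kaspar_filter(v, aln, 170)$reasons)
  expect_true(kaspar_filter(v, aln, 250)$pass)
  ju <- kaspar_filter(v, aln, NULL)
  expect_false(ju$pass)
  expect_true("junction_unevaluable" %in% ju$reasons)
})

test_that("the KASP filter equals a brute-force window re-scan on random variants", {
  set.seed(1234)
  cfg <- filter_config()
  n <- 400
  for (case in 1:250) {
    base <- strsplit(random_dna_str(n), "")[[1]]
    b2 <- base
    nmut <- sample(0:4, 1)
    mut <- if (nmut) sample(60:340, nmut) else integer(0)
    for (p in mut) b2[p] <- setdiff(c("A", "C", "G", "T"), b2[p])[1]
    # random coverage hole and random depths
    pos <- setdiff(1:n, if (runif(1) < 0.3) sample(1:n, 30) else integer(0))
    d1 <- sample(4:20, 1); d2 <- sample(4:20, 1)
    aln <- make_alignment(pos, base[pos], b2[pos], d1, d2)
    jx <- if (runif(1) < 0.5) sort(sample(50:350, 2)) else integer(0)
    snps <- call_snps(aln)
    for (v in seq_len(nrow(snps))) {
      var <- snps[v, ]
      got <- kaspar_filter(var, aln, jx, cfg)
      # independent re-check: explicit window scan on the raw vectors
      p <- var$position
      deep <- d1 >= 7 && d2 >= 7
      win <- setdiff((p - 50):(p + 50), p)
      flank_ok <- all(win >= 1) && all(win <= n) && all(win %in% pos) &&
        !any(win %in% mut)
      junc_ok <- !any(jx >= p - 50 & jx < p + 50)
      expect_identical(got$pass, deep && flank_ok && junc_ok,
                       info = paste(case, p))
    }
  }
})

test_that("copy-number categories follow the three-way published rule", {
  expect_identical(classify_copy_category(0, 1), "i_B_unique")
  expect_identical(classify_copy_category(1, 1), "ii_single_copy_both")
  expect_identical(classify_copy_category(2, 1), "iii_multi_copy")
  expect_identical(classify_copy_category(1, 3), "iii_multi_copy")
  expect_identical(classify_copy_category(1, 0), "i_A_unique")
  expect_error(classify_copy_category(0, 0), "zero copies")
})

test_that("marker sequences carry one bracketed base and lower-case degeneracy", {
  model <- strsplit(random_dna_str(300), "")[[1]]
  var <- data.frame(position = 150, allele_1 = "A", allele_2 = "G",
                    stringsAsFactors = FALSE)
  clean <- design_marker_sequence(var, model, NULL)
  expect_equal(nchar(clean), 101 - 1 + 5)
  expect_equal(substr(clean, 51, 55), "[A/G]")
  expect_equal(lengths(regmatches(clean, gregexpr("\\[", clean))), 1)
  expect_identical(substr(clean, 1, 50),
                   toupper(paste(model[100:149], collapse = "")))

  # an HSV with states C/T ten bases left renders as lower-case "y"
  sec <- data.frame(pos = 140, base_self = "T", base_other = "C",
                    stringsAsFactors = FALSE)
  hsv <- design_marker_sequence(var, model, sec)
  expect_identical(substr(hsv, 41, 41), "y")

  near_end <- data.frame(position = 280, allele_1 = "A", allele_2 = "G")
  expect_error(design_marker_sequence(near_end, model, NULL), "window")
})

test_that("funnel arithmetic validates monotone chains and exact removals", {
  ok <- funnel_report(c(input = 100, kept = 60, markers = 45),
                      removed = c(40, 15))
  expect_equal(ok$count, c(100, 60, 45))
  expect_equal(ok$removed_from_previous, c(NA, 40, 15))
  expect_error(funnel_report(c(100, 120)), "non-increasing")
  expect_error(funnel_report(c(100, 60), removed = 30), "equal the previous")
})

test_that("marker discovery on simulated data is precise, sensitive and A-skewed", {
  ts <- small_truth()
  mk <- small_markers()
  expect_gt(sum(mk$variants$genome == "A"), sum(mk$variants$genome == "B"))
  expect_false(any(duplicated(mk$markers$marker_id)))
  expect_true(all(grepl("^BJ_VH_", mk$markers$marker_id)))
  expect_true(all(vapply(mk$markers$marker_sequence, function(s) {
    length(regmatches(s, gregexpr("\\[[ACGT]/[ACGT]\\]", s))[[1]]) == 1
  }, logical(1))))

  called <- paste(mk$variants$gene_model_id, mk$variants$position)
  truthv <- paste(ts$truth_variants$ref_id, ts$truth_variants$pos)
  expect_gte(mean(called %in% truthv), 0.95)   # precision

  # recall over truth sites covered by both accessions' contigs
  covered <- function(rid, acc, p) {
    ct <- ts$contigs[ts$contigs$ref_id == rid & ts$contigs$accession == acc, ]
    any(ct$start <= p & p <= ct$end)
  }
  tv <- ts$truth_variants
  reachable <- vapply(seq_len(nrow(tv)), function(i) {
    covered(tv$ref_id[i], "acc1", tv$pos[i]) &&
      covered(tv$ref_id[i], "acc2", tv$pos[i])
  }, logical(1))
  expect_gte(mean(truthv[reachable] %in% called), 0.95)  # recall
})
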