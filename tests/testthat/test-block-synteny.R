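# Ancestral-block painting: ortholog-ID parsing, block assignment, per-LG
# calling rules, homoeology links, fragmentation classes, motifs, and truth
# recovery against the simulator's rearrangement log.

demo_block_table <- function() {
  data.frame(
    block_id = c("A", "A", "E", "R", "W"),
    sub_label = c("", "", "", "", ""),
    subgenome_class = c("LF", "MF1", "LF", "MF2", "MF2"),
    reference_lg = c("A10", "A3", "A7", "A2", "A2"),
    at_start = c("At1g02220", "At1g02220", "At2g31040", "At4g12750",
                 "At4g00030"),
    at_end = c("At1g19330", "At1g19330", "At2g47730", "At4g16143",
               "At4g12620"),
    stringsAsFactors = FALSE)
}

test_that("ortholog IDs parse, order and reject malformed input", {
  p <- parse_at_id("At1g02220")
  expect_equal(p$chromosome, 1)
  expect_equal(p$number, 2220)
  expect_identical(parse_at_id("AT3G10000")$at_id, "At3g10000")
  expect_error(parse_at_id("Bra012345"), "malformed")
  expect_error(parse_at_id("At6g10000"), "malformed")

  k <- function(x) parse_at_id(x)$chromosome * 1e5 + parse_at_id(x)$number
  expect_lt(k("At1g07630"), k("At1g07640"))
  expect_lt(k("At1g99999"), k("At2g00001"))
})

test_that("markers match every block interval containing their ID, closed ends", {
  tbl <- demo_block_table()
  inside <- assign_marker_block("At1g05000", tbl)
  expect_setequal(inside$subgenome_class, c("LF", "MF1"))
  expect_true(all(inside$block_id == "A"))

  expect_equal(nrow(assign_marker_block("At2g01000", tbl)), 0)
  expect_equal(assign_marker_block("At1g02220", tbl)$block_id,
               c("A", "A"))                  # boundary is inside
  expect_equal(assign_marker_block("At1g19330", tbl)$block_id, c("A", "A"))
})

mk_markers <- function(lg, blocks, classes, at, cm = seq_along(blocks)) {
  data.frame(marker_id = sprintf("%s_k%02d", lg, seq_along(blocks)),
             lg = lg, pos_cm = cm, block_id = blocks,
             subgenome_class = classes, at_id = at,
             stringsAsFactors = FALSE)
}

test_that("block calls respect the per-genome evidence rules and run breaking", {
  one <- mk_markers("B1", "E", "LF", "At2g31040")
  expect_equal(nrow(call_blocks(one, "B")), 0)   # B needs two markers
  expect_equal(nrow(call_blocks(one, "A")), 1)   # A accepts one

  two <- mk_markers("B1", c("E", "E"), "LF", c("At2g31040", "At2g35000"))
  callB <- call_blocks(two, "B")
  expect_equal(nrow(callB), 1)
  expect_equal(callB$n_markers, 2)
  expect_identical(callB$at_min, "At2g31040")

  # one intervening marker of another block splits the run
  mix <- mk_markers("A1", c("E", "E", "R", "E", "E"),
                    c("LF", "LF", "MF2", "LF", "LF"),
                    c("At2g31040", "At2g33000", "At4g13000", "At2g35000",
                      "At2g36000"))
  calls <- call_blocks(mix, "B")
  expect_equal(sum(calls$block_id == "E"), 2)

  # orientation from ortholog-vs-cM correlation
  fwd <- call_blocks(mk_markers("A2", c("E", "E", "E"), "LF",
                                c("At2g31040", "At2g33000", "At2g35000")), "A")
  expect_identical(fwd$orientation, "+")
  rev_ <- call_blocks(mk_markers("A2", c("E", "E", "E"), "LF",
                                 c("At2g35000", "At2g33000", "At2g31040")), "A")
  expect_identical(rev_$orientation, "-")
})

test_that("homoeology links need two shared single-copy markers and overlap", {
  callsA <- call_blocks(mk_markers("A7", c("E", "E", "E"), "LF",
                                   c("At2g31040", "At2g33000", "At2g35000")),
                        "A")
  callsB <- call_blocks(mk_markers("B4", c("E", "E", "E"), "LF",
                                   c("At2g31040", "At2g33000", "At2g40000")),
                        "B")
  cat_ii <- data.frame(at_id = c("At2g31040", "At2g33000"),
                       marker_id_A = c("A7_k01", "A7_k02"),
                       marker_id_B = c("B4_k01", "B4_k02"),
                       stringsAsFactors = FALSE)
  links <- infer_homoeology(callsA, callsB, cat_ii, min_shared = 2)
  expect_equal(nrow(links), 1)
  expect_equal(links$n_shared, 2)

  expect_equal(nrow(infer_homoeology(callsA, callsB, cat_ii[1, ],
                                     min_shared = 2)), 0)
  expect_equal(nrow(infer_homoeology(callsA, callsB, cat_ii[0, ],
                                     min_shared = 2)), 0)
  # raising min_shared never increases the link count
  n_links <- vapply(1:3, function(ms) {
    nrow(infer_homoeology(callsA, callsB, cat_ii, min_shared = ms))
  }, numeric(1))
  expect_true(all(diff(n_links) <= 0))
})

test_that("fragmentation classes distinguish split, intact, duplicated, absent", {
  # the A(LF) pattern: one B segment, two disjoint A segments
  callsA <- rbind(
    call_blocks(mk_markers("A10", c("A", "A"), "LF",
                           c("At1g02220", "At1g07630")), "A"),
    call_blocks(mk_markers("A6", c("A", "A"), "LF",
                           c("At1g07640", "At1g19330")), "A"))
  callsB <- call_blocks(mk_markers("B4", c("A", "A", "A"), "LF",
                                   c("At1g02220", "At1g10000", "At1g19330")),
                        "B")
  fr <- fragmentation_compare("A", "LF", callsA, callsB)
  expect_identical(fr$classification, "split_in_A")
  expect_equal(nrow(fr$segments), 3)

  sym <- fragmentation_compare("A", "LF", callsB, callsB)
  expect_identical(sym$classification, "intact_both")

  none <- fragmentation_compare("A", "LF", callsA[0, ], callsB)
  expect_identical(none$classification, "absent_in_one")

  dupA <- rbind(
    call_blocks(mk_markers("A1", c("A", "A"), "LF",
                           c("At1g02220", "At1g19330")), "A"),
    call_blocks(mk_markers("A2", c("A", "A"), "LF",
                           c("At1g03000", "At1g18000")), "A"))
  dup <- fragmentation_compare("A", "LF", dupA, callsB)
  expect_identical(dup$classification, "duplicated")
})

test_that("association motifs are shared up to reversal", {
  callsA <- call_blocks(mk_markers("A2", c("R", "R", "W", "W", "E", "E",
                                           "O", "O"),
                                   "MF2",
                                   sprintf("At4g%05d", c(12750, 12800, 11000,
                                                         11100, 10000, 10100,
                                                         9000, 9100))), "A")
  ordB <- mk_markers("B2", c("O", "O", "E", "E", "W", "W", "R", "R"), "MF2",
                     sprintf("At4g%05d", c(9000, 9100, 10000, 10100, 11000,
                                           11100, 12750, 12800)))
  callsB <- call_blocks(ordB, "B")
  res <- association_motifs(callsA, callsB)
  expect_identical(res$motifs_A$A2, c("R", "W", "E", "O"))
  expect_equal(nrow(res$shared), 1)
  expect_identical(res$shared$motif, "R-W-E-O")

  disjoint <- call_blocks(mk_markers("B9", c("K", "K", "V", "V"), "LF",
                                     sprintf("At5g%05d", c(100, 200, 300,
                                                           400))), "B")
  expect_equal(nrow(association_motifs(callsA, disjoint)$shared), 0)
})

test_that("simulated block splits are recovered and unrearranged blocks stay intact", {
  ts <- small_truth()
  mk_from_map <- function(map, ref) {
    m <- merge(map, ref[, c("ref_id", "block_id", "class", "at_id")],
               by.x = "marker_id", by.y = "ref_id")
    data.frame(marker_id = m$marker_id, lg = m$lg, pos_cm = m$pos_cm,
               block_id = m$block_id, subgenome_class = m$class,
               at_id = m$at_id, stringsAsFactors = FALSE)
  }
  map_A <- ts$true_map[grepl("^refA", ts$true_map$marker_id), ]
  map_B <- ts$true_map[grepl("^refB", ts$true_map$marker_id), ]
  calls_A <- call_blocks(mk_from_map(map_A, ts$reference_A), "A")
  calls_B <- call_blocks(mk_from_map(map_B, ts$reference_B), "B")

  seg_truth <- function(layout) {
    key <- paste(layout$block_id, layout$class)
    tab <- table(key)
    names(tab)[tab > 1]
  }
  split_A <- seg_truth(ts$layout_A)
  split_B <- seg_truth(ts$layout_B)
  both_called <- intersect(paste(calls_A$block_id, calls_A$subgenome_class),
                           paste(calls_B$block_id, calls_B$subgenome_class))
  for (key in both_called) {
    parts <- strsplit(key, " ")[[1]]
    fr <- fragmentation_compare(parts[1], parts[2], calls_A, calls_B)
    in_A <- key %in% split_A
    in_B <- key %in% split_B
    want <- if (in_A && in_B) "split_both"
            else if (in_A) "split_in_A"
            else if (in_B) "split_in_B"
            else "intact_both"
    expect_identical(fr$classification, want, info = key)
  }
})
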