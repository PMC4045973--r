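# End-to-end orchestration: simulate -> assign -> markers -> map -> blocks,
# with a machine-readable run report whose totals are re-countable from the
# written TSVs.

#' Pipeline configuration
#'
#' One top-level seed drives every stage (per-stage seeds are derived from
#' it deterministically); defaults equal the published thresholds: E-value
#' 1e-5, identity 80%/100 bp, depth 7, flanks 50, window 101, grouping LOD
#' 4.0, two shared single-copy markers for homoeology, block evidence 1
#' marker (A) / 2 markers (B).
#'
#' @param outdir Output directory for all stage files.
#' @param seed Top-level integer seed.
#' @param sim A [sim_config()] (its own seed is overridden by `seed`).
#' @param assign An [assign_config()].
#' @param filter A [filter_config()].
#' @param lod_threshold Grouping LOD (default 4.0).
#' @param alpha Segregation-distortion level (default 0.05).
#' @param min_shared Shared single-copy markers required for a homoeology
#'   link (default 2).
#' @param min_markers_A,min_markers_B Block evidence rules per genome.
#' @param stages Character vector of stages to run, in order.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1, sim = sim_config(),
                            assign = assign_config(),
                            filter = filter_config(),
                            lod_threshold = 4.0, alpha = 0.05,
                            min_shared = 2, min_markers_A = 1,
                            min_markers_B = 2,
                            stages = c("simulate", "assign", "markers",
                                       "map", "blocks")) {
  structure(list(outdir = outdir, seed = as.integer(seed), sim = sim,
                 assign = assign, filter = filter,
                 lod_threshold = lod_threshold, alpha = alpha,
                 min_shared = min_shared, min_markers_A = min_markers_A,
                 min_markers_B = min_markers_B, stages = stages),
            class = "pipeline_config")
}

#' Run the analysis pipeline end to end
#'
#' Executes the configured stages in dependency order on a simulated study
#' (or a supplied `truth_set`), writing every stage's tables under
#' `config$outdir` and returning a run report with per-stage counts, the
#' marker-development funnel and the derived per-stage seeds. A stage whose
#' prerequisites were not run raises an error.
#'
#' @param config A [pipeline_config()].
#' @param truth_set Optional pre-built [simulate_allopolyploid()] output;
#'   when supplied the simulate stage reuses it (its config must carry the
#'   derived stage seed for byte-identical reruns).
#' @return The run report (list of class `run_report`).
#' @export
run_pipeline <- function(config, truth_set = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages
  report <- list(seed = config$seed,
                 package_version = as.character(utils::packageVersion("allomap")),
                 stage_seeds = list(), stages = list(), outputs = list())
  need <- function(stage, have) {
    if (is.null(have)) {
      stop("stage '", stage, "' requires a prior stage that was not run")
    }
    have
  }

  ts <- truth_set
  if ("simulate" %in% st) {
    sim_seed <- derive_seed(config$seed, 101L)
    report$stage_seeds$simulate <- sim_seed
    if (is.null(ts)) {
      sim_cfg <- config$sim
      sim_cfg$seed <- sim_seed
      ts <- simulate_allopolyploid(validate_sim_config(sim_cfg))
    }
    paths <- write_truth_set(ts, config$outdir)
    report$outputs$inputs <- unname(unlist(paths))
    report$stages$simulate <- list(
      n_reference_A = nrow(ts$reference_A),
      n_reference_B = nrow(ts$reference_B),
      n_contigs = nrow(ts$contigs),
      n_true_allelic_snps = nrow(ts$truth_variants))
  }

  assignments <- NULL
  if ("assign" %in% st) {
    ts <- need("assign", ts)
    assignments <- assign_contigs(
      ts$contigs,
      proteins_A = setNames(ts$reference_A$protein, ts$reference_A$ref_id),
      cds_A = setNames(ts$reference_A$sequence, ts$reference_A$ref_id),
      transcriptome_B = setNames(ts$reference_B$sequence, ts$reference_B$ref_id),
      genome_A = ts$genome_A,
      config = config$assign)
    f <- file.path(config$outdir, "assignments.tsv")
    write_tsv(assignments[, c("contig_id", "accession", "verdict",
                              "gene_model_id", "identity_pct",
                              "aligned_length", "step", "reason")], f)
    report$outputs$assignments <- f
    vt <- table(factor(assignments$verdict,
                       levels = c("A", "B", "B_specific", "ambiguous",
                                  "removed")))
    report$stages$assign <- c(list(n_input = nrow(assignments)),
                              as.list(as.integer(vt)) |>
                                setNames(paste0("n_", names(vt))))
    if (sum(vt) != nrow(assignments)) stop("verdicts do not partition contigs")
  }

  mk <- NULL
  if ("markers" %in% st) {
    assignments <- need("markers", assignments)
    mk <- discover_markers(
      assignments, ts$contigs,
      cds_A = setNames(ts$reference_A$sequence, ts$reference_A$ref_id),
      transcriptome_B = setNames(ts$reference_B$sequence, ts$reference_B$ref_id),
      annotation_A = ts$reference_A[, c("ref_id", "at_id")],
      annotation_B = ts$reference_B[, c("ref_id", "at_id")],
      exons_A = ts$exons_A, config = config$filter)
    fv <- file.path(config$outdir, "variants.tsv")
    fm <- file.path(config$outdir, "markers.tsv")
    write_tsv(mk$variants, fv)
    write_tsv(mk$markers, fm)
    report$outputs$variants <- fv
    report$outputs$markers <- fm
    report$stages$markers <- as.list(mk$funnel)
    report$stages$markers$n_markers <- nrow(mk$markers)
    report$stages$markers$n_snps_A <-
      sum(mk$variants$genome == "A")
    report$stages$markers$n_snps_B <-
      sum(mk$variants$genome == "B")
  }

  lm <- NULL
  mapped <- NULL
  if ("map" %in% st) {
    mk <- need("map", mk)
    # one locus per gene model (the first passing marker), genotyped on the
    # simulated DH population
    sel <- mk$markers[!duplicated(mk$markers$gene_model_id), , drop = FALSE]
    sel <- sel[sel$gene_model_id %in% rownames(ts$dh_genotypes), , drop = FALSE]
    g <- ts$dh_genotypes[sel$gene_model_id, , drop = FALSE]
    rownames(g) <- sel$marker_id
    lm <- build_linkage_map(g, lod_threshold = config$lod_threshold,
                            alpha = config$alpha)
    fmap <- file.path(config$outdir, "linkage_map.tsv")
    write_tsv(lm$map, fmap)
    report$outputs$map <- fmap
    report$stages$map <- list(
      n_markers_tested = nrow(g),
      n_distorted_excluded = length(lm$distorted),
      n_mapped = nrow(lm$map),
      n_linkage_groups = length(lm$groups),
      total_length_cm = round(map_length(lm$map)$total_cm, 1))
    mapped <- merge(lm$map, sel, by = "marker_id")
  }

  if ("blocks" %in% st) {
    mapped <- need("blocks", mapped)
    ann_class <- rbind(
      data.frame(ref_id = ts$reference_A$ref_id, class = ts$reference_A$class,
                 stringsAsFactors = FALSE),
      data.frame(ref_id = ts$reference_B$ref_id, class = ts$reference_B$class,
                 stringsAsFactors = FALSE))
    mapped$subgenome_class <- ann_class$class[match(mapped$gene_model_id,
                                                    ann_class$ref_id)]
    mapped$block_id <- vapply(seq_len(nrow(mapped)), function(i) {
      cand <- assign_marker_block(mapped$at_id[i], ts$block_table)
      cand <- cand[cand$subgenome_class == mapped$subgenome_class[i], ,
                   drop = FALSE]
      if (nrow(cand) == 0) NA_character_ else cand$block_id[1]
    }, character(1))
    mk_df <- mapped[, c("marker_id", "lg", "pos_cm", "block_id",
                        "subgenome_class", "at_id", "genome")]
    calls_A <- call_blocks(mk_df[mk_df$genome == "A", ], "A",
                           config$min_markers_A)
    calls_B <- call_blocks(mk_df[mk_df$genome == "B", ], "B",
                           config$min_markers_B)
    cat_ii <- category_ii_table(mapped)
    links <- infer_homoeology(calls_A, calls_B, cat_ii, config$min_shared)
    frag_keys <- unique(rbind(calls_A[, c("block_id", "subgenome_class")],
                              calls_B[, c("block_id", "subgenome_class")]))
    frags <- lapply(seq_len(nrow(frag_keys)), function(i) {
      fr <- fragmentation_compare(frag_keys$block_id[i],
                                  frag_keys$subgenome_class[i],
                                  calls_A, calls_B)
      data.frame(block_id = fr$block_id, subgenome_class = fr$subgenome_class,
                 classification = fr$classification,
                 n_segments_A = sum(fr$segments$genome == "A"),
                 n_segments_B = sum(fr$segments$genome == "B"),
                 stringsAsFactors = FALSE)
    })
    frags <- do.call(rbind, frags)
    motifs <- association_motifs(calls_A, calls_B)
    drop_list_cols <- function(d) d[, !vapply(d, is.list, logical(1)), drop = FALSE]
    fb <- file.path(config$outdir, "block_calls.tsv")
    fl <- file.path(config$outdir, "homoeology_links.tsv")
    ff <- file.path(config$outdir, "fragmentation.tsv")
    fs <- file.path(config$outdir, "shared_motifs.tsv")
    write_tsv(drop_list_cols(rbind(calls_A, calls_B)), fb)
    write_tsv(drop_list_cols(links), fl)
    write_tsv(frags, ff)
    write_tsv(motifs$shared, fs)
    report$outputs$blocks <- c(fb, fl, ff, fs)
    report$stages$blocks <- list(
      n_block_calls_A = nrow(calls_A),
      n_block_calls_B = nrow(calls_B),
      n_homoeology_links = nrow(links),
      n_fragmentation_records = nrow(frags),
      n_shared_motifs = nrow(motifs$shared))
    report$block_calls <- list(A = calls_A, B = calls_B)
    report$homoeology <- links
    report$fragmentation <- frags
  }

  class(report) <- "run_report"
  report
}

# single-copy (category ii) marker loci mapped in both genomes
category_ii_table <- function(mapped) {
  ii <- mapped[mapped$category == "ii_single_copy_both", , drop = FALSE]
  ats <- intersect(ii$at_id[ii$genome == "A"], ii$at_id[ii$genome == "B"])
  if (length(ats) == 0) {
    return(data.frame(at_id = character(), marker_id_A = character(),
                      marker_id_B = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    at_id = ats,
    marker_id_A = vapply(ats, function(a) {
      ii$marker_id[ii$at_id == a & ii$genome == "A"][1]
    }, character(1)),
    marker_id_B = vapply(ats, function(a) {
      ii$marker_id[ii$at_id == a & ii$genome == "B"][1]
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Write and verify a run report
#'
#' `write_report()` writes the report as JSON plus a TSV stage-count summary
#' and validates it against the shipped schema. `verify_report()` re-counts
#' the rows of the written stage TSVs and errors if any total disagrees with
#' the report (tamper/corruption check).
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param dir Directory to write `report.json` and `report_summary.tsv` into.
#' @return `write_report()` invisibly returns the JSON path;
#'   `verify_report()` invisibly returns TRUE on success.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  validate_report(report)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  slim <- report[c("seed", "package_version", "stage_seeds", "stages",
                   "outputs")]
  pj <- file.path(dir, "report.json")
  jsonlite::write_json(slim, pj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rows <- list()
  for (stage in names(report$stages)) {
    cnt <- report$stages[[stage]]
    rows[[stage]] <- data.frame(stage = stage, metric = names(cnt),
                                value = as.numeric(unlist(cnt)),
                                stringsAsFactors = FALSE)
  }
  write_tsv(do.call(rbind, rows) %||%
              data.frame(stage = character(), metric = character(),
                         value = numeric()),
            file.path(dir, "report_summary.tsv"))
  invisible(pj)
}

#' @rdname write_report
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(
    system.file("extdata", "report-schema.json", package = "allomap"),
    simplifyVector = TRUE)
  missing <- setdiff(schema$required, names(report))
  if (length(missing)) {
    stop("report violates schema; missing fields: ",
         paste(missing, collapse = ", "))
  }
  for (stage in names(report$stages)) {
    v <- unlist(report$stages[[stage]])
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0)) {
      stop("report violates schema: stage '", stage,
           "' has non-numeric or negative counts")
    }
  }
  invisible(TRUE)
}

#' @rdname write_report
#' @param report_dir Directory holding `report.json`.
#' @export
verify_report <- function(report_dir) {
  rep <- jsonlite::read_json(file.path(report_dir, "report.json"),
                             simplifyVector = TRUE)
  recount <- function(path) nrow(read_tsv(path))
  checks <- list(
    c("assignments", "assign", "n_input"),
    c("variants", "markers", "snps_called"),
    c("map", "map", "n_mapped")
  )
  for (ck in checks) {
    path <- rep$outputs[[ck[1]]]
    if (is.null(path) || is.null(rep$stages[[ck[2]]])) next
    got <- recount(path)
    want <- rep$stages[[ck[2]]][[ck[3]]]
    if (got != want) {
      stop("recount mismatch for ", ck[1], ": report says ", want,
           ", file has ", got)
    }
  }
  invisible(TRUE)
}
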