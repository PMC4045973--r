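#' Marker-suitability filter configuration
#'
#' Defaults are the published KASP-suitability thresholds: site read depth of
#' at least 7 in both accessions, a conserved flank of at least 50 bp on each
#' side, and no exon-intron junction inside the 101 bp window containing the
#' variable base.
#'
#' @param min_depth Minimum read depth per accession at the site.
#' @param flank_len Conserved flank length on each side, bases.
#' @param window_len Screening window length; must equal `2*flank_len + 1`.
#' @param require_conserved_flanks Enforce the flank rule (default TRUE).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 7, flank_len = 50, window_len = 101,
                          require_conserved_flanks = TRUE) {
  if (window_len != 2 * flank_len + 1) {
    stop("window_len must equal 2*flank_len + 1")
  }
  structure(list(min_depth = min_depth, flank_len = flank_len,
                 window_len = window_len,
                 require_conserved_flanks = require_conserved_flanks),
            class = "filter_config")
}

#' Align the allelic gene models of two accessions
#'
#' Ends-free (overlap) pairwise alignment of the two accessions' sequences
#' for one gene model. Positions are reported on the accession-1 sequence.
#' If the aligned overlap is shorter than `window_len` the alignment is
#' empty: no marker window could ever fit.
#'
#' @param seq1,seq2 Gene-model sequences of accession 1 and accession 2.
#' @param gene_model_id Identifier carried into results.
#' @param depth1,depth2 Per-accession mean read depths at the gene model
#'   (scalar or per-position vector on each accession's sequence).
#' @param window_len Minimum usable overlap (default 101).
#' @return Object of class `allelic_alignment`: list with `gene_model_id`
#'   and `columns`, a data.frame of aligned column pairs (`pos` on accession
#'   1, `base1`, `base2`, `depth1`, `depth2`, `gap`).
#' @export
align_alleles <- function(seq1, seq2, gene_model_id = NA_character_,
                          depth1 = NA_real_, depth2 = NA_real_,
                          window_len = 101) {
  stopifnot(nchar(seq1) > 0, nchar(seq2) > 0)
  mat <- nuc_matrix()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq1), Biostrings::DNAString(seq2),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  if (length(p) < window_len) {
    cols <- data.frame(pos = integer(), base1 = character(),
                       base2 = character(), depth1 = numeric(),
                       depth2 = numeric(), gap = logical(),
                       stringsAsFactors = FALSE)
    return(structure(list(gene_model_id = gene_model_id, columns = cols),
                     class = "allelic_alignment"))
  }
  start1 <- BiocGenerics::start(Biostrings::pattern(pa))
  start2 <- BiocGenerics::start(Biostrings::subject(pa))
  pos1 <- start1 - 1L + cumsum(p != "-")
  pos1[p == "-"] <- NA_integer_
  pos2 <- start2 - 1L + cumsum(s != "-")
  pos2[s == "-"] <- NA_integer_
  d1 <- if (length(depth1) > 1) depth1[pos1] else rep(depth1, length(p))
  d2 <- if (length(depth2) > 1) depth2[pos2] else rep(depth2, length(p))
  cols <- data.frame(pos = pos1, base1 = p, base2 = s,
                     depth1 = d1, depth2 = d2,
                     gap = p == "-" | s == "-", stringsAsFactors = FALSE)
  structure(list(gene_model_id = gene_model_id, columns = cols),
            class = "allelic_alignment")
}

# build an allelic_alignment directly from two reference-projected consensus
# arrays (base/depth per reference position; NA where uncovered)
allelic_alignment_from_consensus <- function(gene_model_id, cons1, cons2) {
  both <- which(!is.na(cons1$base) & !is.na(cons2$base))
  cols <- data.frame(pos = both,
                     base1 = cons1$base[both], base2 = cons2$base[both],
                     depth1 = cons1$depth[both], depth2 = cons2$depth[both],
                     gap = FALSE, stringsAsFactors = FALSE)
  structure(list(gene_model_id = gene_model_id, columns = cols),
            class = "allelic_alignment")
}

#' Call substitution variants from an allelic alignment
#'
#' One variant per mismatching substitution column; gap and ambiguous (`N`)
#' columns are never emitted as variants.
#'
#' @param alignment An `allelic_alignment`.
#' @return data.frame: `gene_model_id`, `position`, `allele_1`, `allele_2`,
#'   `depth_1`, `depth_2`. Zero rows for an all-match alignment.
#' @export
call_snps <- function(alignment) {
  stopifnot(inherits(alignment, "allelic_alignment"))
  cc <- alignment$columns
  hit <- !cc$gap & cc$base1 != cc$base2 &
    cc$base1 %in% BASES & cc$base2 %in% BASES
  out <- data.frame(gene_model_id = rep(alignment$gene_model_id, sum(hit)),
                    position = cc$pos[hit],
                    allele_1 = cc$base1[hit], allele_2 = cc$base2[hit],
                    depth_1 = cc$depth1[hit], depth_2 = cc$depth2[hit],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify a site as allelic SNP, HSV or PSV
#'
#' Within one genome's gene model: the two accessions differing at the site is
#' an allelic SNP; accessions agreeing while the projected homoeologue (both
#' accessions concordant) carries a different base is an HSV; accessions
#' agreeing while a paralogue carries a different base is a PSV. A site that
#' cannot be projected (gap / missing base) is `undetermined`. When both the
#' homoeologue and a paralogue differ, HSV takes precedence (the cross-genome
#' contrast is the one marker design must tolerate first).
#'
#' @param base_acc1,base_acc2 Site bases of the two accessions in the focal
#'   genome.
#' @param homoeologue Length-2 vector: the two accessions' bases at the
#'   projected site in the other genome, or `NULL` if no homoeologue.
#' @param paralogue Length-2 vector for a within-genome paralogue, or `NULL`.
#' @return One of `"allelic_SNP"`, `"HSV"`, `"PSV"`, `"none"`,
#'   `"undetermined"`.
#' @export
classify_variant <- function(base_acc1, base_acc2, homoeologue = NULL,
                             paralogue = NULL) {
  ok <- function(x) !is.null(x) && !any(is.na(x)) && all(x %in% BASES)
  if (!ok(c(base_acc1, base_acc2))) return("undetermined")
  if (base_acc1 != base_acc2) return("allelic_SNP")
  if (!is.null(homoeologue)) {
    if (!ok(homoeologue)) return("undetermined")
    if (homoeologue[1] == homoeologue[2] && homoeologue[1] != base_acc1) {
      return("HSV")
    }
  }
  if (!is.null(paralogue)) {
    if (!ok(paralogue)) return("undetermined")
    if (paralogue[1] == paralogue[2] && paralogue[1] != base_acc1) {
      return("PSV")
    }
  }
  "none"
}

#' KASP suitability filter for one variant
#'
#' Pass requires: read depth at least `min_depth` in both accessions;
#' `flank_len` alignment columns on each side all present, matching and
#' gap-free (conserved flanks); and no exon-intron junction inside the
#' `window_len` window centred on the variant. A missing exon structure makes
#' the junction check unevaluable and the verdict fail (conservative).
#'
#' @param variant One row from [call_snps()].
#' @param alignment The `allelic_alignment` the variant came from.
#' @param exon_junctions Integer vector of junction positions (a junction
#'   after base `j` of the gene model lies between `j` and `j+1`), or
#'   `NULL` when unknown.
#' @param config A [filter_config()].
#' @return list with `pass` (logical) and `reasons` (character vector, empty
#'   when passing).
#' @export
kaspar_filter <- function(variant, alignment, exon_junctions,
                          config = filter_config()) {
  stopifnot(inherits(alignment, "allelic_alignment"))
  cc <- alignment$columns
  reasons <- character(0)
  if (is.na(variant$depth_1) || is.na(variant$depth_2) ||
      variant$depth_1 < config$min_depth || variant$depth_2 < config$min_depth) {
    reasons <- c(reasons, "depth")
  }
  p <- variant$position
  fl <- config$flank_len
  if (config$require_conserved_flanks) {
    want <- setdiff(seq(p - fl, p + fl), p)
    ix <- match(want, cc$pos)
    flank_ok <- !any(is.na(ix)) &&
      !any(cc$gap[ix]) &&
      all(cc$base1[ix] == cc$base2[ix]) &&
      all(cc$base1[ix] %in% BASES)
    if (!flank_ok) reasons <- c(reasons, "flank")
  }
  if (is.null(exon_junctions)) {
    reasons <- c(reasons, "junction_unevaluable")
  } else if (length(exon_junctions) > 0 &&
             any(exon_junctions >= p - fl & exon_junctions < p + fl)) {
    reasons <- c(reasons, "junction")
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Copy-number marker category of a gene family
#'
#' The three published categories: (i) unique to the B genome (single copy in
#' the allotetraploid), (ii) one A copy with one B homoeologue (two copies),
#' (iii) multiple A paralogues with one or more B homoeologues. A single A
#' copy without any B homoeologue is reported as `"i_A_unique"` for symmetry.
#'
#' @param n_copies_A,n_copies_B Copy counts per genome.
#' @return One of `"i_B_unique"`, `"i_A_unique"`, `"ii_single_copy_both"`,
#'   `"iii_multi_copy"`.
#' @export
classify_copy_category <- function(n_copies_A, n_copies_B) {
  stopifnot(n_copies_A >= 0, n_copies_B >= 0)
  if (n_copies_A + n_copies_B == 0) {
    stop("gene family with zero copies in both genomes")
  }
  if (n_copies_A == 0) return("i_B_unique")
  if (n_copies_B == 0 && n_copies_A == 1) return("i_A_unique")
  if (n_copies_A == 1 && n_copies_B == 1) return("ii_single_copy_both")
  "iii_multi_copy"
}

IUPAC_CODE <- c(
  "AC" = "m", "AG" = "r", "AT" = "w",
  "CG" = "s", "CT" = "y", "GT" = "k",
  "ACG" = "v", "ACT" = "h", "AGT" = "d", "CGT" = "b", "ACGT" = "n"
)

iupac_lower <- function(bases) {
  u <- sort(unique(toupper(bases)))
  if (length(u) == 1) return(tolower(u))
  code <- IUPAC_CODE[[paste(u, collapse = "")]]
  if (is.null(code)) stop("cannot encode bases: ", paste(u, collapse = ","))
  code
}

#' Format a marker sequence for a passing variant
#'
#' The published convention: a `window_len` stretch centred on the variable
#' base, the target site rendered `[X/Y]`, HSV/PSV sites inside the window in
#' lower case (an IUPAC degenerate code when the two states must both be
#' tolerated), all other bases upper case.
#'
#' @param variant One passing row from [call_snps()].
#' @param window_bases Character vector: the accession-1 gene-model bases of
#'   the full model (indexed by position).
#' @param secondary_variants data.frame of HSV/PSV sites on this gene model:
#'   columns `pos`, `base_self`, `base_other`.
#' @param config A [filter_config()].
#' @return The formatted marker sequence string.
#' @export
design_marker_sequence <- function(variant, window_bases, secondary_variants,
                                   config = filter_config()) {
  p <- variant$position
  fl <- config$flank_len
  if (p - fl < 1 || p + fl > length(window_bases)) {
    stop("marker window extends past the gene model")
  }
  win <- toupper(window_bases[(p - fl):(p + fl)])
  if (!is.null(secondary_variants) && nrow(secondary_variants) > 0) {
    sv <- secondary_variants[secondary_variants$pos >= p - fl &
                               secondary_variants$pos <= p + fl &
                               secondary_variants$pos != p, , drop = FALSE]
    for (i in seq_len(nrow(sv))) {
      win[sv$pos[i] - (p - fl) + 1L] <-
        iupac_lower(c(sv$base_self[i], sv$base_other[i]))
    }
  }
  centre <- sprintf("[%s/%s]", toupper(variant$allele_1),
                    toupper(variant$allele_2))
  paste0(paste(win[1:fl], collapse = ""), centre,
         paste(win[(fl + 2):(2 * fl + 1)], collapse = ""))
}

#' Marker-development funnel arithmetic
#'
#' Validates an ordered chain of stage counts: counts must be monotone
#' non-increasing and, when removals are supplied, kept + removed must equal
#' the previous stage exactly.
#'
#' @param counts Named numeric vector of stage counts in pipeline order.
#' @param removed Optional numeric vector of per-step removals
#'   (`length(counts) - 1`).
#' @return data.frame `stage`, `count`, `removed_from_previous`.
#' @export
funnel_report <- function(counts, removed = NULL) {
  if (length(counts) < 1) stop("no stages registered")
  if (any(diff(counts) > 0)) stop("funnel counts must be non-increasing")
  drops <- -diff(counts)
  if (!is.null(removed)) {
    if (length(removed) != length(counts) - 1) {
      stop("removed must have one entry per step")
    }
    if (any(removed != drops)) {
      stop("kept + removed does not equal the previous stage count")
    }
  }
  data.frame(stage = names(counts) %||% as.character(seq_along(counts)),
             count = as.numeric(counts),
             removed_from_previous = c(NA, drops),
             row.names = NULL, stringsAsFactors = FALSE)
}
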