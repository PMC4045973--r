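#' Configuration for the allopolyploid simulator
#'
#' Bundles every tunable of the synthetic-data generator. Defaults encode the
#' biological structure the analysis assumes: a triplicated ancestor
#' fractionated into LF/MF1/MF2 subgenome copies, paralogue divergence larger
#' than homoeologue divergence (older triplication, younger A/B split), and
#' two accessions whose A subgenomes are more polymorphic than their B
#' subgenomes.
#'
#' @param n_blocks Number of ancestral gene blocks, labelled `A`..`X`
#'   (default 24, the full ancestral crucifer karyotype block set).
#' @param genes_per_block Genes per ancestral block.
#' @param gene_length Length of each gene's CDS in bases (rounded up to a
#'   multiple of 3).
#' @param retention_probs Named numeric `c(LF=, MF1=, MF2=)`: per-subgenome
#'   class probability that a gene copy is retained after fractionation.
#'   LF (least fractionated) retains most genes.
#' @param paralogue_divergence Expected substitutions/site between LF/MF1/MF2
#'   paralogous copies within one genome (older event).
#' @param homoeologue_divergence Expected substitutions/site between A and B
#'   homoeologues of the same copy (younger event). Must be smaller than
#'   `paralogue_divergence`.
#' @param allelic_snp_rate_A,allelic_snp_rate_B Expected substitutions/site
#'   between the two accessions within the A (resp. B) subgenome. The A rate
#'   defaults higher: the A subgenomes of the two accessions are the more
#'   variable pair.
#' @param n_rearrangements Block-level translocation/split events applied to
#'   each genome's linkage-group layout.
#' @param contig_coverage_mean Mean fraction of a transcript covered by its
#'   assembled contigs, in (0, 1].
#' @param depth_mean Mean per-contig read depth (Poisson, floored at 1).
#' @param n_dh Number of doubled-haploid individuals genotyped.
#' @param missing_rate Fraction of genotype calls set to missing.
#' @param indel_rate Optional per-site indel rate for `diverge_sequence()`
#'   (default 0: the variant analysis counts substitutions only).
#' @param gene_spacing_cm Genetic distance in cM between adjacent genes on the
#'   true map.
#' @param n_lg_A,n_lg_B Number of linkage groups per genome (defaults 10 and 8).
#' @param seed Integer seed; a fixed seed makes every simulator output
#'   byte-identical.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(genes_per_block = 2, seed = 1)
#' cfg$retention_probs
#' @export
sim_config <- function(n_blocks = 24,
                       genes_per_block = 8,
                       gene_length = 500,
                       retention_probs = c(LF = 0.85, MF1 = 0.55, MF2 = 0.35),
                       paralogue_divergence = 0.12,
                       homoeologue_divergence = 0.07,
                       allelic_snp_rate_A = 0.005,
                       allelic_snp_rate_B = 0.003,
                       n_rearrangements = 3,
                       contig_coverage_mean = 0.8,
                       depth_mean = 20,
                       n_dh = 123,
                       missing_rate = 0.02,
                       indel_rate = 0,
                       gene_spacing_cm = 1,
                       n_lg_A = 10,
                       n_lg_B = 8,
                       seed = 1) {
  cfg <- list(
    n_blocks = as.integer(n_blocks),
    genes_per_block = as.integer(genes_per_block),
    gene_length = as.integer(ceiling(gene_length / 3) * 3),
    retention_probs = retention_probs,
    paralogue_divergence = paralogue_divergence,
    homoeologue_divergence = homoeologue_divergence,
    allelic_snp_rate_A = allelic_snp_rate_A,
    allelic_snp_rate_B = allelic_snp_rate_B,
    n_rearrangements = as.integer(n_rearrangements),
    contig_coverage_mean = contig_coverage_mean,
    depth_mean = depth_mean,
    n_dh = as.integer(n_dh),
    missing_rate = missing_rate,
    indel_rate = indel_rate,
    gene_spacing_cm = gene_spacing_cm,
    n_lg_A = as.integer(n_lg_A),
    n_lg_B = as.integer(n_lg_B),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rp <- cfg$retention_probs
  if (!all(c("LF", "MF1", "MF2") %in% names(rp))) {
    stop("retention_probs must be named LF, MF1, MF2")
  }
  probs <- c(rp, cfg$missing_rate, cfg$contig_coverage_mean)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (cfg$contig_coverage_mean <= 0) stop("contig_coverage_mean must be in (0, 1]")
  if (!(cfg$paralogue_divergence > cfg$homoeologue_divergence &&
        cfg$homoeologue_divergence > max(cfg$allelic_snp_rate_A,
                                         cfg$allelic_snp_rate_B))) {
    stop("require paralogue_divergence > homoeologue_divergence > allelic rates")
  }
  if (cfg$n_blocks < 1 || cfg$n_blocks > 24) stop("n_blocks must be in 1..24")
  if (cfg$n_rearrangements < 0) stop("n_rearrangements must be >= 0")
  if (cfg$n_dh < 1) stop("n_dh must be >= 1")
  cfg
}

#' Write / read a simulator configuration as JSON
#'
#' @param cfg A [sim_config()] object.
#' @param path File path.
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  x <- unclass(cfg)
  x$retention_probs <- as.list(x$retention_probs)   # keep names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$retention_probs <- unlist(x$retention_probs)
  do.call(sim_config, x)
}
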