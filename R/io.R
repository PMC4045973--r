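# File-format helpers. Sequence I/O goes through Biostrings, exon structure
# through rtracklayer GFF3; tabular interchange is plain TSV.

#' Read and write FASTA
#'
#' @param x Named character vector of sequences.
#' @param path File path.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path, width = 70)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}

write_protein_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(x), path, width = 70)
  invisible(path)
}

read_protein_fasta <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  setNames(as.character(s), names(s))
}

#' Read and write the per-contig depth sidecar
#'
#' Two tab-separated columns: `contig_id`, `mean_depth`.
#' @param depths data.frame with `contig_id` and `mean_depth`.
#' @param path File path.
#' @export
write_depth_tsv <- function(depths, path) {
  stopifnot(all(c("contig_id", "mean_depth") %in% names(depths)))
  write_tsv(depths[, c("contig_id", "mean_depth")], path)
}

#' @rdname write_depth_tsv
#' @export
read_depth_tsv <- function(path) {
  read_tsv(path, colClasses = c(contig_id = "character"))
}

#' Read and write a DH genotype matrix
#'
#' Rows are markers, columns individuals; calls are `a`, `b` or `-`.
#' @param g Character matrix with marker rownames.
#' @param path File path.
#' @export
write_genotype_tsv <- function(g, path) {
  df <- data.frame(marker_id = rownames(g), g, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$marker_id
  m
}

#' Read and write exon structure as GFF3 (transcript coordinates)
#'
#' Exon intervals are 1-based closed, on the transcript (`seqid` = gene-model
#' ID), which is the coordinate system the exon-junction marker screen uses.
#'
#' @param exons data.frame with `ref_id`, `start`, `end`.
#' @param path File path.
#' @export
write_exon_gff3 <- function(exons, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = exons$ref_id,
    ranges = IRanges::IRanges(exons$start, exons$end),
    type = "exon"
  )
  gr$ID <- sprintf("%s.exon%d", exons$ref_id,
                   stats::ave(seq_len(nrow(exons)), exons$ref_id, FUN = seq_along))
  gr$Parent <- exons$ref_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_exon_gff3
#' @export
read_exon_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "exon"]
  df <- data.frame(
    ref_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE
  )
  df[order(df$ref_id, df$start), ]
}

#' Read and write the ancestral block definition table
#'
#' Columns: `block_id`, `sub_label`, `subgenome_class`, `reference_lg`,
#' `at_start`, `at_end` (ortholog-ID interval endpoints, closed).
#' @param tbl Block table data.frame.
#' @param path File path.
#' @export
write_block_table <- function(tbl, path) {
  cols <- c("block_id", "sub_label", "subgenome_class", "reference_lg",
            "at_start", "at_end")
  stopifnot(all(cols %in% names(tbl)))
  write_tsv(tbl[, cols], path)
}

#' @rdname write_block_table
#' @export
read_block_table <- function(path) {
  tbl <- read_tsv(path, colClasses = "character")
  validate_block_table(tbl)
  tbl
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", ...)
}
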