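#' Write / read genome annotation as GFF3
#'
#' @param annotation Data.frame (`gene_id`, `start`, `end`, `strand`,
#'   `tss`).
#' @param path Output file.
#' @param seqname Chromosome name used in the GFF3.
#' @return `path`, invisibly.
#' @export
write_genome_gff3 <- function(annotation, path, seqname = "chr") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end),
    strand = annotation$strand
  )
  S4Vectors::mcols(gr)$ID <- annotation$gene_id
  S4Vectors::mcols(gr)$type <- "gene"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_genome_gff3
#' @export
read_genome_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  strand <- as.character(GenomicRanges::strand(gr))
  data.frame(
    gene_id = as.character(S4Vectors::mcols(gr)$ID),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = strand,
    tss = ifelse(strand == "+", GenomicRanges::start(gr),
                 GenomicRanges::end(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write / read a binned density track as bedGraph
#'
#' One bedGraph interval per bin; bins are half-open
#' `[start, start + bin_width)` windows in 1-based coordinates (the
#' 0-based bedGraph convention is handled by the exporter).
#'
#' @param track A `density_track`.
#' @param path Output file.
#' @param seqname Chromosome name.
#' @return `path`, invisibly.
#' @export
write_density_bedgraph <- function(track, path, seqname = "chr") {
  n <- length(track$values)
  bw <- track$bin_width
  origin <- track$origin %||% 1L
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = origin + (seq_len(n) - 1L) * bw,
                              width = bw),
    score = track$values
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_density_bedgraph
#' @param genome_length Optional chromosome length; defaults to the end
#'   of the last interval.
#' @export
read_density_bedgraph <- function(path, genome_length = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- sort(gr)
  w <- GenomicRanges::width(gr)
  bw <- min(w)
  origin <- min(GenomicRanges::start(gr))
  last <- max(GenomicRanges::end(gr))
  genome_length <- genome_length %||% (last - origin + 1)
  n_bins <- as.integer(ceiling(genome_length / bw))
  values <- numeric(n_bins)
  # expand runs the exporter may have merged back into per-bin values
  for (i in seq_along(gr)) {
    b0 <- as.integer((GenomicRanges::start(gr)[i] - origin) / bw) + 1L
    b1 <- as.integer((GenomicRanges::end(gr)[i] + 1L - origin) / bw)
    values[b0:b1] <- S4Vectors::mcols(gr)$score[i]
  }
  structure(
    list(bin_width = as.integer(bw), origin = origin,
         genome_length = genome_length, values = values),
    class = "density_track"
  )
}

#' Write / read an operon map as TSV
#'
#' Columns `operon_id`, `gene_id`, `rank` (transcription order,
#' 1 = leader).
#'
#' @param operons Operon data.frame.
#' @param path File path.
#' @return `path` / the operon data.frame.
#' @export
write_operon_tsv <- function(operons, path) {
  utils::write.table(operons, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_operon_tsv
#' @export
read_operon_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write / read a numeric matrix as TSV with row ids
#'
#' @param mat Numeric matrix with rownames.
#' @param path File path.
#' @param id_column Name of the first (identifier) column.
#' @return `path` / the matrix.
#' @export
write_matrix_tsv <- function(mat, path, id_column = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  mat
}

#' Read processed supplementary tables for a reproduction run
#'
#' Loads the processed expression, ChIP-flag, proteomics and hierarchy
#' tables of a published dataset from a directory of TSV exports (one
#' file per sheet: `expression.tsv` with per-condition normalized
#' values, `chip_flags.tsv` with `gene_id` and a logical
#' `chip_enriched`, `proteome.tsv`, `hierarchy.tsv`, `lengths.tsv`).
#' This is the entry point for re-running the classifiers on the
#' article-distributed processed data instead of synthetic input.
#'
#' @param dir Directory containing the TSV exports.
#' @return A named list of data.frames/matrices (missing files are
#'   omitted).
#' @export
read_supplementary_tables <- function(dir) {
  if (!dir.exists(dir)) {
    stop("supplementary data directory not found: ", dir, call. = FALSE)
  }
  out <- list()
  f <- function(name) file.path(dir, name)
  if (file.exists(f("expression.tsv"))) {
    out$expression <- read_matrix_tsv(f("expression.tsv"))
  }
  if (file.exists(f("chip_flags.tsv"))) {
    out$chip_flags <- utils::read.table(f("chip_flags.tsv"), header = TRUE,
                                        sep = "\t", stringsAsFactors = FALSE)
  }
  if (file.exists(f("proteome.tsv"))) {
    out$proteome <- read_matrix_tsv(f("proteome.tsv"))
  }
  if (file.exists(f("samples.tsv"))) {
    out$samples <- utils::read.table(f("samples.tsv"), header = TRUE,
                                     sep = "\t", stringsAsFactors = FALSE)
  }
  if (file.exists(f("hierarchy.tsv"))) {
    out$hierarchy <- utils::read.table(f("hierarchy.tsv"), header = TRUE,
                                       sep = "\t", stringsAsFactors = FALSE)
  }
  if (file.exists(f("lengths.tsv"))) {
    out$lengths <- utils::read.table(f("lengths.tsv"), header = TRUE,
                                     sep = "\t", stringsAsFactors = FALSE)
  }
  out
}
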