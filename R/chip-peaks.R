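#' Call peaks on a binned read-density track
#'
#' A peak is a maximal contiguous run of bins whose density stays above
#' the threshold (strictly above by default).  Each peak is summarized
#' by its maximum - reported at the center of the (leftmost) maximal bin,
#' so positions carry the +/- bin_width uncertainty inherent to binned
#' data - and by its area, the sum of density over the run's bins.
#'
#' @param track A `density_track` (see [simulate_chip_track()] or
#'   [read_density_bedgraph()]).
#' @param config A [peak_caller_config()].
#' @return A data.frame, one row per peak, sorted by genomic position:
#'   `peak_id`, `start_bin`, `end_bin` (1-based inclusive bin indices),
#'   `start`, `end` (bp), `max_position` (bp, bin center of the leftmost
#'   maximal bin), `max_density`, `area`.
#' @export
call_peaks <- function(track, config = peak_caller_config()) {
  values <- track$values
  if (length(values) == 0L) {
    stop("empty density track", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("negative densities in track", call. = FALSE)
  }
  above <- if (config$strict) values > config$threshold else
    values >= config$threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  bw <- track$bin_width
  origin <- track$origin %||% 1L
  rows <- lapply(seq_along(keep), function(k) {
    i <- keep[k]
    s <- starts[i]; e <- ends[i]
    v <- values[s:e]
    m <- which.max(v)          # leftmost maximal bin
    mbin <- s + m - 1L
    data.frame(
      peak_id = sprintf("peak%04d", k),
      start_bin = s, end_bin = e,
      start = origin + (s - 1L) * bw,
      end = origin + e * bw - 1L,
      max_position = origin + (mbin - 1L) * bw + (bw - 1) / 2,
      max_density = v[m],
      area = sum(v),
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0L) {
    return(data.frame(peak_id = character(), start_bin = integer(),
                      end_bin = integer(), start = numeric(), end = numeric(),
                      max_position = numeric(), max_density = numeric(),
                      area = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Assign peaks to genes by the promoter window
#'
#' A gene collects a peak when its translation start lies within
#' `upstream_window` bp upstream through `downstream_window` bp
#' downstream of the peak maximum, measured along the gene's direction
#' of transcription (set `strand_relative = FALSE` in the config for
#' absolute plus-strand coordinates).  A peak may hit several genes and
#' a gene may collect several peaks.
#'
#' @param peaks Output of [call_peaks()].
#' @param annotation Genome annotation data.frame (`gene_id`, `strand`,
#'   `tss`).
#' @param config A [peak_caller_config()].
#' @return A data.frame, one row per (gene, peak) hit: `gene_id`,
#'   `peak_id`, `distance` (signed bp from translation start to peak
#'   maximum; negative = peak upstream of the start), `max_position`,
#'   `area`, `via_operon` (always `FALSE` here).
#' @export
assign_peaks_to_genes <- function(peaks, annotation,
                                  config = peak_caller_config()) {
  assert_columns(annotation, c("gene_id", "strand", "tss"), "annotation")
  if (any(!annotation$strand %in% c("+", "-"))) {
    stop("annotation contains genes without a valid strand", call. = FALSE)
  }
  empty <- data.frame(gene_id = character(), peak_id = character(),
                      distance = numeric(), max_position = numeric(),
                      area = numeric(), via_operon = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L) return(empty)
  strand_sign <- ifelse(config$strand_relative & annotation$strand == "-",
                        -1, 1)
  hits <- lapply(seq_len(nrow(peaks)), function(i) {
    # u > 0: peak maximum lies upstream of the translation start
    u <- (annotation$tss - peaks$max_position[i]) * strand_sign
    sel <- u >= -config$downstream_window & u <= config$upstream_window
    if (!any(sel)) return(NULL)
    data.frame(
      gene_id = annotation$gene_id[sel],
      peak_id = peaks$peak_id[i],
      distance = -u[sel],
      max_position = peaks$max_position[i],
      area = peaks$area[i],
      via_operon = FALSE,
      stringsAsFactors = FALSE
    )
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) empty else hits[order(hits$gene_id, hits$peak_id), ]
}

#' Propagate promoter peaks through operons
#'
#' Flags each gene as a direct (promoter-bound) target when it carries a
#' window-assigned peak itself, or when any gene upstream of it in
#' transcription order within the same operon does - a promoter-proximal
#' peak affects every gene transcribed after it, but never genes before
#' it.  Genes outside operons use only their own assignments.
#'
#' @param assignments Output of [assign_peaks_to_genes()].
#' @param operons Operon map data.frame (`operon_id`, `gene_id`,
#'   `rank`), members listed in transcription order.
#' @param annotation Genome annotation (defines the gene universe).
#' @return A data.frame, one row per gene: `gene_id`, `direct`,
#'   `via_operon` (inherited rather than own peak), `own_peak`,
#'   `n_peaks` (own window hits), `peaks` (comma-joined supporting peak
#'   ids, own plus inherited).
#' @export
propagate_operons <- function(assignments, operons, annotation) {
  if (anyDuplicated(operons$gene_id)) {
    stop("gene listed in more than one operon", call. = FALSE)
  }
  genes <- annotation$gene_id
  own <- genes %in% assignments$gene_id
  names(own) <- genes
  own_peaks <- split(assignments$peak_id, assignments$gene_id)
  direct <- own
  support <- lapply(genes, function(g) own_peaks[[g]] %||% character())
  names(support) <- genes

  if (nrow(operons) > 0L) {
    ord <- order(operons$operon_id, operons$rank)
    for (members in split(operons$gene_id[ord], operons$operon_id[ord])) {
      inherited <- character()
      for (g in members) {
        support[[g]] <- unique(c(support[[g]], inherited))
        inherited <- unique(c(inherited, own_peaks[[g]] %||% character()))
        direct[g] <- own[g] || length(support[[g]]) > 0L
      }
    }
  }
  data.frame(
    gene_id = genes,
    direct = unname(direct),
    via_operon = unname(direct & !own),
    own_peak = unname(own),
    n_peaks = vapply(genes, function(g)
      length(own_peaks[[g]] %||% character()), integer(1)),
    peaks = vapply(support, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Compare called direct-target flags with planted truth
#'
#' @param flags Output of [propagate_operons()].
#' @param truth Optional [plant_regulon()] table; when supplied the
#'   confusion matrix of the `direct` flag is computed against it.
#' @return A list: `table` (per-gene flags, joined with truth when
#'   given), and with truth also `confusion` (tp/fp/tn/fn),
#'   `sensitivity`, `specificity`.
#' @export
summarize_enrichment <- function(flags, truth = NULL) {
  if (is.null(truth)) {
    return(list(table = flags))
  }
  if (!setequal(flags$gene_id, truth$gene_id)) {
    stop("gene universes of flags and truth do not align", call. = FALSE)
  }
  called <- flags$direct[match(truth$gene_id, flags$gene_id)]
  tp <- sum(called & truth$direct)
  fp <- sum(called & !truth$direct)
  fn <- sum(!called & truth$direct)
  tn <- sum(!called & !truth$direct)
  tab <- merge(flags, truth[, c("gene_id", "direct")],
               by = "gene_id", suffixes = c("_called", "_true"))
  list(
    table = tab,
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}
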