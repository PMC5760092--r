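#' Normalize protein abundances to portions of 100 percent
#'
#' Rescales every sample column so its (observed) abundances sum to
#' 100, the standard relative-abundance convention for TMT reporting.
#' Missing values (`NA`, not-detected proteins) are ignored in the
#' column total.  The operation is idempotent and removes any per-sample
#' scale, so downstream ratios are invariant to raw loading differences.
#'
#' @param raw Protein x sample numeric matrix of non-negative raw
#'   abundances.
#' @return A matrix of the same shape with each column summing to 100.
#' @export
normalize_to_percent <- function(raw) {
  raw <- as.matrix(raw)
  if (any(raw < 0, na.rm = TRUE)) {
    stop("negative abundances", call. = FALSE)
  }
  totals <- colSums(raw, na.rm = TRUE)
  if (any(totals <= 0)) {
    stop("sample column(s) with non-positive total: ",
         paste(colnames(raw)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  sweep(raw, 2L, totals / 100, `/`)
}

#' Per-protein fold changes and t-test significance
#'
#' For each protein the mean normalized abundance of the experimental
#' condition is divided by the mean of the control condition; the
#' significance of the log2 fold change is assessed by a two-sample
#' Student's t-test on per-replicate log2 abundances (pooled variance by
#' default, Welch via `var_equal = FALSE`).  Proteins absent (`NA`)
#' from every replicate of a group are reported as not detected rather
#' than erroring; groups with fewer than two replicates or zero
#' variance yield an undefined (`NA`) p-value.
#'
#' @param abund Protein x sample matrix of normalized abundances (see
#'   [normalize_to_percent()]).
#' @param samples Data.frame mapping `sample` to `condition`.
#' @param exp_condition,ctrl_condition Condition labels.
#' @param var_equal Pooled-variance t-test if `TRUE` (default).
#' @return A data.frame: `protein_id`, `mean_ratio`, `log2_fc`,
#'   `p_value`, `n_exp`, `n_ctrl`, `detected`.
#' @export
protein_fold_changes <- function(abund, samples, exp_condition,
                                 ctrl_condition, var_equal = TRUE) {
  abund <- as.matrix(abund)
  assert_columns(samples, c("sample", "condition"), "samples")
  cond_of <- stats::setNames(samples$condition, samples$sample)[colnames(abund)]
  cols_e <- which(cond_of == exp_condition)
  cols_c <- which(cond_of == ctrl_condition)
  if (length(cols_e) == 0L || length(cols_c) == 0L) {
    stop("condition missing from sample sheet", call. = FALSE)
  }
  res <- lapply(seq_len(nrow(abund)), function(i) {
    e <- abund[i, cols_e]; e <- e[!is.na(e)]
    c_ <- abund[i, cols_c]; c_ <- c_[!is.na(c_)]
    detected <- length(e) > 0L && length(c_) > 0L
    if (!detected) {
      return(data.frame(mean_ratio = NA_real_, log2_fc = NA_real_,
                        p_value = NA_real_, n_exp = length(e),
                        n_ctrl = length(c_), detected = FALSE))
    }
    mr <- mean(e) / mean(c_)
    p <- NA_real_
    if (length(e) >= 2L && length(c_) >= 2L &&
        (stats::sd(log2(e)) > 0 || stats::sd(log2(c_)) > 0)) {
      p <- stats::t.test(log2(e), log2(c_), var.equal = var_equal)$p.value
    }
    data.frame(mean_ratio = mr, log2_fc = log2(mr), p_value = p,
               n_exp = length(e), n_ctrl = length(c_), detected = TRUE)
  })
  out <- do.call(rbind, res)
  out <- cbind(protein_id = rownames(abund) %||%
                 as.character(seq_len(nrow(abund))), out)
  out$protein_id <- as.character(out$protein_id)
  rownames(out) <- NULL
  out
}

#' Call differentially regulated proteins
#'
#' A protein is upregulated when its mean ratio reaches the fold
#' threshold with `p <= alpha`, downregulated when the ratio falls below
#' the reciprocal threshold with `p <= alpha`.  Proteins with an
#' undefined p-value (not detected, too few replicates, degenerate
#' variance) are never called.
#'
#' @param pfc Output of [protein_fold_changes()].
#' @param config A [protein_call_config()].
#' @return A list of character vectors: `up`, `down`.
#' @export
call_regulated_proteins <- function(pfc, config = protein_call_config()) {
  ok <- !is.na(pfc$p_value) & pfc$p_value <= config$alpha
  list(
    up = pfc$protein_id[ok & !is.na(pfc$mean_ratio) &
                          pfc$mean_ratio >= config$fold_threshold],
    down = pfc$protein_id[ok & !is.na(pfc$mean_ratio) &
                            pfc$mean_ratio <= 1 / config$fold_threshold]
  )
}

#' Intersect protein calls with the transcriptional regulon
#'
#' Computes the concordance between protein-level and transcript-level
#' regulation: how many upregulated proteins have upregulated
#' transcripts, how many downregulated proteins have downregulated
#' transcripts, and what fraction of the protein down-set that
#' represents (in the sigma-32 response this fraction is small - most
#' protein loss is not transcriptional).
#'
#' @param protein_calls Output of [call_regulated_proteins()].
#' @param regulon Output of [define_regulon()] /
#'   [annotate_direct()].
#' @param mapping Optional data.frame (`protein_id`, `gene_id`); by
#'   default protein ids are gene ids.
#' @return A list: `n_protein_up`, `n_protein_down`, `up_overlap`,
#'   `down_overlap`, `down_overlap_fraction` (proportion of the protein
#'   down-set with transcript support).
#' @export
integrate_with_regulon <- function(protein_calls, regulon, mapping = NULL) {
  to_gene <- function(ids) {
    if (is.null(mapping)) return(ids)
    mapping$gene_id[match(ids, mapping$protein_id)]
  }
  up_genes <- stats::na.omit(to_gene(protein_calls$up))
  down_genes <- stats::na.omit(to_gene(protein_calls$down))
  reg_up <- regulon$gene_id[regulon$direction == "up"]
  reg_down <- regulon$gene_id[regulon$direction == "down"]
  up_overlap <- length(intersect(up_genes, reg_up))
  down_overlap <- length(intersect(down_genes, reg_down))
  list(
    n_protein_up = length(protein_calls$up),
    n_protein_down = length(protein_calls$down),
    up_overlap = up_overlap,
    down_overlap = down_overlap,
    down_overlap_fraction = if (length(down_genes) > 0)
      down_overlap / length(down_genes) else NA_real_
  )
}
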