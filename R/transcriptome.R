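#' Library-size normalization of a count matrix
#'
#' Scales each sample column to a common total (counts-per-million
#' style; the target defaults to the mean library size so values keep
#' their magnitude).  Use `method = "none"` as a pass-through for
#' already-normalized expression.
#'
#' @param raw_counts Gene x sample numeric matrix of non-negative
#'   counts.
#' @param method `"total"` (equal column sums) or `"none"`.
#' @param target Column total after scaling; default mean of the
#'   original column sums.
#' @return A matrix of the same shape with equal column sums.
#' @export
normalize_library <- function(raw_counts, method = c("total", "none"),
                              target = NULL) {
  method <- match.arg(method)
  raw_counts <- as.matrix(raw_counts)
  if (any(raw_counts < 0)) stop("negative counts", call. = FALSE)
  if (method == "none") return(raw_counts)
  totals <- colSums(raw_counts)
  if (any(totals == 0)) {
    stop("all-zero sample column(s): ",
         paste(colnames(raw_counts)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  target <- target %||% mean(totals)
  sweep(raw_counts, 2L, totals / target, `/`)
}

#' Fold changes between a condition and a reference
#'
#' Computes per-gene linear fold changes as the ratio of (replicate-
#' averaged) normalized expression plus a pseudocount:
#' `FC = (mean expr_cond + pc) / (mean expr_ref + pc)`.
#'
#' @param expr Gene x sample numeric matrix of normalized expression.
#' @param condition,reference Condition labels.
#' @param samples Optional data.frame (`sample`, `condition`) mapping
#'   columns of `expr` to conditions; by default column names are taken
#'   as condition labels (one sample each).
#' @param pseudocount Added to both numerator and denominator (default
#'   1) so zero-expression genes cannot produce infinite or spuriously
#'   large ratios.
#' @return A named numeric vector of linear fold changes.
#' @export
fold_changes <- function(expr, condition, reference, samples = NULL,
                         pseudocount = 1) {
  expr <- as.matrix(expr)
  cond_of <- if (is.null(samples)) {
    stats::setNames(colnames(expr), colnames(expr))
  } else {
    stats::setNames(samples$condition, samples$sample)[colnames(expr)]
  }
  cols_c <- which(cond_of == condition)
  cols_r <- which(cond_of == reference)
  if (length(cols_c) == 0L) stop("condition not present: ", condition,
                                 call. = FALSE)
  if (length(cols_r) == 0L) stop("reference not present: ", reference,
                                 call. = FALSE)
  num <- rowMeans(expr[, cols_c, drop = FALSE]) + pseudocount
  den <- rowMeans(expr[, cols_r, drop = FALSE]) + pseudocount
  fc <- num / den
  stats::setNames(fc, rownames(expr))
}

#' Classify the depletion response
#'
#' A transcript is differentially regulated after chaperone depletion
#' when it crosses the fold threshold in the same direction at both the
#' 6 h and the 9 h timepoint: up when `FC >= t` at both, down when
#' `FC <= 1/t` at both, otherwise none.
#'
#' @param fc_dep6,fc_dep9 Named fold-change vectors over the same genes.
#' @param config A [classifier_config()].
#' @return A named character vector (`up`/`down`/`none`).
#' @export
classify_depletion_response <- function(fc_dep6, fc_dep9,
                                        config = classifier_config()) {
  stopifnot(length(fc_dep6) == length(fc_dep9))
  t <- config$fold_threshold
  out <- rep("none", length(fc_dep6))
  out[fc_dep6 >= t & fc_dep9 >= t] <- "up"
  out[fc_dep6 <= 1 / t & fc_dep9 <= 1 / t] <- "down"
  stats::setNames(out, names(fc_dep6))
}

#' Define the sigma-factor regulon
#'
#' A gene is called regulon member with direction `d` when (i) the
#' depletion call is `d`, (ii) the sigma-factor overproduction fold
#' change crosses the threshold in direction `d`, and (iii) the
#' deletion-background response is milder or absent: either
#' `|log2 FC_del| < log2(fold_threshold)` (absent) or the depletion
#' response exceeds the deletion-background response by at least
#' `milder_factor`-fold on the log2 scale with concordant signs
#' (milder).  Both arms are individually switchable in the config.
#'
#' @param dep_call Output of [classify_depletion_response()].
#' @param fc_v56a Fold changes under constitutive sigma-factor
#'   overproduction.
#' @param fc_rpohdel Fold changes in the sigma-factor deletion
#'   background (depleted).
#' @param fc_dep Depletion fold changes anchoring the "milder"
#'   comparison (the 6 h contrast by convention).
#' @param config A [classifier_config()].
#' @return A data.frame: `gene_id`, `direction`, `direct` (initialized
#'   `FALSE`; see [annotate_direct()]), and the triggering evidence
#'   (`fc_dep`, `fc_v56a`, `fc_rpohdel`).
#' @export
define_regulon <- function(dep_call, fc_v56a, fc_rpohdel, fc_dep,
                           config = classifier_config()) {
  stopifnot(length(dep_call) == length(fc_v56a),
            length(dep_call) == length(fc_rpohdel),
            length(dep_call) == length(fc_dep))
  t <- config$fold_threshold
  l_del <- log2(fc_rpohdel)
  l_dep <- log2(fc_dep)

  v_up <- fc_v56a >= t
  v_down <- fc_v56a <= 1 / t
  absent <- config$absent_arm &
    (abs(l_del) < log2(config$absent_threshold %||% t))
  milder <- config$milder_arm &
    (abs(l_dep) - abs(l_del) >= log2(config$milder_factor)) &
    (sign(l_del) == sign(l_dep))
  del_ok <- absent | milder

  direction <- rep("none", length(dep_call))
  direction[dep_call == "up" & v_up & del_ok] <- "up"
  direction[dep_call == "down" & v_down & del_ok] <- "down"

  data.frame(
    gene_id = names(dep_call) %||% as.character(seq_along(dep_call)),
    direction = direction,
    direct = FALSE,
    fc_dep = unname(fc_dep),
    fc_v56a = unname(fc_v56a),
    fc_rpohdel = unname(fc_rpohdel),
    stringsAsFactors = FALSE
  )
}

#' Flag direct regulon targets from ChIP evidence
#'
#' A regulon gene is a direct target when it is upregulated and carries
#' promoter-proximal binding evidence - an own window-assigned peak or
#' one inherited from an upstream operon member.  Binding evidence on
#' downregulated genes never yields a direct flag: promoter enrichment
#' of an activating sigma factor marks activation only.
#'
#' @param regulon Output of [define_regulon()].
#' @param chip_flags Output of [propagate_operons()] (columns `gene_id`,
#'   `direct`, `via_operon`).
#' @return The regulon table with its `direct` column filled in, plus a
#'   `via_operon` column.
#' @export
annotate_direct <- function(regulon, chip_flags) {
  idx <- match(regulon$gene_id, chip_flags$gene_id)
  bound <- !is.na(idx) & chip_flags$direct[idx]
  regulon$direct <- regulon$direction == "up" & bound
  regulon$via_operon <- regulon$direct &
    chip_flags$via_operon[idx] %in% TRUE
  regulon
}

#' Log-scale scatter statistics between two contrasts
#'
#' Ordinary least-squares regression of `log2(fc_y)` on `log2(fc_x)`
#' over shared genes; the coefficient of determination says whether the
#' two responses are proportional, and the slope compares their
#' magnitudes.
#'
#' @param fc_x,fc_y Named positive fold-change vectors.
#' @return A list: `r_squared`, `slope`, `intercept`, `n`.
#' @export
scatter_stats <- function(fc_x, fc_y) {
  shared <- intersect(names(fc_x), names(fc_y))
  if (length(shared) < 3L) stop("need at least 3 shared genes", call. = FALSE)
  x <- log2(fc_x[shared])
  y <- log2(fc_y[shared])
  fit <- stats::lm(y ~ x)
  # for simple OLS, R^2 is the squared correlation (avoids the
  # summary.lm() perfect-fit warning on noiseless data); a degenerate
  # axis (zero variance, e.g. a flat contrast) has no defined R^2
  r2 <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
    stats::cor(x, y)^2
  list(
    r_squared = r2,
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    n = length(shared)
  )
}
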