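#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator.  The defaults are
#' scaled to a Caulobacter-like chromosome and to the magnitude of the
#' sigma-32 response: a 4 Mb genome carrying 3000 ORFs, planted
#' effect sizes of |log2 fold| = 3 and multiplicative lognormal noise
#' with a 20 percent coefficient of variation.
#'
#' @param seed Integer seed fixing every generated output bit-for-bit.
#' @param n_genes Number of ORFs to place on the genome.
#' @param n_operons Number of multi-gene transcription units (2-4 genes
#'   each); remaining genes are monocistronic.
#' @param genome_length Chromosome length in bp.
#' @param bin_width ChIP density bin width in bp.
#' @param fraction_minus_strand Proportion of transcription units placed
#'   on the minus strand.
#' @param effect_up Linear fold change planted for upregulated genes
#'   (must exceed 1).
#' @param effect_down Linear fold change planted for downregulated genes
#'   (strictly between 0 and 1).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise applied to expression, protein abundance and ChIP
#'   background.
#' @param chip_background_mean Mean ChIP read density of background bins
#'   (density units; keep well below the peak-calling threshold).
#' @param chip_peak_height Maximum read density of a planted binding-site
#'   bump (density units).
#' @param n_replicates Biological replicates per proteomics condition.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 3000L,
                       n_operons = 400L,
                       genome_length = 4e6,
                       bin_width = 10L,
                       fraction_minus_strand = 0.5,
                       effect_up = 8,
                       effect_down = 1 / 8,
                       noise_cv = 0.2,
                       chip_background_mean = 2,
                       chip_peak_height = 50,
                       n_replicates = 3L) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    n_operons = as.integer(n_operons),
    genome_length = as.numeric(genome_length),
    bin_width = as.integer(bin_width),
    fraction_minus_strand = fraction_minus_strand,
    effect_up = effect_up,
    effect_down = effect_down,
    noise_cv = noise_cv,
    chip_background_mean = chip_background_mean,
    chip_peak_height = chip_peak_height,
    n_replicates = as.integer(n_replicates)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$seed) == 1L, is.finite(cfg$seed),
    cfg$n_genes >= 0L,
    cfg$n_operons >= 0L,
    cfg$n_genes >= cfg$n_operons,
    cfg$genome_length > 0,
    cfg$bin_width >= 1L,
    cfg$fraction_minus_strand >= 0, cfg$fraction_minus_strand <= 1,
    cfg$noise_cv >= 0,
    cfg$chip_background_mean >= 0,
    cfg$chip_peak_height > 0,
    cfg$n_replicates >= 1L
  )
  if (cfg$effect_up <= 1) {
    stop("`effect_up` must be a linear fold change > 1", call. = FALSE)
  }
  if (cfg$effect_down <= 0 || cfg$effect_down >= 1) {
    stop("`effect_down` must lie strictly between 0 and 1", call. = FALSE)
  }
  invisible(cfg)
}

#' Peak-caller configuration
#'
#' Holds the constants of the threshold-based peak definition: a density
#' cutoff of 10 and a promoter window reaching 200 bp upstream and 60 bp
#' downstream of the peak maximum (measured along the gene's direction of
#' transcription).
#'
#' @param threshold Density cutoff; contiguous runs of bins above it form
#'   peaks.
#' @param upstream_window Window extent upstream of a translation start
#'   (bp).
#' @param downstream_window Window extent downstream of a translation
#'   start (bp).
#' @param strict If `TRUE` (default), "above threshold" is strict
#'   (density > threshold); bins equal to the threshold terminate a peak.
#' @param strand_relative If `TRUE` (default) the assignment window is
#'   oriented along each gene's strand; `FALSE` applies it in absolute
#'   genomic coordinates (plus-strand orientation for every gene).
#'
#' @return A `peak_caller_config` list.
#' @export
peak_caller_config <- function(threshold = 10,
                               upstream_window = 200,
                               downstream_window = 60,
                               strict = TRUE,
                               strand_relative = TRUE) {
  stopifnot(threshold > 0, upstream_window >= 0, downstream_window >= 0)
  structure(
    list(
      threshold = threshold,
      upstream_window = upstream_window,
      downstream_window = downstream_window,
      strict = isTRUE(strict),
      strand_relative = isTRUE(strand_relative)
    ),
    class = "peak_caller_config"
  )
}

#' Regulon-classifier configuration
#'
#' Constants of the three-way regulon definition: a gene joins the
#' regulon when it crosses `fold_threshold` in the same direction both
#' after 6 h and 9 h of chaperone depletion and upon constitutive
#' sigma-factor overproduction, while the sigma-factor deletion
#' background shows a milder or absent response.  "Milder" means the
#' deletion-background response is at least `milder_factor`-fold smaller
#' (on the log scale) than the depletion response; "absent" means it
#' stays below `fold_threshold`.  Each arm of that disjunction can be
#' switched off to probe the interpretation.
#'
#' @param fold_threshold Linear fold change a gene must reach (>= in the
#'   called direction), default 2.
#' @param milder_factor Minimum fold by which the deletion-background
#'   response must be smaller for the "milder" arm, default 2.
#' @param pseudocount Added to normalized expression before ratios.
#' @param absent_arm,milder_arm Logical switches for the two arms of the
#'   deletion-background test.
#' @param absent_threshold Fold below which the deletion-background
#'   response counts as absent; defaults to `fold_threshold`.  Keeping
#'   it fixed while tightening `fold_threshold` makes the regulon shrink
#'   monotonically (the default couples the two, so a higher threshold
#'   also widens what counts as "no response").
#'
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(fold_threshold = 2,
                              milder_factor = 2,
                              pseudocount = 1,
                              absent_arm = TRUE,
                              milder_arm = TRUE,
                              absent_threshold = NULL) {
  absent_threshold <- absent_threshold %||% fold_threshold
  stopifnot(fold_threshold > 1, milder_factor >= 1, pseudocount >= 0,
            absent_threshold > 1)
  if (!absent_arm && !milder_arm) {
    stop("at least one of `absent_arm`, `milder_arm` must be enabled",
         call. = FALSE)
  }
  structure(
    list(
      fold_threshold = fold_threshold,
      milder_factor = milder_factor,
      pseudocount = pseudocount,
      absent_arm = isTRUE(absent_arm),
      milder_arm = isTRUE(milder_arm),
      absent_threshold = absent_threshold
    ),
    class = "classifier_config"
  )
}

#' Protein differential-abundance call configuration
#'
#' @param fold_threshold Linear fold change a protein must reach, default
#'   1.5.
#' @param alpha Significance level applied to the per-protein t-test
#'   p-value, default 0.05.  No multiple-testing correction is applied:
#'   calls use the raw p-value, as is conventional for threshold+p TMT
#'   screens; interpret counts accordingly.
#'
#' @return A `protein_call_config` list.
#' @export
protein_call_config <- function(fold_threshold = 1.5, alpha = 0.05) {
  stopifnot(fold_threshold > 1, alpha > 0, alpha < 1)
  structure(
    list(fold_threshold = fold_threshold, alpha = alpha),
    class = "protein_call_config"
  )
}
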