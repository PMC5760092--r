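#' Simulate a binned ChIP read-density track
#'
#' Produces a strandless, binned read-density vector over the whole
#' chromosome: lognormal background around `chip_background_mean`
#' (constant when `noise_cv = 0`) plus one Gaussian-shaped bump per
#' planted binding site.  Each direct transcription unit receives a
#' single site at its leader's promoter, centered 20-80 bp upstream of
#' the leader translation start, scaled so the maximal bin reaches
#' exactly `chip_peak_height` above background shape (bump half-width
#' sigma = 40 bp).  Bins are half-open `[start, start + bin_width)`
#' windows starting at coordinate 1.
#'
#' @param annotation,operons Output of [generate_genome()].
#' @param truth Output of [plant_regulon()].
#' @param config A [sim_config()].
#' @return A `density_track` list: `bin_width`, `origin`,
#'   `genome_length`, `values` (one non-negative density per bin), and
#'   `sites` (data.frame of planted site centers, for diagnostics).
#' @export
simulate_chip_track <- function(annotation, operons, truth, config) {
  validate_sim_config(config)
  bw <- config$bin_width
  n_bins <- as.integer(ceiling(config$genome_length / bw))
  withr::with_seed(stage_seed(config$seed, 33L), {
    values <- if (config$noise_cv == 0) {
      rep(config$chip_background_mean, n_bins)
    } else {
      config$chip_background_mean * rlnorm_cv(n_bins, config$noise_cv)
    }

    leaders <- direct_unit_leaders(truth, operons)
    sites <- data.frame(gene_id = character(), center = numeric(),
                        stringsAsFactors = FALSE)
    if (length(leaders) > 0L) {
      ann <- annotation[match(leaders, annotation$gene_id), ]
      offset <- sample(20:80, length(leaders), replace = TRUE)
      center <- ifelse(ann$strand == "+", ann$tss - offset, ann$tss + offset)
      sigma <- 40
      bin_centers <- (seq_len(n_bins) - 0.5) * bw
      for (i in seq_along(center)) {
        lo <- max(1L, floor((center[i] - 4 * sigma) / bw))
        hi <- min(n_bins, ceiling((center[i] + 4 * sigma) / bw))
        idx <- lo:hi
        bump <- exp(-0.5 * ((bin_centers[idx] - center[i]) / sigma)^2)
        values[idx] <- values[idx] + config$chip_peak_height * bump / max(bump)
      }
      sites <- data.frame(gene_id = leaders, center = center,
                          stringsAsFactors = FALSE)
    }
    structure(
      list(bin_width = bw, origin = 1L, genome_length = config$genome_length,
           values = values, sites = sites),
      class = "density_track"
    )
  })
}

# Leader gene of every transcription unit containing a planted direct
# target: rank-1 member for operons, the gene itself for monocistrons.
direct_unit_leaders <- function(truth, operons) {
  direct <- truth$gene_id[truth$direct]
  if (length(direct) == 0L) return(character())
  op_of <- operons$operon_id[match(direct, operons$gene_id)]
  single <- direct[is.na(op_of)]
  ops <- unique(op_of[!is.na(op_of)])
  leaders <- operons$gene_id[operons$rank == 1L &
                               operons$operon_id %in% ops]
  unique(c(single, leaders))
}

#' Simulate normalized expression across perturbation conditions
#'
#' Builds a gene-by-condition matrix of normalized expression values:
#' lognormal baselines times a planted condition multiplier times
#' multiplicative lognormal noise.  Regulon genes carry their planted
#' fold change in the depletion (`dep6`, `dep9`) and overproduction
#' (`v56a`) conditions, no response in the sigma-factor deletion
#' background (`rpoHdel_dep6`, `rpoHdel_dep9`), and an attenuated
#' response - half the log2 fold - in the DNA-binding-impaired point
#' mutant (`d252g_dep6`, `d252g_dep9`).
#'
#' @param annotation Genome annotation (supplies the gene universe).
#' @param truth Output of [plant_regulon()].
#' @param conditions Condition labels to simulate; must be drawn from
#'   `ref`, `dep6`, `dep9`, `v56a`, `rpoHdel_dep6`, `rpoHdel_dep9`,
#'   `d252g_dep6`, `d252g_dep9` and include `ref`.
#' @param config A [sim_config()].
#' @return A numeric matrix (genes x conditions) with `gene_id`
#'   rownames; one sample per condition.
#' @export
simulate_expression <- function(annotation, truth,
                                conditions = c("ref", "dep6", "dep9", "v56a",
                                               "rpoHdel_dep6", "rpoHdel_dep9",
                                               "d252g_dep6", "d252g_dep9"),
                                config = sim_config()) {
  validate_sim_config(config)
  known <- c("ref", "dep6", "dep9", "v56a", "rpoHdel_dep6", "rpoHdel_dep9",
             "d252g_dep6", "d252g_dep9")
  bad <- setdiff(conditions, known)
  if (length(bad) > 0L) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!"ref" %in% conditions) {
    stop("`conditions` must include the reference condition \"ref\"",
         call. = FALSE)
  }
  n <- nrow(annotation)
  fold <- truth$planted_fold[match(annotation$gene_id, truth$gene_id)]
  withr::with_seed(stage_seed(config$seed, 44L), {
    baseline <- stats::rlnorm(n, meanlog = log(500), sdlog = 1)
    mult <- vapply(conditions, function(cond) {
      switch(cond,
             ref = rep(1, n),
             dep6 = ,
             dep9 = ,
             v56a = fold,
             rpoHdel_dep6 = ,
             rpoHdel_dep9 = rep(1, n),
             d252g_dep6 = ,
             d252g_dep9 = 2^(log2(fold) / 2))
    }, numeric(n))
    noise <- matrix(rlnorm_cv(n * length(conditions), config$noise_cv),
                    nrow = n)
    expr <- baseline * mult * noise
    dimnames(expr) <- list(annotation$gene_id, conditions)
    expr
  })
}

#' Generate protein lengths and a functional-category hierarchy
#'
#' Assigns each gene product a sequence length (lognormal around 300
#' residues) and a two-level functional-category path of the kind used
#' for proteomap accounting.  Category assignment is biased by regulon
#' membership - upregulated genes are enriched for protein quality
#' control (folding, sorting and degradation), downregulated genes for
#' translation - so that planted regulation produces realistic
#' mass-fraction reallocation between categories.
#'
#' @param annotation Genome annotation.
#' @param truth Output of [plant_regulon()].
#' @param config A [sim_config()].
#' @return A data.frame: `protein_id`, `length_aa`, `level1`, `level2`.
#' @export
generate_protein_annotation <- function(annotation, truth,
                                        config = sim_config()) {
  categories <- list(
    c("Genetic information processing", "Folding, sorting and degradation"),
    c("Genetic information processing", "Transcription"),
    c("Genetic information processing", "DNA replication and repair"),
    c("Translation", "Ribosome"),
    c("Translation", "Translation factors"),
    c("Metabolism", "Central carbon metabolism"),
    c("Metabolism", "Amino acid metabolism"),
    c("Metabolism", "Energy metabolism"),
    c("Cellular processes", "Membrane transport"),
    c("Cellular processes", "Cell cycle and division"),
    c("Cellular processes", "Signal transduction")
  )
  prob_by_direction <- list(
    up   = c(0.55, 0.05, 0.02, 0.02, 0.02, 0.08, 0.08, 0.06, 0.08, 0.02, 0.02),
    down = c(0.02, 0.05, 0.05, 0.30, 0.20, 0.08, 0.05, 0.05, 0.10, 0.05, 0.05),
    none = c(0.04, 0.06, 0.06, 0.14, 0.06, 0.16, 0.14, 0.12, 0.10, 0.06, 0.06)
  )
  direction <- truth$direction[match(annotation$gene_id, truth$gene_id)]
  withr::with_seed(stage_seed(config$seed, 66L), {
    idx <- vapply(direction, function(d) {
      sample.int(length(categories), 1L, prob = prob_by_direction[[d]])
    }, integer(1))
    len <- pmin(2000L, pmax(50L, round(stats::rlnorm(
      nrow(annotation), meanlog = log(300), sdlog = 0.4))))
    data.frame(
      protein_id = annotation$gene_id,
      length_aa = as.integer(len),
      level1 = vapply(categories[idx], `[`, character(1), 1L),
      level2 = vapply(categories[idx], `[`, character(1), 2L),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a TMT-style protein abundance table
#'
#' Generates per-replicate relative protein abundances for a reference
#' and a depleted condition, normalized so each sample column sums to
#' 100 (the portions-of-100 convention of TMT reporting).  A
#' configurable fraction of regulon genes respond at the protein level
#' with the planted transcript fold; the rest stay flat, emulating
#' incomplete transcript-protein concordance.
#'
#' @param truth Output of [plant_regulon()].
#' @param protein_lengths Data.frame from
#'   [generate_protein_annotation()] (supplies the protein universe) or
#'   a character vector of protein ids.
#' @param config A [sim_config()]; `n_replicates` sets replication.
#' @param conditions Two labels, reference first.
#' @param concordant_fraction Probability that a regulon gene's protein
#'   follows its transcript fold.
#' @return A list: `values` (protein x sample matrix, columns summing to
#'   100), `samples` (data.frame `sample`, `condition`, `replicate`),
#'   `protein_truth` (data.frame `protein_id`, `protein_fold`).
#' @export
simulate_proteome <- function(truth, protein_lengths,
                              config = sim_config(),
                              conditions = c("ref", "dep12"),
                              concordant_fraction = 0.7) {
  validate_sim_config(config)
  stopifnot(length(conditions) == 2L, config$n_replicates >= 2L)
  ids <- if (is.data.frame(protein_lengths)) {
    protein_lengths$protein_id
  } else {
    as.character(protein_lengths)
  }
  fold <- truth$planted_fold[match(ids, truth$gene_id)]
  fold[is.na(fold)] <- 1
  withr::with_seed(stage_seed(config$seed, 55L), {
    concordant <- stats::runif(length(ids)) < concordant_fraction
    protein_fold <- ifelse(concordant, fold, 1)
    baseline <- stats::rlnorm(length(ids), meanlog = 0, sdlog = 1.2)
    nrep <- config$n_replicates
    cols <- list()
    samples <- expand.grid(replicate = seq_len(nrep),
                           condition = conditions,
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)[, 2:1]
    samples$sample <- sprintf("%s_r%d", samples$condition, samples$replicate)
    values <- vapply(seq_len(nrow(samples)), function(j) {
      eff <- if (samples$condition[j] == conditions[2L]) protein_fold else 1
      baseline * eff * rlnorm_cv(length(ids), config$noise_cv)
    }, numeric(length(ids)))
    values <- matrix(values, nrow = length(ids),
                     dimnames = list(ids, samples$sample))
    values <- normalize_to_percent(values)
    list(values = values,
         samples = samples[, c("sample", "condition", "replicate")],
         protein_truth = data.frame(protein_id = ids,
                                    protein_fold = protein_fold,
                                    stringsAsFactors = FALSE))
  })
}

#' Simulate a translation-shutoff decay time course
#'
#' Band intensities follow first-order decay, `100 * 2^(-t / t_half)`,
#' times multiplicative lognormal noise.  An infinite half-life yields a
#' flat (stable) course.
#'
#' @param true_half_life Half-life in minutes (`Inf` for a stable
#'   protein).
#' @param timepoints Sampling times in minutes, starting at 0.
#' @param noise_cv Coefficient of variation of the intensity noise.
#' @param seed Integer seed.
#' @param n_replicates Number of independent chase replicates.
#' @return A data.frame: `replicate`, `time_min`, `intensity`.
#' @export
simulate_decay <- function(true_half_life, timepoints, noise_cv = 0,
                           seed = 1L, n_replicates = 3L) {
  stopifnot(true_half_life > 0, length(timepoints) >= 1L,
            timepoints[1L] == 0, !is.unsorted(timepoints), noise_cv >= 0)
  withr::with_seed(stage_seed(seed, 77L), {
    out <- expand.grid(time_min = timepoints,
                       replicate = seq_len(n_replicates),
                       KEEP.OUT.ATTRS = FALSE)[, 2:1]
    signal <- if (is.finite(true_half_life)) {
      100 * 2^(-out$time_min / true_half_life)
    } else {
      rep(100, nrow(out))
    }
    out$intensity <- signal * rlnorm_cv(nrow(out), noise_cv)
    out
  })
}
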