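#' Run the full synthetic-to-calls pipeline
#'
#' Convenience wrapper chaining every stage on generated data: genome
#' and operon layout, planted regulon, ChIP track simulation and peak
#' calling with operon propagation, multi-condition expression and
#' regulon classification, direct-target annotation, TMT proteome
#' simulation with differential calls and transcript-protein
#' integration, and proteomap-style allocation between the reference
#' and depleted condition.
#'
#' @param config A [sim_config()].
#' @param n_up,n_down,n_direct Planted regulon marginals.
#' @param concordant_fraction Fraction of regulon genes whose protein
#'   follows the transcript fold.
#' @param peak_config A [peak_caller_config()].
#' @param classifier A [classifier_config()].
#' @param protein_config A [protein_call_config()].
#' @return A list with every intermediate (`annotation`, `operons`,
#'   `truth`, `track`, `peaks`, `chip_flags`, `expr`, `regulon`,
#'   `protein`, `protein_fc`, `protein_calls`, `integration`,
#'   `allocation`) plus `summary` (named numeric vector of headline
#'   quantities).
#' @export
run_regulon_pipeline <- function(config = sim_config(),
                                 n_up = 300L, n_down = 80L, n_direct = 180L,
                                 concordant_fraction = 0.7,
                                 peak_config = peak_caller_config(),
                                 classifier = classifier_config(),
                                 protein_config = protein_call_config()) {
  genome <- generate_genome(config)
  truth <- plant_regulon(genome$annotation, genome$operons,
                         n_up = n_up, n_down = n_down, n_direct = n_direct,
                         config = config)

  track <- simulate_chip_track(genome$annotation, genome$operons, truth,
                               config)
  peaks <- call_peaks(track, peak_config)
  assignments <- assign_peaks_to_genes(peaks, genome$annotation, peak_config)
  chip_flags <- propagate_operons(assignments, genome$operons,
                                  genome$annotation)
  enrich <- summarize_enrichment(chip_flags, truth)

  expr <- simulate_expression(genome$annotation, truth, config = config)
  pc <- classifier$pseudocount
  fc <- function(cond) fold_changes(expr, cond, "ref", pseudocount = pc)
  fc_dep6 <- fc("dep6"); fc_dep9 <- fc("dep9"); fc_v56a <- fc("v56a")
  fc_del6 <- fc("rpoHdel_dep6")
  dep_call <- classify_depletion_response(fc_dep6, fc_dep9, classifier)
  regulon <- define_regulon(dep_call, fc_v56a, fc_del6, fc_dep6, classifier)
  regulon <- annotate_direct(regulon, chip_flags)

  prot_ann <- generate_protein_annotation(genome$annotation, truth, config)
  prot <- simulate_proteome(truth, prot_ann, config,
                            concordant_fraction = concordant_fraction)
  pfc <- protein_fold_changes(prot$values, prot$samples, "dep12", "ref")
  calls <- call_regulated_proteins(pfc, protein_config)
  integration <- integrate_with_regulon(calls, regulon)

  inv_ref <- compute_investment(prot$values, prot_ann, "ref", prot$samples)
  inv_dep <- compute_investment(prot$values, prot_ann, "dep12", prot$samples)
  hier <- prot_ann[, c("protein_id", "level1", "level2")]
  alloc_ref <- aggregate_by_category(inv_ref, hier, level = 2L)
  alloc_dep <- aggregate_by_category(inv_dep, hier, level = 2L)
  alloc_change <- category_change(alloc_ref, alloc_dep)

  stats_v56a <- scatter_stats(fc_dep6, fc_v56a)
  stats_del <- scatter_stats(fc_dep6, fc_del6)

  summary <- c(
    regulon_up = sum(regulon$direction == "up"),
    regulon_down = sum(regulon$direction == "down"),
    direct_targets = sum(regulon$direct),
    chip_sensitivity = enrich$sensitivity,
    chip_specificity = enrich$specificity,
    r2_dep_vs_v56a = stats_v56a$r_squared,
    slope_dep_vs_v56a = stats_v56a$slope,
    r2_dep_vs_rpohdel = stats_del$r_squared,
    proteins_up = length(calls$up),
    proteins_down = length(calls$down),
    up_overlap = integration$up_overlap,
    down_overlap_fraction = integration$down_overlap_fraction
  )

  list(
    annotation = genome$annotation, operons = genome$operons, truth = truth,
    track = track, peaks = peaks, chip_flags = chip_flags, enrich = enrich,
    expr = expr,
    fold_changes = list(dep6 = fc_dep6, dep9 = fc_dep9, v56a = fc_v56a,
                        rpoHdel_dep6 = fc_del6),
    regulon = regulon,
    protein = prot, protein_fc = pfc, protein_calls = calls,
    integration = integration,
    allocation = list(ref = alloc_ref, dep = alloc_dep,
                      change = alloc_change),
    summary = summary
  )
}
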