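test_that("genome generation handles the empty case and rejects infeasible packing", {
  cfg <- sim_config(n_genes = 0L, n_operons = 0L, genome_length = 1e4)
  g <- generate_genome(cfg)
  expect_identical(nrow(g$annotation), 0L)
  expect_identical(nrow(g$operons), 0L)
  expect_error(
    generate_genome(sim_config(n_genes = 100L, n_operons = 0L,
                               genome_length = 1e4)),
    "cannot hold")
})

test_that("generated genomes are valid, reproducible and strand-consistent", {
  cfg <- small_config(seed = 1L)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)

  ann <- g1$annotation
  expect_identical(nrow(ann), 60L)
  # non-overlapping with >= 300 bp intergenic spacing, inside the genome
  expect_true(all(diff(ann$start) > 0))
  expect_true(all(ann$start[-1] - ann$end[-nrow(ann)] - 1L >= 300L))
  expect_true(ann$start[1] >= 1 && ann$end[nrow(ann)] <= cfg$genome_length)
  # translation start follows the strand convention
  expect_identical(ann$tss[ann$strand == "+"], ann$start[ann$strand == "+"])
  expect_identical(ann$tss[ann$strand == "-"], ann$end[ann$strand == "-"])

  ops <- g1$operons
  expect_identical(length(unique(ops$operon_id)), 8L)
  for (op in split(ops[order(ops$rank), ], ops$operon_id[order(ops$rank)])) {
    expect_gte(nrow(op), 2L)
    members <- ann[match(op$gene_id, ann$gene_id), ]
    expect_identical(length(unique(members$strand)), 1L)
    # transcription order: increasing coordinates on +, decreasing on -
    if (members$strand[1] == "+") {
      expect_true(all(diff(members$start) > 0))
    } else {
      expect_true(all(diff(members$start) < 0))
    }
    # contiguity on the chromosome
    idx <- sort(match(op$gene_id, ann$gene_id))
    expect_identical(idx, seq(min(idx), max(idx)))
  }
})

test_that("planted regulon has exact marginals and operon-consistent direct targets", {
  cfg <- sim_config(seed = 7L, n_genes = 3000L, n_operons = 400L)
  g <- generate_genome(cfg)
  truth <- plant_regulon(g$annotation, g$operons, n_up = 300L, n_down = 80L,
                         n_direct = 180L, config = cfg)
  expect_identical(sum(truth$direction == "up"), 300L)
  expect_identical(sum(truth$direction == "down"), 80L)
  expect_identical(sum(truth$direct), 180L)
  # direct implies up; fold 1 exactly iff unaffected
  expect_true(all(truth$direction[truth$direct] == "up"))
  expect_identical(truth$planted_fold == 1, truth$direction == "none")
  # a direct operon member implies its whole unit is direct (leader carries
  # the binding site, which propagates to every downstream member)
  in_op <- truth$gene_id %in% g$operons$gene_id
  op_of <- g$operons$operon_id[match(truth$gene_id, g$operons$gene_id)]
  direct_ops <- unique(op_of[truth$direct & in_op])
  members <- g$operons$gene_id[g$operons$operon_id %in% direct_ops]
  expect_true(all(truth$direct[truth$gene_id %in% members]))

  expect_error(
    plant_regulon(g$annotation, g$operons, n_up = 10L, n_down = 0L,
                  n_direct = 50L, config = cfg),
    "infeasible")
})

test_that("chip track: background stays below threshold, planted bumps are called at their gene", {
  cfg <- small_config(seed = 3L, chip_background_mean = 2)
  g <- generate_genome(cfg)
  none <- plant_regulon(g$annotation, g$operons, 0L, 0L, 0L, cfg)
  track0 <- simulate_chip_track(g$annotation, g$operons, none, cfg)
  expect_lt(max(track0$values), 10)
  expect_gte(min(track0$values), 0)

  one <- plant_regulon(g$annotation, g$operons, 1L, 0L, 1L, cfg)
  track1 <- simulate_chip_track(g$annotation, g$operons, one, cfg)
  peaks <- call_peaks(track1, peak_caller_config())
  expect_identical(nrow(peaks), 1L)
  target <- g$annotation[g$annotation$gene_id ==
                           track1$sites$gene_id[1], ]
  updist <- if (target$strand == "+") target$tss - peaks$max_position else
    peaks$max_position - target$tss
  expect_gte(updist, -cfg$bin_width)      # bin-center tolerance
  expect_lte(updist, 200)
  # identical re-simulation under the same seed
  expect_identical(track1, simulate_chip_track(g$annotation, g$operons,
                                               one, cfg))
})

test_that("noiseless expression reproduces planted multipliers exactly", {
  cfg <- small_config(seed = 2L, noise_cv = 0, effect_up = 4,
                      effect_down = 0.25)
  g <- generate_genome(cfg)
  truth <- plant_regulon(g$annotation, g$operons, 10L, 5L, 0L, cfg)
  expr <- simulate_expression(g$annotation, truth, config = cfg)
  up <- truth$gene_id[truth$direction == "up"]
  expect_equal(expr[up, "dep6"] / expr[up, "ref"],
               setNames(rep(4, length(up)), up))
  expect_equal(expr[up, "rpoHdel_dep6"] / expr[up, "ref"],
               setNames(rep(1, length(up)), up))
  # attenuated response: half the log2 fold
  expect_equal(expr[up, "d252g_dep6"] / expr[up, "ref"],
               setNames(rep(2, length(up)), up))
  expect_error(
    simulate_expression(g$annotation, truth, conditions = c("ref", "heat42"),
                        config = cfg),
    "unknown condition")
})

test_that("noisy expression is reproducible and unbiased on the log scale", {
  cfg <- sim_config(seed = 5L, n_genes = 1000L, n_operons = 100L,
                    genome_length = 1.5e6, noise_cv = 0.2)
  g <- generate_genome(cfg)
  truth <- plant_regulon(g$annotation, g$operons, 200L, 0L, 0L, cfg)
  e1 <- simulate_expression(g$annotation, truth, config = cfg)
  e2 <- simulate_expression(g$annotation, truth, config = cfg)
  expect_identical(e1, e2)

  # mean log-ratio across genes within 3 standard errors of planted value
  lr <- log2(e1[, "dep6"] / e1[, "ref"])
  planted <- log2(truth$planted_fold)
  dev <- lr - planted
  se <- sd(dev) / sqrt(length(dev))
  expect_lt(abs(mean(dev)), 3 * se + 1e-12)
})

test_that("simulated proteome columns sum to 100 and preserve planted folds", {
  cfg <- small_config(seed = 4L, noise_cv = 0, effect_up = 2,
                      effect_down = 0.5)
  g <- generate_genome(cfg)
  truth <- plant_regulon(g$annotation, g$operons, 6L, 0L, 0L, cfg)
  ann <- generate_protein_annotation(g$annotation, truth, cfg)
  prot <- simulate_proteome(truth, ann, cfg, concordant_fraction = 1)
  expect_equal(colSums(prot$values), setNames(rep(100, 6),
                                              colnames(prot$values)))
  pfc <- protein_fold_changes(prot$values, prot$samples, "dep12", "ref")
  # correct for the compositional drift the sum-to-100 constraint induces
  drift <- 1 + sum(prot$values[truth$direction == "up", "ref_r1"]) / 100
  planted_up <- pfc$mean_ratio[match(truth$gene_id[truth$direction == "up"],
                                     pfc$protein_id)]
  expect_equal(planted_up * drift, rep(2, 6), tolerance = 1e-9)

  single <- simulate_proteome(truth, "gene0001", cfg)
  expect_true(all(single$values == 100))
})

test_that("decay courses follow the closed form and are seed-reproducible", {
  c0 <- simulate_decay(20, c(0, 10, 20, 40), noise_cv = 0, n_replicates = 1L)
  expect_equal(c0$intensity, 100 * 2^(-c(0, 10, 20, 40) / 20))
  expect_equal(round(c0$intensity, 2), c(100, 70.71, 50, 25))

  stable <- simulate_decay(Inf, c(0, 60, 120), noise_cv = 0)
  expect_true(all(stable$intensity == 100))

  n1 <- simulate_decay(30, c(0, 15, 30), noise_cv = 0.1, seed = 9L)
  n2 <- simulate_decay(30, c(0, 15, 30), noise_cv = 0.1, seed = 9L)
  expect_identical(n1, n2)
})
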