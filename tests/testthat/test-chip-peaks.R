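test_that("call_peaks matches hand-computed regions and boundary semantics", {
  tr <- toy_track(c(0, 5, 12, 15, 11, 9))
  p <- call_peaks(tr, peak_caller_config(threshold = 10))
  expect_identical(nrow(p), 1L)
  expect_identical(p$start_bin, 3L)
  expect_identical(p$end_bin, 5L)
  expect_equal(p$max_density, 15)
  expect_equal(p$area, 38)
  # maximum reported at the center of bin 4 (bp 31-40)
  expect_equal(p$max_position, 35.5)

  expect_identical(nrow(call_peaks(toy_track(rep(0, 10)))), 0L)
  # strictly-above semantics: a constant track at the threshold is silent
  expect_identical(nrow(call_peaks(toy_track(rep(10, 10)))), 0L)
  relaxed <- peak_caller_config(strict = FALSE)
  expect_identical(nrow(call_peaks(toy_track(rep(10, 10)), relaxed)), 1L)

  expect_error(call_peaks(toy_track(numeric())), "empty")
  expect_error(call_peaks(toy_track(c(1, -2, 3))), "negative")
})

test_that("call_peaks equals the naive scan on random tracks, conserves area, and is threshold-monotone", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(20:2000, 1)
    values <- rexp(n, rate = 1 / 6)
    values[sample(n, n %/% 10)] <- 0
    tr <- toy_track(values)
    got <- call_peaks(tr, peak_caller_config(threshold = 10))
    ref <- naive_peak_scan(values, 10)
    expect_identical(got$start_bin, as.integer(ref$start_bin))
    expect_identical(got$end_bin, as.integer(ref$end_bin))
    expect_equal(got$max_density, ref$max_density)
    expect_equal(got$area, ref$area)
    expect_equal(got$max_position,
                 1 + (ref$max_bin - 1) * 10 + 4.5)
    # area conservation over above-threshold bins
    expect_equal(sum(got$area), sum(values[values > 10]))
    # raising the threshold never covers more bins
    lo <- call_peaks(tr, peak_caller_config(threshold = 10))
    hi <- call_peaks(tr, peak_caller_config(threshold = 15))
    expect_lte(sum(hi$end_bin - hi$start_bin + 1),
               sum(lo$end_bin - lo$start_bin + 1))
  }
})

test_that("promoter-window assignment follows strand-relative arithmetic", {
  ann <- toy_annotation(c("plusA", "minusB"), tss = c(1000L, 2000L),
                        strand = c("+", "-"))
  mk_peak <- function(pos) data.frame(peak_id = "p1", start_bin = 1L,
                                      end_bin = 1L, start = pos, end = pos,
                                      max_position = pos, max_density = 50,
                                      area = 50)
  cfg <- peak_caller_config()
  expect_identical(nrow(assign_peaks_to_genes(mk_peak(1)[0, ], ann, cfg)), 0L)

  # plus strand: 150 bp upstream is in; 100 bp downstream is out
  a1 <- assign_peaks_to_genes(mk_peak(850), ann, cfg)
  expect_identical(a1$gene_id, "plusA")
  expect_equal(a1$distance, -150)
  expect_identical(nrow(assign_peaks_to_genes(mk_peak(1100), ann, cfg)), 0L)
  # 60 bp downstream is still in
  expect_identical(assign_peaks_to_genes(mk_peak(1060), ann, cfg)$gene_id,
                   "plusA")

  # minus strand mirror: peak at 2150 is 150 bp upstream of tss 2000
  a2 <- assign_peaks_to_genes(mk_peak(2150), ann, cfg)
  expect_identical(a2$gene_id, "minusB")
  expect_equal(a2$distance, -150)
  # absolute-coordinate compatibility mode treats every gene as plus strand
  abs_cfg <- peak_caller_config(strand_relative = FALSE)
  expect_identical(nrow(assign_peaks_to_genes(mk_peak(2150), ann, abs_cfg)),
                   0L)

  bad <- ann; bad$strand[1] <- "*"
  expect_error(assign_peaks_to_genes(mk_peak(850), bad, cfg), "strand")
})

test_that("window assignment is symmetric under strand reversal with a mirrored track", {
  set.seed(7)
  cfg <- peak_caller_config()
  for (i in 1:50) {
    tss <- 5000L
    pos <- tss + sample(-400:400, 1)
    peak <- data.frame(peak_id = "p", start_bin = 1L, end_bin = 1L,
                       start = pos, end = pos, max_position = pos,
                       max_density = 20, area = 20)
    fwd <- toy_annotation("g", tss, "+")
    hit_fwd <- nrow(assign_peaks_to_genes(peak, fwd, cfg)) > 0
    # mirror the configuration about the translation start
    mpos <- 2 * tss - pos
    mpeak <- peak; mpeak$max_position <- mpos
    rev <- toy_annotation("g", tss, "-")
    hit_rev <- nrow(assign_peaks_to_genes(mpeak, rev, cfg)) > 0
    expect_identical(hit_fwd, hit_rev)
  }
})

test_that("operon propagation is upstream-to-downstream only", {
  ann <- toy_annotation(c("A", "B", "C", "D"),
                        tss = c(1000L, 2000L, 3000L, 9000L),
                        strand = rep("+", 4))
  ops <- data.frame(operon_id = "op1", gene_id = c("A", "B", "C"),
                    rank = 1:3)
  asg <- function(genes) data.frame(
    gene_id = genes, peak_id = paste0("p", seq_along(genes)),
    distance = -100, max_position = 900, area = 30, via_operon = FALSE,
    stringsAsFactors = FALSE)

  # peak on the leader propagates to the whole operon
  f1 <- propagate_operons(asg("A"), ops, ann)
  expect_identical(f1$direct, c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(f1$via_operon, c(FALSE, TRUE, TRUE, FALSE))
  # internal peak reaches only downstream members
  f2 <- propagate_operons(asg("B"), ops, ann)
  expect_identical(f2$direct, c(FALSE, TRUE, TRUE, FALSE))
  # singleton with no peak stays untouched
  expect_false(f1$direct[f1$gene_id == "D"])

  dup <- rbind(ops, data.frame(operon_id = "op2", gene_id = "B", rank = 1L))
  expect_error(propagate_operons(asg("A"), dup, ann), "more than one operon")
})

test_that("enrichment summary equals a brute-force confusion tally", {
  set.seed(11)
  genes <- sprintf("g%03d", 1:200)
  flags <- data.frame(gene_id = genes,
                      direct = runif(200) < 0.3,
                      via_operon = FALSE, own_peak = TRUE,
                      n_peaks = 1L, peaks = "p", stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = genes,
                      direction = "up",
                      direct = runif(200) < 0.25,
                      planted_fold = 8, stringsAsFactors = FALSE)
  s <- summarize_enrichment(flags, truth)
  tp <- sum(flags$direct & truth$direct)
  fp <- sum(flags$direct & !truth$direct)
  fn <- sum(!flags$direct & truth$direct)
  tn <- sum(!flags$direct & !truth$direct)
  expect_identical(unname(s$confusion), c(tp, fp, tn, fn))
  expect_equal(s$sensitivity, tp / (tp + fn))
  expect_equal(s$specificity, tn / (tn + fp))

  none <- flags; none$direct <- FALSE
  s0 <- summarize_enrichment(none, truth)
  expect_equal(s0$sensitivity, 0)
  expect_identical(unname(s0$confusion["fn"]), sum(truth$direct))
})
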