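# Independent reference implementations used as oracles.  These stay
# deliberately naive (per-element loops, closed forms) and share no code
# with the package internals they check.

# O(n) single-pass peak scan: returns start/end bin, leftmost max bin,
# max density and area per above-threshold run.
naive_peak_scan <- function(values, threshold = 10, strict = TRUE) {
  peaks <- list()
  in_peak <- FALSE
  s <- NA_integer_; mx <- -Inf; mbin <- NA_integer_; area <- 0
  for (i in seq_along(values)) {
    hit <- if (strict) values[i] > threshold else values[i] >= threshold
    if (hit) {
      if (!in_peak) {
        in_peak <- TRUE; s <- i; mx <- -Inf; area <- 0
      }
      area <- area + values[i]
      if (values[i] > mx) { mx <- values[i]; mbin <- i }
    } else if (in_peak) {
      peaks[[length(peaks) + 1L]] <-
        c(start_bin = s, end_bin = i - 1L, max_bin = mbin,
          max_density = mx, area = area)
      in_peak <- FALSE
    }
  }
  if (in_peak) {
    peaks[[length(peaks) + 1L]] <-
      c(start_bin = s, end_bin = length(values), max_bin = mbin,
        max_density = mx, area = area)
  }
  if (length(peaks) == 0L) {
    return(data.frame(start_bin = integer(), end_bin = integer(),
                      max_bin = integer(), max_density = numeric(),
                      area = numeric()))
  }
  as.data.frame(do.call(rbind, peaks))
}

# Exhaustive per-gene boolean evaluation of the regulon rule.
brute_regulon_direction <- function(fc6, fc9, fcv, fcdel, fcdep,
                                    fold_threshold = 2, milder_factor = 2,
                                    absent_arm = TRUE, milder_arm = TRUE,
                                    absent_threshold = fold_threshold) {
  n <- length(fc6)
  out <- character(n)
  for (i in seq_len(n)) {
    dep_up <- fc6[i] >= fold_threshold && fc9[i] >= fold_threshold
    dep_down <- fc6[i] <= 1 / fold_threshold && fc9[i] <= 1 / fold_threshold
    ld <- log2(fcdel[i]); la <- log2(fcdep[i])
    ok_absent <- absent_arm && abs(ld) < log2(absent_threshold)
    ok_milder <- milder_arm &&
      (abs(la) - abs(ld) >= log2(milder_factor)) && sign(ld) == sign(la)
    del_ok <- ok_absent || ok_milder
    if (dep_up && fcv[i] >= fold_threshold && del_ok) {
      out[i] <- "up"
    } else if (dep_down && fcv[i] <= 1 / fold_threshold && del_ok) {
      out[i] <- "down"
    } else {
      out[i] <- "none"
    }
  }
  out
}

# Textbook pooled-variance two-sample t-test p-value.
pooled_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}

# Small, fast simulation configuration for unit tests.
small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_genes = 60L, n_operons = 8L,
             genome_length = 1.2e5, ...)
}

# Plain data.frame constructors for hand-built fixtures.
toy_annotation <- function(gene_id, tss, strand, width = 300L) {
  data.frame(
    gene_id = gene_id,
    start = ifelse(strand == "+", tss, tss - width + 1L),
    end = ifelse(strand == "+", tss + width - 1L, tss),
    strand = strand, tss = tss, stringsAsFactors = FALSE
  )
}

toy_track <- function(values, bin_width = 10L) {
  structure(list(bin_width = as.integer(bin_width), origin = 1L,
                 genome_length = length(values) * bin_width,
                 values = values),
            class = "density_track")
}
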