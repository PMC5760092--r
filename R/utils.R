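# Multiplicative lognormal noise with unit mean and the requested
# coefficient of variation.  cv = 0 short-circuits to exact 1s so that
# noiseless runs are bit-exact.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Seed offsets per generator stage keep independently callable stages
# deterministic regardless of call order.  Offsets stay small so that
# seed + offset remains a valid 32-bit integer for any sane user seed.
stage_seed <- function(cfg_seed, offset) {
  as.integer((as.numeric(cfg_seed) + offset) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
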