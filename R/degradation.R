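#' Fit first-order decay to a chase time course
#'
#' Band intensities after translation shutoff are modeled as
#' single-exponential decay, `I(t) = I0 * exp(-k t)`.  Each replicate is
#' normalized to its own t = 0 intensity, then `ln(intensity)` is
#' regressed on time by ordinary least squares with a shared slope and
#' one intercept per replicate.  The half-life is `ln(2) / k`.
#'
#' @param course Data.frame with columns `time_min`, `intensity` and
#'   optionally `replicate`; every replicate must include t = 0 and all
#'   intensities must be positive.
#' @return A `half_life_estimate` list: `k` (per minute), `t_half`
#'   (minutes, `Inf` when `k <= 0`), `censored` (`FALSE`; see
#'   [censor_estimate()]), `censor_bound`, `r_squared` (squared
#'   correlation of fitted and observed log intensities), `n_obs`.
#' @export
fit_decay <- function(course) {
  assert_columns(course, c("time_min", "intensity"), "course")
  if (is.null(course$replicate)) course$replicate <- 1L
  if (any(course$intensity <= 0)) {
    stop("non-positive intensity: log-linear fit undefined", call. = FALSE)
  }
  if (length(unique(course$time_min)) < 3L) {
    stop("need at least 3 distinct timepoints", call. = FALSE)
  }
  by_rep <- split(course, course$replicate)
  norm <- lapply(by_rep, function(d) {
    i0 <- d$intensity[d$time_min == 0]
    if (length(i0) == 0L) {
      stop("replicate without a t = 0 intensity", call. = FALSE)
    }
    d$rel <- d$intensity / mean(i0)
    d
  })
  dat <- do.call(rbind, norm)
  dat$replicate <- factor(dat$replicate)
  fit <- if (nlevels(dat$replicate) > 1L) {
    stats::lm(log(rel) ~ 0 + replicate + time_min, data = dat)
  } else {
    stats::lm(log(rel) ~ time_min, data = dat)
  }
  k <- -unname(coef(fit)[["time_min"]])
  logy <- log(dat$rel)
  r2 <- if (stats::sd(logy) == 0) 1 else cor(fitted(fit), logy)^2
  structure(
    list(
      k = k,
      t_half = if (k > 0) log(2) / k else Inf,
      censored = FALSE,
      censor_bound = NA_real_,
      r_squared = r2,
      n_obs = nrow(dat)
    ),
    class = "half_life_estimate"
  )
}

#' Censor a half-life estimate at the observation window
#'
#' Decay slower than the chase window cannot be quantified; when the
#' fitted rate is non-positive or the half-life exceeds the last
#' observed timepoint, the estimate is reported as a lower bound
#' ("t1/2 > t_max min").
#'
#' @param estimate A `half_life_estimate` from [fit_decay()].
#' @param t_max Last observed timepoint (minutes).
#' @return The estimate with `censored`/`censor_bound` set.
#' @export
censor_estimate <- function(estimate, t_max) {
  stopifnot(inherits(estimate, "half_life_estimate"), t_max > 0)
  if (estimate$k <= 0 || estimate$t_half > t_max) {
    estimate$censored <- TRUE
    estimate$censor_bound <- t_max
  }
  estimate
}

#' @exportS3Method base::format
format.half_life_estimate <- function(x, ...) {
  if (x$censored) {
    sprintf("t1/2 > %g min (censored; R^2 = %.3f, n = %d)",
            x$censor_bound, x$r_squared, x$n_obs)
  } else {
    sprintf("t1/2 = %.1f min (k = %.4g/min, R^2 = %.3f, n = %d)",
            x$t_half, x$k, x$r_squared, x$n_obs)
  }
}

#' @export
print.half_life_estimate <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
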