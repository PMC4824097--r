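# Ensemble-assay fitting: single-exponential chase decay, biphasic
# offset-exponential triplex transients, Chi-dose and distance-series
# inversions, and yield fold-changes.

.series_xy <- function(series) {
  if (inherits(series, "chase_series"))
    return(list(t = series$time_min, y = series$fragment_fraction))
  if (is.data.frame(series) && ncol(series) >= 2L)
    return(list(t = series[[1]], y = series[[2]]))
  stop("expected a 'chase_series' or a two-column data frame")
}

#' Fit a single exponential decay to zero
#'
#' Least-squares fit of `f0 * exp(-k t)` to a Chi-fragment survival series;
#' the half-life is `ln 2 / k`. Uncertainty on the half-life comes from
#' residual-resampling bootstrap (nonparametric; gel densitometry noise
#' structure is unknown, so fits are unweighted).
#'
#' @param series A `chase_series` from [simulate_chase()] or a two-column
#'   data frame (time in minutes, surviving fraction).
#' @param n_boot Bootstrap replicates for the half-life interval (0 skips
#'   the bootstrap).
#' @param seed Optional integer seed for the bootstrap.
#' @return Object of class `decay_fit`: `f0`, `k` (per min), `t_half` (min),
#'   `rss`, `ci_t_half` (95%), and the bootstrap draws `boot_t_half`.
#'   Non-decaying data raise an error.
#' @export
fit_exponential_decay <- function(series, n_boot = 200, seed = NULL) {
  xy <- .series_xy(series)
  t <- xy$t; y <- xy$y
  if (length(t) < 3L) stop("need at least 3 timepoints")
  if (any(y < 0)) stop("fractions must be non-negative")
  sl <- coef(lm(log(pmax(y, 1e-9)) ~ t))
  if (sl[2] > -1e-8) stop("no decay: series is not decreasing")
  fit <- minpack.lm::nlsLM(
    y ~ f0 * exp(-k * t),
    start = list(f0 = unname(min(exp(sl[1]), 1.5)), k = unname(-sl[2])),
    lower = c(f0 = 0, k = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  if (est["k"] <= 0) stop("no decay: fitted rate is not positive")
  fitted_y <- fitted(fit)
  res <- y - fitted_y
  boot <- if (n_boot <= 0) numeric(0) else with_seed_opt(seed, {
    vapply(seq_len(n_boot), function(i) {
      yb <- pmax(0, fitted_y + sample(res, replace = TRUE))
      fb <- tryCatch(minpack.lm::nlsLM(
        yb ~ f0 * exp(-k * t),
        start = as.list(est), lower = c(f0 = 0, k = 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
      if (is.null(fb)) NA_real_ else log(2) / coef(fb)[["k"]]
    }, numeric(1))
  })
  boot <- boot[is.finite(boot)]
  structure(list(f0 = unname(est["f0"]), k = unname(est["k"]),
                 t_half = log(2) / unname(est["k"]),
                 rss = sum(res^2),
                 ci_t_half = if (length(boot) >= 20)
                   unname(quantile(boot, c(0.025, 0.975))) else c(NA, NA),
                 boot_t_half = boot, n = length(t)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Exponential decay fit: f0 = %.3g, k = %.4g /min, t1/2 = %.3g min",
              x$f0, x$k, x$t_half))
  if (is.finite(x$ci_t_half[1]))
    cat(sprintf(" (95%% CI %.3g-%.3g)", x$ci_t_half[1], x$ci_t_half[2]))
  cat("\n")
  invisible(x)
}

#' Half-life fold change between two chase fits
#'
#' Fold change of the first fit's half-life relative to the second's
#' (`t_half_a / t_half_b`), with an interval propagated from the two
#' bootstrap samples when available. `fold_change(a, b) == 1 / fold_change(b, a)`.
#'
#' @param fit_a,fit_b `decay_fit` objects.
#' @return List with `ratio` and 95% `ci`.
#' @export
fold_change <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "decay_fit"), inherits(fit_b, "decay_fit"))
  ratio <- fit_a$t_half / fit_b$t_half
  ci <- c(NA_real_, NA_real_)
  na <- length(fit_a$boot_t_half); nb <- length(fit_b$boot_t_half)
  if (na >= 20 && nb >= 20) {
    m <- min(na, nb)
    r <- fit_a$boot_t_half[seq_len(m)] / fit_b$boot_t_half[seq_len(m)]
    ci <- unname(quantile(r, c(0.025, 0.975)))
  }
  list(ratio = ratio, ci = ci)
}

.biphasic_model <- function(t, a1, k1, d1, a2, k2, d2) {
  a1 * ifelse(t > d1, 1 - exp(-k1 * (t - d1)), 0) +
    a2 * ifelse(t > d2, 1 - exp(-k2 * (t - d2)), 0)
}

#' Fit a sum of two offset exponentials to a triplex transient
#'
#' Model: `a1 (1 - exp(-k1 (t - d1)))_+ + a2 (1 - exp(-k2 (t - d2)))_+`.
#' Phase 1 is by convention the smaller-offset (early) phase, ties broken by
#' the larger rate; on an endpoint-normalized curve the amplitudes sum to
#' ~1, and `a1` is the fraction of the population that reached the reporter
#' without converting to the slow Chi-modified state. The objective is
#' multimodal in the offsets, so the fit is multistarted: offsets seeded at
#' the 10% and 60% signal times, rates at the inverse rise time, amplitudes
#' spread over the starts.
#'
#' @param curve A `triplex_curve` or two-column data frame (time s, signal).
#' @param n_starts Number of multistart initializations.
#' @param equal_rates Constrain the two phases to share one rate.
#' @return Object of class `biphasic_fit`: `a1`, `a2`, `k1`, `k2`, `d1`,
#'   `d2`, `rss`, `converged`.
#' @export
fit_biphasic <- function(curve, n_starts = 8, equal_rates = FALSE) {
  if (inherits(curve, "triplex_curve")) {
    t <- curve$time_s; y <- curve$signal
  } else {
    xy <- .series_xy(curve); t <- xy$t; y <- xy$y
  }
  stopifnot(length(t) >= 8L)
  tq <- function(p) {
    i <- which(y >= p * max(y))[1L]
    if (is.na(i)) t[length(t)] else t[i]
  }
  d1_0 <- tq(0.10); d2_0 <- tq(0.60)
  rise <- max(tq(0.90) - d1_0, diff(range(t)) / 50)
  k0 <- 1 / rise
  a1_grid <- seq(0.15, 0.9, length.out = max(2L, n_starts - 2L))
  starts <- lapply(a1_grid, function(a1)
    list(a1 = a1, k1 = k0, d1 = d1_0, a2 = 1 - a1, k2 = k0, d2 = d2_0))
  starts <- c(starts,
              list(list(a1 = 0.97, k1 = k0, d1 = d1_0, a2 = 0.03,
                        k2 = k0, d2 = tq(0.95)),
                   list(a1 = 0.5, k1 = 2 * k0, d1 = d1_0, a2 = 0.5,
                        k2 = k0 / 2, d2 = tq(0.80))))
  starts <- starts[seq_len(min(length(starts), n_starts))]
  tmax <- max(t)
  best <- NULL
  for (s in starts) {
    fb <- tryCatch({
      if (equal_rates) {
        minpack.lm::nlsLM(
          y ~ .biphasic_model(t, a1, k1, d1, a2, k1, d2),
          start = s[c("a1", "k1", "d1", "a2", "d2")],
          lower = c(0, 1e-4, 0, 0, 0),
          upper = c(1.5, 1e4, tmax, 1.5, tmax),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      } else {
        minpack.lm::nlsLM(
          y ~ .biphasic_model(t, a1, k1, d1, a2, k2, d2),
          start = s,
          lower = c(0, 1e-4, 0, 0, 1e-4, 0),
          upper = c(1.5, 1e4, tmax, 1.5, 1e4, tmax),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      }
    }, error = function(e) NULL)
    if (is.null(fb)) next
    rss <- sum(residuals(fb)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fb, rss = rss)
  }
  if (is.null(best)) stop("biphasic fit did not converge from any start")
  cf <- coef(best$fit)
  if (equal_rates) cf["k2"] <- cf["k1"]
  ph <- rbind(c(cf["a1"], cf["k1"], cf["d1"]),
              c(cf["a2"], cf["k2"], cf["d2"]))
  # a vanishing phase is a degenerate second phase whatever its offset;
  # otherwise order by offset, ties broken by the larger rate
  tot <- sum(ph[, 1])
  if (tot > 0 && min(ph[, 1]) < 0.02 * tot) ord <- order(-ph[, 1])
  else ord <- order(ph[, 3], -ph[, 2])
  ph <- ph[ord, , drop = FALSE]
  structure(list(a1 = unname(ph[1, 1]), k1 = unname(ph[1, 2]),
                 d1 = unname(ph[1, 3]),
                 a2 = unname(ph[2, 1]), k2 = unname(ph[2, 2]),
                 d2 = unname(ph[2, 3]),
                 rss = best$rss, converged = TRUE,
                 equal_rates = equal_rates),
            class = "biphasic_fit")
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat("Biphasic offset-exponential fit\n")
  cat(sprintf("  phase 1: a = %.3g, k = %.3g /s, offset = %.3g s\n",
              x$a1, x$k1, x$d1))
  cat(sprintf("  phase 2: a = %.3g, k = %.3g /s, offset = %.3g s\n",
              x$a2, x$k2, x$d2))
  cat(sprintf("  rss = %.3g\n", x$rss))
  invisible(x)
}

#' Normalized signal amplitude at a fixed time
#'
#' Linear interpolation of the normalized transient at time `t`; the crude
#' first-phase amplitude estimate used for curves too complex to fit (e.g.
#' latch-mutant transients on Chi-containing DNA, read at t = 2 s).
#'
#' @param curve A `triplex_curve` or two-column data frame.
#' @param t Query time (s), within the curve support.
#' @return Interpolated fraction.
#' @export
amplitude_at_time <- function(curve, t) {
  if (inherits(curve, "triplex_curve")) {
    tt <- curve$time_s; y <- curve$signal
  } else {
    xy <- .series_xy(curve); tt <- xy$t; y <- xy$y
  }
  if (t < min(tt) || t > max(tt)) stop("time outside the curve support")
  approx(tt, y, xout = t, ties = "ordered")$y
}

#' Per-Chi recognition probability from a Chi-dose series
#'
#' With independent recognition at each site, the first-phase (unconverted)
#' amplitude on a substrate carrying n Chi sequences is `a1(n) = (1 - c)^n`.
#' Given first-phase amplitudes for several n (including the Chi-free n = 0
#' control) this inverts for the per-Chi probability c by least squares; a
#' single n > 0 point is inverted algebraically.
#'
#' @param points Data frame with columns `n_chi` and `amplitude`.
#' @return List of class `dose_fit`: `c` (per-Chi probability),
#'   `increasing_warning` flag.
#' @export
fit_dose_response <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("n_chi", "amplitude") %in% names(points)))
  n <- points$n_chi; a <- points$amplitude
  if (!any(n == 0)) stop("dose series must include the n = 0 control")
  if (any(a < 0 | a > 1)) stop("amplitudes must lie in [0, 1]")
  inc <- FALSE
  o <- order(n)
  if (any(diff(a[o]) > 0.02)) {
    inc <- TRUE
    warning("first-phase amplitude increases with Chi number beyond tolerance")
  }
  pos <- which(n > 0)
  if (length(pos) == 1L) {
    ci <- 1 - a[pos]^(1 / n[pos])
  } else {
    obj <- function(c) sum((a - (1 - c)^n)^2)
    ci <- optimize(obj, c(0, 1))$minimum
    # optimize never returns the exact boundary; snap degenerate cases
    if (obj(0) <= obj(ci)) ci <- 0
    if (obj(1) <= obj(ci)) ci <- 1
  }
  structure(list(c = ci, increasing_warning = inc,
                 predicted = (1 - ci)^n, n_chi = n, amplitude = a),
            class = "dose_fit")
}

#' Spontaneous isomerization rate from a distance series
#'
#' On Chi-free DNA an enzyme that isomerizes to the slow state at hazard
#' `k_iso` during scanning reaches a reporter at distance L unconverted with
#' probability `a1(L) = exp(-k_iso L / v_pre)`. Least squares on the
#' log-linear form (regression through the origin, since a1(0) = 1) gives
#' `k_iso >= 0`.
#'
#' @param points Data frame with columns `distance_bp` and `amplitude`
#'   (first-phase amplitudes, > 0).
#' @param v_pre Scanning-state translocation rate (bp/s).
#' @return Estimated isomerization rate (per s).
#' @export
fit_isomerization <- function(points, v_pre) {
  stopifnot(is.data.frame(points),
            all(c("distance_bp", "amplitude") %in% names(points)),
            v_pre > 0, nrow(points) >= 2L)
  L <- points$distance_bp; a <- points$amplitude
  if (any(a <= 0)) stop("amplitudes must be positive")
  max(0, -v_pre * sum(L * log(pmin(a, 1))) / sum(L^2))
}

#' Chi-fragment yield fold change
#'
#' Fold change of the first yield relative to the second. When ensemble
#' sizes are supplied (simulated data) a 95% interval is propagated from the
#' binomial sampling error of each yield on the log scale; tabular inputs
#' get a point estimate.
#'
#' @param yield_a,yield_b Yield fractions in (0, 1].
#' @param n_a,n_b Optional ensemble sizes behind each yield.
#' @return List with `ratio` and `ci`.
#' @export
yield_fold_change <- function(yield_a, yield_b, n_a = NULL, n_b = NULL) {
  stopifnot(yield_a > 0, yield_a <= 1, yield_b > 0, yield_b <= 1)
  ratio <- yield_a / yield_b
  ci <- c(NA_real_, NA_real_)
  if (!is.null(n_a) && !is.null(n_b)) {
    se <- sqrt((1 - yield_a) / (yield_a * n_a) +
               (1 - yield_b) / (yield_b * n_b))
    ci <- ratio * exp(c(-1, 1) * 1.96 * se)
  }
  list(ratio = ratio, ci = ci)
}
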