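#' Kinetic parameter set of the gated-scanner model for one enzyme variant
#'
#' The gated scanner is a two-state model of a translocating helicase-nuclease
#' that scans DNA for Chi recombination hotspots. Before Chi recognition the
#' enzyme moves at `v_pre`; each Chi sequence encountered may arrest it in a
#' stalled encounter complex (probability `p_pause` per site), whose dwell is
#' drawn from a gamma law (`pause_shape` sequential kinetic sub-steps of mean
#' `pause_scale` each). A pause resolves either by commitment to the
#' Chi-modified state (probability `p_commit`), after which the enzyme
#' translocates at the reduced rate `v_post` and ignores further Chi sites, or
#' by release and resumption of scanning. Independently of Chi, the enzyme may
#' isomerize spontaneously into the Chi-modified state at hazard `k_iso`
#' (per second of pre-Chi translocation; the latch-destabilised mutant does
#' this measurably) and may detach at hazard `k_detach` (processivity).
#' `k_off_chi` is the dissociation rate of the mature enzyme:Chi complex,
#' measured by the exonuclease-chase footprint assay.
#'
#' @param name Variant label.
#' @param v_pre Translocation rate before Chi recognition (bp/s), > 0.
#' @param v_post Translocation rate in the Chi-modified state (bp/s).
#' @param p_pause Probability of a stalled encounter complex per Chi
#'   encountered, in \[0, 1\].
#' @param pause_shape Integer >= 1; number of kinetic sub-steps of the pause
#'   (gamma shape). Shape 1 is the exponential limit.
#' @param pause_scale Per-step mean dwell (s).
#' @param p_commit Probability that a pause ends in commitment to the
#'   Chi-modified state rather than release, in \[0, 1\].
#' @param k_off_chi Dissociation rate of the mature enzyme:Chi complex
#'   (per minute).
#' @param k_iso Spontaneous isomerization rate to the Chi-modified state
#'   during pre-Chi translocation (per second).
#' @param k_detach Detachment hazard during translocation (per second);
#'   0 means perfectly processive.
#' @return An object of class `enzyme_params`.
#' @examples
#' enzyme_params("wt-like", v_pre = 300, v_post = 225, p_pause = 0.1,
#'               pause_shape = 2, pause_scale = 0.8, p_commit = 0.35,
#'               k_off_chi = log(2) / 3)
#' @export
enzyme_params <- function(name, v_pre, v_post = 0.75 * v_pre, p_pause = 0,
                          pause_shape = 2L, pause_scale = 0.5, p_commit = 0,
                          k_off_chi = 0, k_iso = 0, k_detach = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("v_pre", "v_post", "p_pause", "pause_shape", "pause_scale",
               "p_commit", "k_off_chi", "k_iso", "k_detach")) {
    if (!num1(get(nm))) stop("'", nm, "' must be a finite numeric scalar")
  }
  if (v_pre <= 0) stop("'v_pre' must be > 0")
  if (v_post < 0) stop("'v_post' must be >= 0")
  if (p_pause < 0 || p_pause > 1) stop("'p_pause' must be in [0, 1]")
  if (p_commit < 0 || p_commit > 1) stop("'p_commit' must be in [0, 1]")
  if (pause_shape < 1 || pause_shape != round(pause_shape))
    stop("'pause_shape' must be an integer >= 1")
  if (pause_scale < 0) stop("'pause_scale' must be >= 0")
  if (k_off_chi < 0 || k_iso < 0 || k_detach < 0)
    stop("rates must be >= 0")
  structure(list(name = name, v_pre = v_pre, v_post = v_post,
                 p_pause = p_pause, pause_shape = as.integer(pause_shape),
                 pause_scale = pause_scale, p_commit = p_commit,
                 k_off_chi = k_off_chi, k_iso = k_iso, k_detach = k_detach),
            class = "enzyme_params")
}

#' @export
print.enzyme_params <- function(x, ...) {
  cat("Gated-scanner parameters [", x$name, "]\n", sep = "")
  cat(sprintf("  v_pre %.4g bp/s, v_post %.4g bp/s\n", x$v_pre, x$v_post))
  cat(sprintf("  pause: p = %.4g per Chi, gamma(shape %d, scale %.4g s), p_commit %.4g\n",
              x$p_pause, x$pause_shape, x$pause_scale, x$p_commit))
  cat(sprintf("  k_off_chi %.4g /min (t1/2 %.3g min), k_iso %.4g /s, k_detach %.4g /s\n",
              x$k_off_chi, if (x$k_off_chi > 0) log(2) / x$k_off_chi else Inf,
              x$k_iso, x$k_detach))
  invisible(x)
}

#' DNA substrate geometry for a simulation
#'
#' Positions are 0-based base pairs from the enzyme entry end; the substrate
#' occupies the half-open interval \[0, `length_bp`). Chi sites are
#' coordinates, not sequence matches.
#'
#' @param length_bp Total substrate length (bp).
#' @param chi_positions Ordered (strictly increasing) Chi positions from the
#'   entry end (bp); may be empty for Chi-free DNA.
#' @param triplex_pos Optional position of a triplex/fluorescent reporter
#'   (bp); must lie beyond the last Chi when both are present.
#' @param blocked_far_end Flag: the distal end is blocked so entry is
#'   unidirectional (metadata).
#' @return An object of class `substrate_spec`.
#' @examples
#' substrate_spec(7700, chi_positions = 4588 + 30 * (0:9))
#' @export
substrate_spec <- function(length_bp, chi_positions = numeric(0),
                           triplex_pos = NULL, blocked_far_end = TRUE) {
  stopifnot(is.numeric(length_bp), length(length_bp) == 1L, length_bp > 0)
  chi_positions <- as.numeric(chi_positions)
  if (length(chi_positions)) {
    if (any(chi_positions <= 0) || any(chi_positions >= length_bp))
      stop("every Chi position must lie strictly inside (0, length_bp)")
    if (is.unsorted(chi_positions, strictly = TRUE))
      stop("'chi_positions' must be strictly increasing")
  }
  if (!is.null(triplex_pos)) {
    stopifnot(is.numeric(triplex_pos), length(triplex_pos) == 1L)
    if (triplex_pos <= 0 || triplex_pos >= length_bp)
      stop("'triplex_pos' must lie strictly inside (0, length_bp)")
    if (length(chi_positions) && triplex_pos <= max(chi_positions))
      stop("'triplex_pos' must be beyond the last Chi position")
  }
  structure(list(length_bp = length_bp, chi_positions = chi_positions,
                 triplex_pos = triplex_pos,
                 blocked_far_end = isTRUE(blocked_far_end)),
            class = "substrate_spec")
}

#' Acquisition settings for rendering a magnetic-tweezers trace
#'
#' @param sample_rate_hz Raw camera acquisition rate (Hz).
#' @param filter_rate_hz Analysis bandwidth after block averaging (Hz).
#' @param noise_sd_bp Gaussian positional noise SD per raw sample (bp).
#' @param rise_per_bp_nm Extension per base pair at the applied force
#'   (nm/bp); metadata for unit conversion only.
#' @param force_pn Applied force (pN); metadata only.
#' @param seed Optional integer seed recorded with rendered traces.
#' @return An object of class `trace_config`.
#' @export
trace_config <- function(sample_rate_hz = 60, filter_rate_hz = 3,
                         noise_sd_bp = 30, rise_per_bp_nm = 0.33,
                         force_pn = 3, seed = NULL) {
  stopifnot(sample_rate_hz > 0, filter_rate_hz > 0,
            sample_rate_hz > filter_rate_hz, noise_sd_bp >= 0)
  structure(list(sample_rate_hz = sample_rate_hz,
                 filter_rate_hz = filter_rate_hz,
                 noise_sd_bp = noise_sd_bp,
                 rise_per_bp_nm = rise_per_bp_nm,
                 force_pn = force_pn, seed = seed),
            class = "trace_config")
}

#' Convert a locus-level pause frequency to a per-Chi probability
#'
#' Pause frequency is reported at the level of a Chi locus containing `n_chi`
#' closely spaced sites; the simulator is parameterized per encounter. Under
#' independence the locus frequency f and per-site probability p satisfy
#' f = 1 - (1 - p)^n_chi.
#'
#' @param frequency Locus-level probability of at least one pause, in \[0, 1).
#' @param n_chi Number of Chi sites in the locus (default 10).
#' @return Per-Chi pause probability.
#' @examples
#' locus_to_per_chi(0.66)        # ~0.102 per site for a 10-Chi locus
#' @export
locus_to_per_chi <- function(frequency, n_chi = 10) {
  stopifnot(frequency >= 0, frequency < 1, n_chi >= 1)
  1 - (1 - frequency)^(1 / n_chi)
}

#' Gamma pause scale matching a censored median dwell
#'
#' Dwell times below the instrument resolution `censor_s` are undetectable, so
#' reported medians are medians of the gamma law truncated below at the
#' censor. This inverts that relationship: it returns the scale theta such
#' that the gamma(shape, theta) distribution, conditioned on exceeding
#' `censor_s`, has median `median_s`.
#'
#' @param median_s Target censored median dwell (s), > `censor_s`.
#' @param shape Gamma shape (number of kinetic sub-steps), default 2.
#' @param censor_s Detection limit (s), default 0.33.
#' @return Gamma scale parameter (s).
#' @examples
#' th <- calibrate_pause_scale(1.45)
#' @export
calibrate_pause_scale <- function(median_s, shape = 2, censor_s = 0.33) {
  stopifnot(median_s > censor_s, shape >= 1, censor_s >= 0)
  f <- function(theta) {
    pgamma(median_s, shape, scale = theta) -
      (1 + pgamma(censor_s, shape, scale = theta)) / 2
  }
  # below ~median_s/20 both CDFs saturate at 1 and f is identically 0 in
  # floating point; keep the bracket inside the informative region
  lower <- median_s / 20
  while (f(lower) <= 0 && lower < median_s) lower <- lower * 1.5
  uniroot(f, lower = lower, upper = 100 * median_s, tol = 1e-10)$root
}

#' Median of a censored gamma dwell-time law
#'
#' Median of gamma(shape, scale) conditioned on exceeding `censor_s`; the
#' population counterpart of the median reported over detected pauses.
#'
#' @param shape,scale Gamma parameters.
#' @param censor_s Detection limit (s).
#' @return Censored median (s).
#' @export
censored_gamma_median <- function(shape, scale, censor_s = 0.33) {
  p <- (1 + pgamma(censor_s, shape, scale = scale)) / 2
  qgamma(p, shape, scale = scale)
}
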