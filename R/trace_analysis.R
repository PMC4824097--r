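# Magnetic-tweezers trace analysis: bandwidth filtering, local velocity,
# velocity-threshold pause detection with the instrument-resolution censor,
# censored dwell statistics and the Mood's median comparison.

#' Analysis settings for translocation traces
#'
#' @param filter_rate_hz Target bandwidth of the block-averaging filter (Hz).
#' @param min_pause_s Temporal resolution of the instrument: dwells shorter
#'   than this cannot be detected and are never reported (s).
#' @param velocity_window_s Width of the sliding least-squares window used
#'   for local velocity (s). Two filtered samples by default.
#' @param pause_velocity_frac Fraction of the trace's pre-Chi mean velocity
#'   below which a sample counts as paused. At 0.5 the length of a
#'   below-threshold run is an unbiased estimate of the plateau duration;
#'   other values are corrected for the window-overlap geometry (see
#'   [detect_pauses()]).
#' @param chi_window_bp Positional window `c(start, end)` classifying a
#'   pause as at-Chi (bp). Default spans the packaged ten-Chi locus plus a
#'   spacing margin on both sides: the reported position of a dwell at the
#'   first site sits a few bp below the site itself, because the samples at
#'   the plateau edges average in pre-pause positions.
#' @param profile_bin_bp Bin width of velocity-versus-position profiles (bp).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(filter_rate_hz = 3, min_pause_s = 0.33,
                            velocity_window_s = 2 / filter_rate_hz,
                            pause_velocity_frac = 0.5,
                            chi_window_bp = c(4558, 4958),
                            profile_bin_bp = 100) {
  stopifnot(filter_rate_hz > 0, min_pause_s > 0,
            velocity_window_s > 0,
            pause_velocity_frac > 0, pause_velocity_frac < 1,
            length(chi_window_bp) == 2L,
            chi_window_bp[1] < chi_window_bp[2], profile_bin_bp > 0)
  structure(list(filter_rate_hz = filter_rate_hz, min_pause_s = min_pause_s,
                 velocity_window_s = velocity_window_s,
                 pause_velocity_frac = pause_velocity_frac,
                 chi_window_bp = as.numeric(chi_window_bp),
                 profile_bin_bp = profile_bin_bp),
            class = "analysis_config")
}

#' Reduce a raw trace to the analysis bandwidth
#'
#' Non-overlapping block averages of `round(sample_rate / filter_rate)` raw
#' samples; the output sampling rate is `filter_rate_hz`. White positional
#' noise of SD sigma is attenuated to sigma/sqrt(block).
#'
#' @param trace A `scanner_trace`.
#' @param cfg An [analysis_config].
#' @return A `scanner_trace` at the reduced rate (`filtered = TRUE`).
#' @export
filter_trace <- function(trace, cfg = analysis_config()) {
  stopifnot(inherits(trace, "scanner_trace"))
  k <- max(1L, round(trace$sample_rate_hz / cfg$filter_rate_hz))
  n <- length(trace$time_s)
  nb <- n %/% k
  if (nb < 1L) stop("trace shorter than one filter block")
  idx <- seq_len(nb * k)
  block_mean <- function(x) colMeans(matrix(x[idx], nrow = k))
  out <- trace
  out$time_s <- block_mean(trace$time_s)
  out$position_bp <- block_mean(trace$position_bp)
  out$sample_rate_hz <- trace$sample_rate_hz / k
  out$filtered <- TRUE
  out
}

.ensure_filtered <- function(trace, cfg) {
  if (isTRUE(trace$filtered) ||
      trace$sample_rate_hz <= cfg$filter_rate_hz * 1.0001) return(trace)
  filter_trace(trace, cfg)
}

#' Local translocation velocity
#'
#' Sliding least-squares slope of position versus time over a centred window
#' of `velocity_window_s`; windows are truncated at the trace edges. One
#' velocity per sample, in bp/s.
#'
#' @param trace A filtered `scanner_trace` (raw traces are filtered first).
#' @param cfg An [analysis_config].
#' @return Numeric vector of velocities, same length as the trace.
#' @export
local_velocity <- function(trace, cfg = analysis_config()) {
  trace <- .ensure_filtered(trace, cfg)
  t <- trace$time_s; x <- trace$position_bp
  n <- length(t)
  h <- max(1L, round(cfg$velocity_window_s * trace$sample_rate_hz / 2))
  if (n < 2L || 2L * h + 1L < 2L) stop("velocity window shorter than 2 samples")
  cs <- function(v) cumsum(c(0, v))
  c1 <- cs(rep(1, n)); ct <- cs(t); cx <- cs(x); ctt <- cs(t * t)
  ctx <- cs(t * x)
  i <- seq_len(n)
  j1 <- pmax(1L, i - h); j2 <- pmin(n, i + h)
  m   <- c1[j2 + 1L] - c1[j1]
  st  <- ct[j2 + 1L] - ct[j1]
  sx  <- cx[j2 + 1L] - cx[j1]
  stt <- ctt[j2 + 1L] - ctt[j1]
  stx <- ctx[j2 + 1L] - ctx[j1]
  denom <- stt - st * st / m
  slope <- (stx - st * sx / m) / denom
  slope[denom <= 0] <- NA_real_
  slope
}

# Mean velocity over samples whose full velocity window precedes the first
# entry into the Chi window; falls back to the whole trace when the trace
# never reaches the window.
.pre_chi_reference <- function(trace, vel, cfg) {
  enter <- which(trace$position_bp >= cfg$chi_window_bp[1])[1L]
  if (!is.na(enter)) {
    # interpolate the actual crossing time (the sample grid detects it up
    # to one filtered sample late), then exclude every sample whose
    # velocity window could touch the Chi window
    t_cross <- if (enter == 1L) trace$time_s[1L] else {
      p0 <- trace$position_bp[enter - 1L]; p1 <- trace$position_bp[enter]
      trace$time_s[enter - 1L] +
        (cfg$chi_window_bp[1] - p0) / max(p1 - p0, 1e-9) *
          (trace$time_s[enter] - trace$time_s[enter - 1L])
    }
    cut <- t_cross - cfg$velocity_window_s / 2 - 1 / trace$sample_rate_hz
    use <- trace$time_s < cut
    if (sum(use) >= 2L) return(mean(vel[use], na.rm = TRUE))
  }
  mean(vel, na.rm = TRUE)
}

#' Mean pre-Chi velocity of a trace
#'
#' Mean local velocity from entry up to the first crossing into the Chi
#' window (samples whose velocity window straddles the crossing are
#' excluded so pause plateaus do not leak into the estimate).
#'
#' @param trace A `scanner_trace`.
#' @param cfg An [analysis_config].
#' @return Mean velocity (bp/s).
#' @export
pre_chi_velocity <- function(trace, cfg = analysis_config()) {
  trace <- .ensure_filtered(trace, cfg)
  .pre_chi_reference(trace, local_velocity(trace, cfg), cfg)
}

#' Detect translocation pauses in a trace
#'
#' Maximal runs of samples whose local velocity falls below
#' `pause_velocity_frac` times the trace's pre-Chi mean velocity become
#' candidate events. Run lengths are corrected for the window-overlap
#' geometry of the sliding velocity estimate (a sample is flagged only when
#' the paused fraction of its window exceeds `1 - frac`, so the run
#' under-covers the plateau by `(1 - 2 frac) * window`; the correction
#' vanishes at the default `frac = 0.5`). Events shorter than `min_pause_s`
#' - the instrument resolution - are discarded, never reported. An event is
#' at-Chi when its mean position falls inside `chi_window_bp`.
#'
#' @param trace A `scanner_trace` (raw traces are filtered first).
#' @param cfg An [analysis_config].
#' @return A data frame of events: `start_s`, `duration_s`, `position_bp`,
#'   `at_chi`. Traces without pauses give zero rows.
#' @export
detect_pauses <- function(trace, cfg = analysis_config()) {
  trace <- .ensure_filtered(trace, cfg)
  vel <- local_velocity(trace, cfg)
  ref <- .pre_chi_reference(trace, vel, cfg)
  thr <- cfg$pause_velocity_frac * ref
  low <- !is.na(vel) & vel < thr
  n <- length(low)
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- 1 / trace$sample_rate_hz
  corr <- (1 - 2 * cfg$pause_velocity_frac) * cfg$velocity_window_s
  # sub-sample boundary: linear interpolation of the velocity's threshold
  # crossing just outside the run, so durations are not quantized to the
  # filtered sampling grid
  cross_left <- function(s) {
    if (s == 1L || is.na(vel[s - 1L]) || vel[s - 1L] <= vel[s]) return(s - 0.5)
    (s - 1L) + (vel[s - 1L] - thr) / (vel[s - 1L] - vel[s])
  }
  cross_right <- function(e) {
    if (e == n || is.na(vel[e + 1L]) || vel[e + 1L] <= vel[e]) return(e + 0.5)
    e + (thr - vel[e]) / (vel[e + 1L] - vel[e])
  }
  out <- data.frame(start_s = numeric(0), duration_s = numeric(0),
                    position_bp = numeric(0), at_chi = logical(0))
  for (j in which(r$values)) {
    lft <- cross_left(starts[j]); rgt <- cross_right(ends[j])
    dur <- (rgt - lft) * dt + corr
    if (dur < cfg$min_pause_s) next
    idx <- starts[j]:ends[j]
    pos <- mean(trace$position_bp[idx])
    out <- rbind(out, data.frame(
      start_s = trace$time_s[starts[j]] - (starts[j] - lft) * dt,
      duration_s = dur, position_bp = pos,
      at_chi = pos >= cfg$chi_window_bp[1] & pos <= cfg$chi_window_bp[2]))
  }
  out
}

#' Censored pause statistics over an ensemble of traces
#'
#' Frequency is the fraction of traces showing at least one at-Chi pause;
#' duration summaries (median, mean, quartiles, range) are computed over
#' detected at-Chi events only, i.e. explicitly censored at the instrument
#' resolution `min_pause_s`.
#'
#' @param events_per_trace A list with one [detect_pauses()] data frame per
#'   trace (a single data frame is treated as one trace).
#' @param cfg An [analysis_config].
#' @return An object of class `pause_stats`.
#' @export
pause_statistics <- function(events_per_trace, cfg = analysis_config()) {
  if (is.data.frame(events_per_trace))
    events_per_trace <- list(events_per_trace)
  if (!length(events_per_trace)) stop("no traces supplied")
  at_chi <- lapply(events_per_trace, function(e) e[e$at_chi, , drop = FALSE])
  has <- vapply(at_chi, function(e) nrow(e) > 0L, logical(1))
  dur <- unlist(lapply(at_chi, function(e) e$duration_s))
  q <- if (length(dur)) unname(quantile(dur, c(0.25, 0.5, 0.75)))
       else rep(NA_real_, 3)
  structure(list(n_events = length(dur),
                 n_traces = length(events_per_trace),
                 frequency = mean(has),
                 median_s = q[2], mean_s = if (length(dur)) mean(dur) else NA_real_,
                 q25_s = q[1], q75_s = q[3],
                 min_s = if (length(dur)) min(dur) else NA_real_,
                 max_s = if (length(dur)) max(dur) else NA_real_),
            class = "pause_stats")
}

#' @export
print.pause_stats <- function(x, ...) {
  cat(sprintf("Pause statistics: %d at-Chi events in %d traces\n",
              x$n_events, x$n_traces))
  cat(sprintf("  frequency %.3f; median %.3g s (IQR %.3g-%.3g), mean %.3g s, range %.3g-%.3g s\n",
              x$frequency, x$median_s, x$q25_s, x$q75_s, x$mean_s,
              x$min_s, x$max_s))
  invisible(x)
}

#' Mood's median test for two dwell-time samples
#'
#' Nonparametric comparison of medians: counts of observations above versus
#' not above the pooled grand median form a 2x2 table tested by chi-square
#' with 1 degree of freedom and continuity correction. Values equal to the
#' grand median count as "not above". The test is symmetric in its
#' arguments.
#'
#' @param a,b Numeric samples (non-empty).
#' @return Object of class `moods_median_test`: `table`, `statistic`,
#'   `p_value`, `grand_median`.
#' @export
moods_median_test <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0,
            is.numeric(a), is.numeric(b))
  pooled <- c(a, b)
  gm <- median(pooled)
  if (all(pooled == pooled[1]))
    stop("degenerate samples: all pooled values identical")
  tab <- rbind(a = c(above = sum(a > gm), not_above = sum(a <= gm)),
               b = c(above = sum(b > gm), not_above = sum(b <= gm)))
  if (any(colSums(tab) == 0))
    stop("degenerate table: no variation about the grand median")
  ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
  structure(list(table = tab, statistic = unname(ct$statistic),
                 p_value = unname(ct$p.value), grand_median = gm),
            class = "moods_median_test")
}

#' @export
print.moods_median_test <- function(x, ...) {
  cat("Mood's median test\n")
  cat(sprintf("  grand median %.4g; X-squared = %.4g, p = %.4g\n",
              x$grand_median, x$statistic, x$p_value))
  print(x$table)
  invisible(x)
}

#' Mean velocity as a function of position
#'
#' Bins the pooled local velocities of an ensemble of traces by enzyme
#' position. Bins never visited by any trace are reported with `NA` mean
#' (empty, not zero). The at-Chi pause of a converted population appears as
#' a sharp dip inside the Chi window.
#'
#' @param traces A list of `scanner_trace` objects over a common substrate
#'   (a single trace is accepted).
#' @param cfg An [analysis_config].
#' @return Data frame: `bin_start_bp`, `bin_end_bp`, `mean_velocity`, `n`.
#' @export
mean_velocity_profile <- function(traces, cfg = analysis_config()) {
  if (inherits(traces, "scanner_trace")) traces <- list(traces)
  if (!length(traces)) stop("no traces supplied")
  bw <- cfg$profile_bin_bp
  maxpos <- max(vapply(traces, function(tr) max(tr$position_bp), numeric(1)))
  nbin <- ceiling(maxpos / bw) + 1L
  sums <- numeric(nbin); cnts <- integer(nbin)
  for (tr in traces) {
    tr <- .ensure_filtered(tr, cfg)
    vel <- local_velocity(tr, cfg)
    bin <- pmin(nbin, pmax(1L, floor(tr$position_bp / bw) + 1L))
    ok <- !is.na(vel)
    sums <- sums + unname(tapply_sum(bin[ok], vel[ok], nbin))
    cnts <- cnts + unname(tapply_sum(bin[ok], rep(1L, sum(ok)), nbin))
  }
  data.frame(bin_start_bp = (seq_len(nbin) - 1L) * bw,
             bin_end_bp = seq_len(nbin) * bw,
             mean_velocity = ifelse(cnts > 0, sums / pmax(1L, cnts), NA_real_),
             n = cnts)
}

# grouped sum onto a fixed number of bins
tapply_sum <- function(bin, val, nbin) {
  out <- numeric(nbin)
  agg <- rowsum(val, group = bin)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
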