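# Stochastic simulation of the two-state gated scanner: piecewise-linear
# event paths, rendered bead traces, and the three ensemble assays.

with_seed_opt <- function(seed, code) {
  if (is.null(seed)) force(code)
  else withr::with_seed(as.integer(seed), force(code))
}

#' Draw stalled-encounter-complex dwell times
#'
#' Pause durations at Chi are gamma distributed with integer shape: the dwell
#' is the sum of `pause_shape` sequential exponential kinetic steps of mean
#' `pause_scale` each. Shape 1 recovers a single-exponential dwell.
#'
#' @param params An [enzyme_params] object.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Vector of `n` positive dwell times (s).
#' @export
draw_pause_duration <- function(params, n = 1, seed = NULL) {
  stopifnot(inherits(params, "enzyme_params"))
  with_seed_opt(seed,
    rgamma(n, shape = params$pause_shape, scale = params$pause_scale))
}

#' Simulate one noiseless translocation path
#'
#' Generates the piecewise-linear position-versus-time path of a single
#' enzyme entering the substrate at position 0 and moving toward
#' `length_bp`. In the scanning (pre-Chi) state the enzyme moves at `v_pre`;
#' each Chi site encountered arrests it with probability `p_pause` for a
#' gamma-distributed dwell, which ends either in commitment to the
#' Chi-modified state (probability `p_commit`; thereafter rate `v_post` and
#' Chi sites are ignored) or in resumption of scanning. Spontaneous
#' isomerization to the Chi-modified state occurs at hazard `k_iso` per
#' second of pre-Chi translocation (no pause is emitted on a spontaneous
#' switch), and detachment at hazard `k_detach` terminates the path early.
#'
#' @param params An [enzyme_params] object.
#' @param substrate A [substrate_spec] object.
#' @param seed Optional integer seed.
#' @return An object of class `scanner_path`: vertex vectors `time_s`,
#'   `position_bp` and a ground-truth `events` log (pauses, state switch,
#'   detachment, completion).
#' @export
simulate_path <- function(params, substrate, seed = NULL) {
  stopifnot(inherits(params, "enzyme_params"),
            inherits(substrate, "substrate_spec"))
  with_seed_opt(seed, {
    L <- substrate$length_bp
    chi <- substrate$chi_positions
    tt <- 0; xx <- 0
    vt <- numeric(64); vx <- numeric(64); nv <- 1L  # vertex buffers
    vt[1L] <- 0; vx[1L] <- 0
    push <- function(t, x) {
      if (nv == length(vt)) { vt <<- c(vt, numeric(length(vt)))
                              vx <<- c(vx, numeric(length(vx))) }
      nv <<- nv + 1L; vt[nv] <<- t; vx[nv] <<- x
    }
    state <- "pre"; ci <- 1L
    p_start <- numeric(0); p_dur <- numeric(0); p_pos <- numeric(0)
    p_com <- logical(0)
    switch_ev <- NULL; detach_ev <- NULL; reached_end <- FALSE
    repeat {
      v <- if (state == "pre") params$v_pre else params$v_post
      if (v <= 0) break
      target <- if (state == "pre" && ci <= length(chi)) chi[ci] else L
      dt_move <- (target - xx) / v
      t_iso <- if (state == "pre" && params$k_iso > 0)
        rexp(1, params$k_iso) else Inf
      t_det <- if (params$k_detach > 0) rexp(1, params$k_detach) else Inf
      if (t_det <= dt_move && t_det <= t_iso) {
        xx <- xx + v * t_det; tt <- tt + t_det; push(tt, xx)
        detach_ev <- list(time_s = tt, position_bp = xx)
        break
      }
      if (t_iso < dt_move) {
        xx <- xx + v * t_iso; tt <- tt + t_iso; push(tt, xx)
        state <- "post"
        switch_ev <- list(time_s = tt, position_bp = xx,
                          cause = "spontaneous")
        next
      }
      xx <- target; tt <- tt + dt_move; push(tt, xx)
      if (xx >= L) { reached_end <- TRUE; break }
      # at a Chi site in the scanning state
      ci <- ci + 1L
      if (runif(1) < params$p_pause) {
        d <- rgamma(1, shape = params$pause_shape,
                    scale = params$pause_scale)
        committed <- runif(1) < params$p_commit
        p_start <- c(p_start, tt); p_dur <- c(p_dur, d)
        p_pos <- c(p_pos, xx); p_com <- c(p_com, committed)
        tt <- tt + d; push(tt, xx)
        if (committed) {
          state <- "post"
          switch_ev <- list(time_s = tt, position_bp = xx,
                            cause = "chi_commit")
        }
      }
    }
    structure(list(
      time_s = vt[seq_len(nv)], position_bp = vx[seq_len(nv)],
      events = list(
        pauses = data.frame(start_s = p_start, duration_s = p_dur,
                            position_bp = p_pos, committed = p_com),
        switch = switch_ev, detach = detach_ev, reached_end = reached_end),
      params = params, substrate = substrate, seed = seed),
      class = "scanner_path")
  })
}

#' First-passage time of a path at a position
#'
#' Earliest time at which the (noiseless) path reaches `position_bp`, or `NA`
#' if the enzyme detached before getting there.
#'
#' @param path A `scanner_path`.
#' @param position_bp Query position (bp).
#' @return Arrival time (s) or `NA_real_`.
#' @export
path_time_at <- function(path, position_bp) {
  stopifnot(inherits(path, "scanner_path"))
  x <- path$position_bp; t <- path$time_s
  if (max(x) < position_bp) return(NA_real_)
  i <- which(x >= position_bp)[1L]
  if (i == 1L) return(t[1L])
  if (x[i] == position_bp) {
    # take the earliest vertex at this position (pauses duplicate positions)
    i <- which(x == position_bp)[1L]
    return(t[i])
  }
  # interpolate inside the moving segment [i-1, i]
  t[i - 1L] + (position_bp - x[i - 1L]) / (x[i] - x[i - 1L]) *
    (t[i] - t[i - 1L])
}

#' Render a noiseless path as a sampled bead trace
#'
#' Discretizes a path at the camera sampling rate and adds independent
#' Gaussian positional noise per raw sample, emulating the optically
#' detected bead height converted to base pairs.
#'
#' @param path A `scanner_path` from [simulate_path()].
#' @param cfg A [trace_config]; `cfg$seed` (if set) makes the noise
#'   reproducible.
#' @return An object of class `scanner_trace` with fields `time_s`,
#'   `position_bp`, `sample_rate_hz`, `variant`, `seed` and the ground-truth
#'   `events` log carried over from the path.
#' @export
render_trace <- function(path, cfg = trace_config()) {
  stopifnot(inherits(path, "scanner_path"), inherits(cfg, "trace_config"))
  dur <- path$time_s[length(path$time_s)]
  if (dur <= 0) stop("path has zero duration; nothing to render")
  n <- ceiling(dur * cfg$sample_rate_hz)
  times <- (seq_len(n) - 1) / cfg$sample_rate_hz
  pos <- approx(path$time_s, path$position_bp, xout = times, rule = 2,
                ties = "ordered")$y
  noisy <- with_seed_opt(cfg$seed,
    pos + rnorm(n, sd = cfg$noise_sd_bp))
  structure(list(time_s = times, position_bp = noisy,
                 sample_rate_hz = cfg$sample_rate_hz,
                 noise_sd_bp = cfg$noise_sd_bp,
                 variant = path$params$name, seed = cfg$seed,
                 events = path$events,
                 substrate = path$substrate),
            class = "scanner_trace")
}

#' Convenience wrapper: simulate and render one trace
#'
#' @inheritParams simulate_path
#' @param cfg A [trace_config].
#' @param seed Integer seed driving both the path and the camera noise.
#' @return A `scanner_trace`.
#' @export
simulate_trace <- function(params, substrate, cfg = trace_config(),
                           seed = NULL) {
  with_seed_opt(seed, {
    path <- simulate_path(params, substrate)
    cfg$seed <- NULL
    tr <- render_trace(path, cfg)
    tr$seed <- seed
    tr
  })
}

#' Simulate an exonuclease-chase survival series
#'
#' After Chi recognition the enzyme footprints the 3' end of the Chi
#' fragment; an excess single-strand exonuclease added at time zero degrades
#' the fragment as soon as the enzyme dissociates. Per-molecule dissociation
#' times are exponential with rate `k_off_chi` (per minute), so the expected
#' surviving fraction is exp(-k_off_chi * t). Each timepoint is a separately
#' quenched aliquot of `n_molecules`, so the realized fractions are
#' independent binomial draws, optionally scaled by mean-one multiplicative
#' lognormal measurement noise of coefficient of variation `noise_cv`
#' (densitometry error).
#'
#' @param params An [enzyme_params]; only `k_off_chi` is used.
#' @param timepoints_min Non-negative, increasing sampling times (min).
#' @param n_molecules Ensemble size (> 0).
#' @param noise_cv Coefficient of variation of the measurement noise
#'   (0 disables it).
#' @param seed Optional integer seed.
#' @return Object of class `chase_series` with `time_min`,
#'   `fragment_fraction` and `n_molecules`.
#' @export
simulate_chase <- function(params, timepoints_min, n_molecules,
                           noise_cv = 0, seed = NULL) {
  stopifnot(inherits(params, "enzyme_params"))
  if (n_molecules <= 0) stop("'n_molecules' must be positive")
  if (any(timepoints_min < 0) || is.unsorted(timepoints_min))
    stop("'timepoints_min' must be non-negative and increasing")
  with_seed_opt(seed, {
    t_diss <- if (params$k_off_chi > 0)
      rexp(n_molecules, rate = params$k_off_chi) else rep(Inf, n_molecules)
    frac <- vapply(timepoints_min, function(t) {
      # an independent aliquot per lane
      if (params$k_off_chi <= 0) return(1)
      mean(rexp(n_molecules, rate = params$k_off_chi) > t)
    }, numeric(1))
    if (noise_cv > 0) {
      sdlog <- sqrt(log1p(noise_cv^2))
      frac <- frac * rlnorm(length(frac), meanlog = -sdlog^2 / 2,
                            sdlog = sdlog)
    }
    structure(list(time_min = as.numeric(timepoints_min),
                   fragment_fraction = pmin(1, pmax(0, frac)),
                   n_molecules = n_molecules,
                   dissociation_times_min = t_diss,
                   variant = params$name, seed = seed),
              class = "chase_series")
  })
}

#' Simulate a normalized triplex-displacement transient
#'
#' Each molecule translocates from the free DNA end (via [simulate_path()]);
#' on reaching the triplex reporter it displaces the fluorescent
#' oligonucleotide after an exponential displacement step of rate
#' `displacement_rate`. The population signal at time t is the fraction of
#' displacement events completed by t, normalized to the fluorescent
#' endpoint (molecules that detach before the triplex never contribute).
#' Molecules converted to the Chi-modified state - by commitment at a Chi
#' site or by spontaneous isomerization - arrive late, producing the delayed
#' second phase.
#'
#' @param params An [enzyme_params].
#' @param substrate A [substrate_spec] with `triplex_pos` set.
#' @param n_molecules Ensemble size.
#' @param displacement_rate Rate of the triplex displacement step once the
#'   enzyme arrives (per s).
#' @param seed Optional integer seed.
#' @param n_time Number of points of the output time grid.
#' @return Object of class `triplex_curve` with `time_s`, `signal`,
#'   `n_chi`, `triplex_distance_bp`.
#' @export
simulate_triplex_curve <- function(params, substrate, n_molecules,
                                   displacement_rate = 10, seed = NULL,
                                   n_time = 512) {
  stopifnot(inherits(params, "enzyme_params"),
            inherits(substrate, "substrate_spec"))
  if (is.null(substrate$triplex_pos))
    stop("substrate has no triplex position")
  if (displacement_rate <= 0) stop("'displacement_rate' must be > 0")
  with_seed_opt(seed, {
    arr <- numeric(n_molecules)
    for (i in seq_len(n_molecules)) {
      p <- simulate_path(params, substrate)
      arr[i] <- path_time_at(p, substrate$triplex_pos)
    }
    arr <- arr[!is.na(arr)]
    if (!length(arr)) stop("no molecule reached the triplex")
    done <- arr + rexp(length(arr), rate = displacement_rate)
    grid <- seq(0, max(done) * 1.02, length.out = n_time)
    sig <- ecdf(done)(grid)
    structure(list(time_s = grid, signal = sig,
                   n_chi = sum(substrate$chi_positions <
                                 substrate$triplex_pos),
                   triplex_distance_bp = substrate$triplex_pos,
                   n_molecules = n_molecules, n_arrived = length(arr),
                   displacement_s = done, variant = params$name,
                   seed = seed),
              class = "triplex_curve")
  })
}

#' Simulate the Chi-fragment yield of an ensemble
#'
#' A molecule produces a Chi fragment if and only if it commits to the
#' Chi-modified state at a Chi site on the substrate (detachment before Chi,
#' passing all Chi sites without arrest, failed pauses, and spontaneous
#' isomerization all yield none).
#'
#' @param params An [enzyme_params].
#' @param substrate A [substrate_spec] with at least one Chi site.
#' @param n_molecules Ensemble size.
#' @param seed Optional integer seed.
#' @return Fraction of molecules committing at Chi (numeric scalar).
#' @export
simulate_chi_yield <- function(params, substrate, n_molecules,
                               seed = NULL) {
  stopifnot(inherits(params, "enzyme_params"),
            inherits(substrate, "substrate_spec"))
  if (!length(substrate$chi_positions))
    stop("substrate has no Chi sites")
  with_seed_opt(seed, {
    hits <- 0L
    for (i in seq_len(n_molecules)) {
      p <- simulate_path(params, substrate)
      sw <- p$events$switch
      if (!is.null(sw) && identical(sw$cause, "chi_commit"))
        hits <- hits + 1L
    }
    hits / n_molecules
  })
}
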