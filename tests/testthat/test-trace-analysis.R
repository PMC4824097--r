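test_that("block filtering reduces rate and noise as expected", {
  cfg <- analysis_config()
  # constant trace stays constant at the lower rate
  n <- 1200
  tr <- structure(list(time_s = (0:(n - 1)) / 60,
                       position_bp = rep(500, n), sample_rate_hz = 60),
                  class = "scanner_trace")
  f <- filter_trace(tr, cfg)
  expect_equal(length(f$time_s), floor(n / 20))
  expect_true(all(f$position_bp == 500))
  expect_equal(f$sample_rate_hz, 3)
  # white noise SD sigma becomes sigma / sqrt(20)
  n <- 2e5
  trn <- structure(list(time_s = (0:(n - 1)) / 60,
                        position_bp = withr::with_seed(8, rnorm(n, sd = 30)),
                        sample_rate_hz = 60),
                   class = "scanner_trace")
  fn <- filter_trace(trn, cfg)
  expect_equal(sd(fn$position_bp), 30 / sqrt(20), tolerance = 0.05)
  # too-short trace errors
  short <- structure(list(time_s = (0:5) / 60, position_bp = rep(0, 6),
                          sample_rate_hz = 60), class = "scanner_trace")
  expect_error(filter_trace(short, cfg), "shorter")
})

test_that("local velocity recovers slopes, plateaus and noisy rates", {
  cfg <- analysis_config()
  mk <- function(pos, rate = 3) structure(
    list(time_s = (seq_along(pos) - 1) / rate, position_bp = pos,
         sample_rate_hz = rate, filtered = TRUE), class = "scanner_trace")
  # exact line
  tr <- mk(300 * (0:100) / 3)
  expect_equal(local_velocity(tr, cfg), rep(300, 101), tolerance = 1e-9)
  # inserted plateau reads ~0 in its interior
  pos <- c(300 * (0:30) / 3, rep(3000, 15), 3000 + 300 * (1:30) / 3)
  v <- local_velocity(mk(pos), cfg)
  expect_lt(max(abs(v[35:43])), 1e-6)
  # noisy line: mean velocity within 3% of truth (100 seeds, 10 s trace)
  errs <- vapply(1:100, function(s) {
    p <- free_runner(300)
    path <- simulate_path(p, chi_free_substrate(3000))
    tr <- render_trace(path, trace_config(noise_sd_bp = 30, seed = s))
    mean(local_velocity(filter_trace(tr, cfg), cfg))
  }, numeric(1))
  expect_lt(abs(mean(errs) - 300) / 300, 0.03)
})

test_that("the detector finds inserted plateaus and honours the 0.33 s censor", {
  cfg <- analysis_config()
  sub <- one_chi_substrate(6000, 4588)
  # 2.0 s dwell at the Chi site under default noise: one at-Chi event with
  # duration within 0.4 s, in at least 95 of 100 seeded runs
  hits <- 0L
  for (s in 1:100) {
    tr <- simulate_trace(fixed_pauser(2.0), sub, seed = 4000 + s)
    ev <- detect_pauses(tr, cfg)
    ev <- ev[ev$at_chi, , drop = FALSE]
    if (nrow(ev) == 1L &&
        abs(ev$duration_s - tr$events$pauses$duration_s[1]) <= 0.4)
      hits <- hits + 1L
  }
  expect_gte(hits, 95L)
  # a 0.20 s dwell is below the instrument resolution: never reported
  for (s in 1:30) {
    tr <- simulate_trace(fixed_pauser(0.20), sub, seed = 4200 + s)
    expect_equal(nrow(detect_pauses(tr, cfg)), 0L)
  }
  # pause-free noiseless trace gives an empty list
  clean <- render_trace(simulate_path(free_runner(), sub, seed = 1),
                        trace_config(noise_sd_bp = 0))
  expect_equal(nrow(detect_pauses(clean, cfg)), 0L)
})

test_that("no reported event is ever shorter than the resolution limit", {
  cfg <- analysis_config()
  sub <- one_chi_substrate(6000, 4588)
  p <- enzyme_params("mix", v_pre = 300, v_post = 225, p_pause = 1,
                     pause_shape = 2, pause_scale = 0.3, p_commit = 0.5)
  for (s in 1:40) {
    ev <- detect_pauses(simulate_trace(p, sub, seed = 4400 + s), cfg)
    if (nrow(ev)) expect_true(all(ev$duration_s >= cfg$min_pause_s))
  }
})

test_that("on noiseless traces detected dwells match the generator log", {
  cfg <- analysis_config()
  sub <- one_chi_substrate(6000, 4588)
  p <- enzyme_params("p", v_pre = 300, v_post = 225, p_pause = 1,
                     pause_shape = 2, pause_scale = 1.0, p_commit = 1)
  for (s in 1:20) {
    tr <- withr::with_seed(4600 + s, {
      render_trace(simulate_path(p, sub), trace_config(noise_sd_bp = 0))
    })
    truth <- tr$events$pauses$duration_s[1]
    ev <- detect_pauses(tr, cfg)
    dt <- 1 / cfg$filter_rate_hz
    if (truth < cfg$min_pause_s + dt) {
      # dwells within one filtered sample of the censor sit on the
      # detection boundary: either outcome is within quantization
      expect_lte(nrow(ev), 1L)
      if (nrow(ev) == 1L) expect_lt(abs(ev$duration_s - truth), 0.45)
    } else {
      expect_equal(nrow(ev), 1L)
      # agreement to about one filtered sample
      expect_lt(abs(ev$duration_s - truth), 0.45)
      expect_true(ev$at_chi)
    }
  }
})

test_that("pause statistics summarize censored at-Chi dwells", {
  cfg <- analysis_config()
  ev <- function(dur, pos = 4700) data.frame(
    start_s = 1, duration_s = dur, position_bp = pos,
    at_chi = pos >= cfg$chi_window_bp[1] & pos <= cfg$chi_window_bp[2])
  none <- data.frame(start_s = numeric(0), duration_s = numeric(0),
                     position_bp = numeric(0), at_chi = logical(0))
  st <- pause_statistics(list(ev(1), ev(2), ev(3)), cfg)
  expect_equal(st$median_s, 2)
  expect_equal(st$frequency, 1)
  expect_equal(st$n_events, 3L)
  # 6 of 10 traces with an at-Chi pause
  st6 <- pause_statistics(c(lapply(c(1, 2, 3, 1.5, 2.5, 0.9), ev),
                            rep(list(none), 4)), cfg)
  expect_equal(st6$frequency, 0.6)
  expect_true(st6$q25_s <= st6$median_s && st6$median_s <= st6$q75_s)
  # off-locus events do not count toward frequency
  off <- pause_statistics(list(ev(1, pos = 2000)), cfg)
  expect_equal(off$frequency, 0)
  expect_error(pause_statistics(list(), cfg), "no traces")
})

test_that("Mood's median test matches hand-computed contingency arithmetic", {
  # identical samples split evenly about the grand median
  r <- moods_median_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$p_value, 1.0)
  expect_equal(r$statistic, 0)
  # disjoint samples: table [[0,4],[4,0]]; Yates-corrected chi-square by
  # hand: all margins 4, E = 2 per cell, X2 = 4 * (1.5^2 / 2) = 4.5
  r2 <- moods_median_test(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(unname(r2$table), rbind(c(0, 4), c(4, 0)))
  expect_equal(r2$statistic, 4.5)
  expect_equal(r2$p_value, 1 - pchisq(4.5, df = 1))
  # symmetry
  r2b <- moods_median_test(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_equal(r2b$p_value, r2$p_value)
  # growing location shift never increases the p-value
  a <- withr::with_seed(71, rgamma(30, 2, scale = 1))
  b <- withr::with_seed(72, rgamma(30, 2, scale = 1))
  ps <- vapply(c(0, 0.5, 1, 2, 4),
               function(sh) moods_median_test(a, b + sh)$p_value, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  # degenerate data are refused
  expect_error(moods_median_test(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("velocity-position profiles localize the Chi dip", {
  cfg <- analysis_config()
  # identical constant-velocity traces give a flat profile
  flat <- lapply(1:3, function(s)
    render_trace(simulate_path(free_runner(300), chi_free_substrate(4000),
                               seed = s),
                 trace_config(noise_sd_bp = 0)))
  prof <- mean_velocity_profile(flat, cfg)
  inner <- prof$n > 0 & prof$bin_start_bp > 200 & prof$bin_end_bp < 3800
  expect_true(all(abs(prof$mean_velocity[inner] - 300) < 1))
  # a single trace's profile equals its own binned velocities
  one <- mean_velocity_profile(flat[[1]], cfg)
  expect_equal(one$mean_velocity, prof$mean_velocity, tolerance = 1e-9)
  # an ensemble with at-Chi dwells dips inside the Chi window
  sub <- default_substrate("tweezers")
  paused <- lapply(1:12, function(s)
    simulate_trace(fixed_pauser(2.0), sub, seed = 900 + s))
  pr <- mean_velocity_profile(paused, cfg)
  pr <- pr[pr$n > 10, ]
  dip <- pr$bin_start_bp[which.min(pr$mean_velocity)]
  expect_gte(dip + cfg$profile_bin_bp, cfg$chi_window_bp[1])
  expect_lte(dip, cfg$chi_window_bp[2])
})

test_that("detected pause frequency recovers the generating probability", {
  # dwells far above the censor so every generated pause is detectable
  p <- enzyme_params("f", v_pre = 300, v_post = 225,
                     p_pause = locus_to_per_chi(0.66), pause_shape = 2,
                     pause_scale = 3, p_commit = 0)
  sub <- default_substrate("tweezers")
  cfg <- analysis_config()
  n <- 48
  evs <- lapply(seq_len(n), function(i)
    detect_pauses(simulate_trace(p, sub, seed = 7100 + i), cfg))
  freq <- pause_statistics(evs, cfg)$frequency
  band <- qbinom(c(0.005, 0.995), n, 0.66) / n
  expect_gte(freq, band[1])
  expect_lte(freq, band[2])
})

test_that("the full pipeline recovers the censored median dwell at scale", {
  wt <- make_default_params("wildtype")
  sub <- default_substrate("tweezers")
  cfg <- analysis_config()
  durs <- c()
  s <- 0
  while (length(durs) < 500 && s < 1200) {
    s <- s + 1
    ev <- detect_pauses(simulate_trace(wt, sub, seed = 7500 + s), cfg)
    durs <- c(durs, ev$duration_s[ev$at_chi])
  }
  expect_gte(length(durs), 500)
  expect_equal(median(durs), 1.45, tolerance = 0.15)
})
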