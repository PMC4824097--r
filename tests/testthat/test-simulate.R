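test_that("pause durations follow the gamma dwell law", {
  # shape 1 is the exponential limit: sample mean equals the scale
  p1 <- enzyme_params("e", v_pre = 300, pause_shape = 1, pause_scale = 1.8)
  d1 <- draw_pause_duration(p1, n = 1e5, seed = 11)
  expect_equal(mean(d1), 1.8, tolerance = 0.02)
  expect_true(all(d1 > 0))

  # shape 2: population median from an independent bisection of the CDF
  # F(x) = 1 - (1 + x/theta) exp(-x/theta)
  theta <- 0.9
  cdf2 <- function(x) 1 - (1 + x / theta) * exp(-x / theta)
  lo <- 0; hi <- 20
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (cdf2(mid) < 0.5) lo <- mid else hi <- mid
  }
  p2 <- enzyme_params("e", v_pre = 300, pause_shape = 2, pause_scale = theta)
  d2 <- draw_pause_duration(p2, n = 2e5, seed = 12)
  expect_equal(median(d2), lo, tolerance = 0.01)
  expect_equal(lo / theta, 1.6783, tolerance = 1e-3)
})

test_that("a scanner without pausing or switching runs straight through", {
  p <- free_runner(300)
  path <- simulate_path(p, one_chi_substrate(6000, 3000), seed = 1)
  expect_equal(length(path$time_s), 3L)  # start, chi crossing, end
  expect_equal(max(path$position_bp), 6000)
  expect_equal(path$time_s[length(path$time_s)], 6000 / 300)
  expect_equal(nrow(path$events$pauses), 0L)
  expect_true(path$events$reached_end)
  # noiseless path is non-decreasing and bounded by the substrate
  expect_true(all(diff(path$position_bp) >= 0))
  expect_true(all(path$position_bp <= 6000))
})

test_that("a committed pause produces the deterministic arrival arithmetic", {
  d <- 2.0; L <- 3000; len <- 6000; v <- 300
  p <- fixed_pauser(d, v = v)
  path <- simulate_path(p, one_chi_substrate(len, L), seed = 5)
  expected <- L / v + path$events$pauses$duration_s[1] + (len - L) / p$v_post
  expect_equal(path$time_s[length(path$time_s)], expected, tolerance = 1e-12)
  # the dwell itself concentrates near d
  expect_equal(path$events$pauses$duration_s[1], d, tolerance = 0.25)
  expect_identical(path$events$switch$cause, "chi_commit")
})

test_that("spontaneous switching matches its closed-form first-passage law", {
  k_iso <- 0.08; v <- 300; L <- 5000
  p <- enzyme_params("e", v_pre = v, v_post = 200, k_iso = k_iso)
  n <- 3000
  switched <- withr::with_seed(21, {
    vapply(seq_len(n), function(i) {
      path <- simulate_path(p, chi_free_substrate(L))
      !is.null(path$events$switch)
    }, logical(1))
  })
  expected <- 1 - exp(-k_iso * L / v)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(switched) - expected), 3.5 * se)
})

test_that("per-substrate pause probability follows 1 - (1-p)^m", {
  p_chi <- 0.3; m <- 10
  p <- enzyme_params("e", v_pre = 300, p_pause = p_chi, pause_shape = 2,
                     pause_scale = 0.1, p_commit = 0)
  sub <- substrate_spec(4000, chi_positions = 1000 + 30 * (0:(m - 1)))
  n <- 2000
  paused <- withr::with_seed(22, {
    vapply(seq_len(n), function(i)
      nrow(simulate_path(p, sub)$events$pauses) > 0L, logical(1))
  })
  expected <- 1 - (1 - p_chi)^m
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(paused) - expected), 3.5 * se)
})

test_that("rendering reproduces the path plus calibrated Gaussian noise", {
  p <- free_runner(300)
  path <- simulate_path(p, chi_free_substrate(5000), seed = 3)
  clean <- render_trace(path, trace_config(noise_sd_bp = 0))
  expect_equal(length(clean$time_s),
               ceiling(path$time_s[length(path$time_s)] * 60))
  truth <- approx(path$time_s, path$position_bp, xout = clean$time_s,
                  rule = 2)$y
  expect_equal(clean$position_bp, truth)

  noisy <- render_trace(path, trace_config(noise_sd_bp = 30, seed = 7))
  resid <- noisy$position_bp - truth
  expect_equal(sd(resid), 30, tolerance = 1 / 30)  # 30 +/- 1 bp
  expect_lt(abs(mean(resid)), 1.5)
  # determinism: identical seed, identical trace
  noisy2 <- render_trace(path, trace_config(noise_sd_bp = 30, seed = 7))
  expect_identical(noisy$position_bp, noisy2$position_bp)
})

test_that("chase survival is exponential with the packaged dissociation rate", {
  wt <- make_default_params("wildtype")   # t1/2 = 3 min
  # noiseless, large-n: fraction at one half-life is 1/2
  s <- simulate_chase(wt, c(0, 3), n_molecules = 2e5, seed = 31)
  expect_equal(s$fragment_fraction[1], 1)
  expect_equal(s$fragment_fraction[2], 0.5, tolerance = 0.02)
  # k_off = 0 never decays
  frozen <- enzyme_params("frozen", v_pre = 300, k_off_chi = 0)
  s0 <- simulate_chase(frozen, c(0, 10, 100), 100, seed = 32)
  expect_true(all(s0$fragment_fraction == 1))
  # binomial sampling error at n = 500
  s5 <- simulate_chase(wt, c(0, 3), 500, seed = 33)
  expect_lt(abs(s5$fragment_fraction[2] - 0.5), 3 * sqrt(0.25 / 500))
  # per-molecule dissociation times agree with the exponential law (KS)
  s1k <- simulate_chase(wt, c(0, 3), 1000, seed = 34)
  ks <- suppressWarnings(
    ks.test(s1k$dissociation_times_min, pexp, rate = wt$k_off_chi))
  expect_gt(ks$p.value, 0.01)
  expect_error(simulate_chase(wt, c(0, 3), 0), "positive")
})

test_that("triplex transients encode arrival plus an exponential displacement step", {
  # Chi-free, no switching: single phase, half-rise at L/v + ln2/r
  p <- free_runner(1000)
  sub <- substrate_spec(4500, triplex_pos = 3000)
  r <- 10
  cv <- simulate_triplex_curve(p, sub, 3000, displacement_rate = r,
                               seed = 41)
  t_half <- cv$time_s[which(cv$signal >= 0.5)[1]]
  expect_equal(t_half, 3000 / 1000 + log(2) / r, tolerance = 0.05)
  # endpoint normalization
  expect_equal(cv$signal[length(cv$signal)], 1)
  expect_true(all(diff(cv$signal) >= 0))

  # guaranteed commitment at a single Chi: the whole population is delayed
  pc <- fixed_pauser(0.2, v = 1000)
  sub1 <- substrate_spec(4500, chi_positions = 1000, triplex_pos = 3000)
  cv1 <- simulate_triplex_curve(pc, sub1, 1000, displacement_rate = 50,
                                seed = 42)
  # no early phase: nothing displaced at the unconverted arrival time
  expect_lt(amplitude_at_time(cv1, 3000 / 1000 + 0.1), 0.02)

  # three Chi sites, per-site commitment c: early fraction is (1-c)^3
  c_per <- 0.3
  p3 <- enzyme_params("e", v_pre = 1000, v_post = 100, p_pause = c_per,
                      pause_shape = 2, pause_scale = 0.05, p_commit = 1)
  sub3 <- substrate_spec(4500, chi_positions = c(1000, 1030, 1060),
                         triplex_pos = 3000)
  cv3 <- simulate_triplex_curve(p3, sub3, 2000, displacement_rate = 50,
                                seed = 43)
  # converted molecules crawl at 100 bp/s, arriving far later than 3 s;
  # the plateau at 6 s reads out the unconverted fraction
  early <- amplitude_at_time(cv3, 6)
  expected <- (1 - c_per)^3
  se <- sqrt(expected * (1 - expected) / 2000)
  expect_lt(abs(early - expected), 3.5 * se)
  expect_error(simulate_triplex_curve(p3, substrate_spec(1000), 10),
               "triplex")
})

test_that("Chi-fragment yield equals the commitment probability chain", {
  sub <- one_chi_substrate(5000, 2500)
  none <- enzyme_params("e", v_pre = 300, p_pause = 0)
  expect_equal(simulate_chi_yield(none, sub, 200, seed = 51), 0)
  all_in <- fixed_pauser(0.5)
  expect_equal(simulate_chi_yield(all_in, sub, 200, seed = 52), 1)
  # doubling per-encounter commitment doubles the yield
  a <- enzyme_params("a", v_pre = 300, p_pause = 0.2, pause_shape = 2,
                     pause_scale = 0.1, p_commit = 0.3)
  b <- enzyme_params("b", v_pre = 300, p_pause = 0.2, pause_shape = 2,
                     pause_scale = 0.1, p_commit = 0.6)
  ya <- simulate_chi_yield(a, sub, 5000, seed = 53)
  yb <- simulate_chi_yield(b, sub, 5000, seed = 54)
  se_ratio <- 2 * sqrt((1 - 0.06) / (0.06 * 5000) +
                       (1 - 0.12) / (0.12 * 5000))
  expect_lt(abs(yb / ya - 2), 3.5 * se_ratio)
})

test_that("identical seeds reproduce every simulated object exactly", {
  p <- make_default_params("wildtype")
  s <- default_substrate("tweezers")
  t1 <- simulate_trace(p, s, seed = 99)
  t2 <- simulate_trace(p, s, seed = 99)
  expect_identical(t1$position_bp, t2$position_bp)
  c1 <- simulate_chase(p, 0:5, 200, noise_cv = 0.05, seed = 99)
  c2 <- simulate_chase(p, 0:5, 200, noise_cv = 0.05, seed = 99)
  expect_identical(c1$fragment_fraction, c2$fragment_fraction)
  p37 <- make_default_params("wildtype_37C")
  s3 <- default_substrate("triplex_3chi")
  v1 <- simulate_triplex_curve(p37, s3, 300, seed = 99)
  v2 <- simulate_triplex_curve(p37, s3, 300, seed = 99)
  expect_identical(v1$signal, v2$signal)
})
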