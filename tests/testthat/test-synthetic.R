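test_that("vertex sampling matches its generative recipe", {
  expect_error(sample_vertices(list()), "empty ROI spec")

  one <- sample_vertices("MT", 1, seed = 1)
  expect_equal(nrow(one), 1L)
  expect_true(one$ecc >= 0 && one$ecc <= 10 && one$ve >= 0 && one$ve <= 1)

  # seeded determinism
  a <- sample_vertices("V1", 200, seed = 7)
  b <- sample_vertices("V1", 200, seed = 7)
  expect_identical(a, b)

  # KS test of eccentricities against the truncated-gamma target
  spec <- roi_presets()$MT
  pop <- sample_vertices("MT", 1000, seed = 2)
  trunc_cdf <- function(q) {
    pgamma(pmin(q, 10), shape = spec$ecc_shape, scale = spec$ecc_scale) /
      pgamma(10, shape = spec$ecc_shape, scale = spec$ecc_scale)
  }
  ks <- suppressWarnings(ks.test(pop$ecc, trunc_cdf))
  expect_gt(ks$p.value, 0.01)

  # polar angles uniform: HM wedge occupies a third of the circle
  popu <- sample_vertices("V1", 20000, seed = 3)
  hm_frac <- mean(stereomotion:::polar_is_hm(popu$polar, 30))
  expect_lt(abs(hm_frac - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / 20000))

  # HM over-representation shifts mass into the wedge
  spec_hm <- spec; spec_hm$hm_factor <- 2; spec_hm$name <- "MT"
  pop_hm <- sample_vertices(spec_hm, 20000, seed = 4)
  expect_gt(mean(stereomotion:::polar_is_hm(pop_hm$polar, 30)), 0.5)
})

test_that("percepts follow observer group and stimulus rotation", {
  pro <- observer(1, "stereo_pro")
  strug <- observer(2, "stereo_struggler")

  expect_equal(perceived_direction(pro, "stereoscopic", "toward", FALSE),
               "toward")
  expect_equal(perceived_direction(pro, "perspectiveL", "away", FALSE),
               "away")
  # rotation abolishes the stereoscopic percept for any observer
  expect_equal(perceived_direction(pro, "stereoscopic", "toward", TRUE),
               "none")
  expect_equal(perceived_direction(strug, "stereoscopic", "away", TRUE),
               "none")
  # perspective cues survive rotation
  expect_equal(perceived_direction(strug, "perspectiveR", "toward", TRUE),
               "toward")

  # struggler's unrotated stereoscopic percepts are a fair coin
  set.seed(5)
  p <- perceived_direction(strug, rep("stereoscopic", 1e4),
                           rep("toward", 1e4), FALSE)
  expect_lt(abs(mean(p == "toward") - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("the vertex encoding equation decomposes term by term", {
  sched <- manual_schedule(rep(c("combined", "stereoscopic"), each = 10),
                           rep(c("toward", "away"), 10),
                           percept = rep(c("toward", "away"), 10))

  # all coefficients zero except beta0 -> amplitude = beta0
  pop0 <- manual_population(ecc = 1:4, polar = c(0, 50, 120, 170),
                            beta0 = 0.7)
  expect_equal(unique(as.vector(trial_amplitudes(pop0, sched))), 0.7)

  # percept-tuned vertex on a rotated stereoscopic trial: direction term 0
  popp <- manual_population(ecc = 2, polar = 0, regime = "percept_3d",
                            s_v = 0.9, beta0 = 0.1)
  rot <- manual_schedule("stereoscopic", c("toward", "away"), rotated = TRUE,
                         percept = "none")
  expect_equal(as.vector(trial_amplitudes(popp, rot)), c(0.1, 0.1))
  # retinal-tuned vertex keeps its drive under rotation
  popr <- manual_population(ecc = 2, polar = 0, regime = "retinal_2d",
                            s_v = 0.9, beta0 = 0.1)
  expect_equal(as.vector(trial_amplitudes(popr, rot)), c(1.0, -0.8))

  # injected g_rad appears as the HM - NHM mean difference
  set.seed(6)
  pop_rad <- manual_population(ecc = runif(1e4, 0.5, 8),
                               polar = runif(1e4, -180, 180), g_rad = 0.15)
  amp <- trial_amplitudes(pop_rad, manual_schedule("combined", "toward",
                                                   percept = "toward"))
  hm <- stereomotion:::polar_is_hm(pop_rad$polar, 30)
  expect_equal(mean(amp[, hm]) - mean(amp[, !hm]), 0.15, tolerance = 1e-9)

  # brute-force oracle: full equation evaluated element-wise
  set.seed(7)
  pop_full <- manual_population(ecc = runif(6, 0.5, 9),
                                polar = runif(6, -180, 180),
                                regime = sample(c("retinal_2d", "percept_3d"),
                                                6, replace = TRUE),
                                s_v = rnorm(6), g_ecc = 0.05, g_rad = 0.2,
                                g_int = 0.03, beta0 = 0.4)
  sched2 <- manual_schedule(rep(c("stereoscopic", "combined"), 3),
                            rep(c("toward", "away"), each = 3),
                            percept = c("toward", "none", "away",
                                        "away", "toward", "away"))
  got <- trial_amplitudes(pop_full, sched2)
  ecc_ref <- mean(pop_full$ecc)
  for (t in 1:6) {
    for (v in 1:6) {
      hm_v <- min(abs(pop_full$polar[v]), abs(180 - abs(pop_full$polar[v]))) <= 30
      d_eff <- if (pop_full$regime[v] == "retinal_2d") {
        if (sched2$direction[t] == "toward") 1 else -1
      } else {
        switch(sched2$percept[t], toward = 1, away = -1, none = 0)
      }
      want <- 0.4 + 0.05 * (pop_full$ecc[v] - ecc_ref) + 0.2 * hm_v +
        d_eff * (pop_full$s_v[v] + 0.03 * (pop_full$ecc[v] - ecc_ref))
      expect_equal(got[t, v], want, tolerance = 1e-12)
    }
  }
})

test_that("simulated runs convolve amplitudes with the canonical HRF", {
  # single unit-amplitude trial, no noise: the series is the sampled HRF
  pop <- manual_population(ecc = 2, polar = 0, s_v = 1, beta0 = 0)
  sched <- manual_schedule("stereoscopic", "toward", percept = "toward",
                           onset = 20)
  sched2 <- rbind(sched, sched)       # simulate_run needs >= 1 trial; use 2
  sched2$trial <- 1:2; sched2$onset <- c(20, 200)
  attr(sched2, "tr") <- 1; attr(sched2, "run_trs") <- 360
  run <- simulate_run(pop, sched2, noise = quiet_noise(), seed = 8)
  hrf <- hrf_double_gamma()
  expect_equal(nrow(run$signal), 360)
  expect_equal(run$signal[21:53, 1], hrf, tolerance = 1e-12)
  # peak lands ~5 s after onset
  expect_equal(which.max(run$signal[21:40, 1]) - 1, 5)

  # pure AR(1) noise: empirical lag-1 autocorrelation matches the coefficient
  pop0 <- manual_population(ecc = rep(2, 40), polar = 0, beta0 = 0)
  noise_ar <- noise_params(white_sd = 1, ar1 = 0.3, drift_lin = 0,
                           drift_sin = 0, motion_sd = 0, global_sd = 0)
  run2 <- simulate_run(pop0, sched2, noise = noise_ar, seed = 9)
  ac1 <- mean(apply(run2$signal, 2, function(x)
    acf(x, lag.max = 1, plot = FALSE)$acf[2]))
  expect_lt(abs(ac1 - 0.3), 0.03)

  # a full 40-trial schedule yields exactly 360 rows and 7 nuisance channels
  full <- make_trial_schedule(n_runs = 1, seed = 10)
  full <- simulate_percepts(full, observer(1, "stereo_pro"), seed = 11)
  run3 <- simulate_run(sample_vertices("MT", 10, seed = 12), full, seed = 13)
  expect_equal(dim(run3$signal), c(360L, 10L))
  expect_equal(colnames(run3$nuisance),
               c(paste0("motion", 1:6), "global"))

  # onset beyond the run end is a schedule error
  bad <- manual_schedule("combined", c("toward", "away"),
                         percept = c("toward", "away"), onset = c(0, 400))
  expect_error(simulate_run(pop, bad, seed = 1), "beyond run end")

  # seeded determinism end-to-end
  r1 <- simulate_run(pop0, sched2, seed = 14)
  r2 <- simulate_run(pop0, sched2, seed = 14)
  expect_identical(r1$signal, r2$signal)
  expect_identical(r1$nuisance, r2$nuisance)
})

test_that("behavioral reports apply lapses to percepts", {
  pro <- observer(1, "stereo_pro", lapse = 0)
  strug <- observer(2, "stereo_struggler", lapse = 0)

  sched <- manual_schedule(rep("perspectiveL", 10), "toward",
                           percept = "toward")
  expect_equal(simulate_behavioral_report(pro, sched, seed = 1),
               rep("toward", 10))

  # struggler at chance on stereoscopic trials: percepts are guesses
  n <- 1e4
  big <- manual_schedule(rep("stereoscopic", n),
                         rep(c("toward", "away"), n / 2))
  big <- simulate_percepts(big, strug, seed = 2)
  rep_ <- simulate_behavioral_report(strug, big, seed = 3)
  acc <- mean(rep_ == big$direction)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n))

  # lapse = 0.1 on veridical percepts: accuracy ~ 90%
  lapser <- observer(3, "stereo_pro", lapse = 0.1)
  bigp <- manual_schedule(rep("perspectiveR", n),
                          rep(c("toward", "away"), n / 2))
  bigp <- simulate_percepts(bigp, lapser, seed = 4)
  accp <- mean(simulate_behavioral_report(lapser, bigp, seed = 5) ==
                 bigp$direction)
  expect_lt(abs(accp - 0.9), 4 * sqrt(0.09 / n))
})

test_that("single-trial extraction recovers the eccentricity gradient", {
  # parameter recovery: regress extracted amplitudes on eccentricity;
  # slope within 15% of the injected g_ecc at SNR >= 1
  set.seed(15)
  g_ecc <- 0.1
  pop <- manual_population(ecc = runif(2000, 0.5, 9),
                           polar = runif(2000, -180, 180),
                           g_ecc = g_ecc, beta0 = 0.3)
  obs <- observer(1, "stereo_pro")
  noise <- noise_params(white_sd = 0.3, ar1 = 0.2, drift_lin = 0,
                        drift_sin = 0, motion_sd = 0.01, global_sd = 0.05)
  sched <- make_trial_schedule(n_runs = 2, seed = 16)
  sched <- simulate_percepts(sched, obs, seed = 17)
  amps <- lapply(1:2, function(r) {
    sub <- sched[sched$run == r, ]
    attr(sub, "tr") <- 1; attr(sub, "run_trs") <- 360
    run <- simulate_run(pop, sub, noise = noise, seed = 18 + r)
    # BOLD-amplitude path: keep per-vertex scale (no z-normalization) and
    # skip global-signal regression, which would absorb the spatially
    # coherent amplitude gradient itself
    x <- highpass(run$signal)
    x <- nuisance_regress(x, run$nuisance[, 1:6])
    extract_amplitudes(x, run$onsets)
  })
  vertex_mean <- colMeans(do.call(rbind, amps))
  slope <- unname(coef(lm(vertex_mean ~ pop$ecc))[2])
  # independent gain oracle: steady-state window average of the HRF,
  # including overlap from trials 9 s apart, minus the DC removed by the
  # high-pass filter (the trial train is periodic at 1/9 Hz)
  hrf <- hrf_double_gamma()
  gain <- sum(sapply(0:3, function(k) {
    idx <- (6:9) + 9 * k
    sum(hrf[idx[idx <= length(hrf)]]) / 4
  })) - sum(hrf) / 9
  expect_lt(abs(slope / gain - g_ecc) / g_ecc, 0.15)
})
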