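test_that("dot fields are drawn uniformly over the annulus", {
  f <- make_dot_field(80, seed = 1)
  ecc <- sqrt(f$azimuth^2 + f$elevation^2)
  expect_equal(f$n_dots, 80L)
  expect_true(all(ecc >= 0.25 & ecc <= 8))
  expect_equal(sort(unique(f$polarity)), c("black", "white"))
  expect_true(all(f$left_diameter == 0.16))

  empty <- make_dot_field(0)
  expect_equal(empty$n_dots, 0L)
  expect_s3_class(empty, "dot_field")
  expect_error(make_dot_field(-1), "non-negative")

  # Monte-Carlo uniformity: split the annulus into two equal-area bins at
  # r_mid = sqrt((r_in^2 + r_out^2) / 2); counts should agree within 3
  # binomial SDs
  big <- make_dot_field(1e5, seed = 2)
  r_mid <- sqrt((0.25^2 + 8^2) / 2)
  n_inner <- sum(sqrt(big$azimuth^2 + big$elevation^2) < r_mid)
  expect_lt(abs(n_inner - 5e4), 3 * sqrt(1e5 * 0.25))
})

test_that("stereoscopic advance displaces the monocular images oppositely", {
  f <- make_dot_field(10, seed = 3)
  g <- advance_stereoscopic(f, "toward", dt = 1)
  moved <- !g$reseeded
  expect_true(any(moved))
  expect_equal(g$left_azimuth[moved] - f$left_azimuth[moved],
               rep(1.2, sum(moved)))
  expect_equal(g$right_azimuth[moved] - f$right_azimuth[moved],
               rep(-1.2, sum(moved)))
  d0 <- disparity(f$left_azimuth, f$right_azimuth)
  d1 <- disparity(g$left_azimuth, g$right_azimuth)
  expect_equal(d1[moved] - d0[moved], rep(-2.4, sum(moved)))
  # elevation and size unchanged
  expect_identical(g$left_elevation[moved], f$left_elevation[moved])
  expect_identical(g$left_diameter, f$left_diameter)

  # dt = 0 is the identity
  expect_equal(advance_stereoscopic(f, "toward", 0)[c("left_azimuth",
                                                      "right_azimuth")],
               f[c("left_azimuth", "right_azimuth")])

  # toward then away over equal dt restores the field (no reseed at small dt)
  h <- advance_stereoscopic(advance_stereoscopic(f, "toward", 1 / 120),
                            "away", 1 / 120)
  expect_false(any(h$reseeded))
  expect_equal(h$left_azimuth, f$left_azimuth, tolerance = 1e-12)
  expect_equal(h$right_azimuth, f$right_azimuth, tolerance = 1e-12)
})

test_that("perspective advance follows projective geometry", {
  f <- make_dot_field(20, seed = 4)
  # at the fixation plane the angular diameter is the nominal 0.16 deg
  expect_equal(unique(f$left_diameter), 0.16)

  # toward motion: angular diameter strictly increases frame over frame
  tr <- generate_trial("perspectiveL", "toward", n_frames = 30, n_dots = 20,
                       seed = 5)
  reseeded <- Reduce(`|`, lapply(tr$frames, function(fr) fr$reseeded))
  keep <- which(!reseeded)
  diam <- sapply(tr$frames, function(fr) fr$left_diameter[keep])
  expect_true(all(apply(diam, 1, function(d) all(diff(d) > 0))))
  # the unstimulated eye carries an empty frame
  expect_false(tr$frames[[1]]$eye_present[["right"]])
  expect_true(all(is.na(tr$frames[[1]]$right_azimuth)))

  # halving z (880 -> 440 mm) scales the angular diameter by the
  # tan-projection ratio; independent projection oracle (~2x in the
  # small-angle limit)
  geom <- viewing_geometry()
  phys <- 2 * geom$viewing_distance * tan(0.08 * pi / 180)
  oracle_diam <- function(z) 2 * atan(phys / (2 * z)) * 180 / pi
  f2 <- make_dot_field(1, seed = 6)
  f2$x <- tan(2 * pi / 180) * 880; f2$y <- 0; f2$z <- 880
  f2 <- advance_perspective(f2, "toward", dt = 440 / 51.83, eye = "left")
  expect_false(f2$reseeded[1])
  expect_equal(f2$z[1], 440)
  expect_equal(f2$left_diameter[1], oracle_diam(440), tolerance = 1e-12)
  expect_equal(f2$left_diameter[1] / 0.16, oracle_diam(440) / oracle_diam(880),
               tolerance = 1e-9)
  expect_equal(oracle_diam(440) / oracle_diam(880), 2, tolerance = 1e-3)
})

test_that("disparity follows the right-minus-left convention", {
  expect_equal(disparity(0.5, -0.5), -1)
  expect_equal(disparity(0.3, 0.3), 0)
  expect_error(disparity(NA, 1))
})

test_that("fitted disparity rate matches twice the per-eye speed", {
  for (dir in c("toward", "away")) {
    tr <- generate_trial("stereoscopic", dir, seed = 8)
    slope <- fit_disparity_rate(tr)
    expect_equal(abs(slope), 2.4, tolerance = 1e-6)
    expect_equal(sign(slope), if (dir == "toward") -1 else 1)
  }
})

test_that("90-degree rotation preserves per-frame monocular speeds exactly", {
  tr <- generate_trial("stereoscopic", "toward", n_frames = 40, seed = 9)
  rot <- lapply(tr$frames, rotate_retinal, angle = 90)

  speed_of <- function(frames, eye) {
    az <- sapply(frames, function(f) f[[paste0(eye, "_azimuth")]])
    el <- sapply(frames, function(f) f[[paste0(eye, "_elevation")]])
    sqrt(diff(t(az))^2 + diff(t(el))^2)
  }
  for (eye in c("left", "right"))
    expect_identical(speed_of(tr$frames, eye), speed_of(rot, eye))

  # a leftward-moving left-eye image becomes downward-moving after +90 ccw
  f <- make_dot_field(5, seed = 10)
  g <- advance_stereoscopic(f, "away", 1 / 120)   # away: left eye moves left
  dfr <- rotate_retinal(f); dgr <- rotate_retinal(g)
  expect_true(all(dgr$left_elevation - dfr$left_elevation < 0))
  expect_equal(dgr$left_azimuth, dfr$left_azimuth)

  # rotated stereoscopic: the two eyes carry vertically opposite motion
  expect_true(all((dgr$left_elevation - dfr$left_elevation) *
                    (dgr$right_elevation - dfr$right_elevation) < 0))

  expect_identical(rotate_retinal(f, 0), f)
  expect_error(rotate_retinal(f, 45), "multiple of 90")
})

test_that("combined condition matches the two-eye projection oracle", {
  # disparity rate for a midline dot at small dt converges to I*v/z^2 (rad/s)
  geom <- viewing_geometry()
  pop_f <- make_dot_field(1, seed = 11)
  pop_f$x <- 0; pop_f$y <- tan(3 * pi / 180) * 880; pop_f$z <- 880
  f0 <- stereomotion:::apply_projection(pop_f, c("left", "right"))
  dt <- 1 / 1200
  f1 <- advance_combined(f0, "toward", dt)
  rate <- (disparity(f1$left_azimuth, f1$right_azimuth) -
             disparity(f0$left_azimuth, f0$right_azimuth)) / dt
  oracle <- -(geom$interocular_distance * 51.83 / 880^2) * 180 / pi
  expect_equal(rate, oracle, tolerance = 5e-3)

  # brute-force two-eye projection oracle on a generic dot
  f <- make_dot_field(6, seed = 12)
  f <- stereomotion:::apply_projection(f, c("left", "right"))
  g <- advance_combined(f, "away", 1 / 120)
  i <- which(!g$reseeded)[1]
  z_expect <- 880 + 51.83 / 120
  expect_equal(g$z[i], z_expect)
  expect_equal(g$left_azimuth[i],
               atan((f$x[i] + geom$interocular_distance / 2) / z_expect) *
                 180 / pi, tolerance = 1e-12)
  expect_equal(g$right_azimuth[i],
               atan((f$x[i] - geom$interocular_distance / 2) / z_expect) *
                 180 / pi, tolerance = 1e-12)
})

test_that("retinal positions stay inside the aperture after re-seeding", {
  set.seed(13)
  f <- make_dot_field(50)
  for (i in 1:200) {
    f <- advance_stereoscopic(f, sample(c("toward", "away"), 1), 1 / 20)
    ecc <- sqrt(f$azimuth^2 + f$elevation^2)
    expect_true(all(ecc >= 0.25 - 1e-9 & ecc <= 8 + 1e-9))
  }
  g <- make_dot_field(50)
  for (i in 1:200) {
    g <- advance_combined(g, "toward", 1 / 20)
    ecc <- atan(sqrt(g$x^2 + g$y^2) / g$z) * 180 / pi
    expect_true(all(ecc >= 0.25 - 1e-9 & ecc <= 8 + 1e-9))
  }
})

test_that("frame tables have the documented schema and round-trip via TSV", {
  tr <- generate_trial("stereoscopic", "toward", seed = 14)
  tab <- frame_table(tr)
  expect_equal(nrow(tab), 120 * 80 * 2)
  expect_named(tab, c("frame", "dot", "eye", "azimuth_deg", "elevation_deg",
                      "diameter_deg", "polarity"))

  # single-eye condition only emits the presented eye
  trL <- generate_trial("perspectiveL", "away", n_frames = 10, n_dots = 8,
                        seed = 15)
  expect_equal(unique(frame_table(trL)$eye), "left")

  expect_equal(nrow(frame_table(list())), 0)

  f1 <- make_dot_field(5, seed = 16)
  f2 <- make_dot_field(6, seed = 17)
  expect_error(frame_table(list(f1, f2)), "mixed dot counts")

  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path), add = TRUE)
  write_frame_table(tab, path)
  back <- read_frame_table(path)
  expect_identical(back$azimuth_deg, tab$azimuth_deg)
  expect_identical(back$elevation_deg, tab$elevation_deg)
  expect_identical(back$diameter_deg, tab$diameter_deg)
  expect_identical(back$polarity, tab$polarity)
})
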