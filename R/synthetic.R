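#' ROI presets for the synthetic vertex generator
#'
#' Each preset describes one region of interest of the motion pathway as a
#' generative recipe: an eccentricity distribution (gamma, truncated to
#' 0-10 deg), a variance-explained distribution (beta), a tuning regime and
#' the coefficients of the vertex encoding equation. The regimes encode the
#' central functional contrast: `retinal_2d` vertices respond to coherent
#' retinal motion whether or not a 3D percept exists (V1, MT, MST), while
#' `percept_3d` vertices respond to the perceived motion-in-depth direction
#' and fall silent when the percept is abolished (FST). Coefficient signs are
#' chosen to reproduce the qualitative bias pattern across ROIs (strong
#' eccentricity gradient in V1, horizontal-meridian BOLD bias in MST,
#' horizontal-meridian decodability bias in MT, flat biases in FST), not any
#' particular empirical magnitudes.
#'
#' @return named list of preset lists
#' @export
roi_presets <- function() {
  list(
    V1 = list(n_default = 400L, ecc_shape = 2.0, ecc_scale = 1.5,
              hm_factor = 1, ve_shape1 = 2, ve_shape2 = 6,
              regime = "retinal_2d", g_ecc = 0.06, g_rad = 0.05, g_int = 0,
              s_sd = 0.05, s_hm_gain = 0.5, beta0 = 0.30),
    MT = list(n_default = 120L, ecc_shape = 2.5, ecc_scale = 1.6,
              hm_factor = 1, ve_shape1 = 2, ve_shape2 = 6,
              regime = "retinal_2d", g_ecc = 0.03, g_rad = 0.0, g_int = 0,
              s_sd = 0.05, s_hm_gain = 1.5, beta0 = 0.40),
    MST = list(n_default = 120L, ecc_shape = 3.0, ecc_scale = 1.7,
               hm_factor = 1, ve_shape1 = 2, ve_shape2 = 6,
               regime = "retinal_2d", g_ecc = 0.03, g_rad = 0.15, g_int = 0,
               s_sd = 0.05, s_hm_gain = 0.5, beta0 = 0.45),
    FST = list(n_default = 120L, ecc_shape = 2.0, ecc_scale = 2.5,
               hm_factor = 1, ve_shape1 = 1.5, ve_shape2 = 8,
               regime = "percept_3d", g_ecc = 0, g_rad = 0, g_int = 0,
               s_sd = 0.09, s_hm_gain = 0, beta0 = 0.30)
  )
}

#' Sample a synthetic vertex population
#'
#' Draws a population of cortical surface vertices with pRF structure
#' (eccentricity, polar angle, variance explained) and per-vertex encoding
#' coefficients. Polar angles are uniform over (-180, 180] unless
#' `hm_factor > 1`, which over-represents the horizontal meridian by mixing in
#' extra mass within the +/-30 degree wedge. The direction sensitivity `s_v`
#' is zero-mean across vertices (individual vertices prefer toward or away);
#' for ROIs with `s_hm_gain > 0` its magnitude is amplified near the
#' horizontal meridian, the generative mechanism of a radial decodability
#' bias.
#'
#' @param roi_spec a preset name from [roi_presets()] or a list with the same
#'   fields
#' @param n_vertices number of vertices (default: the preset's `n_default`)
#' @param seed optional RNG seed
#' @param hm_half_width wedge half-width defining "near the horizontal
#'   meridian", deg
#' @return a data.frame of class `vertex_population` with columns `roi`,
#'   `ecc`, `polar`, `ve`, `regime`, `s_v`, `g_ecc`, `g_rad`, `g_int`,
#'   `beta0`; attribute `ecc_ref` holds the population mean eccentricity used
#'   to center the eccentricity terms
#' @export
sample_vertices <- function(roi_spec, n_vertices = NULL, seed = NULL,
                            hm_half_width = 30) {
  if (is.character(roi_spec)) {
    presets <- roi_presets()
    if (!roi_spec %in% names(presets))
      stop("unknown ROI preset: ", roi_spec)
    nm <- roi_spec
    roi_spec <- presets[[roi_spec]]
    roi_spec$name <- nm
  }
  if (is.null(roi_spec) || length(roi_spec) == 0)
    stop("empty ROI spec")
  n <- as.integer(n_vertices %||% roi_spec$n_default)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  # truncated gamma via resampling
  ecc <- stats::rgamma(n, shape = roi_spec$ecc_shape, scale = roi_spec$ecc_scale)
  bad <- ecc > 10
  while (any(bad)) {
    ecc[bad] <- stats::rgamma(sum(bad), shape = roi_spec$ecc_shape,
                              scale = roi_spec$ecc_scale)
    bad <- ecc > 10
  }
  hm_factor <- roi_spec$hm_factor %||% 1
  polar <- stats::runif(n, -180, 180)
  if (hm_factor > 1) {
    # probability that a vertex is forced into the HM wedge beyond its
    # uniform share: wedge occupies 4*half_width/360 of the circle
    p_wedge <- 4 * hm_half_width / 360
    extra <- stats::runif(n) < (hm_factor - 1) * p_wedge
    side <- sample(c(0, 180), sum(extra), replace = TRUE)
    polar[extra] <- side + stats::runif(sum(extra), -hm_half_width, hm_half_width)
  }
  polar <- ((polar + 180) %% 360) - 180
  polar[polar == -180] <- 180
  ve <- stats::rbeta(n, roi_spec$ve_shape1, roi_spec$ve_shape2)
  is_hm <- polar_is_hm(polar, hm_half_width)
  s_v <- (1 + (roi_spec$s_hm_gain %||% 0) * is_hm) *
    stats::rnorm(n, 0, roi_spec$s_sd)
  pop <- data.frame(
    roi = roi_spec$name %||% "ROI",
    ecc = ecc, polar = polar, ve = ve,
    regime = roi_spec$regime,
    s_v = s_v,
    g_ecc = roi_spec$g_ecc, g_rad = roi_spec$g_rad, g_int = roi_spec$g_int,
    beta0 = roi_spec$beta0,
    stringsAsFactors = FALSE
  )
  attr(pop, "ecc_ref") <- mean(ecc)
  attr(pop, "hm_half_width") <- hm_half_width
  class(pop) <- c("vertex_population", "data.frame")
  pop
}

# is a polar angle within half_width degrees of either horizontal meridian?
polar_is_hm <- function(polar, half_width = 30) {
  d <- pmin(abs(polar), abs(180 - abs(polar)))
  d <= half_width
}

#' Observer descriptor
#'
#' Observers split into stereo-pros, who perceive motion-in-depth from
#' stereoscopic cues, and stereo-strugglers, whose stereoscopic-cue percepts
#' are uninformative (guesses) despite intact perspective-cue perception.
#' The lapse rate flips overt reports, not percepts.
#'
#' @param id observer identifier
#' @param group `"stereo_pro"` or `"stereo_struggler"`
#' @param lapse probability of a report lapse, in `[0, 0.5]`
#' @return an object of class `observer`
#' @export
observer <- function(id, group = c("stereo_pro", "stereo_struggler"),
                     lapse = 0.02) {
  group <- match.arg(group)
  stopifnot(lapse >= 0, lapse <= 0.5)
  structure(list(id = id, group = group, lapse = lapse), class = "observer")
}

#' Build a trial schedule
#'
#' Eight motion types (4 cue conditions x 2 directions) each repeated
#' `n_reps` times per run, in randomized order, with 1 s trials followed by
#' 8 s offsets (9 s onset spacing) at TR = 1 s, filling a 360-volume run.
#'
#' @param n_runs number of runs (default 10)
#' @param n_reps repeats per motion type per run (default 5)
#' @param rotated logical: schedule for the rotated-control session
#' @param trial_duration trial length, s
#' @param offset inter-trial offset, s
#' @param tr repetition time, s
#' @param run_trs volumes per run
#' @param seed optional RNG seed for trial-order randomization
#' @return data.frame of class `trial_schedule` with columns `run`, `trial`,
#'   `onset` (s, 0-based), `condition`, `direction`, `rotated`
#' @export
make_trial_schedule <- function(n_runs = 10, n_reps = 5, rotated = FALSE,
                                trial_duration = 1, offset = 8, tr = 1,
                                run_trs = 360, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conditions <- c("stereoscopic", "perspectiveL", "perspectiveR", "combined")
  types <- expand.grid(condition = conditions,
                       direction = c("toward", "away"),
                       stringsAsFactors = FALSE)
  spacing <- trial_duration + offset
  n_trials <- nrow(types) * n_reps
  if ((n_trials - 1) * spacing + trial_duration > run_trs * tr)
    stop("schedule does not fit in the run")
  runs <- lapply(seq_len(n_runs), function(r) {
    idx <- sample(rep(seq_len(nrow(types)), n_reps))
    data.frame(run = r, trial = seq_len(n_trials),
               onset = (seq_len(n_trials) - 1) * spacing,
               condition = types$condition[idx],
               direction = types$direction[idx],
               rotated = rotated, stringsAsFactors = FALSE)
  })
  sched <- do.call(rbind, runs)
  attr(sched, "tr") <- tr
  attr(sched, "run_trs") <- run_trs
  attr(sched, "trial_duration") <- trial_duration
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

#' Perceived motion-in-depth direction on each trial
#'
#' Perspective and combined cues give veridical percepts for every observer.
#' Unrotated stereoscopic trials are veridical for stereo-pros and an
#' uninformative coin flip for stereo-strugglers. Rotated stereoscopic trials
#' yield no motion-in-depth percept (`"none"`) for any observer: the rotation
#' turns the stimulus into transparent 2D motion. Lapses are applied at the
#' report stage, not here.
#'
#' @param obs an [observer()]
#' @param condition character vector of cue conditions
#' @param direction character vector of true directions
#' @param rotated logical vector
#' @return character vector: `"toward"`, `"away"` or `"none"`
#' @export
perceived_direction <- function(obs, condition, direction, rotated = FALSE) {
  n <- max(length(condition), length(direction), length(rotated))
  condition <- rep_len(condition, n)
  direction <- rep_len(direction, n)
  rotated <- rep_len(rotated, n)
  percept <- direction
  stereo <- condition == "stereoscopic"
  percept[stereo & rotated] <- "none"
  if (obs$group == "stereo_struggler") {
    guess <- stereo & !rotated
    percept[guess] <- sample(c("toward", "away"), sum(guess), replace = TRUE)
  }
  percept
}

#' Attach percepts to a schedule
#'
#' @param sched a [make_trial_schedule()] result
#' @param obs an [observer()]
#' @param seed optional RNG seed (drives the struggler's stereoscopic guesses)
#' @return the schedule with a `percept` column
#' @export
simulate_percepts <- function(sched, obs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sched$percept <- perceived_direction(obs, sched$condition, sched$direction,
                                       sched$rotated)
  sched
}

#' Per-trial response amplitude of each vertex
#'
#' The vertex encoding equation. For vertex v on trial t,
#' `A = beta0 + g_ecc * (ecc - ecc_ref) + g_rad * hm + d_eff * (s_v + g_int * (ecc - ecc_ref))`
#' where `hm` indicates a pRF within the horizontal-meridian wedge and
#' `d_eff` is the effective direction drive: for `retinal_2d` vertices it is
#' +/-1 by the true stimulus direction on every trial (coherent retinal
#' motion distinguishes the two labels in all conditions, including the
#' rotated stereoscopic control); for `percept_3d` vertices it follows the
#' percept (+1 toward, -1 away, 0 when there is no motion-in-depth percept).
#'
#' @param pop a [sample_vertices()] population
#' @param sched a schedule with a `percept` column (see [simulate_percepts()])
#' @return numeric matrix, trials x vertices
#' @export
trial_amplitudes <- function(pop, sched) {
  if (is.null(sched$percept))
    stop("schedule lacks a `percept` column; run simulate_percepts() first")
  ecc_ref <- attr(pop, "ecc_ref") %||% mean(pop$ecc)
  hw <- attr(pop, "hm_half_width") %||% 30
  hm <- polar_is_hm(pop$polar, hw)
  dir_sign <- ifelse(sched$direction == "toward", 1, -1)
  percept_sign <- ifelse(sched$percept == "toward", 1,
                         ifelse(sched$percept == "away", -1, 0))
  # trials x vertices effective drive
  d_eff <- outer(dir_sign, as.numeric(pop$regime == "retinal_2d")) +
    outer(percept_sign, as.numeric(pop$regime == "percept_3d"))
  dec <- pop$ecc - ecc_ref
  base <- pop$beta0 + pop$g_ecc * dec + pop$g_rad * hm
  amp <- matrix(base, nrow(sched), nrow(pop), byrow = TRUE) +
    d_eff * matrix(pop$s_v + pop$g_int * dec, nrow(sched), nrow(pop),
                   byrow = TRUE)
  dimnames(amp) <- NULL
  amp
}

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style difference of gammas (response peak 6 s, undershoot peak 16 s,
#' peak-to-undershoot ratio 6), sampled at `tr` and normalized to unit peak.
#'
#' @param length_s kernel length, s
#' @param tr sampling interval, s
#' @param peak response gamma peak, s
#' @param undershoot undershoot gamma peak, s
#' @param ratio peak-to-undershoot amplitude ratio
#' @return numeric kernel
#' @export
hrf_double_gamma <- function(length_s = 32, tr = 1, peak = 6, undershoot = 16,
                             ratio = 6) {
  t <- seq(0, length_s, by = tr)
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
  h / max(h)
}

#' Noise and nuisance parameters of the BOLD simulator
#'
#' Defaults are calibrated so that default-SNR single-trial decoding of a
#' ~100-vertex ROI lands mid-range (60-90 percent correct), leaving headroom
#' for sensitivity tests in both directions.
#'
#' @param white_sd marginal SD of the AR(1) vertex noise, signal units
#' @param ar1 lag-1 autoregressive coefficient
#' @param drift_lin peak-to-peak linear drift amplitude
#' @param drift_sin amplitude of the slow sinusoidal drift
#' @param drift_period period of the sinusoidal drift, s
#' @param motion_sd SD of per-vertex loadings on the 6 motion regressors
#' @param global_sd loading of every vertex on the global confound
#' @return an object of class `noise_params`
#' @export
noise_params <- function(white_sd = 0.8, ar1 = 0.3, drift_lin = 0.5,
                         drift_sin = 0.3, drift_period = 120,
                         motion_sd = 0.03, global_sd = 0.1) {
  structure(list(white_sd = white_sd, ar1 = ar1, drift_lin = drift_lin,
                 drift_sin = drift_sin, drift_period = drift_period,
                 motion_sd = motion_sd, global_sd = global_sd),
            class = "noise_params")
}

#' Simulate one fMRI run
#'
#' Convolves the per-vertex trial-amplitude impulse train with the canonical
#' HRF and adds linear + sinusoidal drift, a global confound, six
#' motion-regressor components (smooth random walks) and AR(1) noise. The
#' returned nuisance channels are the six motion regressors plus the global
#' signal (mean over vertices of the simulated series, consistent with its
#' role as a nuisance regressor).
#'
#' @param pop a [sample_vertices()] population
#' @param sched schedule rows of a single run, with a `percept` column
#' @param noise a [noise_params()]
#' @param seed optional RNG seed
#' @param hrf HRF kernel (default [hrf_double_gamma()])
#' @return an object of class `run_time_series`: list with `signal`
#'   (TR x vertex matrix), `nuisance` (TR x 7), `onsets` (s), `schedule`,
#'   `tr`
#' @export
simulate_run <- function(pop, sched, noise = noise_params(), seed = NULL,
                         hrf = NULL) {
  stopifnot(length(unique(sched$run)) == 1)
  tr <- attr(sched, "tr") %||% 1
  n_tr <- attr(sched, "run_trs") %||% 360
  if (!is.null(seed)) set.seed(seed)
  hrf <- hrf %||% hrf_double_gamma(tr = tr)
  onset_idx <- round(sched$onset / tr) + 1L
  if (any(onset_idx > n_tr)) stop("trial onset beyond run end")
  amp <- trial_amplitudes(pop, sched)
  n_v <- ncol(amp)
  # convolved design: one column per trial, HRF placed at the onset
  design <- matrix(0, n_tr, nrow(sched))
  L <- length(hrf)
  for (i in seq_len(nrow(sched))) {
    idx <- onset_idx[i]:min(n_tr, onset_idx[i] + L - 1L)
    design[idx, i] <- hrf[seq_along(idx)]
  }
  clean <- design %*% amp
  t_s <- (seq_len(n_tr) - 1) * tr
  drift <- noise$drift_lin * (t_s / max(t_s) - 0.5) +
    noise$drift_sin * sin(2 * pi * t_s / noise$drift_period +
                          stats::runif(1, 0, 2 * pi))
  # six smooth random-walk motion channels, standardized
  motion <- apply(matrix(stats::rnorm(n_tr * 6), n_tr, 6), 2, cumsum)
  motion <- scale(motion)
  m_load <- matrix(stats::rnorm(6 * n_v, 0, noise$motion_sd), 6, n_v)
  # smooth global confound shared by all vertices
  g <- as.numeric(stats::filter(stats::rnorm(n_tr), 0.9, "recursive"))
  g <- as.numeric(scale(g))
  innov_sd <- noise$white_sd * sqrt(1 - noise$ar1^2)
  eps <- matrix(stats::rnorm(n_tr * n_v, 0, innov_sd), n_tr, n_v)
  if (noise$ar1 != 0)
    eps <- apply(eps, 2, function(e)
      as.numeric(stats::filter(e, noise$ar1, "recursive")))
  signal <- clean + drift + motion %*% m_load +
    outer(g, rep(noise$global_sd, n_v)) + eps
  nuisance <- cbind(motion, global = rowMeans(signal))
  colnames(nuisance) <- c(paste0("motion", 1:6), "global")
  structure(list(signal = signal, nuisance = nuisance,
                 onsets = sched$onset, schedule = sched, tr = tr),
            class = "run_time_series")
}

#' Simulate behavioral reports
#'
#' The report equals the percept, flipped with probability `lapse`; when the
#' percept is `"none"` the report is a fair coin flip.
#'
#' @param obs an [observer()]
#' @param sched schedule with a `percept` column
#' @param seed optional RNG seed
#' @return character vector of `"toward"`/`"away"` reports
#' @export
simulate_behavioral_report <- function(obs, sched, seed = NULL) {
  if (is.null(sched$percept))
    stop("schedule lacks a `percept` column; run simulate_percepts() first")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(sched)
  flip <- function(d) ifelse(d == "toward", "away", "toward")
  report <- sched$percept
  none <- report == "none"
  report[none] <- sample(c("toward", "away"), sum(none), replace = TRUE)
  lapsed <- stats::runif(n) < obs$lapse & !none
  report[lapsed] <- flip(report[lapsed])
  report
}
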