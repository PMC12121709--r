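# shared fixtures: everything is generated in code at test time

# simulate + preprocess a full session for one observer and one ROI population
sim_session <- function(pop, obs, n_runs = 10, rotated = FALSE, seed = 1,
                        noise = noise_params()) {
  sched <- make_trial_schedule(n_runs = n_runs, rotated = rotated,
                               seed = child_seed(seed, 1))
  sched <- simulate_percepts(sched, obs, seed = child_seed(seed, 2))
  runs <- lapply(seq_len(n_runs), function(r) {
    sub <- sched[sched$run == r, , drop = FALSE]
    attr(sub, "tr") <- attr(sched, "tr")
    attr(sub, "run_trs") <- attr(sched, "run_trs")
    preprocess_run(simulate_run(pop, sub, noise = noise,
                                seed = child_seed(seed, 10 + r)))
  })
  assemble_session(runs)
}

# two-class Gaussian trial matrix: n trials, v vertices, per-vertex class
# separation delta (in SD units), labels balanced toward/away
gaussian_trial_matrix <- function(n = 100, v = 20, delta = 0, seed = 1,
                                  signal_vertices = seq_len(v)) {
  set.seed(seed)
  direction <- rep(c("toward", "away"), length.out = n)
  sgn <- ifelse(direction == "toward", 1, -1)
  x <- matrix(rnorm(n * v), n, v)
  shift <- numeric(v)
  shift[signal_vertices] <- delta / 2
  x <- x + outer(sgn, shift)
  trial_matrix(x, data.frame(run = 1, trial = seq_len(n),
                             condition = "combined", direction = direction,
                             rotated = FALSE, stringsAsFactors = FALSE))
}

# vertex population built by hand (bypasses the samplers)
manual_population <- function(ecc, polar, ve = 0.2, regime = "retinal_2d",
                              s_v = 0, g_ecc = 0, g_rad = 0, g_int = 0,
                              beta0 = 0, roi = "TEST") {
  n <- max(length(ecc), length(polar))
  pop <- data.frame(roi = roi, ecc = rep_len(ecc, n),
                    polar = rep_len(polar, n), ve = rep_len(ve, n),
                    regime = rep_len(regime, n), s_v = rep_len(s_v, n),
                    g_ecc = rep_len(g_ecc, n), g_rad = rep_len(g_rad, n),
                    g_int = rep_len(g_int, n), beta0 = rep_len(beta0, n),
                    stringsAsFactors = FALSE)
  attr(pop, "ecc_ref") <- mean(pop$ecc)
  attr(pop, "hm_half_width") <- 30
  class(pop) <- c("vertex_population", "data.frame")
  pop
}

# minimal single-run schedule with chosen conditions/directions
manual_schedule <- function(condition, direction, rotated = FALSE,
                            percept = NULL, onset = NULL, run_trs = 360) {
  n <- max(length(condition), length(direction))
  sched <- data.frame(run = 1, trial = seq_len(n),
                      onset = onset %||% ((seq_len(n) - 1) * 9),
                      condition = rep_len(condition, n),
                      direction = rep_len(direction, n),
                      rotated = rep_len(rotated, n), stringsAsFactors = FALSE)
  if (!is.null(percept)) sched$percept <- rep_len(percept, n)
  attr(sched, "tr") <- 1
  attr(sched, "run_trs") <- run_trs
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

`%||%` <- function(a, b) if (is.null(a)) b else a

quiet_noise <- function() noise_params(white_sd = 0, ar1 = 0, drift_lin = 0,
                                       drift_sin = 0, motion_sd = 0,
                                       global_sd = 0)
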