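#' Experiment configuration
#'
#' Bundles every tunable of the synthetic experiment. Defaults mirror the
#' standard design: 10 participants, 10 runs of 40 trials (8 motion types x
#' 5 repeats, 1 s trials with 8 s offsets, TR 1 s, 360 volumes), 5,000
#' bootstrap splits with a 10:90 test:train ratio, 500 vertex-equating
#' resamples, 0.2-8 degree eccentricity / 5 percent variance-explained vertex
#' filter, 4 degree central/edge bound and a +/-30 degree horizontal-meridian
#' wedge. Reduced `n_boot`/`n_resample` values are appropriate for quick
#' runs.
#'
#' @param n_participants number of simulated participants
#' @param n_stereo_pro how many of them are stereo-pros (the rest are
#'   stereo-strugglers)
#' @param n_control how many participants also complete the rotated-control
#'   session
#' @param roi_sizes named integer vector of vertices per ROI
#' @param n_runs runs per session
#' @param n_reps repeats per motion type per run
#' @param n_boot bootstrap splits per decode
#' @param n_resample vertex-equating draws
#' @param test_fraction test fraction of the balanced split
#' @param lapse observer report lapse rate
#' @param noise list of [noise_params()] values
#' @param hm_half_width HM wedge half-width, deg
#' @param ecc_bound central/edge eccentricity boundary, deg
#' @param ecc_range vertex-filter eccentricity range, deg
#' @param min_ve vertex-filter variance-explained threshold
#' @param decode run the decoding stage (bias BOLD statistics are produced
#'   either way)
#' @param seed master seed
#' @param out_dir optional output directory for [run_experiment()]
#' @return an object of class `experiment_config`
#' @export
experiment_config <- function(n_participants = 10, n_stereo_pro = 5,
                              n_control = 7,
                              roi_sizes = c(V1 = 400, MT = 120, MST = 120,
                                            FST = 120),
                              n_runs = 10, n_reps = 5, n_boot = 5000,
                              n_resample = 500, test_fraction = 0.10,
                              lapse = 0.02, noise = unclass(noise_params()),
                              hm_half_width = 30, ecc_bound = 4,
                              ecc_range = c(0.2, 8), min_ve = 0.05,
                              decode = TRUE, seed = 1, out_dir = NULL) {
  stopifnot(n_participants >= 1, n_stereo_pro >= 0,
            n_stereo_pro <= n_participants, n_control <= n_participants,
            n_runs >= 1, n_reps >= 1, n_boot >= 1, n_resample >= 1,
            all(roi_sizes >= 1))
  structure(list(n_participants = n_participants,
                 n_stereo_pro = n_stereo_pro, n_control = n_control,
                 roi_sizes = roi_sizes, n_runs = n_runs, n_reps = n_reps,
                 n_boot = n_boot, n_resample = n_resample,
                 test_fraction = test_fraction, lapse = lapse,
                 noise = noise, hm_half_width = hm_half_width,
                 ecc_bound = ecc_bound, ecc_range = ecc_range,
                 min_ve = min_ve, decode = decode, seed = seed,
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Write / read an experiment configuration as YAML
#'
#' @param config an [experiment_config()]
#' @param path file path
#' @return `write_config` returns `path` invisibly; `read_config` returns an
#'   `experiment_config` (round trip is lossless)
#' @export
write_config <- function(config, path) {
  raw <- unclass(config)
  raw$roi_sizes <- as.list(raw$roi_sizes)   # keep ROI names in the YAML map
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$roi_sizes <- unlist(raw$roi_sizes)
  raw$ecc_range <- as.numeric(unlist(raw$ecc_range))
  raw <- raw[!vapply(raw, is.null, logical(1))]
  do.call(experiment_config, raw)
}

#' Classify observers from stereoscopic-cue behavior
#'
#' An observer is labeled a stereo-struggler when their stereoscopic-cue
#' accuracy falls within the binomial 95 percent interval of chance for
#' their trial count, and a stereo-pro when it exceeds the upper bound.
#' Participants with no stereoscopic responses are excluded with a message.
#'
#' @param behavior data.frame with columns `participant`, `n_trials`,
#'   `accuracy` (stereoscopic-cue proportion correct)
#' @return data.frame with columns `participant`, `accuracy`, `group`
#'   (excluded participants are dropped)
#' @export
classify_observers <- function(behavior) {
  stopifnot(all(c("participant", "n_trials", "accuracy") %in% names(behavior)))
  missing_resp <- is.na(behavior$accuracy) | behavior$n_trials == 0
  if (any(missing_resp)) {
    message("excluding participant(s) with no stereoscopic responses: ",
            paste(behavior$participant[missing_resp], collapse = ", "))
    behavior <- behavior[!missing_resp, , drop = FALSE]
  }
  upper <- stats::qbinom(0.975, behavior$n_trials, 0.5) / behavior$n_trials
  data.frame(participant = behavior$participant,
             accuracy = behavior$accuracy,
             group = ifelse(behavior$accuracy > upper, "stereo_pro",
                            "stereo_struggler"),
             stringsAsFactors = FALSE)
}

# simulate + preprocess one session (all ROIs) for one observer
simulate_participant_session <- function(config, obs, pops, rotated, seed) {
  sched <- make_trial_schedule(n_runs = config$n_runs, n_reps = config$n_reps,
                               rotated = rotated, seed = child_seed(seed, 1))
  sched <- simulate_percepts(sched, obs, seed = child_seed(seed, 2))
  noise <- do.call(noise_params, config$noise)
  sessions <- lapply(seq_along(pops), function(i) {
    pop <- pops[[i]]
    runs <- lapply(seq_len(config$n_runs), function(r) {
      sub <- sched[sched$run == r, , drop = FALSE]
      attr(sub, "tr") <- attr(sched, "tr")
      attr(sub, "run_trs") <- attr(sched, "run_trs")
      rts <- simulate_run(pop, sub, noise = noise,
                          seed = child_seed(seed, 100 * i + r))
      # decoding path (z-normalized) and BOLD-amplitude path (raw scale)
      list(decode = preprocess_run(rts),
           bold = preprocess_run(rts, znorm = FALSE, global = FALSE))
    })
    list(decode = assemble_session(lapply(runs, `[[`, "decode")),
         bold = assemble_session(lapply(runs, `[[`, "bold")))
  })
  names(sessions) <- names(pops)
  report <- simulate_behavioral_report(obs, sched,
                                       seed = child_seed(seed, 3))
  list(trial_matrices = lapply(sessions, `[[`, "decode"),
       bold_matrices = lapply(sessions, `[[`, "bold"),
       schedule = sched, report = report)
}

decode_session <- function(tms, config, seed) {
  out <- list()
  for (roi in names(tms)) {
    tm <- tms[[roi]]
    accs <- list(
      stereoscopic = decode_direction(tm, "stereoscopic",
                                      n_boot = config$n_boot,
                                      test_fraction = config$test_fraction,
                                      seed = child_seed(seed, 11)),
      combined = decode_direction(tm, "combined", n_boot = config$n_boot,
                                  test_fraction = config$test_fraction,
                                  seed = child_seed(seed, 12))
    )
    pl <- decode_direction(tm, "perspectiveL", n_boot = config$n_boot,
                           test_fraction = config$test_fraction,
                           seed = child_seed(seed, 13))
    pr <- decode_direction(tm, "perspectiveR", n_boot = config$n_boot,
                           test_fraction = config$test_fraction,
                           seed = child_seed(seed, 14))
    accs$perspective <- perspective_average(pl, pr)
    out[[roi]] <- accs
  }
  out
}

#' Run the full synthetic experiment
#'
#' Simulates every participant (vertex populations, percepts, run time
#' series), preprocesses runs into trial matrices, decodes motion direction
#' per ROI x cue condition for the main and rotated-control sessions,
#' computes coarse-scale bias diagnostics, classifies observers from their
#' simulated behavior, and runs the group-level tests. With `out_dir` set,
#' writes a JSON summary plus TSV tables, all stamped with the configuration
#' hash and master seed.
#'
#' @param config an [experiment_config()]
#' @return (invisibly) the report bundle: list with `config_hash`, `seed`,
#'   `decoding` (long data.frame of mean accuracies), `behavior`,
#'   `classification`, `bias`, `group_stats`
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed
  presets <- roi_presets()
  decoding <- list()
  behavior <- list()
  bias_rows <- list()
  ecc_fit_data <- list()
  for (p in seq_len(config$n_participants)) {
    grp <- if (p <= config$n_stereo_pro) "stereo_pro" else "stereo_struggler"
    obs <- observer(p, grp, lapse = config$lapse)
    pseed <- child_seed(seed, p)
    pops <- lapply(names(config$roi_sizes), function(roi)
      sample_vertices(roi, config$roi_sizes[[roi]],
                      seed = child_seed(pseed, match(roi, names(presets))),
                      hm_half_width = config$hm_half_width))
    names(pops) <- names(config$roi_sizes)
    main <- simulate_participant_session(config, obs, pops, rotated = FALSE,
                                         seed = child_seed(pseed, 1000))
    sessions <- list(main = main)
    if (p <= config$n_control)
      sessions$control <- simulate_participant_session(
        config, obs, pops, rotated = TRUE, seed = child_seed(pseed, 2000))
    for (sess in if (isTRUE(config$decode)) names(sessions) else character()) {
      accs <- decode_session(sessions[[sess]]$trial_matrices, config,
                             seed = child_seed(pseed, 3000 + nchar(sess)))
      for (roi in names(accs))
        for (cond in names(accs[[roi]]))
          decoding[[length(decoding) + 1]] <- data.frame(
            participant = p, group = grp, session = sess, roi = roi,
            condition = cond, accuracy = accs[[roi]][[cond]]$mean_accuracy,
            null_lo = unname(accs[[roi]][[cond]]$null_ci[1]),
            null_hi = unname(accs[[roi]][[cond]]$null_ci[2]),
            stringsAsFactors = FALSE)
    }
    # behavior: stereoscopic-cue accuracy in the main session
    sched <- main$schedule
    stereo <- sched$condition == "stereoscopic" & !sched$rotated
    behavior[[p]] <- data.frame(
      participant = p, true_group = grp, n_trials = sum(stereo),
      accuracy = mean(main$report[stereo] == sched$direction[stereo]),
      stringsAsFactors = FALSE)
    # coarse-scale bias diagnostics on the main session
    for (roi in names(pops)) {
      pop <- pops[[roi]]
      tm <- main$bold_matrices[[roi]]
      ids <- filter_vertices(pop, config$ecc_range, config$min_ve)
      if (length(ids) < 4) next
      pol <- split_polar(ids, pop, config$hm_half_width)
      bg <- bold_group_means(tm, pol, condition = "stereoscopic")
      bias_rows[[length(bias_rows) + 1]] <- data.frame(
        participant = p, roi = roi, stat = "bold_hm_minus_nhm",
        value = bg$difference, stringsAsFactors = FALSE)
      vert_mean <- colMeans(
        tm$amplitudes[tm$labels$condition == "combined", ids, drop = FALSE])
      ecc_fit_data[[length(ecc_fit_data) + 1]] <- data.frame(
        participant = p, roi = roi, ecc = pop$ecc[ids],
        amplitude = vert_mean, stringsAsFactors = FALSE)
    }
  }
  decoding <- if (length(decoding)) do.call(rbind, decoding) else NULL
  behavior <- do.call(rbind, behavior)
  bias <- if (length(bias_rows)) do.call(rbind, bias_rows) else NULL
  ecc_data <- if (length(ecc_fit_data)) do.call(rbind, ecc_fit_data) else NULL
  classification <- classify_observers(behavior)
  group_stats <- list()
  if (!is.null(decoding) && config$n_participants >= 2) {
    main_acc <- decoding[decoding$session == "main", ]
    mt_fst <- main_acc[main_acc$roi %in% c("MT", "FST") &
                         main_acc$condition %in% c("perspective",
                                                   "stereoscopic"), ]
    if (nrow(mt_fst) > 0) {
      names(mt_fst)[names(mt_fst) == "condition"] <- "cue"
      group_stats$cue_by_roi <- tryCatch(
        mixed_model_contrast(mt_fst, response = "accuracy",
                             factors = c("cue", "roi")),
        error = function(e) NULL)
      st <- mt_fst[mt_fst$cue == "stereoscopic", ]
      group_stats$stereo_fst_vs_mt <- mann_whitney_u(
        st$accuracy[st$roi == "FST"], st$accuracy[st$roi == "MT"])
    }
  }
  if (!is.null(ecc_data)) {
    group_stats$ecc_slope <- lapply(split(ecc_data, ecc_data$roi), function(d)
      tryCatch(bold_eccentricity_fit(d, method = "slopes"),
               error = function(e) NULL))
  }
  # the hash covers the scientific configuration, not the output location
  hash_cfg <- unclass(config)
  hash_cfg$out_dir <- NULL
  bundle <- list(config_hash = object_hash(hash_cfg),
                 seed = seed, decoding = decoding, behavior = behavior,
                 classification = classification, bias = bias,
                 ecc_data = ecc_data, group_stats = group_stats)
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config)
  invisible(bundle)
}

write_report_bundle <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$decoding))
    utils::write.table(bundle$decoding,
                       file.path(config$out_dir, "decoding.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$behavior,
                     file.path(config$out_dir, "behavior.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$bias))
    utils::write.table(bundle$bias, file.path(config$out_dir, "bias.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    config_hash = bundle$config_hash, seed = bundle$seed,
    n_participants = config$n_participants,
    n_trials_per_session = config$n_runs * config$n_reps * 8L,
    mean_accuracy_by_roi_condition = if (is.null(bundle$decoding)) NULL else
      stats::aggregate(accuracy ~ roi + condition + session,
                       data = bundle$decoding, FUN = mean),
    classification = bundle$classification)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Validate a report bundle against the shipped schema
#'
#' Checks the bundle's structure against the JSON schema in
#' `inst/schema/report_schema.json` (required top-level fields and the
#' decoding-table columns).
#'
#' @param bundle a [run_experiment()] result
#' @return `TRUE` (invisibly) or an error describing the first violation
#' @export
validate_report <- function(bundle) {
  schema <- jsonlite::read_json(system.file("schema", "report_schema.json",
                                            package = "stereomotion"))
  required <- unlist(schema$required)
  missing <- setdiff(required, names(bundle))
  if (length(missing))
    stop("report bundle lacks required field(s): ",
         paste(missing, collapse = ", "))
  dec_cols <- unlist(schema$properties$decoding$required_columns)
  missing_cols <- setdiff(dec_cols, names(bundle$decoding))
  if (length(missing_cols))
    stop("decoding table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  invisible(TRUE)
}
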