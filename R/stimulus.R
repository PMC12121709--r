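#' Viewing geometry of the display
#'
#' Physical geometry linking world coordinates (mm) to retinal coordinates
#' (degrees of visual angle). Defaults follow a rear-projection setup with an
#' 88 cm viewing distance and a 38.5 cm wide screen. The interocular distance
#' is configurable (65 mm is another common choice); it only enters the
#' perspective projection used by the combined-cue condition, because the
#' stereoscopic condition is specified directly in retinal units.
#'
#' @param viewing_distance distance from the cyclopean eye to the fixation
#'   plane, mm
#' @param interocular_distance distance between the two eyes, mm
#' @param screen_width physical width of the display, mm
#' @return an object of class `viewing_geometry`
#' @export
viewing_geometry <- function(viewing_distance = 880,
                             interocular_distance = 63,
                             screen_width = 385) {
  stopifnot(viewing_distance > 0, interocular_distance > 0, screen_width > 0,
            interocular_distance < viewing_distance)
  structure(list(viewing_distance = viewing_distance,
                 interocular_distance = interocular_distance,
                 screen_width = screen_width),
            class = "viewing_geometry")
}

#' Annular stimulus aperture
#'
#' @param outer_radius outer radius, degrees of visual angle
#' @param inner_radius inner radius, degrees of visual angle
#' @return an object of class `aperture`
#' @export
aperture <- function(outer_radius = 8, inner_radius = 0.25) {
  stopifnot(inner_radius > 0, inner_radius < outer_radius)
  structure(list(outer_radius = outer_radius, inner_radius = inner_radius),
            class = "aperture")
}

#' Kinematic parameters of the motion-in-depth stimulus
#'
#' Dots move at ~51.83 mm/s in world units and 1.2 deg/s per eye in retinal
#' units; in the stereoscopic condition the two eyes translate in opposite
#' directions so binocular disparity changes at twice the per-eye speed
#' (2.4 deg/s). Retinal-unit speeds are authoritative for stereoscopic frames;
#' world-unit speed is authoritative for perspective/combined frames (the two
#' printed speeds are not mutually derivable from the stated geometry, so both
#' are carried in the object).
#'
#' @param world_speed dot speed along the depth axis, mm/s
#' @param per_eye_retinal_speed horizontal monocular image speed, deg/s
#' @param disparity_rate rate of change of binocular disparity, deg/s
#' @param trial_duration trial length, s
#' @param frame_rate display refresh, Hz
#' @return an object of class `motion_params`
#' @export
motion_params <- function(world_speed = 51.83,
                          per_eye_retinal_speed = 1.2,
                          disparity_rate = 2 * per_eye_retinal_speed,
                          trial_duration = 1,
                          frame_rate = 120) {
  stopifnot(world_speed > 0, per_eye_retinal_speed > 0, trial_duration > 0,
            frame_rate > 0)
  structure(list(world_speed = world_speed,
                 per_eye_retinal_speed = per_eye_retinal_speed,
                 disparity_rate = disparity_rate,
                 trial_duration = trial_duration,
                 frame_rate = frame_rate),
            class = "motion_params")
}

#' Cue condition descriptor
#'
#' Four cue conditions carry the toward/away signal: `stereoscopic` (changing
#' disparity + interocular velocity difference, constant dot size),
#' `perspectiveL`/`perspectiveR` (monocular looming/receding dots presented to
#' one eye only) and `combined` (perspective geometry rendered to both eyes).
#' The `rotated` flag marks the 90-degree-rotated control in which each eye's
#' image is rotated about fixation, abolishing the 3D percept for the
#' stereoscopic stimulus while preserving monocular motion energy.
#'
#' @param name one of `"stereoscopic"`, `"perspectiveL"`, `"perspectiveR"`,
#'   `"combined"`
#' @param direction `"toward"` or `"away"`
#' @param rotated logical, 90-degree rotated control
#' @return an object of class `cue_condition`
#' @export
cue_condition <- function(name, direction, rotated = FALSE) {
  name <- match.arg(name, c("stereoscopic", "perspectiveL", "perspectiveR",
                            "combined"))
  direction <- match.arg(direction, c("toward", "away"))
  structure(list(name = name, direction = direction, rotated = isTRUE(rotated)),
            class = "cue_condition")
}

# uniform draw over the annulus area; returns data.frame(azimuth, elevation)
sample_annulus <- function(n, ap) {
  r <- sqrt(stats::runif(n, ap$inner_radius^2, ap$outer_radius^2))
  th <- stats::runif(n, 0, 2 * pi)
  data.frame(azimuth = r * cos(th), elevation = r * sin(th))
}

#' Create a random-dot field
#'
#' Draws `n_dots` dots uniformly over the annular aperture area, with
#' alternating black/white polarity and an angular diameter of 0.16 degrees at
#' the fixation plane. Dots are placed at the fixation depth; both eyes
#' initially see the cyclopean image (zero disparity).
#'
#' @param n_dots number of dots (default 80)
#' @param ap the stimulus [aperture()]
#' @param seed optional RNG seed
#' @param geometry a [viewing_geometry()]
#' @param dot_diameter angular dot diameter at the fixation plane, deg
#' @return an object of class `dot_field`
#' @export
make_dot_field <- function(n_dots = 80, ap = aperture(), seed = NULL,
                           geometry = viewing_geometry(), dot_diameter = 0.16) {
  if (length(n_dots) != 1L || is.na(n_dots) || n_dots < 0)
    stop("`n_dots` must be a single non-negative integer")
  n_dots <- as.integer(n_dots)
  if (!is.null(seed)) set.seed(seed)
  pos <- sample_annulus(n_dots, ap)
  d <- geometry$viewing_distance
  field <- list(
    n_dots = n_dots,
    azimuth = pos$azimuth,
    elevation = pos$elevation,
    x = tand(pos$azimuth) * d,
    y = tand(pos$elevation) * d,
    z = rep(d, n_dots),
    polarity = rep_len(c("black", "white"), n_dots),
    left_azimuth = pos$azimuth,
    left_elevation = pos$elevation,
    left_diameter = rep(dot_diameter, n_dots),
    right_azimuth = pos$azimuth,
    right_elevation = pos$elevation,
    right_diameter = rep(dot_diameter, n_dots),
    eye_present = c(left = TRUE, right = TRUE),
    reseeded = rep(FALSE, n_dots),
    aperture = ap,
    geometry = geometry,
    dot_diameter = dot_diameter,
    # physical dot size chosen so the angular diameter is `dot_diameter`
    # at the fixation plane
    physical_diameter = 2 * d * tand(dot_diameter / 2)
  )
  class(field) <- "dot_field"
  field
}

#' @export
print.dot_field <- function(x, ...) {
  cat(sprintf("<dot_field> %d dots, aperture [%.2f, %.2f] deg, eyes: %s\n",
              x$n_dots, x$aperture$inner_radius, x$aperture$outer_radius,
              paste(names(x$eye_present)[x$eye_present], collapse = "+")))
  invisible(x)
}

cyclopean_eccentricity <- function(field) {
  sqrt(field$azimuth^2 + field$elevation^2)
}

# redraw out-of-aperture dots uniformly in the annulus with fresh phase
# (zero disparity, fixation depth), marking them as reseeded
reseed_dots <- function(field, out, depth = NULL) {
  if (!any(out)) {
    field$reseeded <- rep(FALSE, field$n_dots)
    return(field)
  }
  pos <- sample_annulus(sum(out), field$aperture)
  d <- depth %||% field$geometry$viewing_distance
  field$azimuth[out] <- pos$azimuth
  field$elevation[out] <- pos$elevation
  field$z[out] <- d
  field$x[out] <- tand(pos$azimuth) * d
  field$y[out] <- tand(pos$elevation) * d
  field$left_azimuth[out] <- pos$azimuth
  field$left_elevation[out] <- pos$elevation
  field$right_azimuth[out] <- pos$azimuth
  field$right_elevation[out] <- pos$elevation
  dd <- 2 * atand(field$physical_diameter / (2 * d))
  field$left_diameter[out] <- dd
  field$right_diameter[out] <- dd
  field$reseeded <- out
  field
}

#' Advance a dot field one stereoscopic-cue step
#'
#' Each dot's monocular images translate horizontally at the per-eye retinal
#' speed in opposite directions in the two eyes, so that binocular disparity
#' changes at twice that speed. Toward motion makes the disparity more crossed
#' (more negative under the right-minus-left convention): the left-eye image
#' moves rightward and the right-eye image leftward. Elevation and dot size
#' are unchanged. Dots whose cyclopean eccentricity exits the aperture are
#' redrawn uniformly inside it with fresh (zero) disparity.
#'
#' @param field a `dot_field`
#' @param direction `"toward"` or `"away"`
#' @param dt time step, s
#' @param params [motion_params()]
#' @return the advanced `dot_field`
#' @export
advance_stereoscopic <- function(field, direction, dt,
                                 params = motion_params()) {
  direction <- match.arg(direction, c("toward", "away"))
  stopifnot(dt >= 0)
  s <- if (direction == "toward") 1 else -1
  delta <- params$per_eye_retinal_speed * dt
  field$left_azimuth <- field$left_azimuth + s * delta
  field$right_azimuth <- field$right_azimuth - s * delta
  field$azimuth <- (field$left_azimuth + field$right_azimuth) / 2
  field$elevation <- (field$left_elevation + field$right_elevation) / 2
  ecc <- cyclopean_eccentricity(field)
  out <- ecc > field$aperture$outer_radius | ecc < field$aperture$inner_radius
  reseed_dots(field, out)
}

# monocular perspective projection of world dots from one eye's nodal point
project_eye <- function(field, eye) {
  ex <- if (eye == "left") -field$geometry$interocular_distance / 2
        else field$geometry$interocular_distance / 2
  az <- atand((field$x - ex) / field$z)
  el <- atand(field$y / field$z)
  diam <- 2 * atand(field$physical_diameter / (2 * field$z))
  list(azimuth = az, elevation = el, diameter = diam)
}

apply_projection <- function(field, eyes = c("left", "right")) {
  if ("left" %in% eyes) {
    p <- project_eye(field, "left")
    field$left_azimuth <- p$azimuth
    field$left_elevation <- p$elevation
    field$left_diameter <- p$diameter
  } else {
    field$left_azimuth <- rep(NA_real_, field$n_dots)
    field$left_elevation <- rep(NA_real_, field$n_dots)
    field$left_diameter <- rep(NA_real_, field$n_dots)
  }
  if ("right" %in% eyes) {
    p <- project_eye(field, "right")
    field$right_azimuth <- p$azimuth
    field$right_elevation <- p$elevation
    field$right_diameter <- p$diameter
  } else {
    field$right_azimuth <- rep(NA_real_, field$n_dots)
    field$right_elevation <- rep(NA_real_, field$n_dots)
    field$right_diameter <- rep(NA_real_, field$n_dots)
  }
  field$eye_present <- c(left = "left" %in% eyes, right = "right" %in% eyes)
  # cyclopean retinal position from the cyclopean eye at the origin
  field$azimuth <- atand(field$x / field$z)
  field$elevation <- atand(field$y / field$z)
  field
}

#' Advance a dot field one perspective-cue step
#'
#' World dots translate along the depth axis (toward decreases z); the retinal
#' position and angular diameter of the single presented eye are recomputed by
#' perspective projection, so toward motion produces radial expansion, looming
#' dot size and decreasing density — the monocularly available 3D motion cues.
#' The other eye carries an empty frame. A dot that would cross the eye plane
#' is re-seeded at the fixation depth (the event is logged via `message`); a
#' dot leaving the annular aperture is re-seeded likewise.
#'
#' @inheritParams advance_stereoscopic
#' @param eye `"left"` or `"right"`: the eye receiving the stimulus
#' @return the advanced `dot_field`
#' @export
advance_perspective <- function(field, direction, dt,
                                params = motion_params(),
                                eye = c("left", "right")) {
  eye <- match.arg(eye)
  field <- advance_world_depth(field, direction, dt, params)
  apply_projection(field, eyes = eye)
}

#' Advance a dot field one combined-cue step
#'
#' Same world-depth translation as the perspective condition, but both eyes
#' receive the perspective projection from their own nodal points, so the
#' stimulus carries perspective cues and geometrically consistent changing
#' disparity / interocular velocity differences.
#'
#' @inheritParams advance_stereoscopic
#' @return the advanced `dot_field`
#' @export
advance_combined <- function(field, direction, dt, params = motion_params()) {
  field <- advance_world_depth(field, direction, dt, params)
  apply_projection(field, eyes = c("left", "right"))
}

advance_world_depth <- function(field, direction, dt, params) {
  direction <- match.arg(direction, c("toward", "away"))
  stopifnot(dt >= 0)
  s <- if (direction == "toward") 1 else -1
  field$z <- field$z - s * params$world_speed * dt
  crossed <- field$z <= 1
  if (any(crossed)) {
    message(sprintf("%d dot(s) crossed the eye plane; re-seeded at fixation depth",
                    sum(crossed)))
    field <- reseed_dots(field, crossed)
  }
  ecc <- atand(sqrt(field$x^2 + field$y^2) / field$z)
  out <- ecc > field$aperture$outer_radius | ecc < field$aperture$inner_radius
  reseed_dots(field, out)
}

#' Binocular disparity from monocular azimuths
#'
#' Convention: disparity = right-eye azimuth minus left-eye azimuth, degrees.
#' Negative values are crossed (near) disparities; toward motion drives
#' disparity more negative.
#'
#' @param left_azimuth left-eye azimuth, deg
#' @param right_azimuth right-eye azimuth, deg
#' @return disparity in degrees
#' @export
disparity <- function(left_azimuth, right_azimuth) {
  stopifnot(all(is.finite(left_azimuth)), all(is.finite(right_azimuth)))
  right_azimuth - left_azimuth
}

#' Rotate each eye's retinal image about fixation
#'
#' Used by the rotated control: a 90-degree rotation of both monocular images
#' turns the stereoscopic stimulus' opposite horizontal motions into opposite
#' vertical motions (one eye up, the other down), preserving each dot's
#' per-frame monocular speed exactly while abolishing the motion-in-depth
#' percept. Rotation is counter-clockwise by default and restricted to
#' multiples of 90 degrees so it is numerically exact.
#'
#' @param field a `dot_field`
#' @param angle rotation angle, degrees; multiple of 90
#' @param sense `"ccw"` (default) or `"cw"`
#' @return the rotated `dot_field`
#' @export
rotate_retinal <- function(field, angle = 90, sense = c("ccw", "cw")) {
  sense <- match.arg(sense)
  if (angle %% 90 != 0) stop("`angle` must be a multiple of 90 degrees")
  k <- (angle / 90) %% 4
  if (sense == "cw") k <- (4 - k) %% 4
  rot90 <- function(az, el, k) {
    for (i in seq_len(k)) {
      tmp <- az
      az <- -el
      el <- tmp
    }
    list(az = az, el = el)
  }
  if (k == 0) return(field)
  l <- rot90(field$left_azimuth, field$left_elevation, k)
  r <- rot90(field$right_azimuth, field$right_elevation, k)
  cyc <- rot90(field$azimuth, field$elevation, k)
  field$left_azimuth <- l$az; field$left_elevation <- l$el
  field$right_azimuth <- r$az; field$right_elevation <- r$el
  field$azimuth <- cyc$az; field$elevation <- cyc$el
  field
}

#' Generate a full stimulus trial
#'
#' Produces the per-frame sequence of dot fields for one 1 s trial of a cue
#' condition at the display frame rate (120 frames by default). The first
#' frame is the initial field; each later frame advances by `1/frame_rate`.
#' For the rotated control every frame is rotated by 90 degrees.
#'
#' @param condition condition name or a [cue_condition()]
#' @param direction `"toward"` or `"away"` (ignored if `condition` is a
#'   `cue_condition`)
#' @param rotated logical, 90-degree control
#' @param n_frames number of frames (default `frame_rate * trial_duration`)
#' @param n_dots number of dots
#' @param seed RNG seed for the initial dot placement and any re-seeding
#' @param params [motion_params()]
#' @param ap [aperture()]
#' @param geometry [viewing_geometry()]
#' @return an object of class `trial_frames`: list with elements `frames`
#'   (list of `dot_field`s), `condition`, `times` (s)
#' @export
generate_trial <- function(condition, direction = NULL, rotated = FALSE,
                           n_frames = NULL, n_dots = 80, seed = NULL,
                           params = motion_params(), ap = aperture(),
                           geometry = viewing_geometry()) {
  if (!inherits(condition, "cue_condition"))
    condition <- cue_condition(condition, direction, rotated)
  n_frames <- n_frames %||% round(params$frame_rate * params$trial_duration)
  stopifnot(n_frames >= 1)
  dt <- 1 / params$frame_rate
  field <- make_dot_field(n_dots, ap, seed = seed, geometry = geometry)
  step <- switch(condition$name,
    stereoscopic = function(f) advance_stereoscopic(f, condition$direction, dt, params),
    perspectiveL = function(f) advance_perspective(f, condition$direction, dt, params, eye = "left"),
    perspectiveR = function(f) advance_perspective(f, condition$direction, dt, params, eye = "right"),
    combined = function(f) advance_combined(f, condition$direction, dt, params)
  )
  if (condition$name == "perspectiveL") field <- apply_projection(field, "left")
  if (condition$name == "perspectiveR") field <- apply_projection(field, "right")
  if (condition$name == "combined") field <- apply_projection(field, c("left", "right"))
  frames <- vector("list", n_frames)
  frames[[1]] <- field
  for (i in seq_len(n_frames - 1L) + 1L) {
    field <- step(field)
    frames[[i]] <- field
  }
  if (condition$rotated) frames <- lapply(frames, rotate_retinal, angle = 90)
  structure(list(frames = frames, condition = condition,
                 times = (seq_len(n_frames) - 1) * dt, params = params),
            class = "trial_frames")
}

#' Fit the rate of change of binocular disparity over a trial
#'
#' Tracks one dot's left- and right-eye azimuths across frames, computes the
#' per-frame disparity and fits its least-squares slope against time. By
#' default the first dot that was never re-seeded during the trial is used,
#' so the fitted slope reflects uninterrupted motion.
#'
#' @param trial a `trial_frames` object with both eyes present
#' @param dot optional dot index to track
#' @return signed slope, deg/s
#' @export
fit_disparity_rate <- function(trial, dot = NULL) {
  stopifnot(inherits(trial, "trial_frames"))
  if (!all(trial$frames[[1]]$eye_present))
    stop("disparity requires both eyes to be presented")
  if (is.null(dot)) {
    reseeded <- Reduce(`|`, lapply(trial$frames, function(f) f$reseeded))
    if (all(reseeded)) stop("every dot was re-seeded during the trial")
    dot <- which(!reseeded)[1]
  }
  disp <- vapply(trial$frames, function(f)
    disparity(f$left_azimuth[dot], f$right_azimuth[dot]), numeric(1))
  unname(stats::lm.fit(cbind(1, trial$times), disp)$coefficients[2])
}

#' Long-format frame table of a trial
#'
#' One row per frame x dot x presented eye, with columns `frame`, `dot`,
#' `eye`, `azimuth_deg`, `elevation_deg`, `diameter_deg`, `polarity`.
#'
#' @param trial a `trial_frames` object or list of `dot_field`s
#' @return a data.frame
#' @export
frame_table <- function(trial) {
  frames <- if (inherits(trial, "trial_frames")) trial$frames else trial
  if (length(frames) == 0)
    return(data.frame(frame = integer(), dot = integer(), eye = character(),
                      azimuth_deg = numeric(), elevation_deg = numeric(),
                      diameter_deg = numeric(), polarity = character(),
                      stringsAsFactors = FALSE))
  counts <- vapply(frames, function(f) f$n_dots, integer(1))
  if (length(unique(counts)) != 1L)
    stop("mixed dot counts across frames")
  rows <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    eyes <- names(f$eye_present)[f$eye_present]
    do.call(rbind, lapply(eyes, function(e) {
      data.frame(frame = i, dot = seq_len(f$n_dots), eye = e,
                 azimuth_deg = f[[paste0(e, "_azimuth")]],
                 elevation_deg = f[[paste0(e, "_elevation")]],
                 diameter_deg = f[[paste0(e, "_diameter")]],
                 polarity = f$polarity, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a frame table as TSV
#'
#' Numeric columns are formatted with 17 significant digits so the write/read
#' round trip reproduces doubles exactly.
#'
#' @param tab a frame table from [frame_table()]
#' @param path output path
#' @return `write_frame_table` returns `path` invisibly; `read_frame_table`
#'   returns the table
#' @export
write_frame_table <- function(tab, path) {
  out <- tab
  for (nm in c("azimuth_deg", "elevation_deg", "diameter_deg"))
    out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frame_table
#' @export
read_frame_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(frame = "integer", dot = "integer",
                                          eye = "character",
                                          azimuth_deg = "character",
                                          elevation_deg = "character",
                                          diameter_deg = "character",
                                          polarity = "character"))
  for (nm in c("azimuth_deg", "elevation_deg", "diameter_deg"))
    tab[[nm]] <- as.numeric(tab[[nm]])
  tab
}
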