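#' High-pass filter by discrete-cosine-basis projection removal
#'
#' Removes the projection of each time series onto the DC component and all
#' discrete-cosine basis functions with period >= `1/cutoff` seconds. This
#' gives exact DC removal and no edge ringing; frequencies well above the
#' cutoff pass essentially untouched.
#'
#' @param series numeric vector or TR x vertex matrix
#' @param cutoff cutoff frequency, Hz (default 1/40)
#' @param tr sampling interval, s
#' @return filtered series, same shape as input
#' @export
highpass <- function(series, cutoff = 1 / 40, tr = 1) {
  x <- as.matrix(series)
  if (!all(is.finite(x))) stop("non-finite values in input series")
  n <- nrow(x)
  stopifnot(n >= 4)
  # DCT-II basis k has period 2*n*tr/k seconds; remove k with period >= 1/cutoff
  k_max <- floor(2 * n * tr * cutoff)
  t0 <- seq_len(n) - 0.5
  basis <- cbind(1, vapply(seq_len(k_max), function(k) cos(pi * k * t0 / n),
                           numeric(n)))
  out <- qr.resid(qr(basis), x)
  if (is.vector(series)) out <- drop(out)
  out
}

#' Regress nuisance channels out of a time series
#'
#' Ordinary least squares with an intercept; returns residuals, which are
#' orthogonal to every retained regressor. Collinear regressor columns are
#' dropped with a warning.
#'
#' @param series numeric vector or TR x vertex matrix
#' @param regressors TR x k matrix (e.g. 6 motion channels + global signal)
#' @return residual series, same shape as input
#' @export
nuisance_regress <- function(series, regressors) {
  x <- as.matrix(series)
  r <- as.matrix(regressors)
  if (nrow(r) != nrow(x)) stop("regressor rows must match series rows")
  design <- cbind(intercept = 1, r)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    keep <- qr_d$pivot[seq_len(qr_d$rank)]
    dropped <- colnames(design)[setdiff(seq_len(ncol(design)), keep)]
    warning("dropping collinear regressor column(s): ",
            paste(dropped, collapse = ", "))
    design <- design[, sort(keep), drop = FALSE]
    qr_d <- qr(design)
  }
  out <- qr.resid(qr_d, x)
  if (is.vector(series)) out <- drop(out)
  out
}

#' Peristimulus z-normalization
#'
#' For each lag n = 1..`max_lag` TRs after trial onset, the values at
#' onset + n across the run's trials are z-scored per vertex: each lag ends
#' up with mean 0 and SD 1 across trials. Degenerate SDs (< 1e-12) yield
#' zeros with a warning rather than NaN.
#'
#' @param series numeric vector or TR x vertex matrix (one run)
#' @param onsets trial onsets, s (0-based)
#' @param max_lag number of peristimulus lags (default 9 = the full
#'   trial + offset window at TR 1 s)
#' @param tr sampling interval, s
#' @return z-scored series, same shape as input
#' @export
znorm_peristim <- function(series, onsets, max_lag = 9, tr = 1) {
  x <- as.matrix(series)
  if (length(onsets) < 2) stop("need at least 2 trials to z-score")
  out <- x
  degenerate <- FALSE
  for (lag in seq_len(max_lag)) {
    idx <- round(onsets / tr) + lag
    if (any(idx < 1 | idx > nrow(x))) stop("onset + lag outside the run")
    vals <- x[idx, , drop = FALSE]
    mu <- colMeans(vals)
    sd_ <- apply(vals, 2, stats::sd)
    z <- sweep(vals, 2, mu, "-")
    ok <- sd_ >= 1e-12
    z[, ok] <- sweep(z[, ok, drop = FALSE], 2, sd_[ok], "/")
    if (any(!ok)) {
      z[, !ok] <- 0
      degenerate <- TRUE
    }
    out[idx, ] <- z
  }
  if (degenerate)
    warning("degenerate SD at one or more peristimulus lags; zeros returned")
  if (is.vector(series)) out <- drop(out)
  out
}

#' Extract single-trial response amplitudes
#'
#' Averages the z-scored values at the 6th-9th TRs after each trial onset
#' (1-based, inclusive: 5-8 s post-onset at TR 1 s), yielding one amplitude
#' per trial per vertex.
#'
#' @param z_series z-scored TR x vertex matrix (one run)
#' @param onsets trial onsets, s (0-based)
#' @param window TR indices after onset to average (default `6:9`)
#' @param tr sampling interval, s
#' @return trials x vertex matrix of amplitudes
#' @export
extract_amplitudes <- function(z_series, onsets, window = 6:9, tr = 1) {
  x <- as.matrix(z_series)
  idx <- outer(round(onsets / tr), window, "+")
  if (any(idx < 1 | idx > nrow(x))) stop("averaging window outside the run")
  out <- t(apply(idx, 1, function(i) colMeans(x[i, , drop = FALSE])))
  if (ncol(x) == 1) out <- matrix(out, ncol = 1)
  out
}

#' Preprocess one simulated run into trial amplitudes
#'
#' Applies the single-trial extraction pipeline in its fixed order:
#' high-pass filter, nuisance regression (6 motion channels + global signal),
#' peristimulus z-normalization, then averaging of the 6th-9th post-onset
#' TRs.
#'
#' @param run a [simulate_run()] result
#' @param cutoff high-pass cutoff, Hz
#' @param window averaging window, TR indices after onset
#' @param znorm apply peristimulus z-normalization (the decoding path). Set
#'   `FALSE` for BOLD-amplitude analyses, where per-vertex response scale is
#'   the quantity of interest and z-normalization would remove it
#' @param global include the global-signal channel in nuisance regression.
#'   Set `FALSE` for BOLD-amplitude analyses: regressing out the mean over
#'   vertices also absorbs spatially coherent amplitude structure (for
#'   example an eccentricity gradient shared by most vertices)
#' @return an object of class `trial_matrix` (see [trial_matrix()]) with one
#'   row per trial of the run
#' @export
preprocess_run <- function(run, cutoff = 1 / 40, window = 6:9, znorm = TRUE,
                           global = TRUE) {
  stopifnot(inherits(run, "run_time_series"))
  x <- highpass(run$signal, cutoff = cutoff, tr = run$tr)
  nuis <- if (global) run$nuisance
          else run$nuisance[, colnames(run$nuisance) != "global", drop = FALSE]
  x <- nuisance_regress(x, nuis)
  if (znorm) x <- znorm_peristim(x, run$onsets, tr = run$tr)
  amp <- extract_amplitudes(x, run$onsets, window = window, tr = run$tr)
  trial_matrix(amp, run$schedule[, c("run", "trial", "condition", "direction",
                                     "rotated")],
               provenance = list(cutoff = cutoff, window = window,
                                 znorm = znorm, global = global))
}

#' Trial-by-vertex amplitude matrix with labels
#'
#' @param amplitudes trials x vertex numeric matrix
#' @param labels data.frame with one row per trial (`run`, `condition`,
#'   `direction`, `rotated`, ...)
#' @param provenance optional list (filter cutoff, averaging window, ...)
#' @return an object of class `trial_matrix`
#' @export
trial_matrix <- function(amplitudes, labels, provenance = list()) {
  amplitudes <- as.matrix(amplitudes)
  stopifnot(nrow(amplitudes) == nrow(labels), all(is.finite(amplitudes)))
  structure(list(amplitudes = amplitudes, labels = labels,
                 provenance = provenance),
            class = "trial_matrix")
}

#' @export
print.trial_matrix <- function(x, ...) {
  cat(sprintf("<trial_matrix> %d trials x %d vertices (%d run(s))\n",
              nrow(x$amplitudes), ncol(x$amplitudes),
              length(unique(x$labels$run))))
  invisible(x)
}

#' Concatenate per-run trial matrices into a session
#'
#' @param runs list of `trial_matrix` objects with matching vertex counts
#' @return a single `trial_matrix`; with 10 standard runs, 400 trials and 50
#'   trials per direction x cue condition
#' @export
assemble_session <- function(runs) {
  stopifnot(length(runs) >= 1)
  ncols <- vapply(runs, function(r) ncol(r$amplitudes), integer(1))
  if (length(unique(ncols)) != 1) stop("vertex counts differ across runs")
  amp <- do.call(rbind, lapply(runs, function(r) r$amplitudes))
  labels <- do.call(rbind, lapply(runs, function(r) r$labels))
  rownames(labels) <- NULL
  counts <- table(labels$condition, labels$direction)
  if (length(unique(as.vector(counts))) != 1)
    warning("unbalanced labels across runs")
  trial_matrix(amp, labels, provenance = runs[[1]]$provenance)
}

#' Subset a trial matrix by trial or vertex
#'
#' @param tm a `trial_matrix`
#' @param trials logical/integer index over trials (default all)
#' @param vertices logical/integer index over vertices (default all)
#' @return a `trial_matrix`
#' @export
subset_trials <- function(tm, trials = NULL, vertices = NULL) {
  stopifnot(inherits(tm, "trial_matrix"))
  trials <- trials %||% seq_len(nrow(tm$amplitudes))
  vertices <- vertices %||% seq_len(ncol(tm$amplitudes))
  trial_matrix(tm$amplitudes[trials, vertices, drop = FALSE],
               tm$labels[trials, , drop = FALSE], tm$provenance)
}
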