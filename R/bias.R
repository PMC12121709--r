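#' Filter vertices by pRF quality
#'
#' Keeps vertices with estimated eccentricity within 0.2-8 degrees and pRF
#' model variance explained above 5 percent.
#'
#' @param pop a [sample_vertices()] population
#' @param ecc_range eccentricity bounds, deg (inclusive)
#' @param min_ve variance-explained threshold (exclusive)
#' @return integer vector of surviving vertex indices
#' @export
filter_vertices <- function(pop, ecc_range = c(0.2, 8), min_ve = 0.05) {
  if (is.null(pop$ecc) || is.null(pop$ve))
    stop("population lacks `ecc`/`ve` fields")
  ids <- which(pop$ecc >= ecc_range[1] & pop$ecc <= ecc_range[2] &
                 pop$ve > min_ve)
  if (length(ids) == 0) message("vertex filter left no vertices")
  ids
}

#' Split vertices into central and edge sub-ROIs by eccentricity
#'
#' Central covers pRF eccentricities in `[0.2, bound)`, edge covers
#' `[bound, 8]`; a vertex at exactly the boundary goes to the edge group.
#'
#' @param ids filtered vertex indices (from [filter_vertices()])
#' @param pop the vertex population
#' @param bound eccentricity boundary, deg (default 4)
#' @return an object of class `subroi_split`: list with `kind`, `groups`
#'   (named list of index vectors), `params`
#' @export
split_eccentricity <- function(ids, pop, bound = 4) {
  central <- ids[pop$ecc[ids] < bound]
  edge <- ids[pop$ecc[ids] >= bound]
  if (length(central) < 2 || length(edge) < 2)
    warning("a sub-ROI has fewer than 2 vertices; downstream analyses will skip it")
  structure(list(kind = "eccentricity",
                 groups = list(central = central, edge = edge),
                 params = list(bound = bound)),
            class = "subroi_split")
}

#' Split vertices into horizontal-meridian and non-HM groups by polar angle
#'
#' HM vertices have pRF polar angles within `half_width` degrees of either
#' the right (0 deg) or left (180 deg) horizontal meridian.
#'
#' @param ids filtered vertex indices
#' @param pop the vertex population
#' @param half_width wedge half-width, deg (default 30)
#' @return a `subroi_split` with groups `hm` and `nhm`
#' @export
split_polar <- function(ids, pop, half_width = 30) {
  is_hm <- polar_is_hm(pop$polar[ids], half_width)
  structure(list(kind = "polar",
                 groups = list(hm = ids[is_hm], nhm = ids[!is_hm]),
                 params = list(half_width = half_width)),
            class = "subroi_split")
}

#' @export
print.subroi_split <- function(x, ...) {
  cat(sprintf("<subroi_split> %s: %s\n", x$kind,
              paste(sprintf("%s=%d", names(x$groups),
                            lengths(x$groups)), collapse = ", ")))
  invisible(x)
}

#' Mean BOLD amplitude per sub-ROI group
#'
#' Averages trial amplitudes over trials and vertices within each group of a
#' sub-ROI split and reports the between-group difference (first group minus
#' second).
#'
#' @param tm a `trial_matrix`
#' @param split a `subroi_split`
#' @param condition optional cue-condition filter
#' @param rotated optional rotated-flag filter
#' @param by_direction if `TRUE`, also return per-direction group means
#' @return list with `group_means`, `difference`
#'   (= `group_means[1] - group_means[2]`), and optionally `by_direction`
#' @export
bold_group_means <- function(tm, split, condition = NULL, rotated = NULL,
                             by_direction = FALSE) {
  stopifnot(inherits(tm, "trial_matrix"), inherits(split, "subroi_split"))
  keep <- rep(TRUE, nrow(tm$amplitudes))
  if (!is.null(condition)) keep <- keep & tm$labels$condition %in% condition
  if (!is.null(rotated)) keep <- keep & tm$labels$rotated == rotated
  gm <- vapply(split$groups, function(ids) {
    if (length(ids) == 0) {
      warning("empty sub-ROI group; NaN returned")
      return(NaN)
    }
    mean(tm$amplitudes[keep, ids, drop = FALSE])
  }, numeric(1))
  out <- list(group_means = gm, difference = unname(gm[1] - gm[2]))
  if (by_direction) {
    dirs <- unique(tm$labels$direction[keep])
    out$by_direction <- sapply(dirs, function(d) {
      k2 <- keep & tm$labels$direction == d
      vapply(split$groups, function(ids)
        mean(tm$amplitudes[k2, ids, drop = FALSE]), numeric(1))
    })
  }
  out
}

#' Fit BOLD amplitude against pRF eccentricity
#'
#' Takes long-format data (one row per participant x vertex with the vertex's
#' mean response and eccentricity) and estimates the eccentricity slope.
#' `method = "lmm"` fits a linear mixed-effects model with a fixed
#' eccentricity slope and by-participant random intercepts and slopes;
#' `method = "slopes"` fits per-participant least-squares slopes and tests
#' them against zero with a one-sample t test. Both routes must agree in sign
#' and significance on well-powered simulations.
#'
#' @param data data.frame with columns `participant`, `ecc`, `amplitude`
#' @param method `"lmm"` or `"slopes"`
#' @return list with `slopes` (per participant), `slope` (group estimate),
#'   `statistic`, `p`, `method`
#' @export
bold_eccentricity_fit <- function(data, method = c("lmm", "slopes")) {
  method <- match.arg(method)
  stopifnot(all(c("participant", "ecc", "amplitude") %in% names(data)))
  if (stats::sd(data$ecc) < 1e-12) stop("eccentricity is constant; slope undefined")
  per_part <- split(data, data$participant)
  if (any(vapply(per_part, nrow, integer(1)) < 3))
    stop("need at least 3 vertices per participant")
  slopes <- vapply(per_part, function(d)
    unname(stats::coef(stats::lm(amplitude ~ ecc, data = d))[2]), numeric(1))
  if (method == "lmm" && length(per_part) >= 2) {
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(amplitude ~ ecc + (1 + ecc | participant), data = data)))
    cf <- stats::coef(summary(fit))
    list(slopes = slopes, slope = cf["ecc", "Estimate"],
         statistic = cf["ecc", "t value"], p = cf["ecc", "Pr(>|t|)"],
         method = "lmm")
  } else {
    if (length(slopes) < 2 || stats::sd(slopes) < 1e-10) {
      # noise-free or single-participant case: the slope is a constant
      p <- if (abs(mean(slopes)) < 1e-10) 1 else 0
      return(list(slopes = slopes, slope = mean(slopes),
                  statistic = if (p == 0) Inf * sign(mean(slopes)) else 0,
                  p = p, method = "slopes"))
    }
    tt <- stats::t.test(slopes)
    list(slopes = slopes, slope = mean(slopes),
         statistic = unname(tt$statistic), p = tt$p.value, method = "slopes")
  }
}

#' Decoding-accuracy bias between vertex-count-equated sub-ROIs
#'
#' Decodes motion direction separately within each group of a sub-ROI split.
#' To make the two groups comparable, the larger group is subsampled to the
#' size of the smaller one; this is repeated `n_resample` times and
#' accuracies are averaged over draws. The bias is the difference in decoding
#' accuracy, first group minus second, in percentage points.
#'
#' @param tm a `trial_matrix`
#' @param split a `subroi_split`
#' @param condition optional cue-condition filter
#' @param rotated optional rotated-flag filter
#' @param n_resample number of vertex-equating draws (default 500)
#' @param n_boot bootstrap splits per decode
#' @param seed RNG seed
#' @return list with `bias` (percentage points), `accuracy` (per group),
#'   `equated_n`, `n_resample`; `NULL` (with a warning) if a group has fewer
#'   than 2 vertices
#' @export
equated_subroi_decoding <- function(tm, split, condition = NULL,
                                    rotated = NULL, n_resample = 500,
                                    n_boot = 200, seed = NULL) {
  stopifnot(inherits(tm, "trial_matrix"), inherits(split, "subroi_split"))
  sizes <- lengths(split$groups)
  if (any(sizes < 2)) {
    warning("sub-ROI group with fewer than 2 vertices; skipping")
    return(NULL)
  }
  if (!is.null(seed)) set.seed(seed)
  n_eq <- min(sizes)
  acc <- matrix(NA_real_, n_resample, length(split$groups),
                dimnames = list(NULL, names(split$groups)))
  for (r in seq_len(n_resample)) {
    for (g in seq_along(split$groups)) {
      ids <- split$groups[[g]]
      if (length(ids) > n_eq) ids <- sample(ids, n_eq)
      res <- decode_direction(subset_trials(tm, vertices = ids),
                              condition = condition, rotated = rotated,
                              n_boot = n_boot)
      acc[r, g] <- res$mean_accuracy
    }
  }
  mean_acc <- colMeans(acc)
  list(bias = unname(100 * (mean_acc[1] - mean_acc[2])),
       accuracy = mean_acc, equated_n = n_eq, n_resample = n_resample,
       per_draw = acc)
}
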