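#' Balanced train/test split
#'
#' Randomly splits trials into a test set with equal counts per direction
#' (per class: `max(1, round(test_fraction * class size))` trials) and a
#' training set containing everything else.
#'
#' @param labels character or factor vector of class labels (two classes)
#' @param test_fraction fraction of each class assigned to test (default 0.10)
#' @param seed optional RNG seed
#' @return list with integer vectors `train` and `test`
#' @export
balanced_split <- function(labels, test_fraction = 0.10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2) stop("need at least two classes to split")
  test <- unlist(lapply(classes, function(cl) {
    idx <- which(labels == cl)
    n_test <- max(1L, round(test_fraction * length(idx)))
    sample(idx, n_test)
  }))
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

# standardize columns using training-fold statistics only
fold_standardize <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sd_ <- apply(x_train, 2, stats::sd)
  sd_[sd_ < 1e-12] <- 1
  list(train = sweep(sweep(x_train, 2, mu, "-"), 2, sd_, "/"),
       test = sweep(sweep(x_test, 2, mu, "-"), 2, sd_, "/"))
}

#' Decode motion direction from single-trial amplitudes
#'
#' Linear support-vector-machine decoding of toward vs away with balanced
#' bootstrap splits (10:90 test:train by default) and a matched shuffled-label
#' null: for every bootstrap split the classifier is retrained with the
#' training labels randomly permuted (test labels intact) and scored on the
#' same test set. Features are standardized with training-fold statistics
#' only.
#'
#' @param tm a `trial_matrix`
#' @param condition optional cue condition (or vector of conditions) to
#'   decode; `NULL` uses all trials
#' @param rotated optional logical filter on the rotated flag
#' @param n_boot number of bootstrap splits (default 5000)
#' @param test_fraction test fraction per split
#' @param seed RNG seed
#' @param cost SVM regularization constant C
#' @param kernel SVM kernel (default `"linear"`)
#' @return an object of class `accuracy_result`: list with `boot_acc`,
#'   `null_acc` (length `n_boot` each), `mean_accuracy`, `ci` (2.5/97.5
#'   percentiles), `null_ci`, and metadata
#' @export
decode_direction <- function(tm, condition = NULL, rotated = NULL,
                             n_boot = 5000, test_fraction = 0.10,
                             seed = NULL, cost = 1, kernel = "linear") {
  stopifnot(inherits(tm, "trial_matrix"))
  if (n_boot < 1) stop("`n_boot` must be >= 1")
  keep <- rep(TRUE, nrow(tm$amplitudes))
  if (!is.null(condition)) keep <- keep & tm$labels$condition %in% condition
  if (!is.null(rotated)) keep <- keep & tm$labels$rotated == rotated
  x <- tm$amplitudes[keep, , drop = FALSE]
  y <- factor(tm$labels$direction[keep])
  if (nrow(x) < 20) stop("fewer than 20 trials after filtering")
  if (!all(is.finite(x))) stop("non-finite features")
  if (nlevels(y) < 2) stop("only one class present after filtering")
  if (!is.null(seed)) set.seed(seed)
  boot_acc <- numeric(n_boot)
  null_acc <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    sp <- balanced_split(y, test_fraction)
    st <- fold_standardize(x[sp$train, , drop = FALSE],
                           x[sp$test, , drop = FALSE])
    y_train <- y[sp$train]
    y_test <- y[sp$test]
    fit <- e1071::svm(st$train, y_train, kernel = kernel, cost = cost,
                      scale = FALSE)
    boot_acc[b] <- mean(predict(fit, st$test) == y_test)
    null_fit <- e1071::svm(st$train, sample(y_train), kernel = kernel,
                           cost = cost, scale = FALSE)
    null_acc[b] <- mean(predict(null_fit, st$test) == y_test)
  }
  structure(list(boot_acc = boot_acc, null_acc = null_acc,
                 mean_accuracy = mean(boot_acc),
                 ci = stats::quantile(boot_acc, c(0.025, 0.975)),
                 null_ci = stats::quantile(null_acc, c(0.025, 0.975)),
                 n_boot = n_boot, test_fraction = test_fraction,
                 condition = condition, rotated = rotated,
                 n_trials = nrow(x), n_vertices = ncol(x)),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf(
    "<accuracy_result> mean %.3f [%.3f, %.3f], null 95%% [%.3f, %.3f], n_boot %d\n",
    x$mean_accuracy, x$ci[1], x$ci[2], x$null_ci[1], x$null_ci[2], x$n_boot))
  invisible(x)
}

#' Average the two perspective-cue decoding results
#'
#' Element-wise mean of matched bootstrap (and null) distributions from the
#' left-eye and right-eye perspective conditions; reported perspective-cue
#' accuracy is this average.
#'
#' @param left,right `accuracy_result` objects with equal `n_boot`
#' @return an `accuracy_result`
#' @export
perspective_average <- function(left, right) {
  stopifnot(inherits(left, "accuracy_result"),
            inherits(right, "accuracy_result"))
  if (left$n_boot != right$n_boot) stop("mismatched n_boot")
  boot <- (left$boot_acc + right$boot_acc) / 2
  null <- (left$null_acc + right$null_acc) / 2
  structure(list(boot_acc = boot, null_acc = null,
                 mean_accuracy = mean(boot),
                 ci = stats::quantile(boot, c(0.025, 0.975)),
                 null_ci = stats::quantile(null, c(0.025, 0.975)),
                 n_boot = left$n_boot, test_fraction = left$test_fraction,
                 condition = union(left$condition, right$condition),
                 rotated = left$rotated,
                 n_trials = left$n_trials + right$n_trials,
                 n_vertices = left$n_vertices),
            class = "accuracy_result")
}
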