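#' Wilcoxon signed-rank test with exact small-sample p-values
#'
#' Tests whether paired differences are symmetric about zero. W is the sum of
#' the ranks (of absolute differences, average ranks for ties) carried by
#' positive differences. Zero differences are dropped before ranking. For
#' n <= `exact_max` pairs the two-sided p-value is computed by full
#' enumeration of all 2^n sign assignments (via a polynomial/convolution
#' recursion over the realized ranks, so ties are handled exactly); above
#' that, a normal approximation with tie and continuity corrections is used.
#'
#' @param x numeric vector (condition A, or precomputed differences)
#' @param y optional numeric vector (condition B), same length as `x`
#' @param exact_max largest n for exact enumeration (default 15)
#' @return list with `W`, `p` (two-sided), `n` (non-zero pairs), `method`
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 15) {
  d <- if (is.null(y)) x else x - y
  stopifnot(all(is.finite(d)))
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero; test undefined")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    # doubled ranks are integers even with average-rank ties
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- c(1, rep(0, total))   # counts[s + 1] = #assignments with 2W = s
    for (ri in r2) {
      shifted <- c(rep(0, ri), counts[seq_len(total + 1 - ri)])
      counts <- counts + shifted
    }
    w2 <- as.integer(round(2 * W))
    p_le <- sum(counts[seq_len(w2 + 1)]) / 2^n
    p_ge <- sum(counts[(w2 + 1):(total + 1)]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(W = W, p = p, n = n, method = method)
}

#' Mann-Whitney U test with exact small-sample p-values
#'
#' Rank-sum test for a location difference between two independent samples.
#' U counts the pairs (a_i, b_j) with a_i > b_j, plus half the tied pairs.
#' When the combined sample size is <= `exact_max`, the two-sided p-value is
#' computed by enumerating all C(n+m, n) assignments of the observed values
#' to the two groups (ties handled exactly); otherwise a normal approximation
#' with tie and continuity corrections is used.
#'
#' @param a,b numeric vectors
#' @param exact_max largest combined n for exact enumeration (default 12)
#' @return list with `U`, `p` (two-sided), `n` (c(n_a, n_b)), `method`
#' @export
mann_whitney_u <- function(a, b, exact_max = 12) {
  stopifnot(length(a) >= 1, length(b) >= 1,
            all(is.finite(a)), all(is.finite(b)))
  u_stat <- function(av, bv) {
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  U <- u_stat(a, b)
  n <- length(a)
  m <- length(b)
  if (n + m <= exact_max) {
    pool <- c(a, b)
    combos <- utils::combn(n + m, n)
    us <- apply(combos, 2, function(idx) u_stat(pool[idx], pool[-idx]))
    eps <- 1e-9
    p_le <- mean(us <= U + eps)
    p_ge <- mean(us >= U - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * m / 2
    nt <- n + m
    ties <- table(c(a, b))
    sigma2 <- n * m / 12 *
      ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(U = U, p = p, n = c(length(a), length(b)), method = method)
}

#' Mixed-model contrast for decoding accuracy
#'
#' Fits `response ~ factor1 * factor2 + (1 | participant)` by REML
#' (lmerTest/lme4) and returns the requested fixed-effect test: the
#' interaction by default, or a named main effect. Requires at least two
#' participants and a complete factorial design; missing cells raise an
#' error naming the absent combinations.
#'
#' @param data long-format data.frame
#' @param response name of the response column
#' @param factors character vector of two factor column names
#' @param participant name of the participant column
#' @param term `"interaction"` or one of `factors`
#' @return list with `statistic` (F), `df`, `p`, `term`, `model`
#' @export
mixed_model_contrast <- function(data, response = "accuracy",
                                 factors = c("cue", "roi"),
                                 participant = "participant",
                                 term = "interaction") {
  stopifnot(all(c(response, factors, participant) %in% names(data)))
  if (length(unique(data[[participant]])) < 2)
    stop("need at least 2 participants for a random participant effect")
  cells <- table(data[[factors[1]]], data[[factors[2]]])
  if (any(cells == 0)) {
    missing_cells <- which(cells == 0, arr.ind = TRUE)
    stop("missing factor combinations: ",
         paste(sprintf("%s x %s", rownames(cells)[missing_cells[, 1]],
                       colnames(cells)[missing_cells[, 2]]), collapse = ", "))
  }
  data[[participant]] <- factor(data[[participant]])
  data[[factors[1]]] <- factor(data[[factors[1]]])
  data[[factors[2]]] <- factor(data[[factors[2]]])
  fml <- stats::as.formula(sprintf("%s ~ %s * %s + (1 | %s)", response,
                                   factors[1], factors[2], participant))
  fit <- suppressMessages(suppressWarnings(lmerTest::lmer(fml, data = data)))
  an <- stats::anova(fit)
  row <- if (term == "interaction") sprintf("%s:%s", factors[1], factors[2])
         else term
  if (!row %in% rownames(an)) stop("term not found in the model: ", row)
  list(statistic = an[row, "F value"],
       df = c(an[row, "NumDF"], an[row, "DenDF"]),
       p = an[row, "Pr(>F)"], term = row, model = fit)
}
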