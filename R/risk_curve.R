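#' Weibull mean risk curve
#'
#' The continuous mean risk curve maps a difficulty score x to an IOC
#' probability through the Weibull cumulative distribution function
#' \deqn{y_W(x) = 1 - e^{-(x/\lambda)^k},}
#' with scale \eqn{\lambda} (score units) and shape \eqn{k} (dimensionless).
#'
#' @param scale_lambda Positive scale parameter, in score units.
#' @param shape_k Positive shape parameter.
#' @return An object of class `weibull_curve`.
#' @examples
#' weibull_curve(8.085, 2.871)
#' @export
weibull_curve <- function(scale_lambda, shape_k) {
  if (!is.numeric(scale_lambda) || length(scale_lambda) != 1 ||
      is.na(scale_lambda) || scale_lambda <= 0) {
    stop("`scale_lambda` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(shape_k) || length(shape_k) != 1 || is.na(shape_k) ||
      shape_k <= 0) {
    stop("`shape_k` must be a single positive number", call. = FALSE)
  }
  structure(list(scale_lambda = as.numeric(scale_lambda),
                 shape_k = as.numeric(shape_k)),
            class = "weibull_curve")
}

#' @export
print.weibull_curve <- function(x, ...) {
  cat(sprintf("Weibull risk curve: lambda = %.4f (scale), k = %.4f (shape)\n",
              x$scale_lambda, x$shape_k))
  if (!is.null(attr(x, "objective"))) {
    cat(sprintf("  least-squares objective: %.6g over %d points\n",
                attr(x, "objective"), attr(x, "n_points")))
  }
  invisible(x)
}

#' Weibull CDF of the risk curve
#'
#' @param x Non-negative difficulty score(s).
#' @param curve A [weibull_curve()].
#' @return Probabilities `1 - exp(-(x/lambda)^k)`.
#' @examples
#' weibull_cdf(6, weibull_curve(8.085, 2.871))
#' @export
weibull_cdf <- function(x, curve) {
  stopifnot(inherits(curve, "weibull_curve"))
  if (any(is.na(x)) || any(x < 0)) {
    stop("`x` must be non-negative", call. = FALSE)
  }
  stats::pweibull(x, shape = curve$shape_k, scale = curve$scale_lambda)
}

#' Published per-score IOC risk table
#'
#' The per-score risk of intraoperative complication reported by the external
#' validation study of the difficulty scoring system: scores 0-2 carry 0%
#' risk, scores 3-9 the observed 7/11/13/50/57/50/67%, and scores 10-15 100%
#' (risk assumed equal to 1 above a score of 10, both score-10 patients in
#' the study having had an IOC).
#'
#' @return data.frame with columns `score_min`, `score_max`, `risk`.
#' @export
halls_risk_table <- function() {
  data.frame(
    score_min = c(0L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L),
    score_max = c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 15L),
    risk = c(0, 0.07, 0.11, 0.13, 0.50, 0.57, 0.50, 0.67, 1)
  )
}

#' Expand a score-range risk table to per-score points
#'
#' Replicates each range's risk at every integer score it covers and flags
#' scores above `assume_unity_above` as `assumed` (their risk is an
#' assumption, not an observation).
#'
#' @param table data.frame with columns `score_min`, `score_max`, `risk`;
#'   ranges must be contiguous (no gaps, no overlaps) and risks in \[0, 1\].
#' @param assume_unity_above Integer or `NULL`; scores strictly above it are
#'   flagged `assumed`.  Default 10, the study's convention.
#' @return data.frame `score`, `risk`, `provenance` (`observed`/`assumed`)
#'   with strictly increasing scores; class `risk_points`.
#' @examples
#' expand_risk_table(halls_risk_table())
#' @export
expand_risk_table <- function(table, assume_unity_above = 10) {
  stopifnot(all(c("score_min", "score_max", "risk") %in% names(table)))
  table <- table[order(table$score_min), , drop = FALSE]
  if (any(table$risk < 0 | table$risk > 1)) {
    stop("risks must lie in [0, 1]", call. = FALSE)
  }
  if (any(table$score_max < table$score_min)) {
    stop("score_max must be >= score_min in every range", call. = FALSE)
  }
  if (nrow(table) > 1) {
    gaps <- table$score_min[-1] - table$score_max[-nrow(table)]
    if (any(gaps != 1)) {
      stop("score ranges must be contiguous (no gaps or overlaps)", call. = FALSE)
    }
  }
  score <- unlist(Map(seq, table$score_min, table$score_max))
  risk <- rep(table$risk, table$score_max - table$score_min + 1)
  provenance <- rep("observed", length(score))
  if (!is.null(assume_unity_above)) {
    provenance[score > assume_unity_above] <- "assumed"
  }
  structure(data.frame(score = as.numeric(score), risk = risk,
                       provenance = provenance, stringsAsFactors = FALSE),
            class = c("risk_points", "data.frame"))
}

# Least-squares objective and analytic gradient for the Weibull CDF fit.
# p = c(lambda, k); returns list(value, gradient).
weibull_ls_objective <- function(p, x, y, w) {
  lambda <- p[1]; k <- p[2]
  t <- (x / lambda)^k           # 0^k = 0 for k > 0, x >= 0
  f <- 1 - exp(-t)
  r <- y - f
  value <- sum(w * r^2)
  # dF/dlambda = -exp(-t) * t * k / lambda ; dF/dk = exp(-t) * t * log(x/lambda)
  et <- exp(-t)
  logs <- ifelse(x > 0, log(x / lambda), 0)
  dF_dl <- -et * t * k / lambda
  dF_dk <- et * t * logs
  grad <- c(-2 * sum(w * r * dF_dl), -2 * sum(w * r * dF_dk))
  list(value = value, gradient = grad)
}

#' Fit the Weibull risk curve by nonlinear least squares
#'
#' Minimises \eqn{\sum_i w_i (risk_i - y_W(score_i))^2} over
#' \eqn{\lambda > 0, k > 0} with a bounded quasi-Newton optimiser (L-BFGS-B,
#' analytic gradient, objective tolerance 1e-10).  If the default start
#' (\eqn{\lambda_0} = midpoint of the score range, \eqn{k_0 = 2}) stalls, three
#' further documented starts are tried and the best minimum is kept.
#'
#' The fit is unweighted by default, treating every per-score point equally;
#' `weights` (e.g. the number of patients observed at each score) switches to
#' a weighted fit.
#'
#' @param points A `risk_points` data.frame (see [expand_risk_table()]) or any
#'   data.frame with `score` and `risk` columns; needs >= 3 points with at
#'   least two distinct risks.
#' @param init Optional `c(lambda0, k0)` start.
#' @param weights Optional non-negative weights, one per point.
#' @return A [weibull_curve()] with attributes `objective` (residual sum of
#'   squares), `n_points` and `convergence`.
#' @examples
#' fit_weibull(expand_risk_table(halls_risk_table()))
#' @export
fit_weibull <- function(points, init = NULL, weights = NULL) {
  stopifnot(all(c("score", "risk") %in% names(points)))
  x <- as.numeric(points$score)
  y <- as.numeric(points$risk)
  if (length(x) < 3 || length(unique(y)) < 2) {
    stop("need >= 3 points with at least two distinct risks", call. = FALSE)
  }
  if (any(x < 0) || any(y < 0 | y > 1)) {
    stop("scores must be non-negative and risks in [0, 1]", call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, length(x)) else as.numeric(weights)
  if (length(w) != length(x) || any(w < 0)) {
    stop("`weights` must be non-negative, one per point", call. = FALSE)
  }
  starts <- list(if (is.null(init)) c(mean(range(x)), 2) else as.numeric(init),
                 c(mean(range(x)), 1),
                 c(max(x[x > 0], 1), 3),
                 c(stats::median(x[x > 0]), 0.5))
  fn <- function(p) weibull_ls_objective(p, x, y, w)$value
  gr <- function(p) weibull_ls_objective(p, x, y, w)$gradient
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, fn, gr, method = "L-BFGS-B",
                   lower = c(1e-8, 1e-8), upper = c(1e6, 1e3),
                   control = list(maxit = 1000, factr = 1e-10 / .Machine$double.eps)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("Weibull fit failed from all starting points", call. = FALSE)
  curve <- weibull_curve(best$par[1], best$par[2])
  attr(curve, "objective") <- best$value
  attr(curve, "n_points") <- length(x)
  attr(curve, "convergence") <- best$convergence
  curve
}

# Asymptotic Kolmogorov distribution Q(t) = 2 * sum_{j>=1} (-1)^{j-1} exp(-2 j^2 t^2),
# truncated at 100 terms; upper-tail probability of sqrt(n) * D.
kolmogorov_upper <- function(t, terms = 100) {
  if (t <= 0) return(1)
  j <- seq_len(terms)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))
  min(max(p, 0), 1)
}

#' One-sample Kolmogorov-Smirnov test against a Weibull risk curve
#'
#' Computes the exact supremum distance between the sample's empirical CDF
#' and the hypothesised Weibull CDF by scanning the jump points
#' (`D = max_i max(i/n - F(x_(i)), F(x_(i)) - (i-1)/n)`, ties permitted), and
#' an asymptotic p-value from the Kolmogorov distribution evaluated at
#' `sqrt(n) * D` (series truncated at 100 terms; exact small-sample tables
#' are not implemented).
#'
#' @param sample Non-empty numeric vector of non-negative values.
#' @param curve A [weibull_curve()].
#' @return List of class `llr_gof`: `ks_statistic`, `p_value`, `n`.
#' @export
ks_test_weibull <- function(sample, curve) {
  stopifnot(inherits(curve, "weibull_curve"))
  sample <- as.numeric(sample)
  if (length(sample) == 0 || any(is.na(sample))) {
    stop("`sample` must be non-empty with no missing values", call. = FALSE)
  }
  if (any(sample < 0)) stop("`sample` must be non-negative", call. = FALSE)
  n <- length(sample)
  xs <- sort(sample)
  f <- weibull_cdf(xs, curve)
  # ECDF is right-continuous; with ties, use cumulative counts at each value
  upper_step <- cumsum(rep(1 / n, n))          # F_n(x_(i)) ignoring ties...
  # handle ties: F_n at a tied value is the count of sample <= value
  ecdf_at <- stats::ecdf(xs)(xs)
  lower_step <- c(0, ecdf_at[-n])              # F_n just below x_(i)
  # at tied runs lower_step within the run overstates; recompute per value
  first_of_run <- !duplicated(xs)
  run_lower <- rep(lower_step[first_of_run], times = tabulate(cumsum(first_of_run)))
  d <- max(pmax(ecdf_at - f, f - run_lower))
  structure(list(ks_statistic = d,
                 p_value = kolmogorov_upper(sqrt(n) * d),
                 n = n),
            class = "llr_gof")
}

#' @export
print.llr_gof <- function(x, ...) {
  cat(sprintf("Kolmogorov-Smirnov: D = %.4f, p = %.4f (n = %d, asymptotic)\n",
              x$ks_statistic, x$p_value, x$n))
  invisible(x)
}

#' Mean IOC risk at a difficulty score
#'
#' Evaluates the fitted mean risk curve at a (possibly fractional) score.
#' Scores outside the 0-15 scoring range trigger a warning but the CDF value
#' is still returned.  The difficulty-level band of the integer-rounded score
#' is attached as an attribute `level`.
#'
#' @param score Numeric score(s).
#' @param curve A [weibull_curve()].
#' @return Probability vector with attribute `level`.
#' @examples
#' mean_risk(6, weibull_curve(8.085, 2.871))
#' @export
mean_risk <- function(score, curve) {
  if (any(score < 0 | score > 15)) {
    warning("score outside the 0-15 scoring range; CDF value still computed")
  }
  p <- weibull_cdf(pmax(score, 0), curve)
  rounded <- pmin(pmax(round(score), 0), 15)
  attr(p, "level") <- difficulty_level(rounded)
  p
}
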