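#' Encode the five risk factors as model covariates
#'
#' The multivariate models use x1 (neoadjuvant chemotherapy, 0/1), x2
#' (previous open liver resection, 0/1), x3 (malignant lesion, 0/1), x4
#' (lesion size) and x5 (resection class as ordinal 0/1/2 for
#' minor/technically major/anatomically major).  By default x4 is the
#' continuous size in centimetres — the published per-cm coefficient
#' (0.351) then yields about 3 score points for an 8-9 cm lesion, matching
#' the scoring table's 3-point ceiling — with the 0/1/2 size category
#' available as an alternative coding.
#'
#' @param cohort An `llr_cohort` or data.frame with the five factor columns.
#' @param size_coding `"cm"` (default) or `"category"`.
#' @return Numeric matrix with columns `x1`..`x5`.
#' @export
encode_covariates <- function(cohort, size_coding = c("cm", "category")) {
  size_coding <- match.arg(size_coding)
  size <- cohort$lesion_size_cm
  x4 <- if (size_coding == "cm") size else
    ifelse(size < 3, 0, ifelse(size <= 5, 1, 2))
  cbind(
    x1 = as.numeric(as.logical(cohort$neoadjuvant_chemotherapy)),
    x2 = as.numeric(as.logical(cohort$previous_open_liver_resection)),
    x3 = as.numeric(cohort$lesion_type == "malignant"),
    x4 = as.numeric(x4),
    x5 = c(minor = 0, technically_major = 1,
           anatomically_major = 2)[cohort$resection_class]
  )
}

#' Linear score model
#'
#' Construct a linear model of the difficulty score from an intercept and
#' five covariate coefficients (see [encode_covariates()]), e.g. to hold
#' published coefficients; [fit_linear()] estimates one by least squares.
#'
#' @param intercept Intercept.
#' @param coefficients Numeric vector of 5 coefficients for x1..x5.
#' @param standard_errors,p_values Optional vectors of 6 (intercept first).
#' @param r_squared Optional coefficient of determination.
#' @return Object of class `linear_score_model`.
#' @export
linear_score_model <- function(intercept, coefficients, standard_errors = NULL,
                               p_values = NULL, r_squared = NULL) {
  stopifnot(length(intercept) == 1, length(coefficients) == 5)
  structure(list(intercept = as.numeric(intercept),
                 coefficients = stats::setNames(as.numeric(coefficients),
                                                paste0("x", 1:5)),
                 standard_errors = standard_errors, p_values = p_values,
                 r_squared = r_squared),
            class = "linear_score_model")
}

#' @export
print.linear_score_model <- function(x, ...) {
  co <- c(intercept = x$intercept, x$coefficients)
  cat("Linear difficulty-score model:\n")
  print(round(co, 5))
  if (!is.null(x$r_squared)) cat(sprintf("R-squared: %.5f\n", x$r_squared))
  invisible(x)
}

#' Published multivariate linear approximation of the difficulty score
#'
#' The linear model estimated on the 128-patient external-validation cohort:
#' `y = -1.85180 + 0.67232 x1 + 1.48669 x2 + 2.12691 x3 + 0.35112 x4 +
#' 1.88364 x5` (all coefficient p-values < 0.01; reported R-squared against
#' the 0-15 score 0.83531), with x4 the lesion size in centimetres.
#'
#' @return A [linear_score_model()].
#' @examples
#' predict_linear(published_linear_model(), rbind(rep(0, 5)))
#' @export
published_linear_model <- function() {
  linear_score_model(
    intercept = -1.85180,
    coefficients = c(0.67232, 1.48669, 2.12691, 0.35112, 1.88364),
    standard_errors = c(0.258, 0.213, 0.435, 0.201, 0.033, 0.126),
    r_squared = 0.83531
  )
}

#' Fit the linear score model by ordinary least squares
#'
#' Least-squares fit of the score on the five covariates with the usual
#' normal-theory standard errors, two-sided t-test p-values on n - 6 degrees
#' of freedom, and R-squared = 1 - SSR/SST.
#'
#' A covariate that is constant in the cohort (e.g. no patient with a
#' previous open resection) is not estimable: its coefficient is set to 0
#' with `NA` standard error and p-value, and the model carries a
#' `dropped_constant` attribute naming it.  Genuine collinearity among
#' non-constant columns raises a singular-design error naming the columns.
#'
#' @param covariates Matrix from [encode_covariates()] (n x 5).
#' @param targets Numeric vector of difficulty scores (length n > 6).
#' @return A [linear_score_model()] with standard errors, p-values and
#'   R-squared filled in.
#' @export
fit_linear <- function(covariates, targets) {
  covariates <- as.matrix(covariates)
  stopifnot(ncol(covariates) == 5, nrow(covariates) == length(targets))
  if (length(targets) <= 6) stop("need n > 6 observations", call. = FALSE)
  colnames(covariates) <- paste0("x", 1:5)
  constant <- apply(covariates, 2, function(v) stats::var(v) == 0)
  active <- which(!constant)
  X <- covariates[, active, drop = FALSE]
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    stop("singular design: collinear column(s) among ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  }
  df <- data.frame(y = targets, X)
  fit <- stats::lm(stats::reformulate(colnames(X), "y"), data = df)
  sm <- summary(fit)
  co <- se <- pv <- rep(NA_real_, 5)
  co[active] <- stats::coef(fit)[-1]
  se[active] <- sm$coefficients[-1, "Std. Error"]
  pv[active] <- sm$coefficients[-1, "Pr(>|t|)"]
  co[constant] <- 0
  model <- linear_score_model(
    intercept = stats::coef(fit)[1],
    coefficients = co,
    standard_errors = c(sm$coefficients[1, "Std. Error"], se),
    p_values = c(sm$coefficients[1, "Pr(>|t|)"], pv),
    r_squared = if (stats::var(targets) == 0) 0 else sm$r.squared
  )
  if (any(constant)) {
    attr(model, "dropped_constant") <- paste0("x", which(constant))
  }
  model
}

#' Predict difficulty scores from a linear score model
#'
#' @param model A [linear_score_model()].
#' @param covariates Matrix (n x 5) or vector of length 5.
#' @return Numeric predictions `intercept + covariates %*% coefficients`.
#' @examples
#' predict_linear(published_linear_model(), c(1, 1, 1, 1, 1))
#' @export
predict_linear <- function(model, covariates) {
  stopifnot(inherits(model, "linear_score_model"))
  if (is.null(dim(covariates))) covariates <- matrix(covariates, nrow = 1)
  stopifnot(ncol(covariates) == 5)
  drop(model$intercept + as.matrix(covariates) %*% model$coefficients)
}

#' Fit a conditional-average (Gaussian kernel) score model
#'
#' The nonlinear counterpart of [fit_linear()]: a conditional average
#' estimator that stores the standardized training covariate/score pairs and
#' predicts by a normalized Gaussian-basis average (see [predict_cae()]).
#' Covariates are standardized to mean 0, standard deviation 1 (a zero-scale
#' column is centred only).  The single free parameter, the Gaussian
#' smoothing width in standardized units, is either supplied or selected by
#' leave-one-out cross-validation minimizing mean squared prediction error
#' over 25 logarithmically spaced widths in \[0.05, 5\].
#'
#' @param covariates Matrix (n x 5), n >= 3.
#' @param targets Numeric score vector.
#' @param width Positive width, or `"auto"` (default) for LOO selection.
#' @return Object of class `cae_model`: exemplars, standardization,
#'   `smoothing_width`, and `loo_mse` when auto-selected.
#' @export
fit_cae <- function(covariates, targets, width = "auto") {
  covariates <- as.matrix(covariates)
  n <- nrow(covariates)
  stopifnot(n == length(targets), n >= 3)
  center <- colMeans(covariates)
  scale <- apply(covariates, 2, stats::sd)
  scale[scale == 0] <- 1                      # centred only
  z <- sweep(sweep(covariates, 2, center), 2, scale, "/")

  d2 <- as.matrix(stats::dist(z))^2
  loo_mse_for <- function(sigma) {
    w <- exp(-d2 / (2 * sigma^2))
    diag(w) <- 0
    num <- w %*% targets
    den <- rowSums(w)
    pred <- ifelse(den > 0, num / den,
                   targets[apply(d2 + diag(Inf, n), 1, which.min)])
    mean((pred - targets)^2)
  }
  loo_mse <- NULL
  if (identical(width, "auto")) {
    grid <- exp(seq(log(0.05), log(5), length.out = 25))
    mses <- vapply(grid, loo_mse_for, numeric(1))
    width <- grid[which.min(mses)]
    loo_mse <- min(mses)
  }
  width <- as.numeric(width)
  if (is.na(width) || width <= 0) stop("`width` must be positive", call. = FALSE)
  structure(list(exemplars_z = z, targets = as.numeric(targets),
                 center = center, scale = scale,
                 smoothing_width = width, loo_mse = loo_mse),
            class = "cae_model")
}

#' @export
print.cae_model <- function(x, ...) {
  cat(sprintf("Conditional-average (Gaussian kernel) model: %d exemplars, width %.4g%s\n",
              nrow(x$exemplars_z), x$smoothing_width,
              if (!is.null(x$loo_mse)) sprintf(" (LOO MSE %.4g)", x$loo_mse) else ""))
  invisible(x)
}

#' Predict from a conditional-average model
#'
#' Prediction at query v is the Gaussian-weighted average of exemplar scores,
#' `sum(y_n w_n) / sum(w_n)` with `w_n = exp(-||z - z_n||^2 / (2 sigma^2))`
#' over standardized vectors; if all weights underflow to zero the nearest
#' exemplar's score is returned.  Predictions are convex combinations of the
#' training scores and therefore always lie within their range.
#'
#' @param model A `cae_model`.
#' @param covariates Matrix (m x 5) or vector of length 5, raw (unscaled).
#' @return Numeric predictions.
#' @export
predict_cae <- function(model, covariates) {
  stopifnot(inherits(model, "cae_model"))
  if (is.null(dim(covariates))) covariates <- matrix(covariates, nrow = 1)
  z <- sweep(sweep(as.matrix(covariates), 2, model$center), 2, model$scale, "/")
  sigma2 <- model$smoothing_width^2
  apply(z, 1, function(q) {
    d2 <- colSums((t(model$exemplars_z) - q)^2)
    w <- exp(-d2 / (2 * sigma2))
    s <- sum(w)
    if (s == 0) model$targets[which.min(d2)] else sum(model$targets * w) / s
  })
}

#' Compare model scores with the reference difficulty score
#'
#' Reproduces the score-comparison metrics of the validation study: Pearson
#' correlation, the through-origin regression slope k in `m = k h`, the
#' affine least-squares fit `m = a h + b` with its R-squared, and summaries
#' of the residuals `m - h` (mean, median, mode and maximum absolute value).
#' Residuals are continuous, so the mode is the maximizer of a Gaussian
#' kernel density (Silverman rule-of-thumb bandwidth) on a 1001-point grid
#' over the residual range.
#'
#' @param model_scores Numeric vector of model predictions.
#' @param halls_scores Numeric vector of reference difficulty scores (same
#'   length, >= 3, not all zero).
#' @return List of class `score_comparison`: `pearson_r`,
#'   `slope_through_origin`, `affine_slope`, `affine_intercept`, `r_squared`,
#'   `residual_mean`, `residual_median`, `residual_mode`,
#'   `residual_max_abs`.
#' @export
compare_scores <- function(model_scores, halls_scores) {
  m <- as.numeric(model_scores); h <- as.numeric(halls_scores)
  stopifnot(length(m) == length(h), length(m) >= 3)
  if (all(h == 0)) stop("reference scores must not be all zero", call. = FALSE)
  r <- if (stats::sd(m) == 0 || stats::sd(h) == 0) NA_real_ else stats::cor(m, h)
  k <- sum(m * h) / sum(h * h)
  a <- if (stats::var(h) == 0) NA_real_ else stats::cov(m, h) / stats::var(h)
  b <- mean(m) - a * mean(h)
  fitted <- a * h + b
  sst <- sum((m - mean(m))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum((m - fitted)^2) / sst
  res <- m - h
  mode_val <- if (stats::sd(res) == 0 || diff(range(res)) == 0) res[1] else {
    d <- stats::density(res, bw = stats::bw.nrd0(res), n = 1001,
                        from = min(res), to = max(res))
    d$x[which.max(d$y)]
  }
  structure(list(pearson_r = r, slope_through_origin = k,
                 affine_slope = a, affine_intercept = b, r_squared = r2,
                 residual_mean = mean(res),
                 residual_median = stats::median(res),
                 residual_mode = mode_val,
                 residual_max_abs = max(abs(res))),
            class = "score_comparison")
}

#' @export
print.score_comparison <- function(x, ...) {
  cat(sprintf("Score comparison: r = %.4f, m = %.5f h, m = %.5f h + %.5f (R2 = %.5f)\n",
              x$pearson_r, x$slope_through_origin, x$affine_slope,
              x$affine_intercept, x$r_squared))
  cat(sprintf("  residuals (model - reference): mean %.5f, median %.5f, mode %.5f, max |r| %.3f\n",
              x$residual_mean, x$residual_median, x$residual_mode,
              x$residual_max_abs))
  invisible(x)
}
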