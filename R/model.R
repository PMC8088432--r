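# The frozen predictive model, its centered variant, the compact
# baseline-only model, and the flexible re-estimated GLM.

#' The frozen predictive model
#'
#' Coefficients of the fixed-coefficient model under external validation:
#' predicted change in LSAS is
#' `0.6194 * baseline_LSAS + 8.6290 * amyg_conn - 9.9763`,
#' where `amyg_conn` is the cohort-standardized composite connectivity term.
#' The `centered` variant drops the intercept and expects cohort
#' mean-centered inputs (the modification used when porting the model to a
#' new sample, since intercepts are expected to vary between studies).
#'
#' @param beta_baseline Change-score points per baseline LSAS point.
#' @param beta_conn Change-score points per SD of the connectivity term.
#' @param intercept Intercept in change-score points (unused when
#'   `centered = TRUE`).
#' @param centered Use the intercept-free, mean-centered convention
#'   (default `TRUE`, the external-validation route).
#' @return An object of class `fixed_model_spec`.
#' @export
fixed_model_spec <- function(beta_baseline = 0.6194,
                             beta_conn = 8.6290,
                             intercept = -9.9763,
                             centered = TRUE) {
  structure(
    list(beta_baseline = beta_baseline, beta_conn = beta_conn,
         intercept = intercept, centered = isTRUE(centered)),
    class = "fixed_model_spec"
  )
}

#' @export
print.fixed_model_spec <- function(x, ...) {
  cat(sprintf(
    "<fixed_model_spec> dLSAS = %.4f * baseline + %.4f * amyg_conn%s [%s]\n",
    x$beta_baseline, x$beta_conn,
    if (x$centered) "" else sprintf(" + %.4f", x$intercept),
    if (x$centered) "centered, no intercept" else "original scale"
  ))
  invisible(x)
}

#' Predict treatment response with the frozen full model
#'
#' Evaluates the fixed-coefficient model. In the uncentered convention the
#' intercept is included and raw inputs are expected; in the centered
#' convention the intercept is dropped and `baseline_lsas` must already be
#' cohort mean-centered (`amyg_conn` is mean-zero by construction of the
#' cohort z-score).
#'
#' @param spec A [fixed_model_spec()].
#' @param baseline_lsas Baseline severity (raw or centered per `spec$centered`).
#' @param amyg_conn Standardized composite connectivity term.
#' @return Predicted change in LSAS (points).
#' @export
predict_fixed <- function(spec, baseline_lsas, amyg_conn) {
  stopifnot(inherits(spec, "fixed_model_spec"))
  if (any(!is.finite(baseline_lsas)) || any(!is.finite(amyg_conn))) {
    abort("Model inputs must be finite.")
  }
  out <- spec$beta_baseline * baseline_lsas + spec$beta_conn * amyg_conn
  if (!spec$centered) out <- out + spec$intercept
  out
}

#' Predict treatment response with the compact baseline-only model
#'
#' The benchmark the biomarker must beat: the frozen model with the
#' connectivity term forced to zero.
#'
#' @inheritParams predict_fixed
#' @return Predicted change in LSAS (points).
#' @export
predict_compact <- function(spec, baseline_lsas) {
  predict_fixed(spec, baseline_lsas, amyg_conn = 0)
}

#' Re-estimate the model terms by ordinary least squares
#'
#' The flexible replication route: fits a GLM of the outcome on the supplied
#' regressors (intercept always included) with classical standard errors and
#' two-tailed t probabilities.
#'
#' @param outcome Numeric response (observed change scores).
#' @param regressors Data frame or matrix of predictors (e.g. baseline LSAS
#'   and the connectivity term).
#' @return An object of class `conn_glm` wrapping the fit, with fields
#'   `betas`, `ses`, `tvals`, `pvals`, `dof`. Supports [generics::tidy()]
#'   and [generics::glance()].
#' @export
fit_ols <- function(outcome, regressors) {
  x <- as.data.frame(regressors)
  n <- length(outcome)
  p <- ncol(x) + 1L
  if (nrow(x) != n) abort("`outcome` and `regressors` differ in length.")
  if (n <= p) abort("Need more observations than coefficients (incl. intercept) to fit.")
  dat <- cbind(.outcome = outcome, x)
  fit <- lm(.outcome ~ ., data = dat)
  if (fit$qr$rank < p) abort("Regressor matrix is rank deficient.")
  sm <- summary(fit)$coefficients
  structure(
    list(
      betas = sm[, 1], ses = sm[, 2], tvals = sm[, 3], pvals = sm[, 4],
      dof = fit$df.residual, lm_fit = fit
    ),
    class = "conn_glm"
  )
}

#' @export
print.conn_glm <- function(x, ...) {
  cat(sprintf("<conn_glm> %d terms, %d residual df\n", length(x$betas), x$dof))
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.conn_glm <- function(x, ...) {
  tibble::tibble(
    term = names(x$betas),
    estimate = unname(x$betas),
    std.error = unname(x$ses),
    statistic = unname(x$tvals),
    p.value = unname(x$pvals)
  )
}

#' @export
glance.conn_glm <- function(x, ...) {
  sm <- summary(x$lm_fit)
  tibble::tibble(
    r.squared = sm$r.squared,
    adj.r.squared = sm$adj.r.squared,
    sigma = sm$sigma,
    df.residual = x$dof,
    nobs = length(x$lm_fit$residuals)
  )
}

#' Frozen vs. re-estimated baseline coefficient
#'
#' Checks how much prediction is gained by replacing the frozen baseline
#' slope with the slope re-estimated in the cohort at hand. Both compact
#' models are evaluated in the centered convention (slope times centered
#' baseline, centered outcome) and compared by prediction R-squared: the
#' proportional reduction in squared error of the OLS-slope predictions
#' relative to the frozen-slope predictions.
#'
#' @param data Tibble with `baseline_lsas` and `delta_lsas` columns.
#' @param spec A [fixed_model_spec()] carrying the frozen slope.
#' @return A one-row tibble: `beta_frozen`, `beta_ols`,
#'   `prediction_r2_gain` (positive when the re-estimated slope predicts
#'   better).
#' @export
compare_beta_sources <- function(data, spec = fixed_model_spec()) {
  b <- data$baseline_lsas - mean(data$baseline_lsas)
  y <- data$delta_lsas - mean(data$delta_lsas)
  beta_ols <- sum(b * y) / sum(b * b)
  mse <- function(beta) mean((y - beta * b)^2)
  tibble::tibble(
    beta_frozen = spec$beta_baseline,
    beta_ols = beta_ols,
    prediction_r2_gain = 1 - mse(beta_ols) / mse(spec$beta_baseline)
  )
}
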