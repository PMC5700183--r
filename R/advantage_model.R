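#  advantage_model: regression of horizontal velocity loss on touchdown
#  velocity and take-off angle, residual-distribution banding, and the
#  conversion of a velocity-loss difference into a jump-distance advantage.
#
#  Sign convention: horizontal velocity loss is signed as in the take-off
#  summaries (negative values; a loss of -0.64 m/s is smaller in magnitude
#  than -1.09 m/s). "Reduced loss" therefore means a larger (less negative)
#  value, i.e. a residual above the regression plane.

#' Fit the horizontal velocity-loss regression
#'
#' Ordinary least-squares plane predicting horizontal velocity loss during
#' the take-off step from horizontal touchdown velocity and take-off angle,
#' fitted on a non-amputee reference population. The residual SD uses the
#' n - 3 denominator (three estimated coefficients).
#'
#' @param reference data.frame with columns `v_td` (m/s), `alpha` (deg),
#'   `v_loss` (m/s, signed), n >= 4 rows.
#' @return object of class `loss_regression`: `fit` (the `lm`),
#'   `intercept`, `coef_v_td`, `coef_alpha`, `r_squared`, `residuals`,
#'   `residual_mean`, `residual_sd`, `n`.
#' @export
fit_loss_model <- function(reference) {
  stopifnot(is.data.frame(reference),
            all(c("v_td", "alpha", "v_loss") %in% names(reference)))
  if (nrow(reference) < 4)
    jm_stop("invalid_input", "need at least 4 reference observations")
  fit <- stats::lm(v_loss ~ v_td + alpha, data = reference)
  if (any(is.na(coef(fit))))
    jm_stop("rank_deficient", "reference design is rank deficient (constant predictor?)")
  res <- stats::residuals(fit)
  n <- nrow(reference)
  # suppress summary.lm's note on noiseless (perfect-fit) references
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(fit = fit,
                 intercept = unname(coef(fit)[1]),
                 coef_v_td = unname(coef(fit)["v_td"]),
                 coef_alpha = unname(coef(fit)["alpha"]),
                 r_squared = r2,
                 residuals = unname(res),
                 residual_mean = mean(res),
                 residual_sd = sqrt(sum(res^2) / (n - 3)),
                 n = n),
            class = "loss_regression")
}

#' @export
print.loss_regression <- function(x, ...) {
  cat(sprintf(paste0("<loss_regression> n = %d, R^2 = %.3f\n",
                     "  v_loss = %.3f + %.3f v_td + %.3f alpha, residual SD %.3f m/s\n"),
              x$n, x$r_squared, x$intercept, x$coef_v_td, x$coef_alpha,
              x$residual_sd))
  invisible(x)
}

#' Residual band and distribution diagnostics
#'
#' The band of naturally occurring deviations from the predicted velocity
#' loss: residual mean +/- k residual SD (k = 3 covers 99.7% of a normal
#' distribution). A Gaussian kernel density estimate (rule-of-thumb
#' bandwidth) is returned alongside the fitted normal curve so the
#' normality of the residuals can be checked qualitatively.
#'
#' @param model a [fit_loss_model()] result.
#' @param k band half-width in residual SDs (> 0 for a band; default 3).
#' @return list with `lower`, `upper` (m/s), `k`, `normal` (data.frame
#'   `x`, `density` of the fitted normal) and `kernel` (data.frame `x`,
#'   `density` from the kernel estimate).
#' @export
residual_band <- function(model, k = 3) {
  stopifnot(inherits(model, "loss_regression"))
  if (length(model$residuals) < 2)
    jm_stop("invalid_input", "need at least 2 residuals for a band")
  if (k < 0) jm_stop("invalid_parameter", "k must be non-negative")
  m <- model$residual_mean; s <- model$residual_sd
  if (s > 1e-12) {
    kd <- stats::density(model$residuals)
    xs <- kd$x
    kernel <- data.frame(x = xs, density = kd$y)
    normal <- data.frame(x = xs, density = stats::dnorm(xs, m, s))
  } else {
    kernel <- normal <- data.frame(x = m, density = NA_real_)
  }
  list(lower = m - k * s, upper = m + k * s, k = k,
       normal = normal, kernel = kernel)
}

#' Residual excess beyond the natural-variation band
#'
#' An athlete's residual from the reference regression, measured beyond the
#' inclusive k-SD band; deviations inside the band count as naturally
#' occurring variation and give 0. The sign is positive when the athlete's
#' loss is reduced beyond the band (residual above the upper boundary under
#' the signed-loss convention), so the result feeds directly into
#' [estimate_advantage()].
#'
#' @param model a [fit_loss_model()] result.
#' @param athlete list or data.frame row with `v_td`, `alpha`, `v_loss`.
#' @param k band half-width in residual SDs (default 3).
#' @return excess in m/s (0 inside or on the band boundary; negative when
#'   the loss is excessively large).
#' @export
residual_excess <- function(model, athlete, k = 3) {
  stopifnot(inherits(model, "loss_regression"))
  nd <- data.frame(v_td = athlete$v_td, alpha = athlete$alpha)
  r <- athlete$v_loss - unname(stats::predict(model$fit, nd))
  band <- residual_band(model, k)
  if (r > band$upper) r - band$upper
  else if (r < band$lower) r - band$lower
  else 0
}

#' Take-off performance advantage from a velocity-loss difference
#'
#' Converts a difference in horizontal velocity loss during the take-off
#' step into a jump-distance advantage by multiplying with the ballistic
#' flight time: `advantage = flight_time x delta_v`.
#'
#' @param delta_v difference in horizontal velocity loss, m/s (positive =
#'   the athlete loses less velocity than the reference).
#' @param flight_time ballistic flight time in s (> 0), e.g. from
#'   [flight_time()].
#' @param method label recording how `delta_v` was obtained
#'   (`"direct_reference"` or `"residual_threshold"`).
#' @return object of class `advantage_estimate`: `delta_v_loss`,
#'   `flight_time`, `advantage` (m), `method`.
#' @examples
#' estimate_advantage(0.55, 0.884)$advantage  # 0.49 m
#' @export
estimate_advantage <- function(delta_v, flight_time,
                               method = c("direct_reference",
                                          "residual_threshold")) {
  if (flight_time <= 0) jm_stop("invalid_parameter", "flight time must be positive")
  method <- match.arg(method)
  structure(list(delta_v_loss = delta_v, flight_time = flight_time,
                 advantage = flight_time * delta_v, method = method),
            class = "advantage_estimate")
}

#' @export
print.advantage_estimate <- function(x, ...) {
  cat(sprintf("<advantage_estimate> %.2f m (= %.3f s x %.2f m/s, %s)\n",
              x$advantage, x$flight_time, x$delta_v_loss, x$method))
  invisible(x)
}
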