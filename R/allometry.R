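#' Allometric links from parent mass to propagule traits
#'
#' Two power laws tie the final total mass of a parental plant to the number
#' and the mean mass of the single-node stem fragments (clonal propagules) it
#' yields; two linear links tie the mean propagule mass to the shape and scale
#' of the Weibull size distribution. Defaults are the fitted values used in
#' the simulation experiment:
#' \deqn{N_{prop} = 0.253\, TM^{0.684}, \quad MM_{prop} = 2.727\, TM^{0.354}}
#' \deqn{shape = 0.015\, MM + 0.674, \quad scale = 1.183\, MM - 5.083}
#'
#' @param alpha Multiplier (power law, must be positive) or slope (linear link).
#' @param beta Exponent (power law) or intercept (linear link; may be negative).
#' @return \code{power_law}/\code{linear_link}: parameter objects.
#'   \code{allometry_default}: an \code{"allometry_set"} bundling the four links
#'   (\code{number_law}, \code{meanmass_law}, \code{shape_link},
#'   \code{scale_link}).
#' @export
power_law <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta), alpha > 0, is.finite(beta))
  structure(list(alpha = alpha, beta = beta), class = "power_law")
}

#' @rdname power_law
#' @export
linear_link <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.finite(alpha), is.finite(beta))
  structure(list(alpha = alpha, beta = beta), class = "linear_link")
}

#' @rdname power_law
#' @export
allometry_default <- function() {
  structure(list(
    number_law   = power_law(0.253, 0.684),
    meanmass_law = power_law(2.727, 0.354),
    shape_link   = linear_link(0.015, 0.674),
    scale_link   = linear_link(1.183, -5.083)), class = "allometry_set")
}

#' Expected propagule number from parental mass
#'
#' @param TM_parent Total dry mass of the parental plant, mg (> 0, vectorised).
#' @param law A [power_law()]; defaults to the number law of
#'   [allometry_default()].
#' @return Real-valued expected count \eqn{\alpha TM^\beta}.
#' @export
propagule_number_expected <- function(TM_parent, law = allometry_default()$number_law) {
  stopifnot(inherits(law, "power_law"))
  if (any(TM_parent <= 0)) stop("TM_parent must be positive")
  law$alpha * TM_parent^law$beta
}

#' Realised (integer) propagule count
#'
#' Rounds the expected count half-away-from-zero, floored at 1: any positive
#' parent yields at least one propagule.
#'
#' @inheritParams propagule_number_expected
#' @return Integer count >= 1.
#' @export
propagule_count <- function(TM_parent, law = allometry_default()$number_law) {
  expected <- propagule_number_expected(TM_parent, law)
  pmax(1L, as.integer(floor(expected + 0.5)))
}

#' Mean propagule mass from parental mass
#'
#' @inheritParams propagule_number_expected
#' @param law A [power_law()]; defaults to the mean-mass law.
#' @return Mean propagule dry mass, mg.
#' @export
propagule_mean_mass <- function(TM_parent, law = allometry_default()$meanmass_law) {
  stopifnot(inherits(law, "power_law"))
  if (any(TM_parent <= 0)) stop("TM_parent must be positive")
  law$alpha * TM_parent^law$beta
}

#' Weibull size-distribution parameters from the mean propagule mass
#'
#' Applies the linear links for shape and scale. The scale link has a negative
#' intercept, so a mean mass at or below 5.083/1.183 (about 4.297 mg) gives a
#' non-positive scale and is rejected as an infeasible distribution.
#'
#' @param MM Mean propagule mass, mg (> 0, scalar).
#' @param set An \code{"allometry_set"}.
#' @return A [weibull_params()] object.
#' @export
weibull_params_from_meanmass <- function(MM, set = allometry_default()) {
  stopifnot(inherits(set, "allometry_set"), length(MM) == 1L)
  if (MM <= 0) stop("MM must be positive")
  scale <- set$scale_link$alpha * MM + set$scale_link$beta
  shape <- set$shape_link$alpha * MM + set$shape_link$beta
  if (scale <= 0 || shape <= 0) {
    stop("infeasible size distribution: mean propagule mass ", signif(MM, 6),
         " mg implies non-positive Weibull parameters (scale = ",
         signif(scale, 6), ", shape = ", signif(shape, 6), ")")
  }
  weibull_params(shape = shape, scale = scale)
}

#' Fit a power law by nonlinear least squares
#'
#' Fits \eqn{y = \alpha x^\beta} on the original scale (Levenberg-Marquardt),
#' started from the log-log ordinary-least-squares solution. On data that are
#' exactly log-log linear the result coincides with the log-log OLS solution.
#'
#' @param pairs Data frame (or list) with columns \code{x} and \code{y}, all
#'   positive; at least 3 pairs.
#' @return Object of class \code{"power_law_fit"}: the fitted [power_law()]
#'   plus \code{r_squared} (\eqn{1 - rss/tss} on the original scale),
#'   \code{rss}, \code{n}, \code{fitted}, \code{residuals}.
#' @export
fit_power_law <- function(pairs) {
  d <- .check_pairs(pairs, positive = TRUE, min_n = 3L)
  ll <- stats::lm(log(y) ~ log(x), data = d)
  start <- list(alpha = exp(stats::coef(ll)[[1]]), beta = stats::coef(ll)[[2]])
  fit <- minpack.lm::nlsLM(
    y ~ alpha * x^beta, data = d, start = start,
    lower = c(alpha = 1e-12, beta = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10, ptol = 1e-12))
  est <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((d$y - mean(d$y))^2)
  structure(list(
    law = power_law(est[["alpha"]], est[["beta"]]),
    alpha = est[["alpha"]], beta = est[["beta"]],
    r_squared = 1 - rss / tss, rss = rss, n = nrow(d),
    fitted = stats::fitted(fit), residuals = stats::residuals(fit)),
    class = "power_law_fit")
}

#' Fit a linear link by ordinary least squares
#'
#' @param pairs Data frame with columns \code{x} and \code{y}; at least 3
#'   pairs and non-zero variance in \code{x}.
#' @return Object of class \code{"linear_link_fit"}: the fitted
#'   [linear_link()] (slope \code{alpha}, intercept \code{beta}),
#'   \code{r_squared}, two-sided slope-test \code{p_value}, \code{n}.
#' @export
fit_linear_link <- function(pairs) {
  d <- .check_pairs(pairs, positive = FALSE, min_n = 3L)
  if (stats::var(d$x) == 0) stop("zero variance in x: linear link is unidentifiable")
  fit <- stats::lm(y ~ x, data = d)
  sm <- summary(fit)
  structure(list(
    link = linear_link(stats::coef(fit)[[2]], stats::coef(fit)[[1]]),
    alpha = stats::coef(fit)[[2]], beta = stats::coef(fit)[[1]],
    r_squared = sm$r.squared,
    p_value = sm$coefficients["x", "Pr(>|t|)"],
    n = nrow(d), lm = fit), class = "linear_link_fit")
}

.check_pairs <- function(pairs, positive, min_n) {
  d <- as.data.frame(pairs)
  if (!all(c("x", "y") %in% names(d))) {
    if (ncol(d) >= 2L) names(d)[1:2] <- c("x", "y")
    else stop("pairs must have columns x and y")
  }
  if (nrow(d) < min_n) stop("need at least ", min_n, " pairs, got ", nrow(d))
  if (!is.numeric(d$x) || !is.numeric(d$y)) stop("pairs must be numeric")
  if (positive && (any(d$x <= 0) || any(d$y <= 0))) {
    stop("power-law fitting requires strictly positive pairs")
  }
  d[c("x", "y")]
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power law: y = %.6g * x^%.6g   (n = %d, R^2 = %.4f)\n",
              x$alpha, x$beta, x$n, x$r_squared))
  invisible(x)
}

#' @export
coef.power_law_fit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' @export
predict.power_law_fit <- function(object, newdata, ...) {
  object$alpha * newdata$x^object$beta
}

#' @export
print.linear_link_fit <- function(x, ...) {
  cat(sprintf(
    "Linear link: y = %.6g * x + %.6g   (n = %d, R^2 = %.4f, slope p = %.3g)\n",
    x$alpha, x$beta, x$n, x$r_squared, x$p_value))
  invisible(x)
}

#' @export
coef.linear_link_fit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}
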