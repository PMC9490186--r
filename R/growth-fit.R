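#' Fit a candidate growth family to trajectory data
#'
#' Least-squares fit of one of the six candidate curves to harvested
#' growth-trajectory records. For the capacity-bearing families
#' (monomolecular, logistic3, gompertz) the asymptote is replaced by the
#' nitrogen link \eqn{K = \gamma N + \delta}, so the free parameters are
#' \code{r}, \code{gamma}, \code{delta}; for linear/exponential/power the
#' single free parameter is the slope/rate/exponent. The initial mass
#' \code{M0} is fixed at the measured propagule mass, not estimated.
#'
#' Fitting uses Levenberg-Marquardt least squares
#' (\code{\link[minpack.lm]{nlsLM}}) restarted from a deterministic grid of
#' growth-rate starting values (r in 0.02, 0.05, 0.1, 0.2); capacity starts
#' come from a linear regression of the per-nitrogen-level maximum mass on N.
#' The best converged restart (lowest residual sum of squares) is kept. The
#' information criterion is the least-squares form
#' \eqn{AIC = n \log(rss/n) + 2k} with the additive constant dropped: only
#' rankings between families fitted to the same data are meaningful.
#'
#' @param data Data frame of trajectory records with columns \code{N_level}
#'   (mg/L), \code{t} or \code{harvest_day} (days), and \code{mass} or
#'   \code{dry_mass} (mg).
#' @param family One of [growth_families()].
#' @param M0_fixed Initial dry mass in mg (default 22.38, the measured mean
#'   propagule mass).
#' @return An object of class \code{"growth_fit"} with components
#'   \code{family}, \code{params} (named vector of all curve parameters,
#'   including the fixed \code{M0}), \code{free} (names of estimated
#'   parameters), \code{rss}, \code{n}, \code{k}, \code{aic},
#'   \code{fitted}, \code{residuals}.
#' @seealso [select_growth()], [growth_curve()]
#' @export
fit_growth <- function(data, family, M0_fixed = 22.38) {
  family <- match.arg(family, growth_families())
  stopifnot(is.numeric(M0_fixed), length(M0_fixed) == 1L, M0_fixed > 0)
  d <- .normalize_trajectories(data)
  n <- nrow(d)
  k <- if (family %in% .capacity_families) 3L else 1L
  if (length(unique(d$t)) < 2L) stop("trajectory data must span at least 2 times")
  if (n < k + 1L) {
    stop("underdetermined fit: ", n, " records for ", k,
         " free parameters (need at least ", k + 1L, ")")
  }

  starts <- .growth_start_grid(d, family, M0_fixed)
  d$M0_fix <- M0_fixed
  best <- NULL
  diagnostics <- character(0)
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        .growth_formula(family), data = d, start = s,
        lower = .growth_lower(family),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10,
                                             ptol = 1e-12)),
      error = function(e) e, warning = function(w) w)
    if (inherits(fit, "condition")) {
      diagnostics <- c(diagnostics, conditionMessage(fit))
      next
    }
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("growth fit failed to converge for family '", family, "' after ",
         length(starts), " restarts: ",
         paste(unique(diagnostics), collapse = "; "))
  }

  est <- stats::coef(best$fit)
  params <- c(M0 = M0_fixed, est)
  aic <- n * log(best$rss / n) + 2 * k
  structure(list(
    family = family, params = params, free = names(est),
    rss = best$rss, n = n, k = k, aic = aic,
    fitted = stats::fitted(best$fit), residuals = stats::residuals(best$fit),
    data = d), class = "growth_fit")
}

# accept both internal (t, mass) and greenhouse-CSV (harvest_day, dry_mass) names
.normalize_trajectories <- function(data) {
  stopifnot(is.data.frame(data))
  d <- as.data.frame(data)
  if (!"t" %in% names(d) && "harvest_day" %in% names(d)) d$t <- d$harvest_day
  if (!"mass" %in% names(d) && "dry_mass" %in% names(d)) d$mass <- d$dry_mass
  need <- c("N_level", "t", "mass")
  missing <- setdiff(need, names(d))
  if (length(missing)) stop("trajectory data lacks column(s): ",
                            paste(missing, collapse = ", "))
  for (col in need) {
    if (!is.numeric(d[[col]])) stop("column '", col, "' must be numeric")
  }
  if (any(d$mass <= 0)) stop("dry masses must be positive")
  d[need]
}

.growth_formula <- function(family) {
  M0q <- quote(M0_fix)
  f <- switch(family,
    linear        = mass ~ M0_fix + b * t,
    exponential   = mass ~ M0_fix * exp(r * t),
    power         = mass ~ M0_fix * (t + 1)^b,
    monomolecular = mass ~ (gamma * N_level + delta) -
                      (gamma * N_level + delta - M0_fix) * exp(-r * t),
    logistic3     = mass ~ M0_fix * (gamma * N_level + delta) /
                      (M0_fix + (gamma * N_level + delta - M0_fix) * exp(-r * t)),
    gompertz      = mass ~ (gamma * N_level + delta) *
                      (M0_fix / (gamma * N_level + delta))^(exp(-r * t)))
  f
}

.growth_lower <- function(family) {
  if (family %in% .capacity_families) c(r = 1e-8, gamma = -Inf, delta = 1e-6)
  else if (family == "exponential") c(r = -Inf) else c(b = -Inf)
}

.growth_start_grid <- function(d, family, M0_fix) {
  r_grid <- c(0.02, 0.05, 0.1, 0.2)
  if (family == "linear") {
    b0 <- stats::coef(stats::lm(I(mass - M0_fix) ~ t - 1, data = d))[[1]]
    return(list(list(b = b0), list(b = b0 / 2), list(b = 2 * b0)))
  }
  if (family == "exponential") {
    r0 <- stats::coef(stats::lm(log(mass / M0_fix) ~ t - 1, data = d))[[1]]
    return(lapply(unique(c(r0, r_grid)), function(r) list(r = r)))
  }
  if (family == "power") {
    b0 <- stats::coef(stats::lm(log(mass / M0_fix) ~ log(t + 1) - 1, data = d))[[1]]
    return(list(list(b = b0), list(b = b0 / 2), list(b = 2 * b0)))
  }
  # capacity families: K start from per-N maximum observed mass
  agg <- stats::aggregate(mass ~ N_level, data = d, FUN = max)
  if (nrow(agg) >= 2L) {
    cf <- stats::coef(stats::lm(mass ~ N_level, data = agg))
    delta0 <- max(cf[[1]], 1); gamma0 <- cf[[2]]
  } else {
    delta0 <- max(d$mass); gamma0 <- 0
  }
  lapply(r_grid, function(r) list(r = r, gamma = gamma0, delta = delta0))
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Growth fit:", x$family, "family\n")
  cat("  n =", x$n, " free parameters:", paste(x$free, collapse = ", "), "\n")
  cat("  estimates:\n")
  print(signif(x$params, 6))
  cat(sprintf("  rss = %.6g   AIC = %.4f\n", x$rss, x$aic))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$params

#' @export
AIC.growth_fit <- function(object, ...) object$aic

#' @export
residuals.growth_fit <- function(object, ...) object$residuals

#' Predicted mass from a fitted growth curve
#'
#' @param object A \code{"growth_fit"}.
#' @param newdata Data frame with columns \code{t} and (for capacity-bearing
#'   families) \code{N_level}; defaults to the training records.
#' @param ... Unused.
#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data else newdata
  p <- object$params
  if (object$family %in% .capacity_families) {
    K <- p[["gamma"]] * d$N_level + p[["delta"]]
    pv <- cbind(M0 = p[["M0"]], r = p[["r"]], K = K)
    vapply(seq_len(nrow(d)), function(i)
      growth_curve(d$t[i], object$family, pv[i, ]), numeric(1))
  } else {
    growth_curve(d$t, object$family, p)
  }
}

#' Select the best-fitting growth family by AIC
#'
#' Picks the fit with the minimal information criterion. Ties (within 1e-9)
#' are broken first by fewer free parameters, then by the fixed family order
#' of [growth_families()].
#'
#' @param fits List of \code{"growth_fit"} objects.
#' @return The winning family name (character scalar), with the winning fit
#'   attached as attribute \code{"fit"}.
#' @export
select_growth <- function(fits) {
  if (length(fits) == 0L) stop("no fits supplied")
  stopifnot(all(vapply(fits, inherits, logical(1), "growth_fit")))
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  k <- vapply(fits, function(f) f$k, numeric(1))
  fam <- vapply(fits, function(f) f$family, character(1))
  tied <- which(aic <= min(aic) + 1e-9)
  tied <- tied[k[tied] == min(k[tied])]
  winner <- tied[order(match(fam[tied], growth_families()))][1L]
  structure(fam[winner], fit = fits[[winner]])
}
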