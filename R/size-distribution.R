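#' Weibull size-distribution parameters
#'
#' @param shape Dimensionless shape parameter, > 0.
#' @param scale Scale parameter in mg, > 0. The distribution mean is
#'   \eqn{scale \cdot \Gamma(1 + 1/shape)}.
#' @return Object of class \code{"weibull_params"}.
#' @export
weibull_params <- function(shape, scale) {
  stopifnot(is.numeric(shape), is.numeric(scale), length(shape) == 1L,
            length(scale) == 1L)
  if (!(shape > 0 && scale > 0)) {
    stop("Weibull shape and scale must be strictly positive")
  }
  structure(list(shape = shape, scale = scale), class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull(shape = %.6g, scale = %.6g mg); mean = %.6g mg\n",
              x$shape, x$scale, x$scale * gamma(1 + 1 / x$shape)))
  invisible(x)
}

.dist_families <- c("normal", "lognormal", "gamma", "weibull")

#' Fit a candidate size distribution by maximum likelihood
#'
#' Fits one of the four candidate families (Normal, Log-Normal, Gamma,
#' Weibull) to a sample of propagule dry masses via
#' \code{\link[fitdistrplus]{fitdist}}, and evaluates the Cramér-von Mises
#' statistic of the sample against the fitted CDF. Parameterizations:
#' normal (mean, sd); lognormal (meanlog, sdlog of the log sample); gamma
#' (shape, rate); weibull (shape, scale).
#'
#' @param samples Numeric vector of masses, n >= 5; strictly positive for the
#'   positive-support families.
#' @param family One of \code{"normal"}, \code{"lognormal"}, \code{"gamma"},
#'   \code{"weibull"}.
#' @return Object of class \code{"dist_fit"}: \code{family}, \code{params}
#'   (named vector), \code{loglik}, \code{aic} (\eqn{2k - 2\ell}), \code{cvm},
#'   \code{n}.
#' @export
fit_dist <- function(samples, family) {
  family <- match.arg(family, .dist_families)
  samples <- as.numeric(samples)
  if (length(samples) < 5L) stop("need at least 5 samples, got ", length(samples))
  if (any(!is.finite(samples))) stop("samples must be finite")
  if (stats::var(samples) == 0) stop("degenerate (zero-variance) sample")
  if (family != "normal" && any(samples <= 0)) {
    stop("non-positive sample with positive-support family '", family, "'")
  }
  distname <- switch(family, normal = "norm", lognormal = "lnorm",
                     gamma = "gamma", weibull = "weibull")
  fd <- fitdistrplus::fitdist(samples, distname, method = "mle")
  params <- fd$estimate
  k <- length(params)
  loglik <- fd$loglik
  cdf <- .dist_cdf(distname, params)
  structure(list(
    family = family, params = params, loglik = loglik,
    aic = 2 * k - 2 * loglik, cvm = cvm_statistic(samples, cdf),
    n = length(samples)), class = "dist_fit")
}

.dist_cdf <- function(distname, params) {
  pfun <- get(paste0("p", distname), mode = "function")
  function(q) do.call(pfun, c(list(q = q), as.list(params)))
}

#' @export
print.dist_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): loglik = %.4f, AIC = %.4f, CvM = %.6g\n",
              x$family, x$n, x$loglik, x$aic, x$cvm))
  print(signif(x$params, 6))
  invisible(x)
}

#' @export
coef.dist_fit <- function(object, ...) object$params

#' @export
AIC.dist_fit <- function(object, ...) object$aic

#' Cramér-von Mises goodness-of-fit statistic
#'
#' \deqn{\omega^2 = \frac{1}{12n} + \sum_{i=1}^{n}
#'   \left[F(x_{(i)}) - \frac{2i - 1}{2n}\right]^2}
#' with \eqn{x_{(i)}} the order statistics. The statistic is bounded below by
#' \eqn{1/(12n)}, attained when the sample sits exactly on the CDF's quantiles
#' at the plotting positions \eqn{(2i-1)/(2n)}, and is invariant under a
#' strictly monotone transformation applied to both sample and CDF.
#'
#' @param samples Numeric sample, n >= 1.
#' @param cdf A vectorised distribution function mapping into [0, 1].
#' @return The statistic (non-negative scalar).
#' @export
cvm_statistic <- function(samples, cdf) {
  stopifnot(is.function(cdf))
  x <- sort(as.numeric(samples))
  n <- length(x)
  if (n < 1L) stop("need at least one sample")
  u <- cdf(x)
  if (any(u < -1e-12 | u > 1 + 1e-12)) stop("cdf must map into [0, 1]")
  1 / (12 * n) + sum((u - (2 * seq_len(n) - 1) / (2 * n))^2)
}

#' Per-plant size-distribution selection
#'
#' Fits all four candidate families to each parental plant's propagule-mass
#' sample and declares the family with the smallest Cramér-von Mises statistic
#' the winner for that plant (ties broken by lower AIC). Plants whose sample
#' is too small (n < 5) or whose fits fail are excluded from the tally with a
#' warning.
#'
#' @param plants Named list of numeric vectors (per-plant propagule masses).
#' @param families Candidate families (default all four).
#' @return Object of class \code{"dist_selection"}: \code{winners}
#'   (data.frame plant, family, cvm, aic), \code{tally} (named integer vector
#'   of win counts per family), \code{fits} (nested list), \code{excluded}
#'   (character vector of skipped plants).
#' @export
select_dist_per_plant <- function(plants, families = .dist_families) {
  stopifnot(is.list(plants), length(plants) >= 1L)
  families <- match.arg(families, .dist_families, several.ok = TRUE)
  if (is.null(names(plants))) names(plants) <- paste0("plant_", seq_along(plants))
  winners <- list(); fits <- list(); excluded <- character(0)
  for (id in names(plants)) {
    x <- plants[[id]]
    if (length(x) < 5L) {
      warning("plant '", id, "' excluded: only ", length(x),
              " propagules (need >= 5)")
      excluded <- c(excluded, id)
      next
    }
    fl <- lapply(families, function(f) {
      tryCatch(fit_dist(x, f), error = function(e) NULL)
    })
    names(fl) <- families
    ok <- !vapply(fl, is.null, logical(1))
    if (!any(ok)) {
      warning("plant '", id, "' excluded: all distribution fits failed")
      excluded <- c(excluded, id)
      next
    }
    fl <- fl[ok]
    cvm <- vapply(fl, function(f) f$cvm, numeric(1))
    aic <- vapply(fl, function(f) f$aic, numeric(1))
    best <- order(cvm, aic)[1L]
    winners[[id]] <- data.frame(
      plant = id, family = names(fl)[best], cvm = cvm[best], aic = aic[best],
      stringsAsFactors = FALSE)
    fits[[id]] <- fl
  }
  if (length(winners) == 0L) stop("no plant yielded a successful fit")
  winners <- do.call(rbind, winners)
  rownames(winners) <- NULL
  tally <- table(factor(winners$family, levels = families))
  structure(list(winners = winners, tally = c(tally), fits = fits,
                 excluded = excluded), class = "dist_selection")
}

#' @export
print.dist_selection <- function(x, ...) {
  cat("Size-distribution selection over", nrow(x$winners), "plants\n")
  print(x$tally)
  if (length(x$excluded)) cat("excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Draw propagule masses from a Weibull size distribution
#'
#' Sampling goes through the inverse-CDF transform of uniform draws
#' (\code{qweibull(runif(n))}) so that, for a fixed RNG state, results are
#' reproducible and every draw is strictly positive.
#'
#' @param n Number of draws, >= 1.
#' @param p A [weibull_params()] object.
#' @return Numeric vector of n masses, mg.
#' @export
sample_propagule_masses <- function(n, p) {
  stopifnot(inherits(p, "weibull_params"))
  if (n < 1) stop("n must be at least 1")
  stats::qweibull(stats::runif(n), shape = p$shape, scale = p$scale)
}
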