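#' Default simulation parameters
#'
#' The parameter set used throughout the simulation experiment: logistic growth
#' with relative growth rate \code{r} = 0.103 day^-1, initial propagule mass
#' \code{M0} = 22.38 mg, and an environmental capacity that increases linearly
#' with the nitrogen concentration of the nutrient solution,
#' \eqn{K = \gamma N + \delta} with \eqn{\gamma} = 219.642 mg per (mg N/L) and
#' \eqn{\delta} = 1965.396 mg.
#'
#' @param gamma Capacity slope, mg biomass per unit nitrogen concentration.
#' @param delta Capacity intercept, mg (capacity at N = 0).
#' @return An object of class \code{"capacity_link"}.
#' @examples
#' capacity(10, capacity_link())
#' @export
capacity_link <- function(gamma = 219.642, delta = 1965.396) {
  stopifnot(is.numeric(gamma), is.numeric(delta), length(gamma) == 1L,
            length(delta) == 1L, is.finite(gamma), is.finite(delta))
  structure(list(gamma = gamma, delta = delta), class = "capacity_link")
}

#' @param M0 Initial dry mass of one plant, mg. Must be positive.
#' @param r Relative growth rate, day^-1. Must be positive.
#' @param K Environmental capacity (growth asymptote), mg.
#' @rdname capacity_link
#' @export
growth_params <- function(M0 = 22.38, r = 0.103, K = NULL) {
  stopifnot(M0 > 0, r > 0)
  if (!is.null(K)) stopifnot(K > 0)
  structure(list(M0 = M0, r = r, K = K), class = "growth_params")
}

#' Environmental capacity as a function of nitrogen level
#'
#' Maps a nitrogen concentration to the growth asymptote \eqn{K} through the
#' affine link \eqn{K = \gamma N + \delta}.
#'
#' @param N_level Nitrogen concentration, mg/L. Must be non-negative.
#' @param link A [capacity_link()] object.
#' @return Capacity in mg. Errors if the implied capacity is not positive.
#' @export
capacity <- function(N_level, link = capacity_link()) {
  stopifnot(inherits(link, "capacity_link"), is.numeric(N_level))
  if (any(N_level < 0)) stop("N_level must be non-negative")
  K <- link$gamma * N_level + link$delta
  if (any(K <= 0)) {
    stop("invalid capacity: gamma * N_level + delta must be positive (got ",
         paste(signif(K[K <= 0], 6), collapse = ", "), ")")
  }
  K
}

#' Three-parameter logistic growth curve
#'
#' Closed-form solution of the logistic growth equation
#' \eqn{dM/dt = r M (1 - M/K)}:
#' \deqn{M(t) = \frac{M_0 K}{M_0 + (K - M_0) e^{-rt}}}
#' \code{M(0) = M0} and \code{M(t) -> K} as \code{t} grows; the curve is
#' strictly increasing when \code{M0 < K} and decreasing toward \code{K} when a
#' propagule starts above capacity (tolerated, cannot occur under the default
#' parameters).
#'
#' @param t Time in days, non-negative (vectorised).
#' @param p A [growth_params()] object with a non-NULL \code{K}.
#' @return Dry mass in mg.
#' @export
logistic_mass <- function(t, p) {
  stopifnot(inherits(p, "growth_params"), !is.null(p$K))
  if (any(t < 0)) stop("t must be non-negative")
  p$M0 * p$K / (p$M0 + (p$K - p$M0) * exp(-p$r * t))
}

#' The six candidate growth families
#'
#' @return Character vector of the supported family names.
#' @export
growth_families <- function() {
  c("linear", "exponential", "power", "monomolecular", "logistic3", "gompertz")
}

# families whose asymptote K is replaced by the nitrogen-linked capacity
.capacity_families <- c("monomolecular", "logistic3", "gompertz")

#' Evaluate a candidate growth curve
#'
#' Closed forms of the six candidate families, with mass in mg and time in
#' days. \code{M0} is always supplied (measured propagule mass), so the free
#' parameters are:
#' \describe{
#'   \item{linear}{\eqn{M = M_0 + b t} (slope \code{b})}
#'   \item{exponential}{\eqn{M = M_0 e^{r t}} (rate \code{r})}
#'   \item{power}{\eqn{M = M_0 (t + 1)^b} (exponent \code{b}; the +1 keeps
#'     \eqn{M(0) = M_0} finite)}
#'   \item{monomolecular}{\eqn{M = K - (K - M_0) e^{-r t}} (\code{r}, \code{K})}
#'   \item{logistic3}{the three-parameter logistic, see [logistic_mass()]
#'     (\code{r}, \code{K})}
#'   \item{gompertz}{\eqn{M = K (M_0/K)^{e^{-rt}}} (\code{r}, \code{K})}
#' }
#'
#' @param t Time in days (vectorised).
#' @param family One of [growth_families()].
#' @param params Named numeric vector with \code{M0} plus the family's free
#'   parameters (\code{b} or \code{r}, and \code{K} for the capacity-bearing
#'   families).
#' @return Mass in mg.
#' @export
growth_curve <- function(t, family, params) {
  family <- match.arg(family, growth_families())
  need <- switch(family,
    linear = c("M0", "b"), exponential = c("M0", "r"), power = c("M0", "b"),
    monomolecular = c("M0", "r", "K"), logistic3 = c("M0", "r", "K"),
    gompertz = c("M0", "r", "K"))
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop("incomplete params for family '", family, "': missing ",
         paste(missing, collapse = ", "))
  }
  p <- as.list(params)
  switch(family,
    linear        = p$M0 + p$b * t,
    exponential   = p$M0 * exp(p$r * t),
    power         = p$M0 * (t + 1)^p$b,
    monomolecular = p$K - (p$K - p$M0) * exp(-p$r * t),
    logistic3     = p$M0 * p$K / (p$M0 + (p$K - p$M0) * exp(-p$r * t)),
    gompertz      = p$K * (p$M0 / p$K)^(exp(-p$r * t)))
}
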