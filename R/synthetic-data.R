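#' Ground truth for synthetic greenhouse data
#'
#' Bundles the true parameter values and design descriptors used by the
#' synthetic-data generators. Defaults equal the simulation parameter set:
#' logistic growth (M0 = 22.38 mg, r = 0.103/day, gamma = 219.642,
#' delta = 1965.396) and the four allometric links of [allometry_default()].
#'
#' Two noise components are distinguished. \code{noise_sd} is multiplicative
#' log-normal measurement/process noise applied at each generated stage.
#' \code{vigor_sd} is an additional per-plant log-normal "vigor" factor on
#' total mass in the propagule experiment, representing the large individual
#' variation among greenhouse clonal fragments; it spreads the parent masses
#' enough that the allometric exponents are identifiable from 28 plants, as
#' they evidently were in the real experiment.
#'
#' @param M0,r Growth truth: initial mass (mg) and relative growth rate
#'   (day^-1).
#' @param link A [capacity_link()] holding gamma and delta.
#' @param allometry An \code{"allometry_set"} of true links.
#' @param noise_sd Multiplicative log-normal noise sd (default 0.15).
#' @param vigor_sd Between-plant vigor sd for the propagule experiment
#'   (default 0.40).
#' @param trajectory_N,harvest_days,trajectory_reps Trajectory-experiment
#'   design: nitrogen levels (mg/L), harvest days, replicates per cell.
#' @param propagule_N,propagule_reps,propagule_days Propagule-experiment
#'   design: nitrogen levels, plants per level, growth duration (days).
#' @return Object of class \code{"truth_config"}.
#' @export
truth_config <- function(M0 = 22.38, r = 0.103, link = capacity_link(),
                         allometry = allometry_default(),
                         noise_sd = 0.15, vigor_sd = 0.40,
                         trajectory_N = c(10, 20, 40, 60),
                         harvest_days = c(30, 45, 60, 75),
                         trajectory_reps = 4,
                         propagule_N = c(10, 20, 40, 60),
                         propagule_reps = 7,
                         propagule_days = 45) {
  stopifnot(M0 > 0, r > 0, noise_sd >= 0, vigor_sd >= 0,
            inherits(link, "capacity_link"), inherits(allometry, "allometry_set"),
            trajectory_reps >= 1, propagule_reps >= 1, propagule_days > 0)
  structure(list(
    M0 = M0, r = r, link = link, allometry = allometry,
    noise_sd = noise_sd, vigor_sd = vigor_sd,
    trajectory_N = trajectory_N, harvest_days = harvest_days,
    trajectory_reps = as.integer(trajectory_reps),
    propagule_N = propagule_N, propagule_reps = as.integer(propagule_reps),
    propagule_days = propagule_days), class = "truth_config")
}

#' Generate a synthetic growth-trajectory experiment
#'
#' Emulates the trajectory harvests: every combination of nitrogen level and
#' harvest day gets \code{trajectory_reps} plants whose dry mass is the
#' logistic-curve mean times multiplicative log-normal noise,
#' \eqn{mass = M(t; K(N)) e^{\varepsilon}},
#' \eqn{\varepsilon \sim N(0, noise\_sd^2)}. The default design (4 N levels x
#' 4 harvests x 4 replicates) yields 64 rows. With \code{noise_sd = 0} the
#' rows lie exactly on the logistic surface.
#'
#' @param truth A [truth_config()].
#' @param seed Optional integer seed.
#' @return Data frame with columns \code{plant_id}, \code{N_level},
#'   \code{harvest_day}, \code{dry_mass}.
#' @export
gen_trajectories <- function(truth = truth_config(), seed = NULL) {
  stopifnot(inherits(truth, "truth_config"))
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(rep = seq_len(truth$trajectory_reps),
                      harvest_day = truth$harvest_days,
                      N_level = truth$trajectory_N, KEEP.OUT.ATTRS = FALSE)
  K <- capacity(grid$N_level, truth$link)
  mu <- truth$M0 * K / (truth$M0 + (K - truth$M0) * exp(-truth$r * grid$harvest_day))
  eps <- if (truth$noise_sd > 0) stats::rnorm(nrow(grid), 0, truth$noise_sd) else 0
  data.frame(
    plant_id = sprintf("T%03d", seq_len(nrow(grid))),
    N_level = grid$N_level, harvest_day = grid$harvest_day,
    dry_mass = mu * exp(eps))
}

#' Generate a synthetic propagule (size-distribution) experiment
#'
#' Emulates the second greenhouse experiment: \code{propagule_reps} plants per
#' nitrogen level (28 by default) grown for \code{propagule_days} days. Per
#' plant, total mass is the logistic mean times the plant's vigor factor and
#' measurement noise; the propagule count and mean mass follow the power-law
#' links applied to that observed mass, each with its own multiplicative
#' noise; and the individual propagule masses are drawn from the Weibull
#' distribution implied by the plant's mean propagule mass.
#'
#' @param truth A [truth_config()].
#' @param seed Optional integer seed.
#' @param round_counts If TRUE (default) propagule counts are integers
#'   (rounded half-away-from-zero, floored at 1) as in real data. FALSE keeps
#'   the real-valued expected counts, the validation mode in which a
#'   zero-noise run is exactly invertible by the fitting stages.
#' @return List with components \code{plants} (one row per plant:
#'   \code{plant_id}, \code{N_level}, \code{parent_total_mass},
#'   \code{n_propagules}, \code{mean_propagule_mass}) and \code{propagules}
#'   (one row per propagule: \code{plant_id}, \code{N_level},
#'   \code{propagule_mass}).
#' @export
gen_propagule_plants <- function(truth = truth_config(), seed = NULL,
                                 round_counts = TRUE) {
  stopifnot(inherits(truth, "truth_config"))
  if (!is.null(seed)) set.seed(seed)
  al <- truth$allometry
  plants <- list(); props <- list()
  idx <- 0L
  for (N in truth$propagule_N) {
    K <- capacity(N, truth$link)
    mu <- truth$M0 * K / (truth$M0 + (K - truth$M0) * exp(-truth$r * truth$propagule_days))
    for (rep in seq_len(truth$propagule_reps)) {
      idx <- idx + 1L
      id <- sprintf("P%02d", idx)
      vig <- if (truth$vigor_sd > 0) exp(stats::rnorm(1, 0, truth$vigor_sd)) else 1
      meas <- if (truth$noise_sd > 0) exp(stats::rnorm(1, 0, truth$noise_sd)) else 1
      TM <- mu * vig * meas
      cnt_noise <- if (truth$noise_sd > 0) exp(stats::rnorm(1, 0, truth$noise_sd)) else 1
      mm_noise <- if (truth$noise_sd > 0) exp(stats::rnorm(1, 0, truth$noise_sd)) else 1
      expected <- propagule_number_expected(TM, al$number_law) * cnt_noise
      n_prop <- if (round_counts) max(1L, as.integer(floor(expected + 0.5))) else expected
      MM <- propagule_mean_mass(TM, al$meanmass_law) * mm_noise
      wp <- weibull_params_from_meanmass(MM, al)
      n_draw <- max(1L, as.integer(ceiling(n_prop)))
      masses <- sample_propagule_masses(n_draw, wp)
      plants[[id]] <- data.frame(
        plant_id = id, N_level = N, parent_total_mass = TM,
        n_propagules = n_prop, mean_propagule_mass = MM)
      props[[id]] <- data.frame(
        plant_id = id, N_level = N, propagule_mass = masses)
    }
  }
  plants <- do.call(rbind, plants); rownames(plants) <- NULL
  props <- do.call(rbind, props); rownames(props) <- NULL
  list(plants = plants, propagules = props)
}

#' Default parameter-recovery tolerances
#'
#' Relative-error tolerances for the end-to-end recovery run on the default
#' synthetic designs, fixed in advance at roughly twice the first-order
#' standard error each design propagates to the estimate (details in the
#' methods vignette). The power-law multipliers are only weakly identified
#' because they trade off against the exponents at the mean log-mass of the
#' design, hence their wide band.
#'
#' @return Named numeric vector of relative-error tolerances.
#' @export
recovery_tolerances <- function() {
  c(r = 0.10, gamma = 0.25, delta = 0.25,
    alpha1 = 2.0, beta1 = 0.25, alpha2 = 2.0, beta2 = 0.45,
    alpha4 = 0.45)
}

#' Parameter-recovery report
#'
#' Compares estimates against the generating truth by relative error
#' \eqn{|\hat\theta - \theta| / |\theta|} and flags each parameter against
#' its tolerance.
#'
#' @param estimates Named numeric vector of fitted parameter values.
#' @param truth Named numeric vector of true values; names must cover the
#'   estimates.
#' @param tolerances Named numeric vector of relative-error tolerances
#'   (default [recovery_tolerances()]); parameters without a listed tolerance
#'   get NA pass/fail.
#' @return Data frame with columns \code{parameter}, \code{estimate},
#'   \code{truth}, \code{rel_error}, \code{tolerance}, \code{pass}.
#' @export
recovery_report <- function(estimates, truth, tolerances = recovery_tolerances()) {
  stopifnot(is.numeric(estimates), is.numeric(truth),
            !is.null(names(estimates)), !is.null(names(truth)))
  missing <- setdiff(names(estimates), names(truth))
  if (length(missing)) {
    stop("no truth value for parameter(s): ", paste(missing, collapse = ", "))
  }
  tr <- truth[names(estimates)]
  rel <- abs(estimates - tr) / abs(tr)
  tol <- tolerances[names(estimates)]
  data.frame(
    parameter = names(estimates),
    estimate = unname(estimates), truth = unname(tr),
    rel_error = unname(rel), tolerance = unname(tol),
    pass = unname(ifelse(is.na(tol), NA, rel <= tol)),
    stringsAsFactors = FALSE)
}

#' End-to-end recovery run on synthetic data
#'
#' Generates both synthetic experiments, refits every stage (growth family
#' selection and logistic parameters; the two power laws; the per-plant
#' Weibull fits and the scale-vs-mean-mass linear link; the per-plant
#' size-distribution selection) and reports recovery of each parameter.
#'
#' @param truth A [truth_config()].
#' @param seed Integer seed for the generated data.
#' @return List: \code{report} (from [recovery_report()]),
#'   \code{growth_family} (AIC winner), \code{dist_tally} (per-family win
#'   counts), \code{fits} (the underlying fit objects).
#' @export
recovery_run <- function(truth = truth_config(), seed = 1) {
  traj <- gen_trajectories(truth, seed = seed)
  exp2 <- gen_propagule_plants(truth, seed = seed + 1L)

  fits <- lapply(growth_families(), function(f) {
    tryCatch(fit_growth(traj, f, M0_fixed = truth$M0), error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  family <- select_growth(fits)
  gfit <- attr(family, "fit")

  pl <- exp2$plants
  count_fit <- fit_power_law(data.frame(x = pl$parent_total_mass,
                                        y = pl$n_propagules))
  mm_fit <- fit_power_law(data.frame(x = pl$parent_total_mass,
                                     y = pl$mean_propagule_mass))

  by_plant <- split(exp2$propagules$propagule_mass, exp2$propagules$plant_id)
  sel <- select_dist_per_plant(by_plant)
  wscale <- vapply(sel$fits, function(fl) {
    if (!is.null(fl$weibull)) fl$weibull$params[["scale"]] else NA_real_
  }, numeric(1))
  keep <- !is.na(wscale)
  mm_obs <- pl$mean_propagule_mass[match(names(wscale)[keep], pl$plant_id)]
  scale_fit <- fit_linear_link(data.frame(x = mm_obs, y = wscale[keep]))

  est <- c(r = unname(coef(gfit)[["r"]]),
           gamma = unname(coef(gfit)[["gamma"]]),
           delta = unname(coef(gfit)[["delta"]]),
           alpha1 = count_fit$alpha, beta1 = count_fit$beta,
           alpha2 = mm_fit$alpha, beta2 = mm_fit$beta,
           alpha4 = scale_fit$alpha)
  tru <- c(r = truth$r, gamma = truth$link$gamma, delta = truth$link$delta,
           alpha1 = truth$allometry$number_law$alpha,
           beta1 = truth$allometry$number_law$beta,
           alpha2 = truth$allometry$meanmass_law$alpha,
           beta2 = truth$allometry$meanmass_law$beta,
           alpha4 = truth$allometry$scale_link$alpha)
  list(report = recovery_report(est, tru),
       growth_family = as.character(family),
       dist_tally = sel$tally,
       fits = list(growth = gfit, count = count_fit, meanmass = mm_fit,
                   scale = scale_fit, selection = sel))
}
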