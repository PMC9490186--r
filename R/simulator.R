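#' Configure one two-generation scenario
#'
#' A scenario fixes the nitrogen environment of the parent (\code{parental_N})
#' and of its clonal offspring (\code{offspring_N}), the survival rate of the
#' propagule pool, and the offspring growth time. The parent grows for 75 days
#' from a 22.38 mg fragment by default; all growth follows the
#' three-parameter logistic curve with the nitrogen-linked capacity.
#'
#' @param parental_N,offspring_N Nitrogen concentration, mg/L (> 0).
#' @param survival_rate Fraction of propagules surviving, in (0, 1].
#' @param offspring_time Offspring growth time, days (>= 0).
#' @param parent_time Parent growth time, days (default 75).
#' @param parent_M0 Initial parental fragment mass, mg (default 22.38).
#' @param link A [capacity_link()].
#' @param r Relative growth rate, day^-1, shared by both generations.
#' @param allometry An \code{"allometry_set"} (see [allometry_default()]).
#' @param seed Optional integer seed for the scenario's random draws.
#' @return Object of class \code{"scenario_config"}.
#' @export
scenario_config <- function(parental_N, offspring_N, survival_rate,
                            offspring_time, parent_time = 75,
                            parent_M0 = 22.38, link = capacity_link(),
                            r = 0.103, allometry = allometry_default(),
                            seed = NULL) {
  stopifnot(parental_N > 0, offspring_N > 0, offspring_time >= 0,
            parent_time >= 0, parent_M0 > 0, r > 0,
            inherits(link, "capacity_link"), inherits(allometry, "allometry_set"))
  if (!(survival_rate > 0 && survival_rate <= 1)) {
    stop("survival_rate must lie in (0, 1]")
  }
  structure(list(
    parental_N = parental_N, offspring_N = offspring_N,
    survival_rate = survival_rate, offspring_time = offspring_time,
    parent_time = parent_time, parent_M0 = parent_M0, link = link, r = r,
    allometry = allometry, seed = seed), class = "scenario_config")
}

#' Grow the parental plant
#'
#' Deterministic logistic growth of the parent for \code{parent_time} days at
#' capacity \code{capacity(PN)}.
#'
#' @param PN Parental nitrogen level, mg/L.
#' @param cfg A [scenario_config()] (its \code{parental_N} is ignored in
#'   favour of \code{PN}).
#' @return Total parental dry mass, mg.
#' @export
grow_parent <- function(PN, cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  K <- capacity(PN, cfg$link)
  logistic_mass(cfg$parent_time, growth_params(M0 = cfg$parent_M0, r = cfg$r, K = K))
}

#' Generate the propagule pool of one parent
#'
#' Chains the allometry: the integer propagule count comes from the number
#' law ([propagule_count()]), the pool's Weibull parameters from the
#' deterministic mean-mass law ([propagule_mean_mass()] then
#' [weibull_params_from_meanmass()]), and the individual masses are i.i.d.
#' Weibull draws.
#'
#' @param TM Parental total mass, mg.
#' @param cfg A [scenario_config()].
#' @return Numeric vector of propagule masses, mg.
#' @export
generate_pool <- function(TM, cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  n <- propagule_count(TM, cfg$allometry$number_law)
  MM <- propagule_mean_mass(TM, cfg$allometry$meanmass_law)
  wp <- weibull_params_from_meanmass(MM, cfg$allometry)
  sample_propagule_masses(n, wp)
}

#' Thin a propagule pool to its survivors
#'
#' The survivor count is the survival rate times the pool size, rounded
#' half-away-from-zero and floored at 1; survivors are a uniformly random
#' subset (the draws are i.i.d., so this is statistically equivalent to any
#' positional rule, and the order of propagules along the stem carries no
#' information here). \code{SR = 1} returns the pool unchanged.
#'
#' @param masses Propagule masses, mg.
#' @param SR Survival rate in (0, 1].
#' @return Numeric vector of surviving masses.
#' @export
apply_survival <- function(masses, SR) {
  if (!(SR > 0 && SR <= 1)) stop("SR must lie in (0, 1]")
  n <- length(masses)
  if (SR == 1) return(masses)
  k <- max(1L, as.integer(floor(n * SR + 0.5)))
  masses[sample.int(n, k)]
}

#' Grow surviving offspring
#'
#' Each surviving propagule grows independently (no resource sharing or
#' competition between offspring) along the logistic curve with its own mass
#' as \code{M0} and capacity \code{capacity(ON)}.
#'
#' @param masses Initial offspring masses, mg (> 0).
#' @param ON Offspring nitrogen level, mg/L.
#' @param T Growth time, days (>= 0).
#' @param cfg A [scenario_config()].
#' @return Final offspring masses, mg (same order as input).
#' @export
grow_offspring <- function(masses, ON, T, cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (any(masses <= 0)) stop("offspring masses must be positive")
  if (T < 0) stop("T must be non-negative")
  K <- capacity(ON, cfg$link)
  if (any(masses > K)) {
    warning("propagule mass exceeds capacity(ON); logistic decreases toward K")
  }
  masses * K / (masses + (K - masses) * exp(-cfg$r * T))
}

#' Run one two-generation scenario
#'
#' Composes parent growth, pool generation, survival thinning and offspring
#' growth. If \code{cfg$seed} is set the random stages draw from a stream
#' seeded with it, so a scenario is fully reproducible.
#'
#' @param cfg A [scenario_config()].
#' @return Object of class \code{"run_result"}: a one-row data.frame with
#'   columns \code{PN}, \code{ON}, \code{SR}, \code{T},
#'   \code{parent_mass}, \code{n_propagules}, \code{n_survivors},
#'   \code{total_propagule_mass}, \code{mean_propagule_mass} (survivors),
#'   \code{summed_offspring_mass}, \code{mean_offspring_mass}.
#' @export
run_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  TM <- grow_parent(cfg$parental_N, cfg)
  pool <- generate_pool(TM, cfg)
  survivors <- apply_survival(pool, cfg$survival_rate)
  final <- grow_offspring(survivors, cfg$offspring_N, cfg$offspring_time, cfg)
  out <- data.frame(
    PN = cfg$parental_N, ON = cfg$offspring_N, SR = cfg$survival_rate,
    T = cfg$offspring_time, parent_mass = TM,
    n_propagules = length(pool), n_survivors = length(survivors),
    total_propagule_mass = sum(survivors),
    mean_propagule_mass = mean(survivors),
    summed_offspring_mass = sum(final),
    mean_offspring_mass = mean(final))
  class(out) <- c("run_result", "data.frame")
  out
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf(
    "Scenario PN=%g ON=%g SR=%g T=%g: %d propagules, %d survivors\n",
    x$PN, x$ON, x$SR, x$T, x$n_propagules, x$n_survivors))
  cat(sprintf("  summed offspring mass %.4g mg, mean %.4g mg\n",
              x$summed_offspring_mass, x$mean_offspring_mass))
  invisible(x)
}

#' Factorial designs of the simulation experiment
#'
#' \code{factorial_design()} is the full four-factor design: parental and
#' offspring nitrogen both at 10-60 mg/L in steps of 10, survival rates
#' 25/50/75/100\%, offspring growth times 30, 45, 60, 75, 150 and 300 days,
#' five replicates — 4320 scenarios. \code{propagule_design()} stops the model
#' at the propagule stage (no offspring nitrogen or growth time): 6 parental
#' N levels x 4 survival rates x 5 replicates = 120 scenarios.
#'
#' @param PN,ON Nitrogen level sets, mg/L.
#' @param SR Survival-rate set.
#' @param T Offspring growth times, days.
#' @param replicates Number of replicate runs per cell.
#' @return A list describing the design (level sets + replicates).
#' @export
factorial_design <- function(PN = seq(10, 60, by = 10),
                             ON = seq(10, 60, by = 10),
                             SR = c(0.25, 0.5, 0.75, 1),
                             T = c(30, 45, 60, 75, 150, 300),
                             replicates = 5) {
  stopifnot(length(PN) > 0, length(ON) > 0, length(SR) > 0, length(T) > 0,
            replicates >= 1)
  list(PN = PN, ON = ON, SR = SR, T = T, replicates = as.integer(replicates))
}

#' @rdname factorial_design
#' @export
propagule_design <- function(PN = seq(10, 60, by = 10),
                             SR = c(0.25, 0.5, 0.75, 1),
                             replicates = 5) {
  stopifnot(length(PN) > 0, length(SR) > 0, replicates >= 1)
  list(PN = PN, SR = SR, replicates = as.integer(replicates))
}

# one scenario seed per design row, derived deterministically from the master
# seed and the row index so subsets are reproducible regardless of run order
.scenario_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run the full factorial simulation experiment
#'
#' Expands the design into its scenario grid and runs [run_scenario()] for
#' each cell and replicate. Every scenario gets its own substream seed derived
#' from the master seed and the scenario index, so the table is bit-identical
#' for a fixed master seed and independent of execution order.
#'
#' @param design A [factorial_design()].
#' @param master_seed Integer master seed.
#' @param cfg_args Named list of extra arguments passed to
#'   [scenario_config()] (e.g. a non-default allometry).
#' @return Data frame with one row per scenario (see [run_scenario()]),
#'   plus a \code{replicate} column.
#' @export
run_full_factorial <- function(design = factorial_design(), master_seed = 1,
                               cfg_args = list()) {
  grid <- expand.grid(replicate = seq_len(design$replicates), T = design$T,
                      SR = design$SR, ON = design$ON, PN = design$PN,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("PN", "ON", "SR", "T", "replicate")]
  seeds <- .scenario_seeds(master_seed, nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- do.call(scenario_config, c(list(
      parental_N = grid$PN[i], offspring_N = grid$ON[i],
      survival_rate = grid$SR[i], offspring_time = grid$T[i],
      seed = seeds[i]), cfg_args))
    rows[[i]] <- as.data.frame(run_scenario(cfg))
  }
  out <- do.call(rbind, rows)
  out$replicate <- grid$replicate
  rownames(out) <- NULL
  out
}

#' Run the propagule-stage factorial
#'
#' As [run_full_factorial()] but the model stops after survival thinning:
#' the responses are the total mass, number and mean mass of the surviving
#' propagules of each parent (the quantities behind the propagule-stage
#' ANOVA and summaries).
#'
#' @inheritParams run_full_factorial
#' @param design A [propagule_design()].
#' @return Data frame with columns \code{PN}, \code{SR}, \code{replicate},
#'   \code{parent_mass}, \code{n_propagules}, \code{n_survivors},
#'   \code{total_propagule_mass}, \code{mean_propagule_mass}.
#' @export
run_propagule_factorial <- function(design = propagule_design(),
                                    master_seed = 1, cfg_args = list()) {
  grid <- expand.grid(replicate = seq_len(design$replicates), SR = design$SR,
                      PN = design$PN, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("PN", "SR", "replicate")]
  seeds <- .scenario_seeds(master_seed, nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- do.call(scenario_config, c(list(
      parental_N = grid$PN[i], offspring_N = grid$PN[i],
      survival_rate = grid$SR[i], offspring_time = 0,
      seed = seeds[i]), cfg_args))
    set.seed(seeds[i])
    TM <- grow_parent(grid$PN[i], cfg)
    pool <- generate_pool(TM, cfg)
    survivors <- apply_survival(pool, grid$SR[i])
    rows[[i]] <- data.frame(
      PN = grid$PN[i], SR = grid$SR[i], replicate = grid$replicate[i],
      parent_mass = TM, n_propagules = length(pool),
      n_survivors = length(survivors),
      total_propagule_mass = sum(survivors),
      mean_propagule_mass = mean(survivors))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
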