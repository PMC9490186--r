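cfg10 <- scenario_config(parental_N = 10, offspring_N = 10, survival_rate = 1,
                         offspring_time = 30, seed = 101)

test_that("parent growth is the deterministic logistic at capacity(PN)", {
  expect_equal(grow_parent(10, cfg10), 3847.52117, tolerance = 1e-7)
  expect_equal(grow_parent(60, cfg10), 11663.4464, tolerance = 1e-7)
  cfg0 <- scenario_config(10, 10, 1, 30, parent_time = 0)
  expect_equal(grow_parent(10, cfg0), 22.38)
})

test_that("the propagule pool chains count, mean mass and Weibull sampling", {
  TM <- grow_parent(10, cfg10)
  set.seed(1)
  pool <- generate_pool(TM, cfg10)
  expect_length(pool, 72L)
  expect_true(all(pool > 0))
  set.seed(77); a <- generate_pool(TM, cfg10)
  set.seed(77); b <- generate_pool(TM, cfg10)
  expect_identical(a, b)
  # long-run pool mean equals the implied Weibull mean
  wp <- weibull_params_from_meanmass(propagule_mean_mass(TM))
  expected <- wp$scale * gamma(1 + 1 / wp$shape)
  set.seed(55)
  means <- replicate(1000, mean(generate_pool(TM, cfg10)))
  expect_lt(abs(mean(means) - expected) / expected, 0.01)
})

test_that("survival thinning keeps round(n * SR) propagules, at least one", {
  x <- seq_len(72)
  expect_identical(apply_survival(x, 1), x)
  set.seed(2)
  expect_length(apply_survival(x, 0.25), 18L)
  expect_length(apply_survival(seq_len(3), 0.1), 1L)
  expect_error(apply_survival(x, 0), "\\(0, 1\\]")
  expect_error(apply_survival(x, 1.2), "\\(0, 1\\]")
  # conservation of count across a grid of pool sizes and rates
  for (n in c(1, 7, 72, 153)) {
    for (SR in c(0.25, 0.5, 0.75, 1)) {
      set.seed(n + SR * 100)
      expect_length(apply_survival(seq_len(n), SR),
                    max(1L, as.integer(floor(n * SR + 0.5))))
    }
  }
})

test_that("survival thinning is unbiased for the surviving mean mass", {
  TM <- grow_parent(10, cfg10)
  set.seed(31)
  diffs <- replicate(1000, {
    pool <- generate_pool(TM, cfg10)
    mean(apply_survival(pool, 0.25)) - mean(pool)
  })
  # mean over seeds is zero within Monte-Carlo error (~3 se)
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("offspring grow independently and saturate at capacity(ON)", {
  masses <- c(20, 45, 90)
  expect_equal(grow_offspring(masses, 10, 0, cfg10), masses)
  sat <- grow_offspring(masses, 40, 300, cfg10)
  expect_equal(sat, rep(capacity(40), 3), tolerance = 1e-9)
  # strict order preservation at intermediate times
  grown <- grow_offspring(sort(masses), 20, 45, cfg10)
  expect_true(all(diff(grown) > 0))
  expect_warning(grow_offspring(c(10, 6000), 10, 10, cfg10), "capacity")
  expect_error(grow_offspring(c(-1, 5), 10, 10, cfg10), "positive")
})

test_that("run_scenario composes the chain reproducibly", {
  cfg <- scenario_config(10, 10, 1, 300, seed = 404)
  res <- run_scenario(cfg)
  expect_equal(res$n_propagules, 72L)
  expect_equal(res$n_survivors, 72L)
  expect_equal(res$summed_offspring_mass, 72 * 4161.816, tolerance = 1e-6)
  expect_equal(res$total_propagule_mass,
               res$mean_propagule_mass * res$n_survivors)
  expect_identical(as.data.frame(run_scenario(cfg)), as.data.frame(res))
  # survival halves the summed mass at saturation but not the mean
  half <- run_scenario(scenario_config(10, 10, 0.5, 300, seed = 404))
  expect_equal(half$mean_offspring_mass, res$mean_offspring_mass,
               tolerance = 1e-9)
  expect_equal(half$summed_offspring_mass / res$summed_offspring_mass, 0.5,
               tolerance = 1e-6)
})

test_that("factorial designs expand to the documented sizes", {
  d <- factorial_design()
  expect_equal(length(d$PN) * length(d$ON) * length(d$SR) * length(d$T) *
                 d$replicates, 4320L)
  small <- factorial_design(PN = c(10, 60), ON = c(10, 60), SR = 1, T = 30,
                            replicates = 1)
  runs <- run_full_factorial(small, master_seed = 5)
  expect_equal(nrow(runs), 4L)
  expect_identical(run_full_factorial(small, master_seed = 5), runs)
  expect_false(identical(run_full_factorial(small, master_seed = 6), runs))
  expect_true(all(runs$n_survivors <= runs$n_propagules))
})

test_that("the propagule factorial stops after thinning with exact SR=1 counts", {
  pruns <- run_propagule_factorial(master_seed = 9)
  expect_equal(nrow(pruns), 120L)
  sr1 <- pruns[pruns$SR == 1, ]
  expect_equal(sr1$n_survivors, propagule_count(grow_parent(sr1$PN, cfg10)))
  # seed-averaged mean propagule mass increases with parental N
  agg <- aggregate(mean_propagule_mass ~ PN, data = pruns, FUN = mean)
  expect_true(all(diff(agg$mean_propagule_mass) > 0))
  agg2 <- aggregate(total_propagule_mass ~ PN,
                    data = pruns[pruns$SR == 1, ], FUN = mean)
  expect_true(all(diff(agg2$total_propagule_mass) > 0))
})

test_that("parental effects on mean offspring mass vanish at the late stage", {
  design <- factorial_design(PN = seq(10, 60, by = 10), ON = 30, SR = 1,
                             T = c(30, 300), replicates = 3)
  runs <- run_full_factorial(design, master_seed = 14)
  v <- vapply(c(30, 300), function(tt) {
    cell <- aggregate(mean_offspring_mass ~ PN, data = runs[runs$T == tt, ],
                      FUN = mean)
    var(cell$mean_offspring_mass)
  }, numeric(1))
  expect_lt(v[2] / v[1], 1e-6)
})

test_that("survival rate has no systematic effect on mean offspring mass", {
  seeds <- 1:400
  d <- vapply(seeds, function(s) {
    a <- run_scenario(scenario_config(20, 40, 0.5, 45, seed = s))
    b <- run_scenario(scenario_config(20, 40, 1, 45, seed = s + 5000))
    a$mean_offspring_mass - b$mean_offspring_mass
  }, numeric(1))
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})

test_that("summed offspring mass increases with parental N", {
  design <- factorial_design(PN = seq(10, 60, by = 10), ON = 30, SR = 1,
                             T = 45, replicates = 5)
  runs <- run_full_factorial(design, master_seed = 15)
  agg <- aggregate(summed_offspring_mass ~ PN, data = runs, FUN = mean)
  expect_true(all(diff(agg$summed_offspring_mass) > 0))
})
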