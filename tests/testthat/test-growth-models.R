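test_that("capacity link maps nitrogen levels to the published capacities", {
  link <- capacity_link()
  expect_equal(capacity(0, link), 1965.396)
  expect_equal(capacity(10, link), 4161.816)
  expect_equal(capacity(60, link), 15143.916)
  # affine: capacity(a) + capacity(b) = capacity(a+b) + delta
  for (pair in list(c(10, 20), c(5, 55), c(0, 60))) {
    expect_equal(capacity(pair[1]) + capacity(pair[2]),
                 capacity(sum(pair)) + link$delta)
  }
  expect_error(capacity(-1, link), "non-negative")
  expect_error(capacity(10, capacity_link(gamma = -300, delta = 100)),
               "invalid capacity")
})

test_that("logistic closed form hits its endpoints and the worked value", {
  p <- growth_params(M0 = 22.38, r = 0.103, K = 4161.816)
  expect_equal(logistic_mass(0, p), 22.38)
  expect_equal(logistic_mass(1e6, p), 4161.816, tolerance = 1e-9)
  expect_equal(logistic_mass(75, p), 3847.52117, tolerance = 1e-7)
  expect_error(logistic_mass(-1, p), "non-negative")
})

test_that("logistic closed form solves the logistic ODE", {
  times <- seq(0, 300, by = 5)
  for (N in seq(10, 60, by = 10)) {
    K <- capacity(N)
    p <- growth_params(M0 = 22.38, r = 0.103, K = K)
    ode <- logistic_ode_oracle(times, 22.38, 0.103, K)
    expect_equal(logistic_mass(times, p), ode, tolerance = 1e-8)
  }
})

test_that("logistic growth is monotone in t, K and r below capacity", {
  t_grid <- seq(0, 150, by = 10)
  masses <- logistic_mass(t_grid, growth_params(K = 5000))
  expect_true(all(diff(masses) > 0))
  for (t in c(10, 75, 200)) {
    by_K <- vapply(c(2000, 5000, 10000, 15000), function(K)
      logistic_mass(t, growth_params(K = K)), numeric(1))
    expect_true(all(diff(by_K) > 0))
    by_r <- vapply(c(0.05, 0.103, 0.2, 0.4), function(r)
      logistic_mass(t, growth_params(r = r, K = 5000)), numeric(1))
    expect_true(all(diff(by_r) > 0))
  }
  # above capacity the curve decreases toward K
  high <- logistic_mass(c(0, 50, 500), growth_params(M0 = 9000, K = 5000))
  expect_true(all(diff(high) < 0))
  expect_equal(high[3], 5000, tolerance = 1e-6)
})

test_that("growth_curve closed forms honour M(0) = M0 and fixed points", {
  expect_equal(growth_curve(0, "monomolecular", c(M0 = 22.38, r = 0.1, K = 5000)),
               22.38)
  expect_equal(growth_curve(0, "gompertz", c(M0 = 22.38, r = 0.1, K = 5000)),
               22.38)
  expect_equal(growth_curve(0, "power", c(M0 = 22.38, b = 1.3)), 22.38)
  expect_equal(growth_curve(0, "linear", c(M0 = 22.38, b = 12)), 22.38)
  expect_equal(growth_curve(0, "exponential", c(M0 = 22.38, r = 0.1)), 22.38)
  # logistic at M0 = K stays at K for any time
  expect_equal(growth_curve(c(0, 33, 400), "logistic3",
                            c(M0 = 5000, r = 0.1, K = 5000)),
               rep(5000, 3))
  expect_equal(growth_curve(40, "logistic3", c(M0 = 22.38, r = 0.103, K = 4161.816)),
               logistic_mass(40, growth_params(K = 4161.816)))
  expect_error(growth_curve(1, "logistic3", c(M0 = 22.38, r = 0.103)),
               "incomplete params")
  expect_error(growth_curve(1, "parabola", c(M0 = 1)))
})

test_that("fit_growth recovers truth exactly from noise-free data", {
  traj <- noise_free_trajectories()
  fit <- fit_growth(traj, "logistic3", M0_fixed = 22.38)
  expect_equal(unname(coef(fit)["r"]), 0.103, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["gamma"]), 219.642, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["delta"]), 1965.396, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-6)
  expect_equal(fit$n, 64L)
  expect_equal(fit$k, 3L)
})

test_that("AIC ranks the generating family first on noise-free data", {
  traj <- noise_free_trajectories()
  logi <- fit_growth(traj, "logistic3")
  lin <- fit_growth(traj, "linear")
  expect_lt(logi$aic, lin$aic)
  fits <- lapply(growth_families(), function(f) fit_growth(traj, f))
  expect_equal(as.character(select_growth(fits)), "logistic3")
})

test_that("underdetermined fits and degenerate selections error", {
  two <- data.frame(N_level = c(10, 10), t = c(30, 75), mass = c(900, 3800))
  expect_error(fit_growth(two, "logistic3"), "underdetermined")
  expect_error(select_growth(list()), "no fits")
})

test_that("AIC ties break toward fewer parameters, then family order", {
  traj <- noise_free_trajectories()
  a <- fit_growth(traj, "logistic3")
  b <- fit_growth(traj, "linear")
  # force an exact tie and a parameter difference
  a$aic <- 100; b$aic <- 100
  expect_equal(as.character(select_growth(list(a, b))), "linear")
  c2 <- fit_growth(traj, "exponential"); c2$aic <- 100
  # linear precedes exponential in the fixed family order
  expect_equal(as.character(select_growth(list(c2, a, b))), "linear")
  expect_equal(as.character(select_growth(list(a))), "logistic3")
})

test_that("predict on a growth fit reproduces the training surface", {
  traj <- noise_free_trajectories()
  fit <- fit_growth(traj, "logistic3")
  expect_equal(predict(fit), traj$dry_mass, tolerance = 1e-6)
})
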