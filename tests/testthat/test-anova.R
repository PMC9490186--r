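test_that("degenerate responses give all-zero or exploding F values", {
  d <- data.frame(PN = rep(c(10, 20, 30), each = 4),
                  SR = rep(c(0.25, 1), 6))
  d$y <- 5
  an <- sequential_anova(d, "y", c("PN", "SR"))
  expect_equal(an$F, c(0, 0, 0))
  # exact linear signal in PN: PN blows up, SR carries nothing
  d$y <- 3 + 2 * d$PN
  an2 <- sequential_anova(d, "y", c("PN", "SR"), interaction_order = 1)
  expect_true(is.infinite(an2$F[an2$term == "PN"]))
  expect_equal(an2$F[an2$term == "SR"], 0)
})

test_that("sequential F matches the nested-projection oracle on random tables", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- data.frame(PN = sample(seq(10, 60, 10), 40, TRUE),
                    ON = sample(seq(10, 60, 10), 40, TRUE),
                    SR = sample(c(0.25, 0.5, 0.75, 1), 40, TRUE))
    d$y <- rnorm(40, 100 + d$PN + 0.5 * d$ON * d$SR, 20)
    an <- sequential_anova(d, "y", c("PN", "ON", "SR"))
    cols <- expand_term_cols(d, c("PN", "ON", "SR"))
    oracle <- seq_anova_oracle(d$y, cols)
    expect_equal(an$term, names(cols))
    expect_equal(an$F, oracle$F, tolerance = 1e-8)
    expect_equal(an$df_den[1], oracle$df_den)
    # sequential SS plus residual SS reconstructs the total SS
    expect_equal(sum(an$ss) + attr(an, "rss"), attr(an, "tss"),
                 tolerance = 1e-8)
  }
})

test_that("sequential equals marginal F on an orthogonal centered design", {
  grid <- expand.grid(PN = seq(10, 60, 10), ON = seq(10, 60, 10),
                      SR = c(0.25, 0.5, 0.75, 1))
  grid$PNc <- grid$PN - mean(grid$PN)
  grid$ONc <- grid$ON - mean(grid$ON)
  grid$SRc <- grid$SR - mean(grid$SR)
  set.seed(33)
  grid$y <- rnorm(nrow(grid), grid$PNc + grid$ONc * grid$SRc, 5)
  an <- sequential_anova(grid, "y", c("PNc", "ONc", "SRc"))
  fit <- lm(y ~ PNc * ONc * SRc, data = grid)
  marginal <- summary(fit)$coefficients[-1, "t value"]^2
  expect_equal(unname(an$F), unname(marginal), tolerance = 1e-8)
})

test_that("rank-deficient designs are rejected with the term named", {
  d <- data.frame(PN = rep(seq(10, 60, 10), each = 5), SR = 1)
  set.seed(3)
  d$total <- rnorm(30, d$PN)
  expect_error(sequential_anova(d, "total", c("PN", "SR")), "SR")
})

test_that("propagule-stage ANOVA has the printed degrees of freedom", {
  pruns <- run_propagule_factorial(master_seed = 40)
  t2 <- table2_anova(pruns)
  expect_named(t2, c("total_propagule_mass", "n_survivors",
                     "mean_propagule_mass"))
  for (tb in t2) {
    expect_equal(tb$term, c("PN", "SR", "PN:SR"))
    expect_equal(tb$df_num, rep(1L, 3))
    expect_equal(tb$df_den, rep(116L, 3))
  }
})

test_that("offspring ANOVA has 15 terms in the printed order with df 4304", {
  runs <- run_full_factorial(
    factorial_design(PN = c(10, 60), ON = c(10, 60), SR = c(0.5, 1),
                     T = c(30, 75), replicates = 2), master_seed = 41)
  t3 <- sequential_anova(runs, "summed_offspring_mass",
                         c("PN", "ON", "SR", "T"))
  expect_equal(t3$term,
               c("PN", "ON", "SR", "T", "PN:ON", "PN:SR", "ON:SR", "PN:T",
                 "ON:T", "SR:T", "PN:ON:SR", "PN:ON:T", "PN:SR:T", "ON:SR:T",
                 "PN:ON:SR:T"))
  expect_equal(t3$df_den[1], nrow(runs) - 16L)
})

test_that("figure summaries aggregate cell means with sd/sqrt(reps) errors", {
  pruns <- run_propagule_factorial(
    propagule_design(PN = c(10, 20), SR = c(0.5, 1), replicates = 5),
    master_seed = 42)
  figs <- summarize_figures(propagule_runs = pruns)
  expect_equal(nrow(figs$propagule), 4L)
  cell <- pruns[pruns$PN == 10 & pruns$SR == 0.5, "total_propagule_mass"]
  row <- figs$propagule[figs$propagule$PN == 10 & figs$propagule$SR == 0.5, ]
  expect_equal(row$total_propagule_mass_mean, mean(cell))
  expect_equal(row$total_propagule_mass_se, sd(cell) / sqrt(5))
  # empty subset gives an empty frame with headers
  empty <- summarize_figures(full_runs = pruns[0, ])
  expect_equal(nrow(empty$offspring), 0L)
  expect_true(all(c("T", "PN", "ON") %in% names(empty$offspring)))
})

test_that("mean offspring mass is flat across PN but not ON at saturation", {
  runs <- run_full_factorial(
    factorial_design(PN = seq(10, 60, 10), ON = seq(10, 60, 10), SR = 1,
                     T = 300, replicates = 2), master_seed = 43)
  figs <- summarize_figures(full_runs = runs)
  agg <- figs$offspring
  for (on in unique(agg$ON)) {
    cell <- agg$mean_offspring_mass_mean[agg$ON == on]
    expect_lt(diff(range(cell)) / mean(cell), 1e-6)
  }
  by_on <- aggregate(mean_offspring_mass_mean ~ ON, data = agg, FUN = mean)
  expect_true(all(diff(by_on$mean_offspring_mass_mean) > 0))
})
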