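# Independent oracles used across test files.

# Sequential (Type-I) sums of squares by explicit nested-model projections:
# term_cols is an ordered list of raw model-matrix columns (no intercept).
seq_anova_oracle <- function(y, term_cols) {
  n <- length(y)
  k <- length(term_cols)
  rss <- numeric(k + 1)
  X <- matrix(1, n, 1)
  rss[1] <- sum(qr.resid(qr(X), y)^2)
  for (i in seq_len(k)) {
    X <- cbind(X, term_cols[[i]])
    rss[i + 1] <- sum(qr.resid(qr(X), y)^2)
  }
  ss <- rss[seq_len(k)] - rss[-1]
  df_den <- n - k - 1
  list(ss = ss, F = ss / (rss[k + 1] / df_den), df_den = df_den,
       rss = rss[k + 1])
}

# product-expansion term columns for predictors in data frame d, matching the
# printed-table order (mains, then interactions of increasing order as in
# p1*p2*...*pk)
expand_term_cols <- function(d, predictors) {
  labels <- attr(stats::terms(stats::reformulate(
    paste(predictors, collapse = "*"))), "term.labels")
  cols <- lapply(strsplit(labels, ":", fixed = TRUE), function(tm) {
    Reduce(`*`, lapply(tm, function(p) d[[p]]))
  })
  names(cols) <- labels
  cols
}

# high-accuracy numerical integration of the logistic ODE dM/dt = r M (1 - M/K)
logistic_ode_oracle <- function(times, M0, r, K) {
  out <- deSolve::ode(
    y = c(M = M0), times = times,
    func = function(t, y, parms) list(parms["r"] * y * (1 - y / parms["K"])),
    parms = c(r = r, K = K), method = "lsoda",
    rtol = 1e-12, atol = 1e-10)
  unname(out[, "M"])
}

# noise-free trajectory fixture on the greenhouse design
noise_free_trajectories <- function() {
  gen_trajectories(truth_config(noise_sd = 0, vigor_sd = 0))
}
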