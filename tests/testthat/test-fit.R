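test_that("noise-free decay and association are inverted to machine precision", {
  t <- seq(2, 2 + 29.5, by = 0.5)
  y <- 1 + 1 * exp(-(t - 2) / 9.5)
  f <- fit_one_phase(t, y, "decay", t0 = 2)
  expect_lt(abs(f$tau - 9.5) / 9.5, 1e-6)
  expect_lt(max(abs(residuals(f))), 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_identical(f$df, length(t) - 3L)         # three free parameters
  expect_true(f$converged)

  ya <- 2 - 0.9 * exp(-(t - 2) / 2)
  fa <- fit_one_phase(t, ya, "association", t0 = 2)
  expect_lt(abs(fa$tau - 2) / 2, 1e-6)
  expect_lt(max(abs(residuals(fa))), 1e-8)
})

test_that("association fit is the reflection of the decay fit", {
  set.seed(83)
  t <- seq(0, 20, by = 0.5)
  y <- 2 - 0.8 * exp(-t / 3) + rnorm(length(t), 0, 0.02)
  fa <- fit_one_phase(t, y, "association", t0 = 0)
  fd <- fit_one_phase(t, 4 - y, "decay", t0 = 0)   # reflect about 2
  expect_equal(fa$coefficients[["K"]], fd$coefficients[["K"]],
               tolerance = 1e-6)
  expect_equal(fa$coefficients[["y0"]], 4 - fd$coefficients[["y0"]],
               tolerance = 1e-6)
  expect_equal(abs(residuals(fa)), abs(residuals(fd)), tolerance = 1e-6)
})

test_that("R squared matches hand arithmetic and its edge cases", {
  y <- c(2, 1.5, 1.2, 1.0); yhat <- c(2, 1.6, 1.1, 1.0)
  # SS_res = 0.02, SS_tot about mean 1.425 = 0.5675
  expect_equal(r_squared(y, yhat), 1 - 0.02 / 0.5675)
  expect_equal(r_squared(y, yhat), 0.9647577, tolerance = 1e-6)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4L)), 0)
  expect_warning(r2 <- r_squared(c(1, 1), c(1, 0.9)), "zero total")
  expect_true(is.na(r2))
})

test_that("rescaling time rescales tau and leaves R squared unchanged", {
  set.seed(29)
  t <- seq(0, 15, by = 0.5)
  y <- 1.2 + 0.8 * exp(-t / 4) + rnorm(length(t), 0, 0.03)
  f1 <- fit_one_phase(t, y, "decay", t0 = 0)
  f2 <- fit_one_phase(3 * t, y, "decay", t0 = 0)
  expect_equal(f2$tau, 3 * f1$tau, tolerance = 1e-6)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-8)
  expect_equal(f2$ci95_tau, 3 * f1$ci95_tau, tolerance = 1e-5)
})

test_that("constant traces are flagged unidentifiable instead of lying", {
  t <- seq(2, 17, by = 0.5)
  suppressWarnings(f <- fit_one_phase(t, rep(1.5, length(t)), "decay",
                                      t0 = 2))
  expect_false(f$identifiable && f$converged &&
                 abs(f$coefficients[["y0"]] - f$coefficients[["plateau"]]) >
                   1e-6 && diff(f$ci95_tau) < Inf)
  expect_true(f$ci95_tau[1L] <= f$tau || !is.finite(f$tau))
})

test_that("the fit window starts at the treatment time", {
  t <- seq(0, 17, by = 0.5)
  y <- ifelse(t < 2, 2, 1 + 1 * exp(-(t - 2) / 5))
  f <- fit_one_phase(t, y, "decay", t0 = 2)
  expect_identical(f$n_points, sum(t >= 2))
  expect_lt(abs(f$tau - 5) / 5, 1e-6)
  # including the baseline as a flat segment uses every point
  fb <- fit_one_phase(t, y, "decay", t0 = 2, include_baseline = TRUE)
  expect_identical(fb$n_points, length(t))
  expect_lt(abs(fb$tau - 5) / 5, 1e-5)
  expect_error(fit_one_phase(t, y, "decay", t0 = 100), "after t0")
  expect_error(fit_one_phase(t[1:3], y[1:3], "decay", t0 = 0),
               "at least 4")
})

test_that("tau estimation is near the efficiency bound with honest CI coverage", {
  # the asymptotic bound for this design, from the Jacobian at the truth
  tau <- 9.5; K <- 1 / tau; s <- 0.05
  tp <- seq(0, 14.5, by = 0.5)
  e <- exp(-K * tp)
  J <- cbind(e, 1 - e, -tp * 1 * e)
  bound_se_tau <- sqrt((s^2 * solve(t(J) %*% J))[3L, 3L]) / K^2
  implied_median <- qnorm(0.75) * bound_se_tau / tau

  set.seed(1234)
  n_sim <- 80L
  err <- numeric(n_sim); cover <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    y <- 1 + e + rnorm(length(tp), 0, s)
    f <- fit_one_phase(tp, y, "decay", t0 = 0)
    err[i] <- abs(f$tau - tau) / tau
    cover[i] <- f$ci95_tau[1L] <= tau && tau <= f$ci95_tau[2L]
  }
  expect_lt(median(err), 1.3 * implied_median)   # near-efficient
  expect_gte(mean(cover), 0.9)
})

test_that("profile-likelihood interval brackets the asymptotic one sanely", {
  set.seed(55)
  t <- seq(0, 30, by = 1)
  y <- 1 + exp(-t / 9.5) + rnorm(length(t), 0, 0.04)
  fa <- fit_one_phase(t, y, "decay", t0 = 0, ci = "asymptotic")
  fp <- fit_one_phase(t, y, "decay", t0 = 0, ci = "profile")
  expect_equal(fa$tau, fp$tau)                   # same point estimate
  expect_true(fp$ci95_tau[1L] < fp$tau && fp$tau < fp$ci95_tau[2L])
  # both intervals should cover the truth here
  expect_true(fp$ci95_tau[1L] <= 9.5 && 9.5 <= fp$ci95_tau[2L])
})

test_that("model object supports the standard S3 verbs", {
  t <- seq(0, 15, by = 0.5)
  set.seed(99)
  y <- 1.1 + 0.9 * exp(-t / 6) + rnorm(length(t), 0, 0.02)
  f <- fit_one_phase(t, y, "decay", t0 = 0)
  expect_named(coef(f), c("y0", "plateau", "K"))
  expect_length(fitted(f), length(t))
  expect_equal(fitted(f) + residuals(f), y, tolerance = 1e-12)
  expect_equal(predict(f), fitted(f))
  expect_equal(dim(vcov(f)), c(3L, 3L))
  sim <- simulate(f, nsim = 3L, seed = 1)
  expect_identical(dim(sim), c(length(t), 3L))
  expect_output(print(f), "tau")
  expect_output(print(summary(f)), "Coefficients")
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); plot(f); grDevices::dev.off()
  expect_true(file.exists(tf))
  unlink(tf)
})
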