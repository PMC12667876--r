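#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, with the total sum of squares taken about the
#' mean of the observed values in the fit window.
#'
#' @param values observed values.
#' @param fitted fitted values, same length.
#' @return R squared; `NA` (with a warning) when the observations have
#'   zero variance.
#' @export
r_squared <- function(values, fitted) {
  stopifnot(length(values) == length(fitted), length(values) >= 2L)
  ss_tot <- sum((values - mean(values))^2)
  if (ss_tot == 0) {
    warning("zero total sum of squares: R squared undefined")
    return(NA_real_)
  }
  1 - sum((values - fitted)^2) / ss_tot
}

one_phase_curve <- function(p, t, t0) {
  p[["plateau"]] + (p[["y0"]] - p[["plateau"]]) * exp(-p[["K"]] * (t - t0))
}

#' Fit a constrained one-phase exponential to a ratio trace
#'
#' Least-squares fit of
#' \deqn{y = plateau + (y_0 - plateau)\, e^{-K (t - t_0)}}
#' to the points at or after the treatment time \eqn{t_0}, with the rate
#' constant constrained to \eqn{K > 0} by bounded Levenberg-Marquardt
#' (the bound is enforced directly rather than by reparameterising, so
#' the parameter covariance stays interpretable).  Decay and association
#' are the same curve approached from opposite sides; `model` only picks
#' the starting values.
#'
#' Reported alongside the coefficients: the time constant `tau = 1/K`,
#' its 95% confidence interval (asymptotic Jacobian-based variance of K,
#' delta-method transform `var(tau) = var(K)/K^4`, Student-t critical
#' value at `df = n - 3`; optionally a profile-likelihood interval), R
#' squared about the fit-window mean, and the degrees of freedom.
#'
#' @param times numeric vector of times (minutes).
#' @param values observed ratios, same length; `NA`s are dropped.
#' @param model `"decay"` or `"association"`.
#' @param t0 treatment time (minutes); the fit window is `times >= t0`.
#'   Points before `t0` are excluded unless `include_baseline = TRUE`, in
#'   which case they enter as a constant-`y0` pre-treatment segment.
#' @param include_baseline include pre-treatment points as a flat segment.
#' @param ci `"asymptotic"` (default) or `"profile"` for the tau interval.
#' @param trace optionally a `ratio_trace` data frame in place of
#'   `times`/`values` (uses its `time_min`, `ratio` and treatment time).
#' @return an object of class `one_phase_fit`.
#' @examples
#' t <- seq(0, 15, by = 0.5)
#' y <- 1 + 1 * exp(-t / 9.5)
#' f <- fit_one_phase(t, y, model = "decay", t0 = 0)
#' coef(f); f$tau
#' @export
fit_one_phase <- function(times, values, model = c("decay", "association"),
                          t0 = 0, include_baseline = FALSE,
                          ci = c("asymptotic", "profile"), trace = NULL) {
  model <- match.arg(model)
  ci <- match.arg(ci)
  if (!is.null(trace)) {
    stopifnot(inherits(trace, "ratio_trace") || is.data.frame(trace))
    times <- trace$time_min
    values <- trace$ratio
    if (missing(t0))
      t0 <- attr(trace, "treatment_time_min") %||% 0
  }
  stopifnot(length(times) == length(values))
  keep <- is.finite(times) & !is.na(values) & is.finite(values)
  times <- times[keep]; values <- values[keep]
  win <- times >= t0
  if (!any(win)) stop("no data points at or after t0 = ", t0)
  tw <- times[win]; yw <- values[win]
  if (length(tw) < 4L)
    stop("need at least 4 points after t0 to fit 3 parameters")

  span <- max(tw) - min(tw)
  if (span <= 0) stop("fit window has zero time span")
  start <- c(y0 = yw[which.min(tw)],
             plateau = if (model == "decay") min(yw) else max(yw),
             K = log(2) / (span / 2))

  tb <- times[!win]; yb <- values[!win]
  use_base <- include_baseline && length(tb) > 0L
  resid_fn <- function(p) {
    r <- yw - one_phase_curve(p, tw, t0)
    if (use_base) r <- c(yb - p[["y0"]], r)
    r
  }
  n_points <- length(yw) + if (use_base) length(yb) else 0L
  df <- n_points - 3L
  if (df < 1L) stop("not enough points for error estimation (df < 1)")

  fit <- minpack.lm::nls.lm(par = start, lower = c(-Inf, -Inf, 0),
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-10, ptol = 1e-10, maxfev = 10000,
                              maxiter = 1000))
  p <- fit$par
  K <- p[["K"]]
  converged <- fit$info %in% 1:4 && K > 1e-9
  fitted_w <- one_phase_curve(p, tw, t0)
  resids <- yw - fitted_w
  ss_res <- sum(resid_fn(p)^2)
  sigma2 <- ss_res / df
  vcov <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  identifiable <- !is.null(vcov) && all(is.finite(diag(vcov))) &&
    all(diag(vcov) >= 0) && K > 1e-9
  tau <- if (K > 0) 1 / K else Inf
  if (ci == "asymptotic") {
    if (identifiable) {
      se_tau <- sqrt(vcov["K", "K"]) / K^2          # delta method
      tcrit <- stats::qt(0.975, df)
      ci_tau <- c(max(tau - tcrit * se_tau, 0), tau + tcrit * se_tau)
    } else {
      ci_tau <- c(0, Inf)
    }
  } else {
    ci_tau <- profile_ci_tau(tw, yw, tb, yb, use_base, t0, p, ss_res, df)
  }

  structure(list(coefficients = p, tau = tau, ci95_tau = ci_tau,
                 r_squared = r_squared(yw, fitted_w), df = df,
                 n_points = n_points, converged = converged,
                 identifiable = identifiable, residuals = resids,
                 fitted.values = fitted_w, times = tw, values = yw,
                 t0 = t0, model = model, sigma = sqrt(sigma2),
                 vcov = vcov, ci_method = ci, include_baseline = use_base,
                 optim_info = fit$info, optim_message = fit$message),
            class = "one_phase_fit")
}

# Profile-likelihood CI for tau = 1/K.  For fixed K the model is linear
# in (plateau, amplitude), so the profiled SSR comes from a plain linear
# solve; the 95% bound is SSR(K) <= SSR_min * (1 + qF(0.95; 1, df)/df).
profile_ci_tau <- function(tw, yw, tb, yb, use_base, t0, p_hat, ss_min, df) {
  ssr_at <- function(K) {
    e <- exp(-K * (tw - t0))
    X <- cbind(1, e)
    y <- yw
    if (use_base) {
      # baseline observes y0 = plateau + amplitude directly
      X <- rbind(X, cbind(1, rep(1, length(yb))))
      y <- c(yw, yb)
    }
    co <- tryCatch(stats::lm.fit(X, y)$coefficients,
                   error = function(e2) c(mean(y), 0))
    sum((y - X %*% co)^2)
  }
  K_hat <- p_hat[["K"]]
  crit <- ss_min * (1 + stats::qf(0.95, 1, df) / df)
  f <- function(K) ssr_at(K) - crit
  lo <- tryCatch({
    kl <- K_hat
    while (kl > K_hat * 1e-6 && f(kl / 2) < 0) kl <- kl / 2
    if (f(kl / 2) < 0) 0 else stats::uniroot(f, c(kl / 2, K_hat))$root
  }, error = function(e) 0)
  hi <- tryCatch({
    kh <- K_hat
    while (kh < K_hat * 1e6 && f(kh * 2) < 0) kh <- kh * 2
    if (f(kh * 2) < 0) Inf else stats::uniroot(f, c(K_hat, kh * 2))$root
  }, error = function(e) Inf)
  # K interval maps to a reversed tau interval
  c(if (hi == 0 || !is.finite(hi)) 0 else 1 / hi,
    if (lo <= 0) Inf else 1 / lo)
}

#' @export
print.one_phase_fit <- function(x, digits = 4, ...) {
  cat("One-phase", x$model, "fit (K constrained > 0)\n")
  cat("  y0 =", signif(x$coefficients[["y0"]], digits),
      " plateau =", signif(x$coefficients[["plateau"]], digits),
      " K =", signif(x$coefficients[["K"]], digits), "/min\n")
  cat(sprintf("  tau = %s min, 95%% CI [%s, %s] (%s)\n",
              signif(x$tau, digits), signif(x$ci95_tau[1L], digits),
              signif(x$ci95_tau[2L], digits), x$ci_method))
  cat(sprintf("  R2 = %s, DF = %d, n = %d%s\n",
              signif(x$r_squared, digits), x$df, x$n_points,
              if (!x$converged) " [NOT CONVERGED]"
              else if (!x$identifiable) " [UNIDENTIFIABLE]" else ""))
  invisible(x)
}

#' @export
summary.one_phase_fit <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(pmax(diag(object$vcov), 0))
        else rep(NA_real_, 3L)
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se)
  structure(list(fit = object, coefficients = tab), class = "summary.one_phase_fit")
}

#' @export
print.summary.one_phase_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  print(x$coefficients)
  cat("\nResidual SD:", signif(x$fit$sigma, 4), "on", x$fit$df,
      "degrees of freedom\n")
  invisible(x)
}

#' @export
coef.one_phase_fit <- function(object, ...) object$coefficients

#' @export
fitted.one_phase_fit <- function(object, ...) object$fitted.values

#' @export
residuals.one_phase_fit <- function(object, ...) object$residuals

#' @export
vcov.one_phase_fit <- function(object, ...) object$vcov

#' @export
predict.one_phase_fit <- function(object, newtimes = NULL, ...) {
  t <- if (is.null(newtimes)) object$times else newtimes
  y <- one_phase_curve(object$coefficients, pmax(t, object$t0), object$t0)
  if (object$include_baseline || any(t < object$t0))
    y[t < object$t0] <- object$coefficients[["y0"]]
  y
}

#' @export
simulate.one_phase_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0,
                                                         object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "times") <- object$times
  out
}

#' @export
plot.one_phase_fit <- function(x, ci_band = TRUE, n_curve = 200, ...) {
  graphics::plot(x$times, x$values, pch = 16, col = "grey30",
                 xlab = "time (min)", ylab = "ratio", ...)
  tt <- seq(min(x$times), max(x$times), length.out = n_curve)
  yy <- predict(x, tt)
  if (ci_band && !is.null(x$vcov) && x$identifiable) {
    # delta-method pointwise band on the mean curve
    g <- function(t) {
      e <- exp(-x$coefficients[["K"]] * (t - x$t0))
      c(e, 1 - e,
        -(t - x$t0) * (x$coefficients[["y0"]] -
                         x$coefficients[["plateau"]]) * e)
    }
    se <- vapply(tt, function(t) {
      gr <- g(t); sqrt(max(t(gr) %*% x$vcov %*% gr, 0))
    }, 0)
    tcrit <- stats::qt(0.975, x$df)
    graphics::polygon(c(tt, rev(tt)),
                      c(yy - tcrit * se, rev(yy + tcrit * se)),
                      col = grDevices::adjustcolor("steelblue", 0.25),
                      border = NA)
  }
  graphics::lines(tt, yy, col = "steelblue", lwd = 2)
  graphics::abline(v = x$t0, lty = 3)
  invisible(x)
}
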