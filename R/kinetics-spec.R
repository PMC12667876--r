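#' Ground-truth kinetic model of biosensor enrichment
#'
#' Describes how a biosensor channel's vesicular enrichment ratio evolves
#' around the treatment time in a simulated movie.  Three models are
#' supported: a constant ratio (negative controls), a one-phase decay
#' (inhibitor washes the biosensor off the membranes) and a one-phase
#' association (an enzyme is acutely recruited and the biosensor follows).
#'
#' Both exponential models share the closed form
#' \deqn{y(t) = plateau + (y_0 - plateau)\,e^{-K (t - t_0)}, \quad t \ge t_0}
#' with \eqn{y(t) = y_0} for \eqn{t < t_0}; decay has `y0 > plateau`,
#' association `y0 < plateau`.
#'
#' @param model `"constant"`, `"one_phase_decay"` or
#'   `"one_phase_association"`.
#' @param y0 baseline ratio (dimensionless, >= 0).
#' @param plateau asymptotic ratio (dimensionless, >= 0); ignored for the
#'   constant model.
#' @param K rate constant in 1/min (> 0); required for the exponential
#'   models.  The time constant is `tau = 1/K`.
#' @param treatment_time_min time of stimulation in minutes from movie
#'   start (>= 0); default 2 min of baseline.
#' @return an object of class `kinetics_spec`.
#' @examples
#' k <- kinetics_spec("one_phase_decay", y0 = 2, plateau = 1, K = 1 / 9.5)
#' enrichment_at(k, c(0, 2, 2 + 9.5))
#' @export
kinetics_spec <- function(model = c("constant", "one_phase_decay",
                                    "one_phase_association"),
                          y0, plateau = y0, K = NULL,
                          treatment_time_min = 2) {
  model <- match.arg(model)
  stopifnot(is.numeric(y0), length(y0) == 1L,
            is.numeric(plateau), length(plateau) == 1L,
            is.numeric(treatment_time_min), length(treatment_time_min) == 1L)
  if (!is.finite(y0) || y0 < 0) stop("y0 must be finite and >= 0")
  if (!is.finite(plateau) || plateau < 0)
    stop("plateau must be finite and >= 0")
  if (!is.finite(treatment_time_min) || treatment_time_min < 0)
    stop("treatment_time_min must be finite and >= 0")
  if (model != "constant") {
    if (is.null(K) || !is.numeric(K) || length(K) != 1L ||
        !is.finite(K) || K <= 0)
      stop("K must be a finite positive rate (1/min) for model '", model, "'")
    if (model == "one_phase_decay" && y0 < plateau)
      warning("one_phase_decay with y0 < plateau rises, not decays")
    if (model == "one_phase_association" && y0 > plateau)
      warning("one_phase_association with y0 > plateau decays, not rises")
  } else {
    K <- NA_real_
    plateau <- y0
  }
  structure(list(model = model, y0 = y0, plateau = plateau, K = K,
                 treatment_time_min = treatment_time_min),
            class = "kinetics_spec")
}

#' @export
print.kinetics_spec <- function(x, ...) {
  cat("Kinetics:", x$model, "\n")
  if (x$model == "constant") {
    cat("  y0 =", x$y0, "\n")
  } else {
    cat(sprintf("  y0 = %g, plateau = %g, K = %g /min (tau = %.4g min), t0 = %g min\n",
                x$y0, x$plateau, x$K, 1 / x$K, x$treatment_time_min))
  }
  invisible(x)
}

#' Evaluate the enrichment model at given times
#'
#' @param kinetics a [kinetics_spec()].
#' @param t_min numeric vector of times in minutes (>= 0).
#' @return enrichment ratio at each time (dimensionless).
#' @export
enrichment_at <- function(kinetics, t_min) {
  stopifnot(inherits(kinetics, "kinetics_spec"), is.numeric(t_min))
  if (any(!is.finite(t_min)) || any(t_min < 0))
    stop("t_min must be finite and >= 0")
  if (kinetics$model == "constant")
    return(rep_len(kinetics$y0, length(t_min)))
  dt <- pmax(t_min - kinetics$treatment_time_min, 0)
  kinetics$plateau + (kinetics$y0 - kinetics$plateau) * exp(-kinetics$K * dt)
}
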