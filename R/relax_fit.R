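#' Control parameters for the gradient-descent relaxometry fit
#'
#' Hyperparameters of the voxelwise steepest-descent fit used by
#' [relax_fit()] and [fit_map()].  The defaults are the acquisition-matched
#' constants the analysis was designed around: start at
#' `(M0, T1) = (8000, 150)` for T1 series or `(M0, T2) = (8000, 75)` for T2
#' series, iterate at most 75000 times with learning rate `1e-6`.
#'
#' @param m0_init Initial M0 (signal units).  Default 8000.
#' @param t1_init Initial T1 in ms (used for T1 series).  Default 150.
#' @param t2_init Initial T2 in ms (used for T2 series).  Default 75.
#' @param loop_limit Hard cap on iterations.  Default 75000.
#' @param learning_rate Shared steepest-descent step scale for the
#'   `"raw"` mode.  Default `1e-6`.
#' @param early_stop_tol Relative parameter-change threshold below which the
#'   fit is declared converged; `0` disables early stopping so the loop
#'   always runs to `loop_limit`.  Default `1e-10`.
#' @param positivity_floor Lower clamp for the relaxation time in ms, keeping
#'   the exponential defined.  Default `1e-3`.
#' @param mode `"raw"` for plain shared-rate steepest descent, or `"scaled"`
#'   for the per-parameter-scaled fallback: steps scaled by the diagonal of
#'   the Gauss-Newton Hessian with backtracking on the loss and a relative
#'   per-iteration step cap.  The scaled mode converges over a far wider
#'   range of true `(M0, T)` but is not the default.
#' @param step_cap Maximum relative parameter change per iteration in
#'   `"scaled"` mode.  Default 0.25.
#' @param scaled_rate Initial step fraction of the diagonally-scaled step in
#'   `"scaled"` mode (backtracking halves it as needed).  Default 1.
#' @return A list of class `"relax_control"`.
#' @export
relax_control <- function(m0_init = 8000, t1_init = 150, t2_init = 75,
                          loop_limit = 75000, learning_rate = 1e-6,
                          early_stop_tol = 1e-10, positivity_floor = 1e-3,
                          mode = c("raw", "scaled"), step_cap = 0.25,
                          scaled_rate = 1) {
  mode <- match.arg(mode)
  if (loop_limit < 1) zf_validation_error("loop_limit must be >= 1")
  if (learning_rate <= 0) zf_validation_error("learning_rate must be > 0")
  if (positivity_floor <= 0) zf_validation_error("positivity_floor must be > 0")
  if (early_stop_tol < 0) zf_validation_error("early_stop_tol must be >= 0")
  structure(list(m0_init = m0_init, t1_init = t1_init, t2_init = t2_init,
                 loop_limit = as.integer(loop_limit),
                 learning_rate = learning_rate,
                 early_stop_tol = early_stop_tol,
                 positivity_floor = positivity_floor, mode = mode,
                 step_cap = step_cap, scaled_rate = scaled_rate),
            class = "relax_control")
}

t_init_for <- function(control, model) {
  if (model == "T1") control$t1_init else control$t2_init
}

#' Fit the monoexponential relaxation model to one signal-versus-time curve
#'
#' Steepest descent on the sum of squared residuals between the measured
#' intensities and [t1_signal()] / [t2_signal()], starting from the fixed
#' initial constants in [relax_control()].  This is the scalar contract that
#' [fit_map()] applies to every masked voxel.
#'
#' @param signal Numeric vector of non-negative magnitude intensities.
#' @param times Numeric vector of TR (T1) or TE (T2) values in ms, strictly
#'   increasing, same length as `signal` (length >= 2).
#' @param model `"T1"` or `"T2"`.
#' @param control A [relax_control()] object.
#' @param trace If `TRUE`, record the SSE after every iteration (available as
#'   `$trace` on the result).
#' @return An object of class `"relax_fit"` with components `m0`, `t_value`,
#'   `iterations`, `converged`, `degenerate`, `sse`, plus the data and
#'   control used.  An all-zero signal yields the degenerate result
#'   `m0 = 0`, `t_value = NA` with `degenerate = TRUE` rather than an error.
#' @seealso [nls_oracle_fit()] for the independent least-squares check,
#'   [fit_map()] for whole-volume fitting.
#' @examples
#' te <- c(12.2, 36.6, 60.94)
#' fit <- relax_fit(t2_signal(8000, 50, te), te, "T2")
#' coef(fit)
#' @export
relax_fit <- function(signal, times, model = c("T1", "T2"),
                      control = relax_control(), trace = FALSE) {
  model <- match.arg(model)
  signal <- as.double(signal); times <- as.double(times)
  if (length(signal) != length(times) || length(signal) < 2)
    zf_validation_error("signal and times must have equal length >= 2")
  if (any(!is.finite(signal)) || any(!is.finite(times)))
    zf_domain_error("signal and times must be finite")
  if (any(signal < 0))
    zf_domain_error("magnitude signal must be non-negative")
  res <- gd_fit_cpp(matrix(signal, ncol = 1), times,
                    model = if (model == "T1") 0L else 1L,
                    m0_init = control$m0_init,
                    t_init = t_init_for(control, model),
                    loop_limit = control$loop_limit,
                    learning_rate = control$learning_rate,
                    early_stop_tol = control$early_stop_tol,
                    positivity_floor = control$positivity_floor,
                    mode = if (control$mode == "raw") 0L else 1L,
                    step_cap = control$step_cap,
                    scaled_rate = control$scaled_rate,
                    trace = isTRUE(trace))
  structure(list(m0 = res$m0[1], t_value = res$t_value[1],
                 iterations = res$iterations[1],
                 converged = res$converged[1], degenerate = res$degenerate[1],
                 sse = res$sse[1], trace = res$trace,
                 model = model, signal = signal, times = times,
                 control = control),
            class = "relax_fit")
}

#' @export
print.relax_fit <- function(x, ...) {
  cat(sprintf("Monoexponential %s fit (gradient descent, %s mode)\n",
              x$model, x$control$mode))
  if (x$degenerate) {
    cat("  degenerate: all-zero signal, no fit performed\n")
    return(invisible(x))
  }
  cat(sprintf("  M0 = %.4g   %s = %.4g ms\n", x$m0, x$model, x$t_value))
  cat(sprintf("  SSE = %.6g after %d iteration(s); converged: %s\n",
              x$sse, x$iterations, x$converged))
  invisible(x)
}

#' @export
coef.relax_fit <- function(object, ...) {
  setNames(c(object$m0, object$t_value),
           c("m0", if (object$model == "T1") "t1" else "t2"))
}

#' @export
fitted.relax_fit <- function(object, ...) {
  if (object$degenerate) return(rep(NA_real_, length(object$times)))
  relax_signal(object$model, object$m0, object$t_value, object$times)
}

#' @export
residuals.relax_fit <- function(object, ...) object$signal - fitted(object)

#' @export
predict.relax_fit <- function(object, newtimes = object$times, ...) {
  if (object$degenerate) zf_domain_error("cannot predict from degenerate fit")
  relax_signal(object$model, object$m0, object$t_value, newtimes)
}

#' Simulate magnitude signals from a fitted relaxation curve
#'
#' Draws Rician magnitude samples around the fitted curve:
#' \eqn{\sqrt{(S+n_1)^2 + n_2^2}} with `n1, n2 ~ N(0, sigma^2)`.
#'
#' @param object A `"relax_fit"`.
#' @param nsim Number of replicate signal vectors.
#' @param seed Optional integer seed.
#' @param sigma Gaussian channel noise level (signal units).  Default 0.
#' @param ... Unused.
#' @return A matrix with `nsim` columns, one simulated signal vector each.
#' @export
simulate.relax_fit <- function(object, nsim = 1, seed = NULL, sigma = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- fitted(object)
  vapply(seq_len(nsim), function(i) rician_noise(s, sigma),
         numeric(length(s)))
}

#' @export
summary.relax_fit <- function(object, ...) {
  object$rmse <- sqrt(object$sse / length(object$signal))
  class(object) <- c("summary.relax_fit", class(object))
  object
}

#' @export
print.summary.relax_fit <- function(x, ...) {
  print.relax_fit(x, ...)
  if (!x$degenerate) {
    cat(sprintf("  RMSE = %.6g over %d time points\n", x$rmse,
                length(x$times)))
    cat(sprintf("  times (ms): %s\n", paste(x$times, collapse = ", ")))
  }
  invisible(x)
}

#' @export
plot.relax_fit <- function(x, n_curve = 200, ...) {
  if (x$degenerate) zf_domain_error("cannot plot degenerate fit")
  tt <- seq(0, max(x$times) * 1.1, length.out = n_curve)
  plot(x$times, x$signal, pch = 19,
       xlab = if (x$model == "T1") "TR (ms)" else "TE (ms)",
       ylab = "signal", ...)
  lines(tt, predict(x, tt))
  title(sprintf("%s fit: M0 = %.3g, %s = %.3g ms", x$model, x$m0, x$model,
                x$t_value))
  invisible(x)
}

#' Independent least-squares oracle for the relaxation fit
#'
#' Fits the same monoexponential model by an independent route: the exact
#' two-point closed form for two-echo T2 data, log-linear regression for
#' longer clean T2 decays, and Levenberg-Marquardt nonlinear least squares
#' (via \pkg{minpack.lm}) in general.  Used to cross-check the
#' gradient-descent fitter in tests and QC, never as the fitter itself.
#'
#' @inheritParams relax_fit
#' @return Named vector `c(m0, t_value)`.
#' @export
nls_oracle_fit <- function(signal, times, model = c("T1", "T2")) {
  model <- match.arg(model)
  signal <- as.double(signal); times <- as.double(times)
  if (length(signal) != length(times) || length(signal) < 2)
    zf_validation_error("signal and times must have equal length >= 2")
  if (any(!is.finite(signal)) || any(!is.finite(times)))
    zf_domain_error("signal and times must be finite")

  if (model == "T2" && length(signal) == 2 && all(signal > 0) &&
      signal[1] != signal[2]) {
    t2 <- (times[2] - times[1]) / log(signal[1] / signal[2])
    return(c(m0 = signal[1] * exp(times[1] / t2), t_value = t2))
  }

  if (model == "T2" && all(signal > 0)) {
    # log-linear start (exact on noiseless monoexponential decays)
    fit <- lm(log(signal) ~ times)
    t2 <- -1 / coef(fit)[[2]]
    m0 <- exp(coef(fit)[[1]])
    start <- list(m0 = m0, tv = if (t2 > 0) t2 else 50)
  } else if (model == "T2") {
    start <- list(m0 = max(signal), tv = diff(range(times)) / 2)
  } else {
    start <- list(m0 = max(signal) * 1.05, tv = times[[2]])
  }

  df <- data.frame(y = signal, t = times)
  form <- if (model == "T1") y ~ m0 * (1 - exp(-t / tv))
          else y ~ m0 * exp(-t / tv)
  fit <- minpack.lm::nlsLM(form, data = df, start = start,
                           lower = c(0, 1e-6),
                           control = nls.control(maxiter = 500,
                                                 warnOnly = TRUE))
  p <- coef(fit)
  c(m0 = unname(p["m0"]), t_value = unname(p["tv"]))
}
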