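new_parameter_map <- function(m0, t_value, converged, iterations, sse, mask,
                              series_type, voxel_size, hyperparams) {
  structure(list(m0 = m0, t_value = t_value, converged = converged,
                 iterations = iterations, sse = sse, mask = mask,
                 series_type = series_type, voxel_size = voxel_size,
                 hyperparams = hyperparams),
            class = "parameter_map")
}

#' Default fit mask for a series
#'
#' Background exclusion used when [fit_map()] is given no explicit mask:
#' a voxel is fitted when its maximum signal across time points exceeds
#' `threshold` (default 5%) of the series-wide maximum.
#'
#' @param series A `"zf_series"`.
#' @param threshold Fraction of the global maximum.  Default 0.05.
#' @return Logical array shaped like one volume.
#' @export
default_fit_mask <- function(series, threshold = 0.05) {
  mx <- Reduce(pmax, lapply(series$volumes, function(v) v$data))
  mx > threshold * max(mx)
}

#' Fit T1 or T2 maps voxelwise over an acquisition series
#'
#' Applies the scalar gradient-descent contract of [relax_fit()] to every
#' masked voxel of the series (the implementation batches voxels through one
#' compiled core; updates are identical to the scalar path).  Repeated
#' acquisitions, when present on the series, are arithmetically averaged per
#' time point before fitting.  Unmasked voxels carry `NaN` sentinels and
#' `mask = FALSE`.
#'
#' @param series A `"zf_series"` (T1 or T2; the model follows the series
#'   type).
#' @param mask Optional logical array shaped like one volume; default
#'   [default_fit_mask()].
#' @param control A [relax_control()].
#' @return An object of class `"parameter_map"` with volume-shaped planes
#'   `m0`, `t_value` (ms), `converged`, `iterations`, `sse`, `mask`, plus
#'   `series_type`, `voxel_size` and the hyperparameters used.
#' @examples
#' ph <- make_phantom(phantom_spec(grid = c(16, 10, 8)))
#' ser <- simulate_series(ph, series_type = "T2")
#' map <- fit_map(ser$series)
#' summary(map)
#' @export
fit_map <- function(series, mask = NULL, control = relax_control()) {
  if (!inherits(series, "zf_series")) zf_validation_error("not a zf_series")
  vols <- series$volumes
  if (!is.null(series$repetitions)) {
    vols <- lapply(seq_along(vols), function(i)
      average_volumes(c(list(vols[[i]]), series$repetitions[[i]])))
  }
  shape <- dim(vols[[1]]$data)
  if (is.null(mask)) mask <- default_fit_mask(series)
  if (!identical(dim(mask), shape))
    zf_validation_error("mask shape does not match the series volumes")
  mask <- mask & TRUE  # coerce to logical array

  idx <- which(mask)
  sig <- vapply(vols, function(v) v$data[idx], numeric(length(idx)))
  sig <- if (length(idx) == 1) matrix(sig, nrow = 1) else sig
  model <- series$series_type
  # the raw-gradient-descent learning rate is a dimensional constant tied to
  # the expected signal scale; flag data far from the initialisation scale
  if (control$mode == "raw" && length(idx)) {
    med_max <- median(apply(sig, 1, max))
    if (med_max < 0.1 * control$m0_init || med_max > 10 * control$m0_init)
      warning(sprintf(paste0(
        "median peak signal (%.3g) is far from m0_init (%.3g); the fixed ",
        "learning rate of the raw-mode fit is scale-dependent - consider ",
        "mode = 'scaled' or rescaling"), med_max, control$m0_init))
  }
  res <- gd_fit_cpp(t(sig), series$times_ms,
                    model = if (model == "T1") 0L else 1L,
                    m0_init = control$m0_init,
                    t_init = t_init_for(control, model),
                    loop_limit = control$loop_limit,
                    learning_rate = control$learning_rate,
                    early_stop_tol = control$early_stop_tol,
                    positivity_floor = control$positivity_floor,
                    mode = if (control$mode == "raw") 0L else 1L,
                    step_cap = control$step_cap,
                    scaled_rate = control$scaled_rate, trace = FALSE)

  plane <- function(fill) array(fill, shape)
  m0 <- plane(NaN); tv <- plane(NaN); sse <- plane(NaN)
  it <- plane(0L); conv <- plane(FALSE)
  m0[idx] <- res$m0; tv[idx] <- res$t_value; sse[idx] <- res$sse
  it[idx] <- res$iterations; conv[idx] <- res$converged
  # degenerate voxels (all-zero signal inside the mask) are dropped from
  # the fit mask: t is undefined there
  mask[idx[res$degenerate]] <- FALSE
  tv[idx[res$degenerate]] <- NaN

  new_parameter_map(m0, tv, conv, it, sse, mask, model,
                    vols[[1]]$voxel_size, control)
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("<parameter_map> %s map, %s voxels (%d fitted)\n",
              x$series_type, paste(dim(x$m0), collapse = " x "),
              sum(x$mask)))
  invisible(x)
}

#' @export
summary.parameter_map <- function(object, ...) {
  m <- object$mask
  s <- list(series_type = object$series_type, n_fitted = sum(m),
            n_converged = sum(object$converged[m]),
            t_quartiles = stats::quantile(object$t_value[m],
                                          c(.25, .5, .75), na.rm = TRUE),
            m0_median = median(object$m0[m], na.rm = TRUE),
            mean_iterations = mean(object$iterations[m]),
            hyperparams = object$hyperparams)
  class(s) <- "summary.parameter_map"
  s
}

#' @export
print.summary.parameter_map <- function(x, ...) {
  cat(sprintf("%s parameter map: %d fitted voxels, %d converged\n",
              x$series_type, x$n_fitted, x$n_converged))
  cat(sprintf("  %s quartiles (ms): %s\n", x$series_type,
              paste(signif(x$t_quartiles, 5), collapse = " / ")))
  cat(sprintf("  median M0: %.5g; mean iterations: %.1f\n",
              x$m0_median, x$mean_iterations))
  invisible(x)
}

#' @export
plot.parameter_map <- function(x, slice = ceiling(dim(x$m0)[3] / 2),
                               what = c("t_value", "m0"), ...) {
  what <- match.arg(what)
  img <- x[[what]][, , slice]
  img[!x$mask[, , slice]] <- NA
  image(seq_len(nrow(img)) - 1, seq_len(ncol(img)) - 1, img,
        col = gray.colors(128), xlab = "x (px)", ylab = "y (px)",
        main = sprintf("%s %s, slice %d", x$series_type, what, slice), ...)
  invisible(x)
}
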