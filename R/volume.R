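#' Construct a 3D magnitude image volume
#'
#' A minimal in-memory container for one magnitude MR volume: a 3D numeric
#' array plus per-axis voxel spacing in mm.  Axis convention throughout the
#' package: first array axis x (left-right), second y (dorso-ventral), third
#' z (the rostro-caudal slice axis).  Voxel indices are 0-based in all
#' coordinate tables; sub-pixel positions are allowed.
#'
#' @param data 3D numeric array of finite, non-negative intensities.
#' @param voxel_size Numeric length-3 (or scalar, recycled) spacing in mm.
#' @return An object of class `"zf_volume"`.
#' @export
volume <- function(data, voxel_size = c(1, 1, 1)) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (!is.array(data) || length(dim(data)) != 3)
    zf_validation_error("data must be a 3D array")
  if (any(dim(data) < 1)) zf_validation_error("all dimensions must be >= 1")
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    zf_validation_error("voxel_size must be three positive finite values")
  if (any(!is.finite(data)))
    zf_validation_error("volume intensities must be finite")
  structure(list(data = data, voxel_size = as.double(voxel_size)),
            class = "zf_volume")
}

#' @export
print.zf_volume <- function(x, ...) {
  cat(sprintf("<zf_volume> %s voxels at %s mm\n",
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$voxel_size, 4), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.zf_volume <- function(x) dim(x$data)

#' Construct a multi-TR / multi-TE acquisition series
#'
#' An ordered set of co-registered volumes indexed by repetition time (T1
#' series) or echo time (T2 series).  Optional `repetitions` carries repeated
#' acquisitions per time point; [fit_map()] averages them before fitting.
#'
#' @param volumes List of [volume()] objects, all the same shape and spacing.
#' @param series_type `"T1"` or `"T2"`.
#' @param times_ms Strictly increasing positive TR or TE values (ms), one per
#'   volume; at least two time points are required.
#' @param repetitions Optional list (one element per time point) of lists of
#'   repeated [volume()]s.
#' @return An object of class `"zf_series"`.
#' @export
acquisition_series <- function(volumes, series_type = c("T1", "T2"),
                               times_ms, repetitions = NULL) {
  series_type <- match.arg(series_type)
  if (!is.list(volumes) || length(volumes) < 2)
    zf_validation_error("need at least 2 volumes / time points")
  if (length(times_ms) != length(volumes))
    zf_validation_error("times_ms must match the number of volumes")
  if (any(times_ms <= 0) || any(diff(times_ms) <= 0))
    zf_validation_error("times_ms must be strictly increasing and > 0")
  d1 <- dim(volumes[[1]]$data); v1 <- volumes[[1]]$voxel_size
  for (v in volumes) {
    if (!inherits(v, "zf_volume")) zf_validation_error("volumes must be zf_volume")
    if (!identical(dim(v$data), d1))
      zf_validation_error("all volumes must share one shape")
    if (!isTRUE(all.equal(v$voxel_size, v1)))
      zf_validation_error("all volumes must share one voxel size")
  }
  if (!is.null(repetitions)) {
    if (length(repetitions) != length(volumes))
      zf_validation_error("repetitions must have one entry per time point")
    for (reps in repetitions) for (r in reps)
      if (!identical(dim(r$data), d1))
        zf_validation_error("repetition volumes must share the series shape")
  }
  structure(list(volumes = volumes, series_type = series_type,
                 times_ms = as.double(times_ms), repetitions = repetitions),
            class = "zf_series")
}

#' @export
print.zf_series <- function(x, ...) {
  cat(sprintf("<zf_series> %s series, %d time points (%s ms)\n",
              x$series_type, length(x$times_ms),
              paste(x$times_ms, collapse = ", ")))
  cat(sprintf("  volume shape %s, voxel %s mm%s\n",
              paste(dim(x$volumes[[1]]$data), collapse = " x "),
              paste(signif(x$volumes[[1]]$voxel_size, 4), collapse = " x "),
              if (is.null(x$repetitions)) ""
              else sprintf(", %d repetition set(s)",
                           length(x$repetitions[[1]]))))
  invisible(x)
}

#' Voxelwise arithmetic mean of volumes
#'
#' Averages repeated (aligned) acquisitions into one volume.
#'
#' @param vols List of [volume()]s of equal shape and spacing.
#' @return A [volume()].
#' @export
average_volumes <- function(vols) {
  if (length(vols) < 1) zf_validation_error("need at least one volume")
  d1 <- dim(vols[[1]]$data)
  acc <- array(0, d1)
  for (v in vols) {
    if (!identical(dim(v$data), d1))
      zf_validation_error("volume shapes differ")
    if (!isTRUE(all.equal(v$voxel_size, vols[[1]]$voxel_size)))
      zf_validation_error("voxel sizes differ")
    acc <- acc + v$data
  }
  volume(acc / length(vols), vols[[1]]$voxel_size)
}
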