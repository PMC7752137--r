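#' ROI specification for white-matter intensity measurement
#'
#' Describes where the paired 2x2-pixel regions sit: a reference slice at
#' the caudal end of the rhombencephalic ventricle plus `n_extra_slices`
#' further slices taken moving rostrally, each with a periventricular
#' grey-zone (PGZ, white matter) center and an optic-tectum (grey matter)
#' center in pixel coordinates.
#'
#' @param reference_slice 0-based slice index of the reference slice.
#' @param centers List with one element per measured slice (reference first,
#'   then rostral), each `list(pgz = c(x, y), tectum = c(x, y))`.
#' @param rostral_direction `+1` or `-1`: which way along the slice axis is
#'   rostral.
#' @param roi_size Pixels per ROI side.  Default 2.
#' @return An object of class `"roi_spec"`.
#' @export
roi_spec <- function(reference_slice, centers, rostral_direction = 1,
                     roi_size = 2) {
  if (roi_size < 1) zf_validation_error("roi_size must be >= 1")
  if (!rostral_direction %in% c(-1, 1))
    zf_validation_error("rostral_direction must be +1 or -1")
  for (ct in centers)
    if (!all(c("pgz", "tectum") %in% names(ct)))
      zf_validation_error("each slice entry needs pgz and tectum centers")
  structure(list(reference_slice = as.integer(reference_slice),
                 n_extra_slices = length(centers) - 1L,
                 rostral_direction = as.integer(rostral_direction),
                 roi_size = as.integer(roi_size), centers = centers),
            class = "roi_spec")
}

roi_slices <- function(spec) {
  spec$reference_slice +
    spec$rostral_direction * (seq_along(spec$centers) - 1L)
}

#' Read / write an ROI specification as YAML
#'
#' @param path YAML file path.
#' @return `read_roi_spec()` returns a [roi_spec()].
#' @export
read_roi_spec <- function(path) {
  if (!file.exists(path)) zf_io_error(sprintf("no ROI spec at '%s'", path))
  y <- yaml::read_yaml(path)
  need <- c("reference_slice", "rostral_direction", "roi_size", "centers")
  if (!all(need %in% names(y)))
    zf_format_error(sprintf("ROI spec missing field(s): %s",
                            paste(setdiff(need, names(y)), collapse = ", ")))
  centers <- lapply(y$centers, function(ct)
    list(pgz = as.double(unlist(ct$pgz)),
         tectum = as.double(unlist(ct$tectum))))
  roi_spec(y$reference_slice, centers, y$rostral_direction, y$roi_size)
}

#' @rdname read_roi_spec
#' @param spec A [roi_spec()].
#' @export
write_roi_spec <- function(spec, path) {
  yaml::write_yaml(list(reference_slice = spec$reference_slice,
                        rostral_direction = spec$rostral_direction,
                        roi_size = spec$roi_size,
                        centers = lapply(spec$centers, function(ct)
                          list(pgz = as.double(ct$pgz),
                               tectum = as.double(ct$tectum)))),
                   path)
  invisible(path)
}

#' Mean intensity of a square pixel ROI
#'
#' The footprint is the `size x size` block whose lower-index corner is
#' `round(center - (size - 1) / 2)` (0-based pixel coordinates; ties round
#' half to even as in base [round()]).  It must lie fully inside the plane.
#'
#' @param slice_image 2D numeric matrix (x by y).
#' @param center Length-2 (sub-)pixel ROI center `(x, y)`.
#' @param size Pixels per side.  Default 2.
#' @return Arithmetic mean of the footprint intensities.
#' @export
extract_roi_mean <- function(slice_image, center, size = 2) {
  if (size < 1) zf_validation_error("size must be >= 1")
  corner <- round(as.double(center) - (size - 1) / 2)
  if (any(corner < 0) || corner[1] + size > nrow(slice_image) ||
      corner[2] + size > ncol(slice_image))
    zf_validation_error("ROI footprint extends outside the slice")
  xs <- corner[1] + seq_len(size); ys <- corner[2] + seq_len(size)
  mean(slice_image[xs, ys])
}

#' Normalized white-matter intensity over the ROI slices
#'
#' For the reference slice and each further rostral slice, takes the mean of
#' the PGZ (white matter) ROI and divides by the mean of the optic-tectum
#' (grey matter) ROI on the same slice; the summary value is the arithmetic
#' mean of the per-slice ratios.
#'
#' @param vol A [volume()] (typically the T2-weighted image at one TE, or a
#'   fitted map plane wrapped as a volume).
#' @param spec A [roi_spec()].
#' @param direction `"pgz_over_tectum"` (default, white over grey) or
#'   `"tectum_over_pgz"`.
#' @return A list with `per_slice` (`data.frame(slice_index, pgz_mean,
#'   tectum_mean, normalized)`) and `summary` (mean normalized ratio), plus
#'   the `direction` used.
#' @export
normalized_wm_intensity <- function(vol, spec,
                                    direction = c("pgz_over_tectum",
                                                  "tectum_over_pgz")) {
  direction <- match.arg(direction)
  if (!inherits(vol, "zf_volume")) zf_validation_error("not a zf_volume")
  slices <- roi_slices(spec)
  nz <- dim(vol$data)[3]
  if (any(slices < 0 | slices > nz - 1))
    zf_validation_error("ROI slice index outside the volume")
  rows <- lapply(seq_along(slices), function(i) {
    pl <- vol$data[, , slices[i] + 1]
    ct <- spec$centers[[i]]
    pgz <- extract_roi_mean(pl, ct$pgz, spec$roi_size)
    tec <- extract_roi_mean(pl, ct$tectum, spec$roi_size)
    denom <- if (direction == "pgz_over_tectum") tec else pgz
    if (denom == 0)
      zf_domain_error(sprintf(
        "zero denominator ROI mean on slice %d", slices[i]))
    data.frame(slice_index = slices[i], pgz_mean = pgz, tectum_mean = tec,
               normalized = if (direction == "pgz_over_tectum") pgz / tec
                            else tec / pgz)
  })
  per_slice <- do.call(rbind, rows)
  list(per_slice = per_slice, summary = mean(per_slice$normalized),
       direction = direction)
}
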