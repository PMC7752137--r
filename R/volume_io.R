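#' Write / read an acquisition series as NIfTI volumes plus a JSON manifest
#'
#' `write_series()` writes one NIfTI-1 file per time point and a
#' `manifest.json` sidecar recording `series_type`, `times_ms`,
#' `voxel_size_mm` and the per-time-point file names (including repetition
#' files when present).  `read_series()` reads the manifest back and
#' validates the result against the [acquisition_series()] invariants.
#'
#' @param series A `"zf_series"`.
#' @param path Directory to write into (created if missing) / to read from.
#'   `read_series()` also accepts the path of the manifest file itself.
#' @return `write_series()` returns `path` invisibly; `read_series()`
#'   returns a `"zf_series"`.
#' @export
write_series <- function(series, path) {
  if (!inherits(series, "zf_series")) zf_validation_error("not a zf_series")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) zf_io_error(sprintf("cannot create '%s'", path))
  files <- sprintf("vol_%03d.nii.gz", seq_along(series$volumes))
  for (i in seq_along(series$volumes))
    write_nifti_volume(series$volumes[[i]], file.path(path, files[i]))
  rep_files <- NULL
  if (!is.null(series$repetitions)) {
    rep_files <- lapply(seq_along(series$repetitions), function(i) {
      reps <- series$repetitions[[i]]
      fs <- sprintf("vol_%03d_rep_%02d.nii.gz", i, seq_along(reps))
      for (j in seq_along(reps))
        write_nifti_volume(reps[[j]], file.path(path, fs[j]))
      fs
    })
  }
  manifest <- list(series_type = series$series_type,
                   times_ms = series$times_ms,
                   voxel_size_mm = series$volumes[[1]]$voxel_size,
                   files = files)
  if (!is.null(rep_files)) manifest$repetition_files <- rep_files
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  mf <- if (dir.exists(path)) file.path(path, "manifest.json") else path
  if (!file.exists(mf))
    zf_format_error(sprintf("manifest not found at '%s'", mf))
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  need <- c("series_type", "times_ms", "voxel_size_mm", "files")
  if (!all(need %in% names(manifest)))
    zf_format_error(sprintf("manifest missing field(s): %s",
                            paste(setdiff(need, names(manifest)),
                                  collapse = ", ")))
  base <- dirname(mf)
  vs <- as.double(manifest$voxel_size_mm)
  vols <- lapply(manifest$files, function(f)
    read_nifti_volume(file.path(base, f), vs))
  reps <- NULL
  if (!is.null(manifest$repetition_files)) {
    reps <- lapply(manifest$repetition_files, function(fs)
      lapply(fs, function(f) read_nifti_volume(file.path(base, f), vs)))
  }
  acquisition_series(vols, manifest$series_type,
                     as.double(manifest$times_ms), repetitions = reps)
}

write_nifti_volume <- function(vol, file) {
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`pixdim<-`(img, vol$voxel_size)
  RNifti::writeNifti(img, file, datatype = "double")
}

read_nifti_volume <- function(file, voxel_size = NULL) {
  if (!file.exists(file)) zf_io_error(sprintf("missing volume file '%s'", file))
  img <- RNifti::readNifti(file)
  a <- array(as.double(img), dim(img))
  vs <- if (is.null(voxel_size)) RNifti::pixdim(img)[1:3] else voxel_size
  volume(a, vs)
}

#' Read / write landmark tables
#'
#' Landmarks are tab-separated UTF-8 tables with a header row and columns
#' `frame_id, name, x, y, slice`; `(x, y)` are 0-based (sub-)pixel positions
#' within slice `slice`, and `frame_id` identifies the volume / time point
#' each set annotates.  The three primary registration landmarks are the two
#' eye-lens centers and the vagal-lobe tip.
#'
#' @param path TSV file path.
#' @return `read_landmarks()`: a list of class `"zf_landmarks"`, one
#'   `data.frame(name, x, y, slice)` per `frame_id`.  An empty table yields
#'   an empty set with a warning.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) zf_io_error(sprintf("no landmark file '%s'", path))
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("empty landmark table: returning empty set")
    return(structure(list(), class = "zf_landmarks"))
  }
  need <- c("frame_id", "name", "x", "y", "slice")
  if (!all(need %in% names(df)))
    zf_format_error(sprintf("landmark table must have columns %s",
                            paste(need, collapse = ", ")))
  as_landmark_set(df)
}

as_landmark_set <- function(df) {
  out <- lapply(split(df, df$frame_id), function(g) {
    if (anyDuplicated(g$name))
      zf_validation_error(sprintf(
        "duplicate landmark name(s) in frame '%s': %s", g$frame_id[1],
        paste(unique(g$name[duplicated(g$name)]), collapse = ", ")))
    data.frame(name = g$name, x = as.double(g$x), y = as.double(g$y),
               slice = as.double(g$slice), stringsAsFactors = FALSE)
  })
  structure(out, class = "zf_landmarks")
}

#' @rdname read_landmarks
#' @param landmarks A `"zf_landmarks"` set (or plain data.frame with the
#'   five columns).
#' @export
write_landmarks <- function(landmarks, path) {
  df <- if (is.data.frame(landmarks)) landmarks else
    do.call(rbind, lapply(names(landmarks), function(id)
      cbind(frame_id = id, landmarks[[id]])))
  if (is.null(df))
    df <- data.frame(frame_id = character(), name = character(),
                     x = double(), y = double(), slice = double())
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write paired axon/myelin fiber contour tables
#'
#' Fiber contours are TSV tables with columns
#' `fiber_id, boundary, vertex_order, x, y` (boundary `"axon"` or
#' `"myelin"`; closure of each polygon is implicit).  On reading, every
#' fiber is validated: exactly the two boundaries, at least 3 vertices each,
#' simple (non-self-intersecting) polygons, and the axon polygon strictly
#' inside the myelin polygon.
#'
#' @param path TSV file path.
#' @param unit Length unit of the coordinates (`"nm"` or `"um"`); stored on
#'   the result as attribute `unit`.
#' @return A `data.frame` of class `"zf_contours"` sorted by fiber,
#'   boundary, vertex order.
#' @export
read_contours <- function(path, unit = c("nm", "um")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) zf_io_error(sprintf("no contour file '%s'", path))
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("fiber_id", "boundary", "vertex_order", "x", "y")
  if (!all(need %in% names(df)))
    zf_format_error(sprintf("contour table must have columns %s",
                            paste(need, collapse = ", ")))
  validate_contours(df)
  df <- df[order(df$fiber_id, df$boundary, df$vertex_order), need]
  attr(df, "unit") <- unit
  class(df) <- c("zf_contours", "data.frame")
  df
}

validate_contours <- function(df) {
  if (!all(df$boundary %in% c("axon", "myelin")))
    zf_validation_error("boundary must be 'axon' or 'myelin'")
  for (id in unique(df$fiber_id)) {
    g <- df[df$fiber_id == id, ]
    bs <- sort(unique(g$boundary))
    if (!identical(bs, c("axon", "myelin")))
      zf_validation_error(sprintf(
        "fiber '%s' must have exactly an axon and a myelin boundary", id))
    ax <- g[g$boundary == "axon", ]; ax <- ax[order(ax$vertex_order), ]
    my <- g[g$boundary == "myelin", ]; my <- my[order(my$vertex_order), ]
    for (b in list(axon = ax, myelin = my)) {
      if (nrow(b) < 3)
        zf_validation_error(sprintf(
          "fiber '%s': each boundary needs >= 3 vertices", id))
      if (!polygon_is_simple(cbind(b$x, b$y)))
        zf_validation_error(sprintf(
          "fiber '%s': self-intersecting contour", id))
    }
    if (!polygon_inside(cbind(ax$x, ax$y), cbind(my$x, my$y)))
      zf_validation_error(sprintf(
        "fiber '%s': axon contour not strictly inside myelin contour", id))
  }
  invisible(df)
}

#' @rdname read_contours
#' @param contours A contour `data.frame` with the five columns.
#' @export
write_contours <- function(contours, path) {
  write.table(contours, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a fitted parameter map
#'
#' `write_parameter_map()` stores one NIfTI plane per component (M0, the
#' fitted relaxation time, convergence flag, iteration count, residual SSE,
#' fit mask) plus a JSON sidecar recording the series type and every
#' hyperparameter actually used.  Masked voxels must hold finite positive
#' relaxation times; voxels outside the mask carry `NaN` sentinels.
#'
#' @param map A `"parameter_map"` from [fit_map()].
#' @param path Output directory.
#' @return `write_parameter_map()` returns `path` invisibly;
#'   `read_parameter_map()` returns a `"parameter_map"`.
#' @export
write_parameter_map <- function(map, path) {
  if (!inherits(map, "parameter_map")) zf_validation_error("not a parameter_map")
  bad <- map$mask & (!is.finite(map$t_value) | !is.finite(map$m0))
  if (any(bad))
    zf_validation_error("non-finite parameter value inside the fit mask")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) zf_io_error(sprintf("cannot create '%s'", path))
  vs <- map$voxel_size
  planes <- list(m0 = map$m0, t_value = map$t_value,
                 converged = map$converged + 0, iterations = map$iterations + 0,
                 sse = map$sse, mask = map$mask + 0)
  for (nm in names(planes))
    write_nifti_volume(volume_allow_na(planes[[nm]], vs),
                       file.path(path, paste0(nm, ".nii.gz")))
  side <- c(list(series_type = map$series_type,
                 voxel_size_mm = vs),
            unclass(map$hyperparams))
  jsonlite::write_json(side, file.path(path, "parameter_map.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# volume() rejects non-finite values; parameter planes legitimately carry
# NaN sentinels outside the mask, so bypass that single check here.
volume_allow_na <- function(data, voxel_size) {
  structure(list(data = data, voxel_size = as.double(voxel_size)),
            class = "zf_volume")
}

#' @rdname write_parameter_map
#' @export
read_parameter_map <- function(path) {
  sf <- file.path(path, "parameter_map.json")
  if (!file.exists(sf)) zf_format_error(sprintf("no sidecar at '%s'", sf))
  side <- jsonlite::read_json(sf, simplifyVector = TRUE)
  vs <- as.double(side$voxel_size_mm)
  rd <- function(nm) read_nifti_raw(file.path(path, paste0(nm, ".nii.gz")))
  hp_names <- setdiff(names(side), c("series_type", "voxel_size_mm"))
  new_parameter_map(m0 = rd("m0"), t_value = rd("t_value"),
                    converged = rd("converged") > 0.5,
                    iterations = array(as.integer(round(rd("iterations"))),
                                       dim(rd("iterations"))),
                    sse = rd("sse"), mask = rd("mask") > 0.5,
                    series_type = side$series_type, voxel_size = vs,
                    hyperparams = side[hp_names])
}

read_nifti_raw <- function(file) {
  if (!file.exists(file)) zf_io_error(sprintf("missing plane file '%s'", file))
  img <- RNifti::readNifti(file)
  array(as.double(img), dim(img))
}
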