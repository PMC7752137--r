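#' In-plane rigid transform
#'
#' A 2D rigid-body transform (rotation by `theta` about `center`, then
#' translation by `(tx, ty)`), the motion model used to correct sub-pixel
#' movement between acquisitions: a point `p` maps to
#' `R(theta) (p - center) + center + (tx, ty)`.
#'
#' @param theta Rotation in radians.
#' @param tx,ty Translation in pixels.
#' @param center Length-2 rotation center in pixels.  Default `c(0, 0)`.
#' @return An object of class `"rigid2d"`.
#' @export
rigid2d <- function(theta = 0, tx = 0, ty = 0, center = c(0, 0)) {
  if (!all(is.finite(c(theta, tx, ty, center))))
    zf_validation_error("transform parameters must be finite")
  structure(list(theta = theta, tx = tx, ty = ty,
                 center = as.double(center)), class = "rigid2d")
}

#' @export
print.rigid2d <- function(x, ...) {
  cat(sprintf("<rigid2d> theta = %.6g deg, t = (%.6g, %.6g) px%s\n",
              x$theta * 180 / pi, x$tx, x$ty,
              if (!is.null(attr(x, "rms_residual")))
                sprintf(", landmark RMS = %.3g px", attr(x, "rms_residual"))
              else ""))
  invisible(x)
}

rigid_matrix <- function(T) {
  matrix(c(cos(T$theta), sin(T$theta), -sin(T$theta), cos(T$theta)), 2, 2)
}

#' Apply / invert / compose rigid transforms on 2D points
#'
#' `transform_points()` maps an `n x 2` matrix of `(x, y)` points through a
#' [rigid2d()]; `invert_rigid2d()` returns the inverse transform;
#' `compose_rigid2d()` returns `a` followed by `b` (i.e. `b(a(p))`).
#'
#' @param T,a,b [rigid2d()] transforms.
#' @param pts `n x 2` numeric matrix.
#' @return Transformed points / a `"rigid2d"`.
#' @export
transform_points <- function(T, pts) {
  pts <- rbind(pts)  # tolerate a single point given as a vector
  R <- rigid_matrix(T)
  sweep(t(R %*% t(sweep(pts, 2, T$center))), 2,
        -(T$center + c(T$tx, T$ty)))
}

#' @rdname transform_points
#' @export
invert_rigid2d <- function(T) {
  # rewrite with center 0: p' = R p + d, d = center + t - R center
  d <- T$center + c(T$tx, T$ty) - rigid_matrix(T) %*% T$center
  Rinv_d <- rigid_matrix(rigid2d(-T$theta)) %*% d
  rigid2d(-T$theta, -Rinv_d[1], -Rinv_d[2])
}

#' @rdname transform_points
#' @export
compose_rigid2d <- function(a, b) {
  # b(a(p)) with both rewritten about center 0
  da <- a$center + c(a$tx, a$ty) - rigid_matrix(a) %*% a$center
  db <- b$center + c(b$tx, b$ty) - rigid_matrix(b) %*% b$center
  d <- rigid_matrix(b) %*% da + db
  rigid2d(a$theta + b$theta, d[1], d[2])
}

#' Estimate the least-squares rigid transform between landmark sets
#'
#' Closed-form 2D orthogonal Procrustes: centroid alignment plus SVD of the
#' 2x2 cross-covariance with reflections excluded, giving the rotation +
#' translation (no scaling) that maps the source landmarks onto the
#' destination landmarks in the least-squares sense.  Points are matched by
#' `name`; at least two shared names are required.  If the shared points are
#' degenerate (coincident), the rotation is ill-posed: a translation-only
#' transform is returned, flagged with attribute `rotation_illposed`.
#'
#' @param src,dst Landmark data frames with columns `name, x, y` (a single
#'   frame of a `"zf_landmarks"` set).
#' @return A [rigid2d()] with attribute `rms_residual` (px).
#' @export
estimate_rigid2d <- function(src, dst) {
  shared <- intersect(src$name, dst$name)
  if (length(shared) < 2)
    zf_validation_error("need >= 2 landmarks shared by name")
  P <- as.matrix(src[match(shared, src$name), c("x", "y")])
  Q <- as.matrix(dst[match(shared, dst$name), c("x", "y")])
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  illposed <- sum(Pc^2) < 1e-20
  if (illposed) {
    R <- diag(2)
  } else {
    H <- t(Pc) %*% Qc
    sv <- svd(H)
    S <- diag(c(1, sign(det(sv$v %*% t(sv$u)))))
    R <- sv$v %*% S %*% t(sv$u)
  }
  d <- cq - R %*% cp
  T <- rigid2d(atan2(R[2, 1], R[1, 1]), d[1], d[2])
  res <- transform_points(T, P) - Q
  attr(T, "rms_residual") <- sqrt(mean(rowSums(res^2)))
  attr(T, "rotation_illposed") <- illposed
  T
}

#' Resample a volume under an in-plane rigid transform
#'
#' Applies the same 2D transform to every slice (the transform is estimated
#' on one representative slice and propagated through the volume).  The
#' output pixel at `p` samples the input at `T^{-1}(p)` with bilinear
#' interpolation; samples falling outside the slice are filled with 0,
#' matching the magnitude-image background.
#'
#' @param vol A [volume()].
#' @param T A [rigid2d()].
#' @return A [volume()] of identical shape.
#' @export
apply_transform_slicewise <- function(vol, T) {
  if (!inherits(vol, "zf_volume")) zf_validation_error("not a zf_volume")
  d <- dim(vol$data)
  Ti <- invert_rigid2d(T)
  grid <- cbind(rep(seq_len(d[1]) - 1, times = d[2]),
                rep(seq_len(d[2]) - 1, each = d[1]))
  s <- transform_points(Ti, grid)
  x0 <- floor(s[, 1]); y0 <- floor(s[, 2])
  fx <- s[, 1] - x0; fy <- s[, 2] - y0
  out <- array(0, d)
  val <- function(plane, ix, iy) {
    v <- numeric(length(ix))
    ok <- ix >= 0 & ix <= d[1] - 1 & iy >= 0 & iy <= d[2] - 1
    v[ok] <- plane[cbind(ix[ok] + 1, iy[ok] + 1)]
    v
  }
  for (z in seq_len(d[3])) {
    pl <- vol$data[, , z]
    out[, , z] <- (1 - fx) * (1 - fy) * val(pl, x0, y0) +
      fx * (1 - fy) * val(pl, x0 + 1, y0) +
      (1 - fx) * fy * val(pl, x0, y0 + 1) +
      fx * fy * val(pl, x0 + 1, y0 + 1)
  }
  volume(out, vol$voxel_size)
}

#' Align an acquisition series to a reference time point via landmarks
#'
#' Estimates, for every volume, the rigid transform taking its landmarks
#' onto the reference volume's landmarks, and resamples the volume into the
#' reference frame.  Transforms are returned for QC alongside the aligned
#' series.
#'
#' @param series A `"zf_series"`.
#' @param landmarks A `"zf_landmarks"` set (or plain list of per-frame
#'   data frames) with one entry per volume, in series order.
#' @param reference_index 1-based index of the reference time point.
#' @return A list with `series` (aligned `"zf_series"`) and `transforms`
#'   (list of [rigid2d()], identity at the reference index).
#' @export
align_series <- function(series, landmarks, reference_index = 1) {
  if (!inherits(series, "zf_series")) zf_validation_error("not a zf_series")
  if (length(landmarks) != length(series$volumes))
    zf_validation_error("need one landmark set per volume")
  ref <- landmarks[[reference_index]]
  transforms <- vector("list", length(series$volumes))
  vols <- series$volumes
  for (i in seq_along(vols)) {
    if (is.null(landmarks[[i]]))
      zf_validation_error(sprintf("missing landmark set for volume %d", i))
    T <- estimate_rigid2d(landmarks[[i]], ref)
    transforms[[i]] <- T
    if (i != reference_index &&
        (abs(T$theta) > 1e-15 || abs(T$tx) > 1e-15 || abs(T$ty) > 1e-15))
      vols[[i]] <- apply_transform_slicewise(vols[[i]], T)
  }
  list(series = acquisition_series(vols, series$series_type,
                                   series$times_ms,
                                   repetitions = series$repetitions),
       transforms = transforms)
}
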