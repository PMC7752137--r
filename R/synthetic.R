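#' Rician magnitude noise
#'
#' Magnitude-image noise model: the noisy value is
#' \eqn{\sqrt{(S + n_1)^2 + n_2^2}} with independent
#' `n1, n2 ~ N(0, sigma^2)`, matching the distribution of magnitude
#' reconstructions of complex Gaussian-noise MR data.
#'
#' @param s Noiseless signal (any shape).
#' @param sigma Gaussian channel noise SD in signal units; `0` returns `s`
#'   unchanged.
#' @return Noisy values shaped like `s`.
#' @export
rician_noise <- function(s, sigma) {
  if (sigma < 0) zf_domain_error("sigma must be >= 0")
  if (sigma == 0) return(s)
  n <- length(s)
  out <- sqrt((s + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  if (!is.null(dim(s))) dim(out) <- dim(s)
  out
}

# white-matter T2 that yields a target PGZ/tectum signal ratio at echo time
# te against a grey-matter T2 (equal M0 in both compartments)
t2_for_ratio <- function(ratio, t2_grey, te) 1 / (1 / t2_grey - log(ratio) / te)

#' Specification of a digital zebrafish-brain phantom
#'
#' Ground-truth geometry and tissue parameters for [make_phantom()]: an
#' ellipsoidal brain (grey matter with a periventricular white-matter band)
#' inside an ellipsoidal skull shell, with known landmark positions, ROI
#' placements, and per-compartment `(M0, T1, T2)`.  The skull compartment
#' has `M0 = 0`: cortical bone is signal-void on spin-echo images, so it is
#' excluded by the default fit mask while still defining the skull-width
#' normalizer through its landmarks.
#'
#' Defaults describe a wild-type-like specimen on a desk-scale grid: the
#' brain/skull proportions give normalized length/width/height of about
#' 1.11 / 0.958 / 0.629, and the white-matter T2 is set so the white/grey
#' T2-weighted signal ratio at TE = 36.6 ms is 0.743.
#'
#' @param grid Grid shape `(nx, ny, nz)`.  Default `c(48, 24, 28)`.
#' @param voxel_size_mm Isotropic voxel size in mm.  Default 0.1.
#' @param skull_width_mm Outer skull width (the normalizer).  Default 2.
#' @param brain_length_mm,brain_width_mm,brain_height_mm Brain ellipsoid
#'   extents in mm.
#' @param grey,white Lists `list(m0, t1, t2)` for the two tissue
#'   compartments (ms for t1/t2).  The default white-matter `t2` is derived
#'   from `wm_ratio_target` at `ratio_te`.
#' @param wm_ratio_target Target white/grey signal ratio used to derive the
#'   default white-matter T2.  Default 0.743.
#' @param ratio_te Echo time (ms) at which the ratio target applies.
#'   Default 36.6.
#' @param noise_sigma Default Rician sigma for simulated series.  Default 0.
#' @param seed Integer seed recorded on the spec.  Default 1.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(grid = c(48, 24, 28), voxel_size_mm = 0.1,
                         skull_width_mm = 2,
                         brain_length_mm = 1.11 * skull_width_mm,
                         brain_width_mm = 0.958 * skull_width_mm,
                         brain_height_mm = 0.629 * skull_width_mm,
                         grey = list(m0 = 8000, t1 = 180, t2 = 75),
                         white = list(m0 = 8000, t1 = 280, t2 = NULL),
                         wm_ratio_target = 0.743, ratio_te = 36.6,
                         noise_sigma = 0, seed = 1) {
  if (is.null(white$t2))
    white$t2 <- t2_for_ratio(wm_ratio_target, grey$t2, ratio_te)
  for (cp in list(grey, white))
    if (any(unlist(cp) < 0) || cp$t1 <= 0 || cp$t2 <= 0)
      zf_validation_error("compartment m0 must be >= 0 and t1, t2 > 0")
  if (noise_sigma < 0) zf_domain_error("noise_sigma must be >= 0")
  vs <- voxel_size_mm
  if (brain_length_mm >= grid[3] * vs || brain_width_mm >= grid[1] * vs ||
      brain_height_mm >= grid[2] * vs || skull_width_mm > grid[1] * vs)
    zf_validation_error("geometry does not fit inside the grid")
  if (brain_width_mm > skull_width_mm)
    zf_validation_error("brain wider than skull")
  structure(list(grid = as.integer(grid), voxel_size_mm = vs,
                 skull_width_mm = skull_width_mm,
                 brain_length_mm = brain_length_mm,
                 brain_width_mm = brain_width_mm,
                 brain_height_mm = brain_height_mm,
                 grey = grey, white = white,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Ground-truth landmark table of a phantom, without building its volumes
#'
#' Computes the registration landmarks (eye-lens centers, vagal-lobe tip)
#' and the eight morphometry landmarks (brain / skull extremal points) for a
#' [phantom_spec()] directly from its geometry.  Used by [make_phantom()]
#' and, on its own, by cohort-scale morphometry simulations where the image
#' volumes themselves are not needed.
#'
#' @param spec A [phantom_spec()].
#' @return `data.frame(name, x, y, slice)` in 0-based voxel coordinates.
#' @export
phantom_landmarks <- function(spec) {
  g <- spec$grid; vs <- spec$voxel_size_mm
  cx <- (g[1] - 1) / 2; cy <- (g[2] - 1) / 2; cz <- (g[3] - 1) / 2
  a_br <- spec$brain_width_mm / (2 * vs)
  b_br <- spec$brain_height_mm / (2 * vs)
  c_br <- spec$brain_length_mm / (2 * vs)
  a_sk <- spec$skull_width_mm / (2 * vs)
  rbind(
    data.frame(name = "lens_left",      x = cx - 8, y = cy - 2, slice = cz),
    data.frame(name = "lens_right",     x = cx + 8, y = cy - 2, slice = cz),
    data.frame(name = "vagal_lobe_tip", x = cx,     y = cy + 6, slice = cz),
    data.frame(name = "olfactory_tip",  x = cx, y = cy, slice = cz - c_br),
    data.frame(name = "tectum_end",     x = cx, y = cy, slice = cz + c_br),
    data.frame(name = "tectum_left",    x = cx - a_br, y = cy, slice = cz),
    data.frame(name = "tectum_right",   x = cx + a_br, y = cy, slice = cz),
    data.frame(name = "brain_top",      x = cx, y = cy + b_br, slice = cz),
    data.frame(name = "brain_bottom",   x = cx, y = cy - b_br, slice = cz),
    data.frame(name = "skull_left",     x = cx - a_sk, y = cy, slice = cz),
    data.frame(name = "skull_right",    x = cx + a_sk, y = cy, slice = cz))
}

#' Generate a digital phantom with known ground truth
#'
#' Builds piecewise-constant M0/T1/T2 truth volumes for the geometry in a
#' [phantom_spec()], together with compartment masks, the full landmark
#' table (registration landmarks: both eye-lens centers and the vagal-lobe
#' tip; morphometry landmarks: brain and skull extremal points), the ROI
#' specification (reference slice at the caudal measurement plane plus two
#' more slices moving rostrally), and a truth record (normalized
#' morphometry values and the analytic white/grey intensity ratio).
#' Deterministic given the spec.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `"zf_phantom"`: `spec`, truth arrays
#'   `m0`, `t1`, `t2`, logical `masks` (`brain`, `white`, `grey`), the
#'   `landmarks` data frame, `roi` ([roi_spec()]), and `truth` list.
#' @export
make_phantom <- function(spec) {
  g <- spec$grid; vs <- spec$voxel_size_mm
  cx <- (g[1] - 1) / 2; cy <- (g[2] - 1) / 2; cz <- (g[3] - 1) / 2
  # semi-axes in voxel units
  a_br <- spec$brain_width_mm / (2 * vs)
  b_br <- spec$brain_height_mm / (2 * vs)
  c_br <- spec$brain_length_mm / (2 * vs)
  a_sk <- spec$skull_width_mm / (2 * vs)
  b_sk <- max(b_br + 1.5, 0.4 * g[2])
  c_sk <- max(c_br + 1.5, 0.45 * g[3])

  x <- (seq_len(g[1]) - 1) - cx
  y <- (seq_len(g[2]) - 1) - cy
  z <- (seq_len(g[3]) - 1) - cz
  X <- array(rep(x, times = g[2] * g[3]), g)
  Y <- array(rep(rep(y, each = g[1]), times = g[3]), g)
  Z <- array(rep(z, each = g[1] * g[2]), g)

  brain <- (X / a_br)^2 + (Y / b_br)^2 + (Z / c_br)^2 <= 1
  rsk <- (X / a_sk)^2 + (Y / b_sk)^2 + (Z / c_sk)^2
  shell_out <- (X / (a_sk + 1.5))^2 + (Y / (b_sk + 1.5))^2 +
    (Z / (c_sk + 1.5))^2
  skull <- shell_out <= 1 & rsk > 1
  # periventricular white-matter band: mid-dorsoventral slab through the
  # brain; its half-thickness scales down with small brains so the grey
  # tectum ROI still fits above it
  band <- min(1.5, 0.25 * b_br)
  white <- brain & abs(Y) <= band
  grey <- brain & !white

  m0 <- array(0, g); t1 <- array(NaN, g); t2 <- array(NaN, g)
  m0[grey] <- spec$grey$m0; t1[grey] <- spec$grey$t1; t2[grey] <- spec$grey$t2
  m0[white] <- spec$white$m0; t1[white] <- spec$white$t1
  t2[white] <- spec$white$t2
  # skull stays M0 = 0 (signal-void bone)

  lm <- phantom_landmarks(spec)

  ref_off <- min(3, floor(0.5 * c_br))
  ref_slice <- round(cz + ref_off)
  tec_off <- max(band + 1.5, 0.55 * b_br)
  centers <- lapply(0:2, function(k)
    list(pgz = c(cx, cy), tectum = c(cx, cy + tec_off)))
  roi <- roi_spec(ref_slice, centers, rostral_direction = -1, roi_size = 2)
  # the generator must place its own ROIs in the intended compartments
  for (i in seq_along(centers)) {
    zi <- ref_slice - (i - 1) + 1
    chk <- function(ct, mask, what) {
      corner <- round(ct - 0.5)
      cells <- as.matrix(expand.grid(corner[1] + 1:2, corner[2] + 1:2))
      if (!all(mask[cbind(cells, zi)]))
        zf_validation_error(sprintf(
          "phantom geometry: %s ROI on slice %d leaves its compartment",
          what, zi - 1))
    }
    chk(centers[[i]]$pgz, white, "PGZ")
    chk(centers[[i]]$tectum, grey, "tectum")
  }

  truth <- list(
    normalized_length = spec$brain_length_mm / spec$skull_width_mm,
    normalized_width = spec$brain_width_mm / spec$skull_width_mm,
    normalized_height = spec$brain_height_mm / spec$skull_width_mm,
    wm_ratio = function(te) {
      (spec$white$m0 * exp(-te / spec$white$t2)) /
        (spec$grey$m0 * exp(-te / spec$grey$t2))
    })

  structure(list(spec = spec, m0 = m0, t1 = t1, t2 = t2,
                 masks = list(brain = brain, white = white, grey = grey,
                              skull = skull),
                 landmarks = lm, roi = roi, truth = truth),
            class = "zf_phantom")
}

#' @export
print.zf_phantom <- function(x, ...) {
  cat(sprintf("<zf_phantom> %s grid, %d brain voxels (%d white, %d grey)\n",
              paste(x$spec$grid, collapse = " x "), sum(x$masks$brain),
              sum(x$masks$white), sum(x$masks$grey)))
  invisible(x)
}

#' Smooth-field phantom for interpolation-sensitive checks
#'
#' A phantom with uniform M0 and gently (linearly) varying T1/T2 fields over
#' the whole grid and no background: because the fields are locally linear,
#' bilinear resampling is nearly exact on it, which isolates motion /
#' registration effects from tissue-edge interpolation error.  Used for the
#' motion-corrupted-versus-motion-free end-to-end comparison.
#'
#' @param grid Grid shape.  Default `c(32, 16, 12)`.
#' @param voxel_size_mm Voxel size.  Default 0.1.
#' @param m0 Uniform equilibrium signal.  Default 8000.
#' @param t1_base,t2_base Field centers in ms.  Defaults 150 / 75.
#' @param rel_slope Total relative variation of each field across the grid
#'   in x and y.  Default 0.1.
#' @return A `"zf_phantom"` whose brain mask covers the full grid.
#' @export
smooth_phantom <- function(grid = c(32, 16, 12), voxel_size_mm = 0.1,
                           m0 = 8000, t1_base = 150, t2_base = 75,
                           rel_slope = 0.1) {
  g <- as.integer(grid)
  cx <- (g[1] - 1) / 2; cy <- (g[2] - 1) / 2
  X <- array(rep((seq_len(g[1]) - 1) - cx, times = g[2] * g[3]), g)
  Y <- array(rep(rep((seq_len(g[2]) - 1) - cy, each = g[1]), times = g[3]), g)
  ramp <- 1 + rel_slope * (X / g[1] + 0.6 * Y / g[2])
  lm <- rbind(
    data.frame(name = "lens_left",      x = cx - 6, y = cy - 2,
               slice = (g[3] - 1) / 2),
    data.frame(name = "lens_right",     x = cx + 6, y = cy - 2,
               slice = (g[3] - 1) / 2),
    data.frame(name = "vagal_lobe_tip", x = cx,     y = cy + 4,
               slice = (g[3] - 1) / 2))
  spec <- list(grid = g, voxel_size_mm = voxel_size_mm,
               grey = list(m0 = m0, t1 = t1_base, t2 = t2_base),
               white = list(m0 = m0, t1 = t1_base, t2 = t2_base),
               noise_sigma = 0, seed = 1L)
  structure(list(spec = spec, m0 = array(m0, g), t1 = t1_base * ramp,
                 t2 = t2_base * ramp,
                 masks = list(brain = array(TRUE, g),
                              white = array(FALSE, g),
                              grey = array(TRUE, g),
                              skull = array(FALSE, g)),
                 landmarks = lm, roi = NULL,
                 truth = list()),
            class = "zf_phantom")
}

# default acquisition timing (TR in ms for T1 series, TE in ms for T2 series)
default_times <- function(series_type) {
  if (series_type == "T1") c(50, 150, 275, 450, 600)
  else c(12.2, 36.6, 60.94)
}

#' Simulate a multi-TR / multi-TE acquisition series from a phantom
#'
#' For each time point the noiseless volume is the signal model applied
#' voxelwise to the truth maps ([t1_signal()] / [t2_signal()]); an optional
#' per-acquisition rigid motion is then applied slice-wise, and finally
#' Rician noise is added (independently per repetition).  Landmark tables
#' for every time point are produced by moving the phantom's registration
#' landmarks with the same true transforms.
#'
#' @param phantom A `"zf_phantom"`.
#' @param series_type `"T1"` or `"T2"`.
#' @param times_ms TR or TE values in ms; defaults to the acquisition sets
#'   `c(50, 150, 275, 450, 600)` (T1) / `c(12.2, 36.6, 60.94)` (T2).
#' @param noise_sigma Rician sigma; defaults to the spec's.
#' @param motion Optional list of true [rigid2d()] transforms, one per time
#'   point (`NULL` entries mean no motion).
#' @param n_rep Repetitions per time point (1 = none stored).
#' @param seed Integer seed; defaults to the spec's.
#' @return List with `series` (`"zf_series"`), `landmarks`
#'   (`"zf_landmarks"`, one frame per time point), and `transforms`
#'   (true per-volume [rigid2d()]s).
#' @export
simulate_series <- function(phantom, series_type = c("T1", "T2"),
                            times_ms = NULL, noise_sigma = NULL,
                            motion = NULL, n_rep = 1, seed = NULL) {
  series_type <- match.arg(series_type)
  if (is.null(times_ms)) times_ms <- default_times(series_type)
  if (is.null(noise_sigma)) noise_sigma <- phantom$spec$noise_sigma
  if (noise_sigma < 0) zf_domain_error("noise_sigma must be >= 0")
  if (is.null(seed)) seed <- phantom$spec$seed
  set.seed(seed)
  vs <- rep(phantom$spec$voxel_size_mm, 3)
  tmap <- if (series_type == "T1") phantom$t1 else phantom$t2
  sig_fun <- if (series_type == "T1") t1_signal else t2_signal

  reg_names <- c("lens_left", "lens_right", "vagal_lobe_tip")
  lm0 <- phantom$landmarks[phantom$landmarks$name %in% reg_names, ]

  vols <- vector("list", length(times_ms))
  reps <- if (n_rep > 1) vector("list", length(times_ms)) else NULL
  lms <- vector("list", length(times_ms))
  trs <- vector("list", length(times_ms))
  for (i in seq_along(times_ms)) {
    s <- array(0, phantom$spec$grid)
    inb <- phantom$masks$brain
    s[inb] <- sig_fun(phantom$m0[inb], tmap[inb], times_ms[i])
    v <- volume(s, vs)
    T <- if (!is.null(motion) && !is.null(motion[[i]])) motion[[i]]
         else rigid2d()
    trs[[i]] <- T
    if (T$theta != 0 || T$tx != 0 || T$ty != 0)
      v <- apply_transform_slicewise(v, T)
    li <- lm0
    li[, c("x", "y")] <- transform_points(T, as.matrix(lm0[, c("x", "y")]))
    lms[[i]] <- li
    vols[[i]] <- volume(rician_noise(v$data, noise_sigma), vs)
    if (n_rep > 1)
      reps[[i]] <- lapply(seq_len(n_rep - 1), function(j)
        volume(rician_noise(v$data, noise_sigma), vs))
  }
  names(lms) <- sprintf("frame_%02d", seq_along(lms))
  list(series = acquisition_series(vols, series_type, times_ms,
                                   repetitions = reps),
       landmarks = structure(lms, class = "zf_landmarks"),
       transforms = trs)
}

#' Simulate a single T2-weighted volume at one echo time
#'
#' Convenience wrapper used by the ROI-intensity analyses: the T2-weighted
#' image of the phantom at echo time `te` with Rician noise.
#'
#' @inheritParams simulate_series
#' @param te Echo time in ms.  Default 36.6.
#' @return A [volume()].
#' @export
simulate_t2w <- function(phantom, te = 36.6, noise_sigma = NULL,
                         seed = NULL) {
  if (is.null(noise_sigma)) noise_sigma <- phantom$spec$noise_sigma
  if (is.null(seed)) seed <- phantom$spec$seed
  set.seed(seed)
  s <- array(0, phantom$spec$grid)
  inb <- phantom$masks$brain
  s[inb] <- t2_signal(phantom$m0[inb], phantom$t2[inb], te)
  volume(rician_noise(s, noise_sigma), rep(phantom$spec$voxel_size_mm, 3))
}

#' Default two-genotype phantom parameters
#'
#' The wild-type specimen uses the [phantom_spec()] defaults; the mutant
#' differs in the directions seen in vanishing-white-matter models: a
#' smaller brain (normalized length/width/height 0.933 / 0.836 / 0.551
#' against the wild-type 1.11 / 0.958 / 0.629) and a white-matter T2 shifted
#' toward grey so the white/grey intensity ratio rises from 0.743 to 0.849.
#'
#' @param grid,voxel_size_mm Passed to [phantom_spec()].
#' @return Named list of two [phantom_spec()]s (`wildtype`, `mutant`).
#' @export
cohort_group_specs <- function(grid = c(48, 24, 28), voxel_size_mm = 0.1) {
  sw <- 2
  list(
    wildtype = phantom_spec(grid, voxel_size_mm, skull_width_mm = sw,
                            brain_length_mm = 1.11 * sw,
                            brain_width_mm = 0.958 * sw,
                            brain_height_mm = 0.629 * sw,
                            wm_ratio_target = 0.743),
    mutant = phantom_spec(grid, voxel_size_mm, skull_width_mm = sw,
                          brain_length_mm = 0.933 * sw,
                          brain_width_mm = 0.836 * sw,
                          brain_height_mm = 0.551 * sw,
                          wm_ratio_target = 0.849))
}

#' Simulate a two-group cohort of phantoms
#'
#' Draws `n_per_group` specimens per genotype around the group parameters,
#' with between-specimen biological variability: brain extents scaled by a
#' common factor `1 + N(0, cv_size)` (skull fixed, so normalized measures
#' carry the same CV) and white-matter T2 scaled by `1 + N(0, cv_t2)`.
#' Per-specimen seeds are derived deterministically from `seed`.
#'
#' @param group_specs Named list of two [phantom_spec()]s; default
#'   [cohort_group_specs()].
#' @param n_per_group Specimens per group.  Default 6.
#' @param cv_size,cv_t2 Coefficients of variation of the size factor and the
#'   white-matter T2.  Defaults 0.05 and 0.05.
#' @param seed Master seed.
#' @return List of specimens, each
#'   `list(genotype, spec, seed)`; build artifacts per specimen with
#'   [make_phantom()], [simulate_series()] or [simulate_t2w()].
#' @export
simulate_cohort <- function(group_specs = cohort_group_specs(),
                            n_per_group = 6, cv_size = 0.05, cv_t2 = 0.05,
                            seed = 1) {
  if (n_per_group < 1) zf_validation_error("n_per_group must be >= 1")
  if (length(group_specs) != 2) zf_validation_error("need two group specs")
  out <- list(); k <- 0
  for (gname in names(group_specs)) {
    base <- group_specs[[gname]]
    for (i in seq_len(n_per_group)) {
      k <- k + 1
      si <- derive_seed(seed, k)
      set.seed(si)
      fs <- 1 + if (cv_size > 0) rnorm(1, 0, cv_size) else 0
      ft <- 1 + if (cv_t2 > 0) rnorm(1, 0, cv_t2) else 0
      sp <- base
      sp$brain_length_mm <- base$brain_length_mm * fs
      sp$brain_width_mm <- base$brain_width_mm * fs
      sp$brain_height_mm <- base$brain_height_mm * fs
      sp$white$t2 <- base$white$t2 * ft
      sp$seed <- derive_seed(si, 1)
      out[[k]] <- list(genotype = gname, spec = sp, seed = sp$seed)
    }
  }
  out
}

#' Generate a synthetic fiber contour set with known G-ratios
#'
#' Draws per-fiber G-ratios from `N(g_mean, g_sd)` (resampling draws outside
#' the valid open interval, count attached as attribute `n_resampled`) and
#' axon diameters from a log-normal, then builds concentric polygonal
#' contour pairs: the myelin outer contour is the axon contour scaled by
#' `1/g`, so the perimeter-based true G-ratio is exact by construction (also
#' for the elliptical option, since the shapes are similar).  Optional
#' radial vertex jitter roughens the contours.
#'
#' @param n_fibers Number of fibers.
#' @param g_mean,g_sd G-ratio distribution.  Defaults 0.593 / 0.085
#'   (wild-type-like); mutant-like fibers use 0.690 / 0.076.
#' @param diameter_meanlog,diameter_sdlog Log-normal axon diameter (nm).
#'   Defaults `log(800)` and 0.4.
#' @param vertices Vertices per contour (>= 8).  Default 64.
#' @param jitter_sd Relative radial jitter SD.  Default 0.
#' @param aspect_max Maximum ellipse aspect ratio (1 = circles).  Default 1.
#' @param seed Integer seed.
#' @return List with `contours` (a validated `"zf_contours"`-style
#'   data frame) and `truth` (`data.frame(fiber_id, g_true, axon_diameter)`).
#' @export
make_fiber_set <- function(n_fibers, g_mean = 0.593, g_sd = 0.085,
                           diameter_meanlog = log(800),
                           diameter_sdlog = 0.4, vertices = 64,
                           jitter_sd = 0, aspect_max = 1, seed = 1) {
  if (g_mean <= 0 || g_mean >= 1) zf_validation_error("g_mean must be in (0,1)")
  if (vertices < 8) zf_validation_error("vertices must be >= 8")
  set.seed(seed)
  g_hi <- min(0.98, 1 / (1 + 8 * jitter_sd) - 0.005)
  n_res <- 0
  draw_g <- function() {
    repeat {
      g <- rnorm(1, g_mean, g_sd)
      if (g > 0.05 && g < g_hi) return(g)
      n_res <<- n_res + 1
    }
  }
  th <- seq(0, 2 * pi, length.out = vertices + 1)[-(vertices + 1)]
  xs <- vector("list", n_fibers); ys <- vector("list", n_fibers)
  gs <- numeric(n_fibers); ds <- numeric(n_fibers)
  for (i in seq_len(n_fibers)) {
    g <- draw_g()
    d <- exp(rnorm(1, diameter_meanlog, diameter_sdlog))
    r <- d / 2
    asp <- if (aspect_max > 1) runif(1, 1, aspect_max) else 1
    phase <- runif(1, 0, 2 * pi)
    base <- cbind(sqrt(asp) * cos(th + phase), sin(th + phase) / sqrt(asp))
    jit <- function() if (jitter_sd > 0)
      1 + pmax(pmin(rnorm(vertices, 0, jitter_sd), 3 * jitter_sd),
               -3 * jitter_sd) else 1
    ax <- r * base * jit()
    my <- (r / g) * base * jit()
    xs[[i]] <- c(ax[, 1], my[, 1]); ys[[i]] <- c(ax[, 2], my[, 2])
    gs[i] <- g; ds[i] <- d
  }
  if (n_res > 0)
    warning(sprintf("resampled %d G-ratio draw(s) outside the valid range",
                    n_res))
  ids <- sprintf("fiber_%04d", seq_len(n_fibers))
  # radial (star-shaped) construction with the clamped jitter margin makes
  # the contours simple and strictly nested by construction; the readers
  # re-validate on ingest
  contours <- data.frame(
    fiber_id = rep(ids, each = 2 * vertices),
    boundary = rep(rep(c("axon", "myelin"), each = vertices), n_fibers),
    vertex_order = rep(seq_len(vertices), 2 * n_fibers),
    x = unlist(xs), y = unlist(ys), stringsAsFactors = FALSE)
  out <- list(contours = contours,
              truth = data.frame(fiber_id = ids, g_true = gs,
                                 axon_diameter = ds,
                                 stringsAsFactors = FALSE))
  attr(out, "n_resampled") <- n_res
  out
}
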