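#' Euclidean distance between two voxel-space points, in mm
#'
#' Scales each axis by the voxel size before taking the Euclidean distance;
#' points are `(x, y, slice)` voxel coordinates (sub-pixel allowed).
#'
#' @param a,b Numeric length-3 points in voxel coordinates.
#' @param voxel_size mm per axis (length 3, or scalar for isotropic grids).
#' @return Distance in mm.
#' @export
measure_distance <- function(a, b, voxel_size) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (length(a) != 3 || length(b) != 3 || length(voxel_size) != 3)
    zf_validation_error("points and voxel_size must have length 3")
  if (any(voxel_size <= 0)) zf_validation_error("voxel_size must be > 0")
  sqrt(sum(((as.double(a) - as.double(b)) * voxel_size)^2))
}

#' Normalize a measurement to the specimen's skull width
#'
#' @param measure Measurement in mm.
#' @param skull_width Same-specimen skull width in mm; must be `> 0`.
#' @return Unitless ratio `measure / skull_width`.
#' @export
normalize_to_skull <- function(measure, skull_width) {
  if (any(skull_width <= 0)) zf_domain_error("skull_width must be > 0")
  measure / skull_width
}

# endpoint landmark names for each brain measurement; skull width is the
# within-specimen normalizer
morpho_pairs <- list(
  brain_length = c("olfactory_tip", "tectum_end"),
  tectum_width = c("tectum_left", "tectum_right"),
  brain_height = c("brain_top", "brain_bottom"),
  skull_width  = c("skull_left", "skull_right"))

#' Brain size measurements from a specimen's landmark table
#'
#' Computes the three brain measurements (olfactory-bulb tip to tectum end,
#' maximum tectum width, maximum brain height at the central ventricle) plus
#' the skull width from named landmarks, and normalizes each brain
#' measurement to the same specimen's skull width.
#'
#' @param landmarks One specimen's landmark `data.frame` (columns
#'   `name, x, y, slice`) containing the eight morphometry landmarks
#'   `olfactory_tip, tectum_end, tectum_left, tectum_right, brain_top,
#'   brain_bottom, skull_left, skull_right`.
#' @param voxel_size mm per axis.
#' @return `data.frame(name, value_mm, normalized)`; `normalized` is `NA`
#'   for the skull width itself.
#' @export
measure_morphometry <- function(landmarks, voxel_size) {
  pt <- function(nm) {
    r <- landmarks[landmarks$name == nm, ]
    if (nrow(r) != 1)
      zf_validation_error(sprintf("landmark '%s' missing or duplicated", nm))
    c(r$x, r$y, r$slice)
  }
  value_mm <- vapply(morpho_pairs, function(p)
    measure_distance(pt(p[1]), pt(p[2]), voxel_size), numeric(1))
  sw <- value_mm[["skull_width"]]
  out <- data.frame(name = names(morpho_pairs), value_mm = unname(value_mm),
                    normalized = unname(normalize_to_skull(value_mm, sw)),
                    stringsAsFactors = FALSE)
  out$normalized[out$name == "skull_width"] <- NA_real_
  out
}

#' Two-sample comparison of measurement groups
#'
#' Two-tailed two-sample t-test, pooled-variance Student's form by default
#' (Welch's unequal-variance form by option), as used for all pairwise group
#' comparisons in the pipeline.
#'
#' @param a,b Numeric vectors of per-specimen values (each `n >= 2`).
#' @param method `"student"` (pooled variance) or `"welch"`.
#' @return An object of class `"group_comparison"`: group means, SDs and
#'   sizes, `t_statistic`, `degrees_of_freedom`, two-tailed `p_value`,
#'   and the method used.
#' @examples
#' compare_groups(c(1.05, 1.1, 1.2), c(0.9, 0.93, 0.88))
#' @export
compare_groups <- function(a, b, method = c("student", "welch")) {
  method <- match.arg(method)
  a <- as.double(a); b <- as.double(b)
  if (length(a) < 2 || length(b) < 2)
    zf_validation_error("each group needs n >= 2")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    zf_domain_error("group values must be finite")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      zf_domain_error("zero variance in both groups with equal means: t undefined")
    # degenerate but directional: the limit of vanishing within-group spread
    ht <- list(statistic = c(t = sign(mean(a) - mean(b)) * Inf),
               parameter = c(df = length(a) + length(b) - 2), p.value = 0)
  } else {
    ht <- t.test(a, b, var.equal = (method == "student"))
  }
  structure(list(mean_a = mean(a), mean_b = mean(b),
                 sd_a = sd(a), sd_b = sd(b),
                 n_a = length(a), n_b = length(b),
                 t_statistic = unname(ht$statistic),
                 degrees_of_freedom = unname(ht$parameter),
                 p_value = ht$p.value,
                 method = if (method == "student") "student_pooled" else "welch"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Two-sample comparison (%s)\n", x$method))
  cat(sprintf("  group A: mean = %.4g, SD = %.4g, n = %d\n",
              x$mean_a, x$sd_a, x$n_a))
  cat(sprintf("  group B: mean = %.4g, SD = %.4g, n = %d\n",
              x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("  t = %.4g on %.4g df, two-tailed p = %.4g\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value))
  invisible(x)
}
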