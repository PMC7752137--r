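#' Perimeter of a closed polygon
#'
#' Sum of consecutive edge lengths including the closing edge from the last
#' vertex back to the first.  Orientation-invariant.
#'
#' @param contour `n x 2` numeric matrix of vertices (n >= 3), implicit
#'   closure.
#' @return Total perimeter in the coordinate unit.
#' @export
polygon_perimeter <- function(contour) {
  contour <- as.matrix(contour)
  n <- nrow(contour)
  if (n < 3) zf_validation_error("polygon needs >= 3 vertices")
  d <- contour[c(2:n, 1), ] - contour
  sum(sqrt(rowSums(d^2)))
}

# brute-force O(n^2) segment-intersection test for polygon simplicity;
# adjacent edges share an endpoint and are exempt.
#' Test whether a closed polygon is simple (non-self-intersecting)
#'
#' @param contour `n x 2` vertex matrix, implicit closure.
#' @return `TRUE` if no two non-adjacent edges intersect.
#' @export
polygon_is_simple <- function(contour) {
  contour <- as.matrix(contour)
  n <- nrow(contour)
  if (n < 3) zf_validation_error("polygon needs >= 3 vertices")
  nxt <- c(2:n, 1)
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- cross2(p4 - p3, p1 - p3); d2 <- cross2(p4 - p3, p2 - p3)
    d3 <- cross2(p2 - p1, p3 - p1); d4 <- cross2(p2 - p1, p4 - p1)
    if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
        ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    on_seg <- function(p, a, b)
      min(a[1], b[1]) <= p[1] && p[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= p[2] && p[2] <= max(a[2], b[2])
    (d1 == 0 && on_seg(p1, p3, p4)) || (d2 == 0 && on_seg(p2, p3, p4)) ||
      (d3 == 0 && on_seg(p3, p1, p2)) || (d4 == 0 && on_seg(p4, p1, p2))
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # skip adjacent edges (sharing a vertex), including the wrap-around pair
    if (j == i + 1 || (i == 1 && j == n)) next
    if (seg_int(contour[i, ], contour[nxt[i], ],
                contour[j, ], contour[nxt[j], ])) return(FALSE)
  }
  TRUE
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

point_in_polygon <- function(p, poly) {
  # even-odd ray casting
  n <- nrow(poly); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > p[2]) != (poly[j, 2] > p[2]) &&
        p[1] < (poly[j, 1] - poly[i, 1]) * (p[2] - poly[i, 2]) /
          (poly[j, 2] - poly[i, 2]) + poly[i, 1])
      inside <- !inside
    j <- i
  }
  inside
}

# inner strictly inside outer: every inner vertex inside, and no edge
# crossings between the two polygons
polygon_inside <- function(inner, outer) {
  for (i in seq_len(nrow(inner)))
    if (!point_in_polygon(inner[i, ], outer)) return(FALSE)
  ni <- nrow(inner); no <- nrow(outer)
  nxi <- c(2:ni, 1); nxo <- c(2:no, 1)
  for (i in seq_len(ni)) for (j in seq_len(no)) {
    a <- inner[i, ]; b <- inner[nxi[i], ]
    cc <- outer[j, ]; d <- outer[nxo[j], ]
    d1 <- cross2(d - cc, a - cc); d2 <- cross2(d - cc, b - cc)
    d3 <- cross2(b - a, cc - a); d4 <- cross2(b - a, d - a)
    if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
        ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(FALSE)
  }
  TRUE
}

#' Perimeter-based fiber metrics from an axon/myelin contour pair
#'
#' The G-ratio is the ratio of the axon boundary perimeter to the myelin
#' outer boundary perimeter.  Diameter and thickness use
#' perimeter-equivalent-circle conventions consistent with that definition:
#' `axon_diameter = P_axon / pi` and
#' `myelin_thickness = (P_myelin - P_axon) / (2 pi)`.  Area-equivalent
#' variants (`diameter = 2 sqrt(A/pi)`) are available via `convention`.
#'
#' @param axon,myelin `n x 2` vertex matrices (same length unit).
#' @param fiber_id Identifier carried into the result.
#' @param convention `"perimeter"` (default) or `"area"` for the diameter /
#'   thickness definitions; the G-ratio itself is always perimeter-based.
#' @return One-row `data.frame(fiber_id, p_axon, p_myelin, g_ratio,
#'   axon_diameter, myelin_thickness)`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 65)[-65]
#' fiber_metrics(cbind(cos(th), sin(th)), cbind(2 * cos(th), 2 * sin(th)))
#' @export
fiber_metrics <- function(axon, myelin, fiber_id = "fiber",
                          convention = c("perimeter", "area")) {
  convention <- match.arg(convention)
  axon <- as.matrix(axon); myelin <- as.matrix(myelin)
  pa <- polygon_perimeter(axon); pm <- polygon_perimeter(myelin)
  if (pa >= pm)
    zf_validation_error(sprintf(
      "fiber '%s': axon perimeter (%.4g) >= myelin perimeter (%.4g), g >= 1",
      fiber_id, pa, pm))
  if (convention == "perimeter") {
    dia <- pa / pi
    thick <- (pm - pa) / (2 * pi)
  } else {
    area <- function(p) {
      n <- nrow(p); nx <- c(2:n, 1)
      abs(sum(p[, 1] * p[nx, 2] - p[nx, 1] * p[, 2])) / 2
    }
    ra <- sqrt(area(axon) / pi); rm <- sqrt(area(myelin) / pi)
    dia <- 2 * ra
    thick <- rm - ra
  }
  data.frame(fiber_id = fiber_id, p_axon = pa, p_myelin = pm,
             g_ratio = pa / pm, axon_diameter = dia,
             myelin_thickness = thick, stringsAsFactors = FALSE)
}

#' Fiber metrics for every fiber in a contour table
#'
#' @param contours A `"zf_contours"` table from [read_contours()] (or any
#'   data frame with its columns, already validated).
#' @inheritParams fiber_metrics
#' @return `data.frame` with one row per fiber.
#' @export
fiber_metrics_table <- function(contours,
                                convention = c("perimeter", "area")) {
  convention <- match.arg(convention)
  ids <- unique(contours$fiber_id)
  do.call(rbind, lapply(ids, function(id) {
    g <- contours[contours$fiber_id == id, ]
    ax <- g[g$boundary == "axon", ]; ax <- ax[order(ax$vertex_order), ]
    my <- g[g$boundary == "myelin", ]; my <- my[order(my$vertex_order), ]
    fiber_metrics(cbind(ax$x, ax$y), cbind(my$x, my$y), id, convention)
  }))
}

#' Group summaries and comparison of fiber G-ratios
#'
#' Per-group descriptive statistics of the G-ratio plus the two-group
#' comparison via [compare_groups()].  Optionally also reports G-ratio
#' means binned by axon-diameter quantile, to separate myelin-thickness
#' effects from axon-caliber effects.
#'
#' @param metrics `data.frame` from [fiber_metrics_table()].
#' @param groups Character/factor vector of group labels, one per row of
#'   `metrics` (exactly two distinct groups).
#' @param method Passed to [compare_groups()].
#' @param n_bins If `> 0`, additionally bin fibers by axon-diameter quantile
#'   and report per-bin group means.
#' @return A list of class `"fiber_summary"`: `per_group`
#'   (`data.frame(group, n, mean, sd)` of G-ratio), `comparison`
#'   (a `"group_comparison"`), and optionally `by_diameter_bin`.
#' @export
summarize_fibers <- function(metrics, groups, method = "student",
                             n_bins = 0) {
  groups <- as.character(groups)
  if (length(groups) != nrow(metrics))
    zf_validation_error("one group label per fiber required")
  lv <- unique(groups)
  if (length(lv) != 2) zf_validation_error("exactly two groups required")
  gs <- split(metrics$g_ratio, factor(groups, levels = lv))
  if (any(vapply(gs, length, 1L) < 2))
    zf_validation_error("each group needs >= 2 fibers")
  per_group <- data.frame(group = lv,
                          n = vapply(gs, length, 1L),
                          mean = vapply(gs, mean, 1),
                          sd = vapply(gs, sd, 1),
                          row.names = NULL, stringsAsFactors = FALSE)
  comparison <- tryCatch(compare_groups(gs[[1]], gs[[2]], method),
                         zfqmri_domain_error = function(e) NULL)
  out <- list(per_group = per_group, comparison = comparison)
  if (n_bins > 0) {
    br <- stats::quantile(metrics$axon_diameter,
                          probs = seq(0, 1, length.out = n_bins + 1))
    bin <- cut(metrics$axon_diameter, unique(br), include.lowest = TRUE)
    out$by_diameter_bin <- stats::aggregate(
      metrics$g_ratio, list(bin = bin, group = groups),
      function(v) c(n = length(v), mean = mean(v)))
  }
  class(out) <- "fiber_summary"
  out
}

#' @export
print.fiber_summary <- function(x, ...) {
  cat("G-ratio group summary\n")
  print(x$per_group, row.names = FALSE)
  if (is.null(x$comparison))
    cat("  (group comparison undefined: no within-group variance)\n")
  else print(x$comparison)
  invisible(x)
}
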