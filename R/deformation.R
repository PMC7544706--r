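#' Slice geometry model
#'
#' Describes the slice volume in the imaging frame: `z = 0` at the top
#' imaged surface, z increasing downward, the slice occupying
#' `[0, nominal_thickness]`. `measured_thickness`, when known, is the
#' thickness after compression and must lie in `(0, nominal_thickness]`.
#'
#' @param nominal_thickness Cut thickness in micrometres (default 300, the
#'   standard for acute slices used in patch-clamp work).
#' @param measured_thickness Optional measured (possibly shrunken) thickness.
#' @return A `slice_model` object.
#' @export
slice_model <- function(nominal_thickness = 300, measured_thickness = NULL) {
  if (nominal_thickness <= 0) stop("nominal_thickness must be > 0", call. = FALSE)
  if (!is.null(measured_thickness)) {
    if (measured_thickness <= 0 || measured_thickness > nominal_thickness) {
      stop("measured_thickness must be in (0, nominal_thickness]", call. = FALSE)
    }
  }
  structure(list(nominal_thickness = nominal_thickness,
                 measured_thickness = measured_thickness),
            class = "slice_model")
}

#' @export
print.slice_model <- function(x, ...) {
  cat(sprintf("<slice_model: nominal %.1f um%s>\n", x$nominal_thickness,
              if (is.null(x$measured_thickness)) ""
              else sprintf(", measured %.1f um", x$measured_thickness)))
  invisible(x)
}

new_deformation_profile <- function(family, s, cum_s, params, xy_dilation) {
  if (xy_dilation <= 0) stop("xy_dilation must be > 0", call. = FALSE)
  structure(list(family = family, s = s, cum_s = cum_s,
                 params = params, xy_dilation = xy_dilation),
            class = "deformation_profile")
}

#' @export
print.deformation_profile <- function(x, ...) {
  cat(sprintf("<deformation_profile: %s; mean z-shrinkage %.1f%%; xy dilation x%.3f>\n",
              x$family, 100 * x$cum_s(1), x$xy_dilation))
  invisible(x)
}

#' Deformation profiles for embedded slices
#'
#' A deformation profile models the embedding-induced distortion of a slice
#' as a depth-dependent local z-compression plus an isotropic xy-dilation.
#' The local shrinkage `s(u)` is a fraction in `[0, 1)` of normalized depth
#' `u = z / T` (0 = top surface, 1 = bottom); a point initially at depth `z`
#' maps to `z' = integral from 0 to z of (1 - s(zeta/T)) d zeta`, so the
#' deformed thickness is `T' = T * (1 - mean(s))`. `xy_dilation` is the
#' lateral scale factor `g` applied about the slice centre (> 1 = dilation).
#'
#' * `profile_uniform()`: constant `s(u)` — the assumption implicit in
#'   linear z-correction, useful as a control condition.
#' * `profile_thirds()`: piecewise-constant `s` over the upper, middle and
#'   lower thirds of the slice depth, matching depth-stratified differential
#'   shrinkage measurements.
#' * `profile_table()`: piecewise-constant `s` over arbitrary depth breaks.
#' * [calibrate_quadratic_profile()]: smooth symmetric-quadratic `s`.
#'
#' @param total_shrinkage Mean shrinkage fraction in `[0, 1)`.
#' @param top,middle,bottom Per-third shrinkage fractions in `[0, 1)`.
#' @param breaks Increasing normalized-depth breakpoints from 0 to 1.
#' @param values Shrinkage fraction on each interval of `breaks`
#'   (`length(values) == length(breaks) - 1`).
#' @param xy_dilation Isotropic lateral scale factor g (> 0; default 1).
#' @return A `deformation_profile`.
#' @examples
#' p <- profile_thirds(0.451, 0.304, 0.443)
#' deformed_thickness(p, slice_model(300)) # 180.2
#' @export
profile_uniform <- function(total_shrinkage, xy_dilation = 1) {
  check_fraction(total_shrinkage, "total_shrinkage")
  new_deformation_profile(
    family = "uniform",
    s = function(u) rep(total_shrinkage, length(u)),
    cum_s = function(u) total_shrinkage * u,
    params = list(total_shrinkage = total_shrinkage),
    xy_dilation = xy_dilation
  )
}

#' @rdname profile_uniform
#' @export
profile_thirds <- function(top, middle, bottom, xy_dilation = 1) {
  profile_table(breaks = c(0, 1, 2, 3) / 3, values = c(top, middle, bottom),
                xy_dilation = xy_dilation, family = "thirds")
}

#' @rdname profile_uniform
#' @export
profile_table <- function(breaks, values, xy_dilation = 1, family = "table") {
  if (length(values) != length(breaks) - 1L) {
    stop("need one shrinkage value per interval of `breaks`", call. = FALSE)
  }
  if (breaks[1] != 0 || breaks[length(breaks)] != 1 || any(diff(breaks) <= 0)) {
    stop("`breaks` must increase strictly from 0 to 1", call. = FALSE)
  }
  for (v in values) check_fraction(v, "shrinkage value")
  s_fun <- function(u) {
    idx <- findInterval(u, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    values[idx]
  }
  # cumulative integral of s from 0 to u, exact for the step function
  cum_edges <- c(0, cumsum(values * diff(breaks)))
  cum_fun <- function(u) {
    idx <- findInterval(u, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    cum_edges[idx] + values[idx] * (u - breaks[idx])
  }
  new_deformation_profile(
    family = family, s = s_fun, cum_s = cum_fun,
    params = list(breaks = breaks, values = values),
    xy_dilation = xy_dilation
  )
}

check_fraction <- function(v, what) {
  if (length(v) != 1 || is.na(v) || v < 0 || v >= 1) {
    stop(what, " must be a fraction in [0, 1); got ", v, call. = FALSE)
  }
  invisible(v)
}

#' Calibrate a symmetric quadratic depth profile
#'
#' Fits `s(u) = a + b (u - 1/2)^2` to two depth-resolved shrinkage
#' measurements: the overall mean shrinkage and the mean shrinkage within
#' the marginal zones (top and bottom 20% of the depth). Both constraints
#' are linear in `(a, b)` because the exact integrals of `(u - 1/2)^2` are
#' `1/12` over `[0, 1]` and `49/300` over the marginal 20% zones, so the
#' calibration is an exact 2x2 solve. Surface-weighted shrinkage
#' (`marginal20 > total`) gives `b > 0`.
#'
#' @param total_shrinkage Mean shrinkage fraction over the full depth.
#' @param marginal20_shrinkage Mean shrinkage fraction over the top and
#'   bottom 20% zones; must be `>= total_shrinkage`.
#' @param xy_dilation Lateral scale factor g (default 1).
#' @return A quadratic `deformation_profile`; the fitted coefficients are in
#'   `$params$a` and `$params$b`.
#' @examples
#' p <- calibrate_quadratic_profile(0.42, 0.613)
#' p$params          # a ~ 0.2190, b = 2.4125
#' mean_shrinkage(p, 1/3, 2/3)  # ~ 0.241
#' @export
calibrate_quadratic_profile <- function(total_shrinkage, marginal20_shrinkage,
                                        xy_dilation = 1) {
  check_fraction(total_shrinkage, "total_shrinkage")
  check_fraction(marginal20_shrinkage, "marginal20_shrinkage")
  if (marginal20_shrinkage < total_shrinkage) {
    stop("marginal20_shrinkage must be >= total_shrinkage", call. = FALSE)
  }
  # mean of (u - 1/2)^2: 1/12 over [0,1]; over [0,.2] u [.8,1]:
  # (1/0.2) * int_{0.8}^{1} (u-.5)^2 du = 49/300
  m_full <- 1 / 12
  m_marg <- 49 / 300
  b <- (marginal20_shrinkage - total_shrinkage) / (m_marg - m_full)
  a <- total_shrinkage - b * m_full
  s_fun <- function(u) a + b * (u - 0.5)^2
  smin <- min(s_fun(c(0, 0.5, 1)))
  smax <- max(s_fun(c(0, 0.5, 1)))
  if (smin < 0 || smax >= 1) {
    stop(sprintf(
      "calibrated profile leaves [0, 1): s ranges [%.4f, %.4f]", smin, smax),
      call. = FALSE)
  }
  cum_fun <- function(u) a * u + b * ((u - 0.5)^3 + 0.125) / 3
  new_deformation_profile(
    family = "quadratic", s = s_fun, cum_s = cum_fun,
    params = list(a = a, b = b,
                  total_shrinkage = total_shrinkage,
                  marginal20_shrinkage = marginal20_shrinkage),
    xy_dilation = xy_dilation
  )
}

#' Profile summaries
#'
#' `mean_shrinkage()` is the exact mean of the local shrinkage `s(u)` over a
#' normalized-depth interval. `deformed_thickness()` is the slice thickness
#' after deformation, `T' = T * (1 - mean(s))`. `local_axial_scale()` is the
#' local z scale factor `1 - s(z/T)` at an absolute depth.
#'
#' @param p A `deformation_profile`.
#' @param lower,upper Normalized depth interval (defaults: full depth).
#' @param slice A [slice_model()].
#' @param z Absolute depth(s) in micrometres.
#' @return Scalars (fraction, micrometres, scale factor respectively).
#' @export
mean_shrinkage <- function(p, lower = 0, upper = 1) {
  (p$cum_s(upper) - p$cum_s(lower)) / (upper - lower)
}

#' @rdname mean_shrinkage
#' @export
deformed_thickness <- function(p, slice) {
  slice$nominal_thickness * (1 - p$cum_s(1))
}

#' @rdname mean_shrinkage
#' @export
local_axial_scale <- function(p, z, slice) {
  1 - p$s(z / slice$nominal_thickness)
}

#' Depth coordinate map of a deformation
#'
#' Maps an original depth `z` (in the undeformed slice, `0 <= z <= T`) to
#' its deformed depth `z' = integral_0^z (1 - s(zeta/T)) d zeta`. The map is
#' strictly increasing (no fold-over), with `z'(0) = 0` and `z'(T) = T'`.
#' `depth_map_inverse()` inverts it numerically (bisection via
#' [stats::uniroot()] to 1e-10 um).
#'
#' @param p A `deformation_profile`.
#' @param slice A [slice_model()].
#' @param z Depth(s) in micrometres within `[0, T]`; values outside are a
#'   domain error (points outside the slice volume are invalid).
#' @param z_deformed Deformed depth(s) within `[0, T']`.
#' @return Mapped depth(s) in micrometres.
#' @export
depth_map <- function(p, slice, z) {
  T_nom <- slice$nominal_thickness
  tol <- 1e-9 * T_nom
  if (any(z < -tol | z > T_nom + tol)) {
    stop("depth(s) outside the slice volume [0, ", T_nom, "]", call. = FALSE)
  }
  u <- pmin(pmax(z / T_nom, 0), 1)
  T_nom * (u - p$cum_s(u))
}

#' @rdname depth_map
#' @export
depth_map_inverse <- function(p, slice, z_deformed) {
  T_nom <- slice$nominal_thickness
  vapply(z_deformed, function(zd) {
    stats::uniroot(function(z) depth_map(p, slice, z) - zd,
                   lower = 0, upper = T_nom, tol = 1e-10)$root
  }, numeric(1))
}

#' Apply a slice deformation to a morphology
#'
#' Transforms every node: depth via [depth_map()] (depth-dependent
#' z-compression) and lateral position by isotropic dilation about the slice
#' centre, `(x, y) -> centre + g * ((x, y) - centre)`. Topology and radii
#' are unchanged. Nodes with z outside `[0, T]` are an error (they lie
#' outside the slice volume); they are never silently clamped, since
#' clamping would corrupt length metrics.
#'
#' @param m A morphology (slice frame: z in `[0, T]`).
#' @param p A `deformation_profile`.
#' @param slice A [slice_model()].
#' @param center Length-2 xy centre of dilation; defaults to the centroid of
#'   the node coordinates (a stand-in for the slice centre, which drops out
#'   of all length metrics).
#' @return The deformed morphology.
#' @export
apply_deformation <- function(m, p, slice, center = NULL) {
  T_nom <- slice$nominal_thickness
  tol <- 1e-9 * T_nom
  bad <- m$z < -tol | m$z > T_nom + tol
  if (any(bad)) {
    stop("node(s) outside the slice volume [0, ", T_nom, "]: ids ",
         paste(utils::head(m$id[bad], 10), collapse = ", "),
         if (sum(bad) > 10) ", ..." else "", call. = FALSE)
  }
  if (is.null(center)) center <- c(mean(m$x), mean(m$y))
  g <- p$xy_dilation
  m$x <- center[1] + g * (m$x - center[1])
  m$y <- center[2] + g * (m$y - center[2])
  m$z <- depth_map(p, slice, m$z)
  m
}

#' Apply a slice deformation to a spine set
#'
#' Spine attachment points move with the tissue exactly like morphology
#' nodes. Offset vectors are local: the lateral components scale by the
#' xy-dilation g and the axial component by the local axial scale
#' `1 - s(z/T)` at the attachment depth.
#'
#' @param spines A spine tibble (columns `x, y, z, ox, oy, oz`), as from
#'   [gen_spines()].
#' @inheritParams apply_deformation
#' @return The deformed spine tibble.
#' @export
apply_deformation_spines <- function(spines, p, slice, center = NULL) {
  if (nrow(spines) == 0) return(spines)
  if (is.null(center)) center <- c(mean(spines$x), mean(spines$y))
  g <- p$xy_dilation
  ax <- local_axial_scale(p, spines$z, slice)
  spines$x <- center[1] + g * (spines$x - center[1])
  spines$y <- center[2] + g * (spines$y - center[2])
  spines$z <- depth_map(p, slice, spines$z)
  spines$ox <- g * spines$ox
  spines$oy <- g * spines$oy
  spines$oz <- ax * spines$oz
  spines
}
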