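#' Slice shrinkage percentage
#'
#' Shrinkage is the difference of the measured and the nominal thickness
#' expressed as a percentage of the nominal value,
#' `100 * (nominal - measured) / nominal`. A measured value above nominal
#' (dilation) is an error here; use [dimension_change_percent()] for signed
#' changes.
#'
#' @param measured Measured thickness (micrometres), in `(0, nominal]`.
#' @param nominal Nominal thickness (micrometres, default 300).
#' @return Shrinkage in percent.
#' @examples
#' shrinkage_percent(174, 300) # 42
#' @export
shrinkage_percent <- function(measured, nominal = 300) {
  if (any(measured <= 0)) stop("measured thickness must be > 0", call. = FALSE)
  if (any(measured > nominal)) {
    stop("measured exceeds nominal; for signed (dilation-aware) changes use ",
         "dimension_change_percent()", call. = FALSE)
  }
  100 * (nominal - measured) / nominal
}

#' Signed dimensional change
#'
#' `100 * (measured - reference) / reference`: positive values are dilation,
#' negative values shrinkage. This is the dilation-aware companion of
#' [shrinkage_percent()].
#'
#' @param measured Measured dimension(s).
#' @param reference Reference dimension(s) (> 0).
#' @return Signed change in percent.
#' @export
dimension_change_percent <- function(measured, reference) {
  if (any(reference <= 0)) stop("reference must be > 0", call. = FALSE)
  100 * (measured - reference) / reference
}

#' Differential shrinkage of matched segments
#'
#' The degree of differential shrinkage between two measurements of the same
#' dendritic segment: the difference of the two z-extents normalized to the
#' first, `(first - second) / first`. The first measurement is the reference
#' state (e.g. the minimally shrunken embedding).
#'
#' @param first,second z-extents in micrometres (vectors), or
#'   `path_segment` objects.
#' @return Fraction(s); positive = the structure shrank.
#' @export
differential_shrinkage <- function(first, second) {
  z1 <- if (inherits(first, "path_segment")) z_extent(first) else first
  z2 <- if (inherits(second, "path_segment")) z_extent(second) else second
  if (any(z1 == 0)) stop("first z-extent is zero", call. = FALSE)
  (z1 - z2) / z1
}

#' Depth-stratified differential shrinkage table
#'
#' Replicates the depth-thirds measurement procedure: select unbranched
#' segments primarily oriented along the z-axis (chord within
#' `angle_threshold` degrees of vertical in the reference frame), assign
#' each to the upper, middle or lower third of the slice by its midpoint
#' depth in the *before* frame, and summarise the differential shrinkage
#' `(before - after) / before` of the z-extents per third.
#'
#' @param before Morphology or list of morphologies in the reference state.
#' @param after The same structure(s) in the second state (matched node ids).
#' @param slice A [slice_model()] defining the depth thirds.
#' @param n_per_third If given, exactly this many qualifying segments are
#'   used per third (the first ones in traversal order); an error reports
#'   the count found if a third has fewer.
#' @param angle_threshold Maximal chord angle from vertical, degrees
#'   (default 30).
#' @return Tibble with columns `third`, `n_segments`, `mean_shrinkage`,
#'   `sd_shrinkage` (fractions).
#' @export
depth_thirds_table <- function(before, after, slice, n_per_third = NULL,
                               angle_threshold = 30) {
  pairs <- match_tree_pairs(before, after)
  segs <- purrr::map_dfr(pairs, function(pr) {
    tb <- segments_table(pr$a)
    ta <- segments_table(pr$b, frame = pr$a)
    tibble::tibble(depth_mid = tb$depth_mid, angle_deg = tb$angle_deg,
                   z_before = tb$z_extent, z_after = ta$z_extent)
  })
  segs <- dplyr::filter(segs, .data$angle_deg <= angle_threshold,
                        .data$z_before > 0)
  T_nom <- slice$nominal_thickness
  segs$third <- cut(segs$depth_mid, breaks = T_nom * c(0, 1, 2, 3) / 3,
                    labels = c("top", "middle", "bottom"),
                    include.lowest = TRUE)
  if (!is.null(n_per_third)) {
    counts <- table(segs$third)
    short <- counts < n_per_third
    if (any(short)) {
      stop(sprintf("requested %d segments per third but found only %s",
                   n_per_third,
                   paste(sprintf("%d (%s)", counts[short],
                                 names(counts)[short]), collapse = ", ")),
           call. = FALSE)
    }
    segs <- dplyr::slice_head(dplyr::group_by(segs, .data$third),
                              n = n_per_third)
  }
  segs$shrinkage <- (segs$z_before - segs$z_after) / segs$z_before
  dplyr::summarise(dplyr::group_by(segs, third = .data$third, .drop = FALSE),
                   n_segments = dplyr::n(),
                   mean_shrinkage = mean(.data$shrinkage),
                   sd_shrinkage = stats::sd(.data$shrinkage),
                   .groups = "drop")
}

#' Landmark distance changes in the slice plane
#'
#' Compares all pairwise distances between labelled landmarks in two states
#' of the slice (e.g. recording chamber vs after embedding). The change of
#' each pair is normalized to its reference distance:
#' `(d_test - d_ref) / d_ref`, positive = dilation.
#'
#' @param ref,test Landmark tibbles with columns `label`, `x`, `y`; both
#'   must carry the same labels.
#' @return Tibble with `label_a`, `label_b`, `d_ref`, `d_test`,
#'   `rel_change` (fraction).
#' @examples
#' lm <- tibble::tibble(label = c("a", "b"), x = c(0, 10), y = 0)
#' lm2 <- dplyr::mutate(lm, x = x * 1.042, y = y * 1.042)
#' landmark_distance_change(lm, lm2)$rel_change # 0.042
#' @export
landmark_distance_change <- function(ref, test) {
  if (nrow(ref) < 2) stop("need at least 2 landmarks", call. = FALSE)
  if (!setequal(ref$label, test$label) || anyDuplicated(ref$label)) {
    stop("landmark labels do not match between the two sets", call. = FALSE)
  }
  test <- test[match(ref$label, test$label), ]
  pairs <- utils::combn(nrow(ref), 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  d_ref <- sqrt((ref$x[i] - ref$x[j])^2 + (ref$y[i] - ref$y[j])^2)
  d_test <- sqrt((test$x[i] - test$x[j])^2 + (test$y[i] - test$y[j])^2)
  tibble::tibble(
    label_a = ref$label[i], label_b = ref$label[j],
    d_ref = d_ref, d_test = d_test,
    rel_change = (d_test - d_ref) / d_ref
  )
}

# Unit chord direction of a segment projected onto a plane ("xy" or "yz"),
# plus the projected polyline length.
project_segment <- function(host, plane) {
  comp <- switch(plane, xy = c("x", "y"), yz = c("y", "z"),
                 stop("plane must be 'xy' or 'yz'", call. = FALSE))
  p1 <- c(host[[comp[1]]][1], host[[comp[2]]][1])
  p2 <- c(host[[comp[1]]][nrow(host)], host[[comp[2]]][nrow(host)])
  len <- sum(sqrt(diff(host[[comp[1]]])^2 + diff(host[[comp[2]]])^2))
  chord <- p2 - p1
  list(axis = if (sum(chord^2) > 0) chord / sqrt(sum(chord^2)) else c(NA, NA),
       length = len, comp = comp)
}

#' Projection-dependent spine density
#'
#' Emulates spine counting on an image stack projected onto a named plane:
#' a spine is visible iff the component of its offset vector perpendicular
#' to the projected shaft axis (after projecting the offset onto the same
#' plane) has magnitude at least `visibility_threshold`. The density is the
#' visible count divided by the projected shaft length in that plane.
#' Because axial compression shrinks only z-offsets, xy-projected density is
#' unaffected by pure z-deformation while yz-projected density can only
#' drop.
#'
#' @param spines Spine tibble with attachment coordinates `x, y, z` and
#'   offset components `ox, oy, oz` (micrometres).
#' @param host A `path_segment` carrying the shaft polyline.
#' @param plane `"xy"` or `"yz"`.
#' @param visibility_threshold Minimal resolvable perpendicular offset in
#'   micrometres (> 0).
#' @return Spines per micrometre of projected shaft.
#' @export
spine_density_projection <- function(spines, host,
                                     plane = c("xy", "yz"),
                                     visibility_threshold = 0.25) {
  plane <- match.arg(plane)
  if (visibility_threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  pr <- project_segment(host, plane)
  if (pr$length == 0) {
    stop("shaft has zero projected length in the ", plane, " plane",
         call. = FALSE)
  }
  if (nrow(spines) == 0) return(0)
  off <- switch(plane,
                xy = cbind(spines$ox, spines$oy),
                yz = cbind(spines$oy, spines$oz))
  along <- off %*% pr$axis
  perp <- off - along %*% t(pr$axis)
  visible <- sqrt(rowSums(perp^2)) >= visibility_threshold
  sum(visible) / pr$length
}

#' Resolution-limited 3-D spine density
#'
#' A stand-in model for 3-D spine counting in image stacks: a spine is
#' countable iff its offset is resolvable in at least one direction — the
#' lateral (xy) offset magnitude reaches `lateral_resolution` OR the axial
#' offset magnitude reaches `axial_resolution`. The density is the countable
#' count per micrometre of 3-D shaft length. Axial compression shrinks
#' z-offsets, so the countable number can only decrease under deformation.
#' The defaults are typical confocal resolution values, not measured ones.
#'
#' @inheritParams spine_density_projection
#' @param lateral_resolution In-plane resolution limit, micrometres
#'   (default 0.25).
#' @param axial_resolution Axial resolution limit, micrometres (default 0.7).
#' @return Spines per micrometre of shaft.
#' @export
spine_density_3d <- function(spines, host, lateral_resolution = 0.25,
                             axial_resolution = 0.7) {
  if (lateral_resolution <= 0 || axial_resolution <= 0) {
    stop("resolutions must be > 0", call. = FALSE)
  }
  len <- segment_length(host)
  if (len == 0) stop("shaft has zero length", call. = FALSE)
  if (nrow(spines) == 0) return(0)
  countable <- sqrt(spines$ox^2 + spines$oy^2) >= lateral_resolution |
    abs(spines$oz) >= axial_resolution
  sum(countable) / len
}
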