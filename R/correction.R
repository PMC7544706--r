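#' Linear z-correction factor
#'
#' The standard shrinkage compensation used for reconstructions from
#' embedded slices: the quotient of the nominal slice thickness and the
#' measured (shrunken) thickness. Applying the factor to all z-coordinates
#' restores the slice extent to its nominal thickness, and would restore all
#' geometry if (and only if) the compression were uniform in depth.
#'
#' @param nominal Nominal slice thickness in micrometres (> 0).
#' @param measured Measured thickness of the shrunken slice in micrometres;
#'   must be in `(0, nominal]`.
#' @return A `correction_factor` object with `$value = nominal / measured`.
#' @examples
#' correction_factor(300, 174)$value # 1.7241...
#' @export
correction_factor <- function(nominal, measured) {
  if (nominal <= 0) stop("nominal thickness must be > 0", call. = FALSE)
  if (measured <= 0) stop("measured thickness must be > 0", call. = FALSE)
  if (measured > nominal) {
    stop("measured thickness exceeds nominal; a z-correction factor < 1 is ",
         "not a shrinkage correction", call. = FALSE)
  }
  structure(list(value = nominal / measured,
                 nominal_thickness = nominal,
                 measured_thickness = measured),
            class = "correction_factor")
}

#' @export
print.correction_factor <- function(x, ...) {
  cat(sprintf("<correction_factor: %.6g = %.6g / %.6g um>\n",
              x$value, x$nominal_thickness, x$measured_thickness))
  invisible(x)
}

#' Apply the linear z-correction to a morphology
#'
#' Multiplies every z-coordinate by the correction factor, scaling about
#' z = 0 (the top imaged surface, consistent with the depth-map origin).
#' x, y, radii and topology are unchanged.
#'
#' @param m A morphology.
#' @param f A [correction_factor()] or a plain numeric factor >= 1.
#' @return The corrected morphology.
#' @export
apply_linear_z_correction <- function(m, f) {
  val <- if (inherits(f, "correction_factor")) f$value else f
  if (!is.numeric(val) || length(val) != 1 || val <= 0) {
    stop("correction factor must be a positive scalar", call. = FALSE)
  }
  m$z <- val * m$z
  m
}

#' Residual depth-dependent error after linear correction
#'
#' Quantifies how well (or poorly) the linear z-correction restores
#' geometry at different depths. For each unbranched segment primarily
#' oriented along the z-axis (chord within `angle_threshold` degrees of
#' vertical in the original frame), the relative z-extent error
#' `(corrected - original) / original` is computed and segments are grouped
#' into depth bins by their midpoint depth in the original frame. Positive
#' values mean overcorrection. Under a surface-weighted (non-uniform)
#' deformation the linear factor undercorrects near the slice surfaces and
#' overcorrects the middle.
#'
#' @param original Morphology (or list of morphologies) in the undeformed
#'   frame.
#' @param corrected The same structure(s) after deformation and linear
#'   correction; must share node ids and topology with `original`.
#' @param slice A [slice_model()]; bins partition `[0, nominal_thickness]`.
#' @param breaks Normalized depth breakpoints of the bins (default thirds).
#' @param labels Bin labels (default `"top"`, `"middle"`, `"bottom"` when
#'   three bins are requested).
#' @param angle_threshold Maximal chord angle from vertical, degrees.
#' @return A tibble with columns `bin`, `n_segments`, `mean_residual`,
#'   `sd_residual` (residuals as fractions; positive = overcorrection).
#' @export
residual_error_by_depth <- function(original, corrected, slice,
                                    breaks = c(0, 1, 2, 3) / 3,
                                    labels = NULL,
                                    angle_threshold = 30) {
  pairs <- match_tree_pairs(original, corrected)
  if (is.null(labels)) {
    labels <- if (length(breaks) == 4) c("top", "middle", "bottom")
              else paste0("bin", seq_len(length(breaks) - 1))
  }
  segs <- purrr::map_dfr(pairs, function(pr) {
    tab_before <- segments_table(pr$a)
    tab_after <- segments_table(pr$b, frame = pr$a)
    tibble::tibble(
      depth_mid = tab_before$depth_mid,
      angle_deg = tab_before$angle_deg,
      z_before = tab_before$z_extent,
      z_after = tab_after$z_extent
    )
  })
  segs <- dplyr::filter(segs, .data$angle_deg <= angle_threshold,
                        .data$z_before > 0)
  if (nrow(segs) == 0) {
    stop("no segments within ", angle_threshold, " degrees of vertical",
         call. = FALSE)
  }
  segs$bin <- cut(segs$depth_mid, breaks = breaks * slice$nominal_thickness,
                  labels = labels, include.lowest = TRUE)
  segs$residual <- (segs$z_after - segs$z_before) / segs$z_before
  dplyr::summarise(dplyr::group_by(segs, bin = .data$bin, .drop = FALSE),
                   n_segments = dplyr::n(),
                   mean_residual = mean(.data$residual),
                   sd_residual = stats::sd(.data$residual),
                   .groups = "drop")
}

# Pair up one morphology or a list of morphologies with its counterpart,
# checking that node ids and topology match.
match_tree_pairs <- function(a, b) {
  alist <- if (inherits(a, "morphology")) list(a) else a
  blist <- if (inherits(b, "morphology")) list(b) else b
  if (length(alist) != length(blist)) {
    stop("the two collections have different numbers of trees", call. = FALSE)
  }
  purrr::map2(alist, blist, function(x, y) {
    if (!identical(x$id, y$id) || !identical(x$parent, y$parent)) {
      stop("matched trees must share node ids and topology", call. = FALSE)
    }
    list(a = x, b = y)
  })
}
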