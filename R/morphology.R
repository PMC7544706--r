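#' Neuronal morphologies as tibbles
#'
#' A `morphology` is a tibble with one row per reconstruction node and the
#' seven SWC columns: `id`, `type` (SWC structure code), `x`, `y`, `z`
#' (micrometres), `radius` (micrometres) and `parent` (`-1` for the root).
#' Header comment lines of the source file are kept in the `"swc_header"`
#' attribute. Rows are stored in topological order, so every parent row
#' precedes its children.
#'
#' The coordinate convention throughout the package is the slice frame:
#' `z = 0` at the top imaged surface, increasing downward into the slice.
#'
#' @param nodes A data frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`.
#' @param header Character vector of header comment lines (without the
#'   leading `#`).
#' @return A `morphology` tibble.
#' @examples
#' m <- as_morphology(data.frame(
#'   id = 1:3, type = 3, x = 0, y = 0, z = c(0, 5, 10),
#'   radius = 0.5, parent = c(-1, 1, 2)
#' ))
#' total_length(m)
#' @export
as_morphology <- function(nodes, header = character()) {
  required <- c("id", "type", "x", "y", "z", "radius", "parent")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0) {
    stop("morphology is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  nodes <- tibble::as_tibble(nodes)[required]
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  m <- new_morphology(nodes, header)
  validate_morphology(m)
  normalize_morphology(m)
}

new_morphology <- function(nodes, header = character()) {
  structure(nodes,
            swc_header = as.character(header),
            class = c("morphology", class(tibble::tibble())))
}

validate_morphology <- function(m) {
  if (nrow(m) == 0) stop("morphology has no nodes", call. = FALSE)
  if (anyDuplicated(m$id)) {
    dup <- unique(m$id[duplicated(m$id)])
    stop("duplicated node id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(m$radius < 0)) stop("negative radius", call. = FALSE)
  roots <- which(m$parent == -1L)
  if (length(roots) != 1L) {
    stop("morphology must have exactly one root (parent -1); found ",
         length(roots), call. = FALSE)
  }
  nonroot <- m$parent != -1L
  if (!all(m$parent[nonroot] %in% m$id)) {
    bad <- unique(m$parent[nonroot][!m$parent[nonroot] %in% m$id])
    stop("dangling parent id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  # acyclicity: a full topological ordering must exist
  if (is.null(topological_order(m))) stop("cycle detected in parent links", call. = FALSE)
  invisible(m)
}

# Returns row indices in an order where parents precede children,
# or NULL if no such order exists (cycle).
topological_order <- function(m) {
  n <- nrow(m)
  placed <- logical(n)
  placed_ids <- integer(0)
  order_idx <- integer(0)
  remaining <- seq_len(n)
  while (length(remaining) > 0) {
    ready <- remaining[m$parent[remaining] == -1L |
                         m$parent[remaining] %in% placed_ids]
    if (length(ready) == 0) return(NULL)
    order_idx <- c(order_idx, ready)
    placed_ids <- c(placed_ids, m$id[ready])
    remaining <- setdiff(remaining, ready)
  }
  order_idx
}

normalize_morphology <- function(m) {
  ord <- topological_order(m)
  new_morphology(tibble::as_tibble(m)[ord, ], attr(m, "swc_header"))
}

#' @export
print.morphology <- function(x, ...) {
  cat(sprintf("<morphology: %d nodes, total length %.2f um, z range [%.2f, %.2f] um>\n",
              nrow(x), total_length(x), min(x$z), max(x$z)))
  NextMethod()
}

#' Read an SWC reconstruction file
#'
#' Parses the plain-text SWC dialect: whitespace-separated 7-column records
#' (`id type x y z radius parent`), `#` comment lines. Both Unix and Windows
#' line endings are accepted. Header comments are preserved in the
#' `"swc_header"` attribute of the result. Malformed records (wrong column
#' count, non-numeric fields), dangling parent references and cycles raise
#' errors naming the offending line.
#'
#' @param file Path to an SWC file, a connection, or a character vector of
#'   lines (for `text_lines = TRUE` style input detection: a vector of
#'   length > 1 or containing a newline is treated as file content).
#' @return A [as_morphology()] tibble in topological order.
#' @export
read_swc <- function(file) {
  if (is.character(file) &&
      (length(file) > 1 || grepl("\n", file[1]) || !file.exists(file[1]))) {
    looks_like_record <- grepl("^\\s*(#|-?[0-9])", file[1])
    if (length(file) == 1 && !grepl("\n", file[1]) &&
        !file.exists(file[1]) && !looks_like_record) {
      stop("file not found: ", file[1], call. = FALSE)
    }
    lines <- unlist(strsplit(file, "\n", fixed = TRUE))
  } else {
    lines <- readLines(file, warn = FALSE)
  }
  lines <- sub("\r$", "", lines)
  is_comment <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)
  header <- sub("^\\s*#\\s?", "", lines[is_comment])
  data_ln <- which(!is_comment & !is_blank)
  if (length(data_ln) == 0) stop("no data records in SWC input", call. = FALSE)
  fields <- strsplit(trimws(lines[data_ln]), "\\s+")
  ncol_bad <- lengths(fields) != 7L
  if (any(ncol_bad)) {
    stop("line ", data_ln[which(ncol_bad)[1]],
         ": expected 7 whitespace-separated fields, got ",
         lengths(fields)[which(ncol_bad)[1]], call. = FALSE)
  }
  mat <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE))
  bad_num <- which(rowSums(is.na(mat)) > 0)
  if (length(bad_num) > 0) {
    stop("line ", data_ln[bad_num[1]], ": non-numeric field", call. = FALSE)
  }
  nodes <- tibble::tibble(
    id = as.integer(mat[, 1]), type = as.integer(mat[, 2]),
    x = mat[, 3], y = mat[, 4], z = mat[, 5],
    radius = mat[, 6], parent = as.integer(mat[, 7])
  )
  # error messages with line numbers for structural problems
  nonroot <- nodes$parent != -1L
  dangling <- nonroot & !(nodes$parent %in% nodes$id)
  if (any(dangling)) {
    stop("line ", data_ln[which(dangling)[1]], ": parent id ",
         nodes$parent[which(dangling)[1]], " does not exist", call. = FALSE)
  }
  m <- new_morphology(nodes, header)
  if (is.null(topological_order(m))) {
    stop("cycle detected in parent links (first record at line ", data_ln[1], ")",
         call. = FALSE)
  }
  as_morphology(nodes, header)
}

#' Write a morphology to SWC text
#'
#' Emits nodes in topological order (every parent line precedes its
#' children), so the output is re-readable by [read_swc()] with an identical
#' node table. Coordinates and radii are written with 9 significant digits.
#'
#' @param m A morphology.
#' @param file Path or connection; if `NULL`, the lines are returned as a
#'   character vector.
#' @return Invisibly, the character vector of lines written.
#' @export
write_swc <- function(m, file = NULL) {
  m <- normalize_morphology(m)
  header <- attr(m, "swc_header")
  lines <- c(
    if (length(header) > 0) paste0("# ", header),
    sprintf("%d %d %s %s %s %s %d",
            m$id, m$type,
            sprintf("%.9g", m$x), sprintf("%.9g", m$y), sprintf("%.9g", m$z),
            sprintf("%.9g", m$radius), m$parent)
  )
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

edge_table <- function(m) {
  child <- which(m$parent != -1L)
  pidx <- match(m$parent[child], m$id)
  tibble::tibble(
    child = child, parent = pidx,
    dx = m$x[child] - m$x[pidx],
    dy = m$y[child] - m$y[pidx],
    dz = m$z[child] - m$z[pidx]
  )
}

#' Total dendritic path length
#'
#' Sum of Euclidean parent-child edge lengths over the whole tree, in
#' micrometres. A single-node morphology has length 0. Invariant under node
#' re-indexing and rigid rotation.
#'
#' @param m A morphology.
#' @return Length in micrometres (scalar).
#' @export
total_length <- function(m) {
  e <- edge_table(m)
  sum(sqrt(e$dx^2 + e$dy^2 + e$dz^2))
}

#' Flatten a morphology into the xy-plane
#'
#' Sets all z-coordinates to zero, reducing the reconstruction from 3-D to
#' 2-D for in-plane length measurements. Topology, x, y and radii are
#' unchanged; the operation is idempotent and never increases total length.
#'
#' @param m A morphology.
#' @return The flattened morphology.
#' @export
flatten_xy <- function(m) {
  m$z <- 0
  m
}

# Unbranched path decomposition: list of row-index vectors. Each path runs
# from the root or a branch point to the next branch point or tip; interior
# nodes have exactly one child.
morph_paths <- function(m) {
  n <- nrow(m)
  pidx <- match(m$parent, m$id)             # NA at root
  n_children <- tabulate(pidx[!is.na(pidx)], nbins = n)
  children <- split(which(!is.na(pidx)), factor(pidx[!is.na(pidx)], levels = seq_len(n)))
  is_start <- is.na(pidx) | n_children >= 2L
  paths <- list()
  for (s in which(is_start)) {
    for (ch in children[[s]]) {
      path <- c(s, ch)
      cur <- ch
      while (n_children[cur] == 1L) {
        cur <- children[[cur]][1]
        path <- c(path, cur)
      }
      paths[[length(paths) + 1L]] <- path
    }
  }
  if (length(paths) == 0 && n >= 1) paths <- list(seq_len(min(n, 1L)))
  paths
}

#' Gaussian spatial smoothing of reconstruction trajectories
#'
#' Reduces the raggedness of traced neurite trajectories with an iterated
#' 3-point kernel (weights 1/4, 1/2, 1/4, a binomial approximation of a
#' Gaussian) applied independently to each unbranched path. Branch points
#' and path endpoints are anchored, so topology-defining coordinates never
#' move. Tracing noise is typically far stronger along the optical axis, so
#' the z-coordinate takes its own (usually larger) iteration count; the
#' defaults are one pass in the xy-plane and 15 passes along z.
#'
#' @param m A morphology.
#' @param xy_iterations Number of smoothing passes applied to x and y
#'   (default 1). Zero is the identity.
#' @param z_iterations Number of passes applied to z (default 15).
#' @param window Kernel width; only the 3-point window is supported.
#' @return The smoothed morphology (topology and radii unchanged).
#' @export
gaussian_smooth <- function(m, xy_iterations = 1L, z_iterations = 15L, window = 3L) {
  if (window != 3L) stop("only the 3-point window is supported", call. = FALSE)
  if (xy_iterations < 0 || z_iterations < 0) {
    stop("iteration counts must be non-negative", call. = FALSE)
  }
  paths <- morph_paths(m)
  smooth_vec <- function(v, iters) {
    n <- length(v)
    if (n < 3 || iters == 0) return(v)
    for (i in seq_len(iters)) {
      v[2:(n - 1)] <- 0.25 * v[1:(n - 2)] + 0.5 * v[2:(n - 1)] + 0.25 * v[3:n]
    }
    v
  }
  for (p in paths) {
    m$x[p] <- smooth_vec(m$x[p], xy_iterations)
    m$y[p] <- smooth_vec(m$y[p], xy_iterations)
    m$z[p] <- smooth_vec(m$z[p], z_iterations)
  }
  m
}

#' Extract an unbranched dendritic segment
#'
#' Returns the nodes along the unbranched path connecting two nodes, in path
#' order, as a `path_segment` tibble. Errors if the two nodes are not joined
#' by a single unbranched stretch (i.e. the path crosses a branch point).
#'
#' @param m A morphology.
#' @param from,to Node ids of the segment endpoints.
#' @return A `path_segment`: the node rows in path order.
#' @seealso [z_extent()], [xy_length()]
#' @export
extract_segment <- function(m, from, to) {
  paths <- morph_paths(m)
  for (p in paths) {
    ids <- m$id[p]
    i <- match(from, ids)
    j <- match(to, ids)
    if (!is.na(i) && !is.na(j)) {
      rng <- if (i <= j) p[i:j] else p[j:i]
      return(as_path_segment(tibble::as_tibble(m)[rng, ]))
    }
  }
  stop("nodes ", from, " and ", to,
       " are not connected by an unbranched path", call. = FALSE)
}

#' Path segments
#'
#' A `path_segment` is an ordered tibble of nodes along one unbranched
#' dendritic stretch, with at least the coordinate columns `x`, `y`, `z`.
#' Row order is traversal order along the path.
#'
#' @param df A data frame of ordered nodes with columns `x`, `y`, `z`.
#' @return A `path_segment` tibble.
#' @export
as_path_segment <- function(df) {
  if (!all(c("x", "y", "z") %in% names(df))) {
    stop("path segment needs x, y, z columns", call. = FALSE)
  }
  structure(tibble::as_tibble(df),
            class = c("path_segment", class(tibble::tibble())))
}

#' Segment extent measures
#'
#' `z_extent()` is the z-range `max(z) - min(z)` of the segment, the quantity
#' compared across embedding states in depth-stratified shrinkage analysis.
#' `xy_length()` is the summed in-plane projection of the segment's edges;
#' `segment_length()` the full 3-D polyline length.
#'
#' @param seg A `path_segment` (ordered node tibble with x, y, z).
#' @return Micrometres (scalar).
#' @export
z_extent <- function(seg) max(seg$z) - min(seg$z)

#' @rdname z_extent
#' @export
xy_length <- function(seg) {
  n <- nrow(seg)
  if (n < 2) return(0)
  sum(sqrt(diff(seg$x)^2 + diff(seg$y)^2))
}

#' @rdname z_extent
#' @export
segment_length <- function(seg) {
  n <- nrow(seg)
  if (n < 2) return(0)
  sum(sqrt(diff(seg$x)^2 + diff(seg$y)^2 + diff(seg$z)^2))
}

# Angle (degrees) between the segment chord and the z-axis; 0 = vertical.
chord_angle_z <- function(seg) {
  v <- c(seg$x[nrow(seg)] - seg$x[1],
         seg$y[nrow(seg)] - seg$y[1],
         seg$z[nrow(seg)] - seg$z[1])
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(90)
  acos(min(1, abs(v[3]) / nv)) * 180 / pi
}

# One row per unbranched path of m: extents and descriptors used by the
# depth-stratified procedures. Depths/angles are taken from `frame`
# (defaults to m itself), which must share node ids and topology.
segments_table <- function(m, frame = m) {
  stopifnot(identical(m$id, frame$id), identical(m$parent, frame$parent))
  paths <- morph_paths(m)
  purrr::map_dfr(seq_along(paths), function(k) {
    p <- paths[[k]]
    seg <- tibble::as_tibble(m)[p, ]
    ref <- tibble::as_tibble(frame)[p, ]
    tibble::tibble(
      path_id = k,
      n_nodes = length(p),
      depth_mid = (min(ref$z) + max(ref$z)) / 2,
      angle_deg = chord_angle_z(ref),
      z_extent = max(seg$z) - min(seg$z),
      xy_length = xy_length(seg)
    )
  })
}
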