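#' Configuration for the synthetic morphology generator
#'
#' Bundles every parameter of the synthetic inputs: slice-confined branching
#' morphologies with controllable orientation anisotropy, spines with 3-D
#' offsets around dendritic shafts, planar landmark sets and vertical test
#' segments. Identical configuration and seed always produce identical
#' output.
#'
#' Defaults are chosen to emulate the study conditions: a 300 um slice, six
#' neurons per replication, isotropic dendritic orientation, a 3-D spine
#' density of 1.25 per um (the reference-state value) with ~1 um spine
#' offsets, and 8 planar landmarks.
#'
#' @param seed Integer random seed.
#' @param thickness Slice nominal thickness, micrometres (> 0).
#' @param n_neurons Number of neurons per replication run.
#' @param n_nodes Nodes per generated tree (>= 2).
#' @param step_length,step_sd Mean and SD of the inter-node step, um.
#' @param branch_prob Per-step probability that a growing tip bifurcates.
#' @param orientation_bias Fraction in `[0, 1]`: 0 = isotropic growth
#'   directions, 1 = strictly vertical neurites.
#' @param spine_density Spines per micrometre of dendrite (Poisson mean).
#' @param spine_offset_mean,spine_offset_sd Spine offset magnitude
#'   distribution (normal, truncated at 0.05 um), with isotropic direction.
#' @param n_landmarks Number of labelled planar landmarks (>= 2).
#' @param xy_extent Lateral extent of the slice region used for landmark
#'   and segment placement, micrometres.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             thickness = 300,
                             n_neurons = 6L,
                             n_nodes = 400L,
                             step_length = 6,
                             step_sd = 1.5,
                             branch_prob = 0.06,
                             orientation_bias = 0,
                             spine_density = 1.25,
                             spine_offset_mean = 1.0,
                             spine_offset_sd = 0.3,
                             n_landmarks = 8L,
                             xy_extent = 1000) {
  cfg <- list(seed = as.integer(seed), thickness = thickness,
              n_neurons = as.integer(n_neurons), n_nodes = as.integer(n_nodes),
              step_length = step_length, step_sd = step_sd,
              branch_prob = branch_prob, orientation_bias = orientation_bias,
              spine_density = spine_density,
              spine_offset_mean = spine_offset_mean,
              spine_offset_sd = spine_offset_sd,
              n_landmarks = as.integer(n_landmarks), xy_extent = xy_extent)
  if (cfg$thickness <= 0) stop("thickness must be > 0", call. = FALSE)
  if (cfg$n_neurons < 0 || cfg$n_nodes < 2 || cfg$n_landmarks < 0) {
    stop("counts must be non-negative (n_nodes >= 2)", call. = FALSE)
  }
  if (cfg$orientation_bias < 0 || cfg$orientation_bias > 1) {
    stop("orientation_bias must be in [0, 1]", call. = FALSE)
  }
  if (cfg$spine_density < 0) stop("spine_density must be >= 0", call. = FALSE)
  if (cfg$step_length <= 0 || cfg$step_length >= cfg$thickness) {
    stop("step_length must be in (0, thickness)", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Derive a sub-seed per generator function and index; keeps every generator
# independently reproducible under one top-level seed.
seed_for <- function(cfg, what, index = 1L) {
  off <- c(neuron = 0L, spines = 50000L, segments = 100000L,
           landmarks = 150000L, hosts = 200000L)[[what]]
  as.integer(cfg$seed + off + 101L * as.integer(index))
}

unit_vector_iso <- function(n = 1) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Generate a synthetic slice-confined neuron
#'
#' Grows a random branching tree by a stochastic walk: tips extend by
#' normally distributed steps and bifurcate with a fixed per-step
#' probability, until the requested node count is reached. Growth
#' directions blend an isotropic random unit vector with the vertical axis
#' according to `orientation_bias` (0 = isotropic, 1 = strictly vertical;
#' at 1 each tip keeps a persistent up/down heading). All nodes stay
#' strictly inside the slice volume `(0, thickness)` — steps that would
#' leave it are reflected in z — and the soma is placed in the upper half
#' of the slice, mirroring how slices are mounted with the recorded somata
#' nearer the top surface. This is a geometric stand-in, not a biophysical
#' growth model: only the orientation and length statistics matter for
#' deformation analysis.
#'
#' @param cfg A [generator_config()].
#' @param index Neuron index (decorrelates neurons within one config).
#' @return A [as_morphology()] tibble, deterministic per (config, index).
#' @export
gen_neuron <- function(cfg, index = 1L) {
  withr::with_seed(seed_for(cfg, "neuron", index), {
    T_nom <- cfg$thickness
    margin <- min(1, T_nom / 100)
    beta <- cfg$orientation_bias
    n_target <- cfg$n_nodes
    x <- y <- z <- radius <- numeric(n_target)
    parent <- integer(n_target)
    z[1] <- stats::runif(1, 0.15 * T_nom, 0.5 * T_nom)  # soma, upper half
    x[1] <- 0; y[1] <- 0; radius[1] <- 8; parent[1] <- -1L
    n <- 1L
    tips <- 1L
    tip_sign <- c(sample(c(-1, 1), 1))
    while (n < n_target && length(tips) > 0) {
      new_tips <- integer(0)
      new_signs <- numeric(0)
      for (k in seq_along(tips)) {
        if (n >= n_target) break
        tip <- tips[k]
        n_child <- if (stats::runif(1) < cfg$branch_prob) 2L else 1L
        placed_children <- integer(0)
        for (cc in seq_len(n_child)) {
          if (n >= n_target) break
          step <- max(0.5, stats::rnorm(1, cfg$step_length, cfg$step_sd))
          sgn <- if (cc == 1L) tip_sign[k] else -tip_sign[k]
          placed <- FALSE
          for (try in 1:20) {
            u <- unit_vector_iso(1)[1, ]
            dir <- (1 - beta) * u + beta * c(0, 0, sgn)
            dir <- dir / sqrt(sum(dir^2))
            zn <- z[tip] + step * dir[3]
            if (zn <= margin || zn >= T_nom - margin) {
              # reflect the vertical component back into the slice
              dir[3] <- -dir[3]
              sgn <- -sgn
              zn <- z[tip] + step * dir[3]
            }
            if (zn > margin && zn < T_nom - margin) { placed <- TRUE; break }
          }
          if (!placed) next
          n <- n + 1L
          x[n] <- x[tip] + step * dir[1]
          y[n] <- y[tip] + step * dir[2]
          z[n] <- zn
          radius[n] <- 0.5
          parent[n] <- tip
          placed_children <- c(placed_children, n)
          new_tips <- c(new_tips, n)
          new_signs <- c(new_signs, sgn)
        }
      }
      if (length(new_tips) == 0) break
      tips <- new_tips
      tip_sign <- new_signs
    }
    nodes <- tibble::tibble(
      id = seq_len(n), type = c(1L, rep(3L, n - 1L)),
      x = x[1:n], y = y[1:n], z = z[1:n],
      radius = radius[1:n], parent = parent[1:n]
    )
    as_morphology(nodes, header = sprintf(
      "synthetic neuron (seed %d, index %d)", cfg$seed, index))
  })
}

#' Generate spines along a morphology
#'
#' Draws a Poisson number of spines with mean `spine_density x total
#' dendritic length`, attaches them at uniformly random arc-length positions
#' along the tree's edges, and gives each an isotropic 3-D offset vector
#' with normally distributed magnitude (truncated at 0.05 um). Columns:
#' `spine_id`, attachment `x, y, z`, offset `ox, oy, oz`.
#'
#' @param cfg A [generator_config()].
#' @param host A morphology (or `path_segment`-like node tibble in tree
#'   form) carrying the dendritic shafts.
#' @param index Index to decorrelate multiple spine sets under one seed.
#' @return A spine tibble (possibly empty).
#' @export
gen_spines <- function(cfg, host, index = 1L) {
  empty <- tibble::tibble(spine_id = integer(), x = numeric(), y = numeric(),
                          z = numeric(), ox = numeric(), oy = numeric(),
                          oz = numeric())
  e <- edge_table(host)
  elen <- sqrt(e$dx^2 + e$dy^2 + e$dz^2)
  L <- sum(elen)
  if (L == 0 || cfg$spine_density == 0) return(empty)
  withr::with_seed(seed_for(cfg, "spines", index), {
    n <- stats::rpois(1, cfg$spine_density * L)
    if (n == 0) {
      empty
    } else {
      pos <- sort(stats::runif(n, 0, L))
      cum <- cumsum(elen)
      edge_idx <- findInterval(pos, cum, left.open = TRUE) + 1L
      t_along <- (pos - c(0, cum)[edge_idx]) / elen[edge_idx]
      pi_ <- e$parent[edge_idx]; ci <- e$child[edge_idx]
      ax <- host$x[pi_] + t_along * (host$x[ci] - host$x[pi_])
      ay <- host$y[pi_] + t_along * (host$y[ci] - host$y[pi_])
      az <- host$z[pi_] + t_along * (host$z[ci] - host$z[pi_])
      dirs <- unit_vector_iso(n)
      mag <- pmax(0.05, stats::rnorm(n, cfg$spine_offset_mean, cfg$spine_offset_sd))
      tibble::tibble(spine_id = seq_len(n), x = ax, y = ay, z = az,
                     ox = mag * dirs[, 1], oy = mag * dirs[, 2],
                     oz = mag * dirs[, 3])
    }
  })
}

#' Generate vertical test segments stratified by depth third
#'
#' Produces `n_per_third` purely vertical two-node segments fully contained
#' in each depth third of the slice, at random lateral positions — the
#' in-silico analogue of sampling z-oriented dendritic stretches at three
#' depths. Each segment is its own small morphology.
#'
#' @param cfg A [generator_config()].
#' @param n_per_third Segments per third (default 15, i.e. 45 in total).
#' @param segment_length Segment z-extent in micrometres; must be smaller
#'   than a third of the slice thickness.
#' @return A tibble with columns `segment_id`, `third`, `z_mid` and a
#'   list-column `tree` of morphologies.
#' @export
gen_vertical_segments <- function(cfg, n_per_third = 15L, segment_length = 30) {
  T_nom <- cfg$thickness
  if (segment_length >= T_nom / 3) {
    stop("segment_length must be below thickness/3 = ", T_nom / 3, call. = FALSE)
  }
  withr::with_seed(seed_for(cfg, "segments", 1L), {
    thirds <- c("top", "middle", "bottom")
    out <- purrr::map_dfr(1:3, function(k) {
      lo <- (k - 1) * T_nom / 3
      hi <- k * T_nom / 3
      pad <- segment_length / 2 + min(0.5, T_nom / 600)
      z_mid <- stats::runif(n_per_third, lo + pad, hi - pad)
      xs <- stats::runif(n_per_third, -cfg$xy_extent / 2, cfg$xy_extent / 2)
      ys <- stats::runif(n_per_third, -cfg$xy_extent / 2, cfg$xy_extent / 2)
      tibble::tibble(
        third = thirds[k], z_mid = z_mid,
        tree = purrr::pmap(list(xs, ys, z_mid), function(xx, yy, zm) {
          as_morphology(tibble::tibble(
            id = 1:2, type = 3L, x = xx, y = yy,
            z = c(zm - segment_length / 2, zm + segment_length / 2),
            radius = 0.5, parent = c(-1L, 1L)
          ))
        })
      )
    })
    out$segment_id <- seq_len(nrow(out))
    out[c("segment_id", "third", "z_mid", "tree")]
  })
}

#' Generate a labelled planar landmark set
#'
#' Uniformly random labelled points in the lateral slice extent, for
#' landmark-distance comparisons across embedding states.
#'
#' @param cfg A [generator_config()]; needs `n_landmarks >= 2`.
#' @return A tibble with columns `label`, `x`, `y` (micrometres).
#' @export
gen_landmarks <- function(cfg) {
  if (cfg$n_landmarks < 2) stop("need at least 2 landmarks", call. = FALSE)
  withr::with_seed(seed_for(cfg, "landmarks", 1L), {
    tibble::tibble(
      label = sprintf("L%02d", seq_len(cfg$n_landmarks)),
      x = stats::runif(cfg$n_landmarks, -cfg$xy_extent / 2, cfg$xy_extent / 2),
      y = stats::runif(cfg$n_landmarks, -cfg$xy_extent / 2, cfg$xy_extent / 2)
    )
  })
}

# Horizontal multi-node shaft at a given depth; host for spine-density
# comparisons (kept in-plane so shaft length is unaffected by z-compression,
# as for the image-stack segments used in spine counting). Oriented near the
# y-axis so both the xy- and the yz-projection of the shaft are
# well-conditioned, as for segments selected for side-view counting.
gen_horizontal_shaft <- function(cfg, index = 1L, length_um = 40, n_nodes = 9L) {
  withr::with_seed(seed_for(cfg, "hosts", index), {
    T_nom <- cfg$thickness
    depth <- stats::runif(1, 0.1 * T_nom, 0.9 * T_nom)
    x0 <- stats::runif(1, -cfg$xy_extent / 2, cfg$xy_extent / 2)
    y0 <- stats::runif(1, -cfg$xy_extent / 2, cfg$xy_extent / 2)
    theta <- pi / 2 + stats::runif(1, -pi / 12, pi / 12)
    s <- seq(0, length_um, length.out = n_nodes)
    as_morphology(tibble::tibble(
      id = seq_len(n_nodes), type = 3L,
      x = x0 + s * cos(theta), y = y0 + s * sin(theta), z = depth,
      radius = 0.5,
      parent = c(-1L, seq_len(n_nodes - 1L))
    ))
  })
}
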