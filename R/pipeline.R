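#' Exact Wilcoxon signed-rank test for small paired samples
#'
#' Computes the two-sided exact p-value of the Wilcoxon signed-rank test by
#' enumerating the distribution of the positive-rank sum over all `2^n`
#' equally likely sign assignments (realised as an exact convolution, which
#' is identical to full enumeration). Ties among the absolute differences
#' are handled with mid-ranks; zero differences are dropped (with their
#' count reported). The two-sided p-value is
#' `min(1, 2 * min(P(V <= v), P(V >= v)))`. For six concordant pairs this
#' yields 2/64 = 0.03125 and for eight concordant pairs 2/256 = 0.0078125.
#'
#' @param x First measurement vector, or the paired differences if `y` is
#'   `NULL`.
#' @param y Optional second measurement vector; differences are `x - y`.
#' @return An `exact_wilcoxon` object: `statistic` (positive-rank sum V),
#'   `p_value`, `n` (non-zero pairs), `n_zero`, `flag` (`"ok"` or
#'   `"all_zero"`). Supports [generics::tidy()].
#' @examples
#' wilcoxon_signed_rank_exact(rep(1, 6))$p_value # 0.03125
#' @export
wilcoxon_signed_rank_exact <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(list(statistic = 0, p_value = 1, n = 0L,
                          n_zero = n_zero, flag = "all_zero"),
                     class = "exact_wilcoxon"))
  }
  if (n > 25) {
    stop("exact enumeration is limited to n <= 25 non-zero pairs; ",
         "got ", n, " (use a large-sample approximation instead)",
         call. = FALSE)
  }
  r <- rank(abs(d))            # mid-ranks under ties: multiples of 0.5
  v_obs <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))
  # distribution of 2V over all 2^n sign patterns, by convolution
  maxs <- sum(r2)
  prob <- numeric(maxs + 1L)
  prob[1] <- 1
  for (rk in r2) {
    shifted <- c(numeric(rk), prob[seq_len(maxs + 1L - rk)])
    prob <- 0.5 * (prob + shifted)
  }
  v2 <- as.integer(round(2 * v_obs))
  p_le <- sum(prob[seq_len(v2 + 1L)])
  p_ge <- sum(prob[(v2 + 1L):(maxs + 1L)])
  p <- min(1, 2 * min(p_le, p_ge))
  structure(list(statistic = v_obs, p_value = p, n = n,
                 n_zero = n_zero, flag = "ok"),
            class = "exact_wilcoxon")
}

#' @export
print.exact_wilcoxon <- function(x, ...) {
  cat(sprintf("<exact Wilcoxon signed-rank: V = %.1f, n = %d, p = %.6g%s>\n",
              x$statistic, x$n, x$p_value,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' @rdname tidy.kinetics_fit
#' @exportS3Method generics::tidy
tidy.exact_wilcoxon <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n = x$n, n_zero = x$n_zero, flag = x$flag)
}

new_replication_report <- function(config_echo, lengths, tests, thirds,
                                   landmarks, spines, spine_tests, meta) {
  structure(list(config_echo = config_echo, lengths = lengths, tests = tests,
                 thirds = thirds, landmarks = landmarks, spines = spines,
                 spine_tests = spine_tests, meta = meta),
            class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf("<replication_report: %d neurons, seed %d, profile %s>\n",
              nrow(x$lengths), x$meta$seed, x$meta$profile_family))
  cat(sprintf("  deformed thickness %.1f um (nominal %.1f), correction factor %.4f\n",
              x$meta$deformed_thickness, x$meta$nominal_thickness,
              x$meta$correction_factor))
  cat("  paired tests:\n")
  for (i in seq_len(nrow(x$tests))) {
    cat(sprintf("    %-28s p = %.6g (n = %d)\n", x$tests$comparison[i],
                x$tests$p_value[i], x$tests$n[i]))
  }
  invisible(x)
}

#' Run the in-silico re-embedding replication
#'
#' End-to-end replication of the paired embedding comparison: synthetic
#' neurons are generated in the reference (minimally shrunken) state,
#' deformed by the given profile (the conventional re-embedding), then
#' linearly z-corrected with the factor derived from the deformed slice
#' thickness. Per neuron the report holds 3-D total dendritic length under
#' baseline / deformed / corrected conditions and in-plane (flattened) 2-D
#' length under baseline / deformed, plus normalized changes. Exact paired
#' Wilcoxon signed-rank tests compare each condition against baseline. The
#' report also carries the depth-thirds differential-shrinkage table (from
#' generated vertical segments), the landmark-distance table, and spine
#' densities (xy / yz projection and resolution-limited 3-D) on horizontal
#' shaft segments before and after deformation.
#'
#' @param cfg A [generator_config()].
#' @param profile A `deformation_profile` describing the re-embedding
#'   deformation.
#' @param slice A [slice_model()]; defaults to the config's thickness.
#' @param correct Apply the linear z-correction arm (default `TRUE`).
#' @param n_spine_segments Number of spine-bearing shaft segments
#'   (default 8).
#' @param n_per_third Vertical test segments per depth third (default 15).
#' @param out_dir If non-`NULL`, the report is also rendered to delimited
#'   text files there via [report_render()].
#' @return A `replication_report`.
#' @export
run_replication <- function(cfg, profile, slice = NULL, correct = TRUE,
                            n_spine_segments = 8L, n_per_third = 15L,
                            out_dir = NULL) {
  if (is.null(slice)) slice <- slice_model(cfg$thickness)
  T_nom <- slice$nominal_thickness
  T_def <- deformed_thickness(profile, slice)
  cf <- correction_factor(T_nom, T_def)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  # --- per-neuron length metrics -------------------------------------------
  lengths <- stage("neurons", {
    purrr::map_dfr(seq_len(cfg$n_neurons), function(i) {
      m0 <- gen_neuron(cfg, index = i)
      md <- apply_deformation(m0, profile, slice)
      mc <- if (correct) apply_linear_z_correction(md, cf) else md
      tibble::tibble(
        neuron = i,
        length_baseline = total_length(m0),
        length_deformed = total_length(md),
        length_corrected = total_length(mc),
        length2d_baseline = total_length(flatten_xy(m0)),
        length2d_deformed = total_length(flatten_xy(md))
      )
    })
  })
  if (nrow(lengths) > 0) {
    lengths <- dplyr::mutate(
      lengths,
      change_deformed_pct = dimension_change_percent(.data$length_deformed,
                                                     .data$length_baseline),
      change_corrected_pct = dimension_change_percent(.data$length_corrected,
                                                      .data$length_baseline),
      change2d_deformed_pct = dimension_change_percent(.data$length2d_deformed,
                                                       .data$length2d_baseline)
    )
  }

  tests <- stage("tests", {
    if (nrow(lengths) == 0) {
      tibble::tibble(comparison = character(), statistic = numeric(),
                     p_value = numeric(), n = integer())
    } else {
      cmp <- list(
        deformed_vs_baseline_3d =
          wilcoxon_signed_rank_exact(lengths$length_deformed,
                                     lengths$length_baseline),
        corrected_vs_baseline_3d =
          wilcoxon_signed_rank_exact(lengths$length_corrected,
                                     lengths$length_baseline),
        deformed_vs_baseline_2d =
          wilcoxon_signed_rank_exact(lengths$length2d_deformed,
                                     lengths$length2d_baseline)
      )
      purrr::imap_dfr(cmp, function(w, nm) {
        tibble::tibble(comparison = nm, statistic = w$statistic,
                       p_value = w$p_value, n = w$n)
      })
    }
  })

  # --- depth-thirds differential shrinkage ---------------------------------
  thirds <- stage("depth_thirds", {
    segs <- gen_vertical_segments(cfg, n_per_third = n_per_third)
    deformed_trees <- purrr::map(segs$tree, apply_deformation, p = profile,
                                 slice = slice)
    depth_thirds_table(segs$tree, deformed_trees, slice,
                       n_per_third = n_per_third)
  })

  # --- landmark distances ---------------------------------------------------
  landmarks <- stage("landmarks", {
    ref <- gen_landmarks(cfg)
    g <- profile$xy_dilation
    test <- dplyr::mutate(ref, x = g * .data$x, y = g * .data$y)
    landmark_distance_change(ref, test)
  })

  # --- spine densities -------------------------------------------------------
  spine_parts <- stage("spines", {
    rows <- purrr::map_dfr(seq_len(n_spine_segments), function(i) {
      host0 <- gen_horizontal_shaft(cfg, index = i)
      sp0 <- gen_spines(cfg, host0, index = i)
      center <- c(mean(host0$x), mean(host0$y))
      hostd <- apply_deformation(host0, profile, slice, center = center)
      spd <- apply_deformation_spines(sp0, profile, slice, center = center)
      seg0 <- as_path_segment(host0)
      segd <- as_path_segment(hostd)
      tibble::tibble(
        segment = i, n_spines = nrow(sp0),
        density_xy_baseline = spine_density_projection(sp0, seg0, "xy"),
        density_xy_deformed = spine_density_projection(spd, segd, "xy"),
        density_yz_baseline = spine_density_projection(sp0, seg0, "yz"),
        density_yz_deformed = spine_density_projection(spd, segd, "yz"),
        density_3d_baseline = spine_density_3d(sp0, seg0),
        density_3d_deformed = spine_density_3d(spd, segd)
      )
    })
    w3 <- wilcoxon_signed_rank_exact(rows$density_3d_deformed,
                                     rows$density_3d_baseline)
    wyz <- wilcoxon_signed_rank_exact(rows$density_yz_deformed,
                                      rows$density_yz_baseline)
    list(rows = rows, tests = tibble::tibble(
      comparison = c("spine_3d_deformed_vs_baseline",
                     "spine_yz_deformed_vs_baseline"),
      statistic = c(w3$statistic, wyz$statistic),
      p_value = c(w3$p_value, wyz$p_value),
      n = c(w3$n, wyz$n)
    ))
  })

  config_echo <- tibble::tibble(
    key = c(names(cfg), "profile_family", "xy_dilation", "correct"),
    value = c(vapply(cfg, function(v) format(v, digits = 15), character(1)),
              profile$family, format(profile$xy_dilation, digits = 15),
              as.character(correct))
  )

  report <- new_replication_report(
    config_echo = config_echo,
    lengths = lengths, tests = tests, thirds = thirds,
    landmarks = landmarks,
    spines = spine_parts$rows, spine_tests = spine_parts$tests,
    meta = list(seed = cfg$seed, profile_family = profile$family,
                nominal_thickness = T_nom, deformed_thickness = T_def,
                correction_factor = cf$value)
  )
  if (!is.null(out_dir)) report_render(report, out_dir)
  report
}

#' Render a replication report to delimited text
#'
#' Writes each report table as a TSV file plus a config echo (`key: value`
#' lines) and a run log containing the seed and the MD5 of the config echo.
#' Serialization is deterministic: rendering the same report twice yields
#' byte-identical files.
#'
#' @param report A `replication_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
report_render <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(lengths = report$lengths, tests = report$tests,
                 depth_thirds = report$thirds, landmarks = report$landmarks,
                 spine_density = report$spines,
                 spine_tests = report$spine_tests)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(tables[[nm]], f)
    files <- c(files, f)
  }
  cfg_file <- file.path(dir, "config.txt")
  writeLines(sprintf("%s: %s", report$config_echo$key,
                     report$config_echo$value), cfg_file)
  log_file <- file.path(dir, "run_log.txt")
  writeLines(c(
    sprintf("seed: %d", report$meta$seed),
    sprintf("profile_family: %s", report$meta$profile_family),
    sprintf("nominal_thickness_um: %.6g", report$meta$nominal_thickness),
    sprintf("deformed_thickness_um: %.6g", report$meta$deformed_thickness),
    sprintf("correction_factor: %.10g", report$meta$correction_factor),
    sprintf("config_md5: %s", unname(tools::md5sum(cfg_file)))
  ), log_file)
  invisible(c(files, cfg_file, log_file))
}
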