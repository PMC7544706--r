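sl300 <- slice_model(300)

test_that("shrinkage percentage follows the nominal-thickness definition", {
  expect_equal(shrinkage_percent(300, 300), 0)
  expect_equal(shrinkage_percent(174, 300), 42)
  expect_equal(shrinkage_percent(151.8, 300), 49.4)
  expect_error(shrinkage_percent(310, 300), "dimension_change_percent")
  expect_error(shrinkage_percent(0, 300), "> 0")
  # the dilation-aware variant reports signed changes
  expect_equal(dimension_change_percent(312.6, 300), 4.2)
  expect_equal(dimension_change_percent(291.3, 300), -2.9)
})

test_that("differential shrinkage normalizes to the first measurement", {
  expect_equal(differential_shrinkage(20, 20), 0)
  expect_equal(differential_shrinkage(20, 10), 0.5)
  expect_error(differential_shrinkage(0, 10), "zero")
  seg1 <- as_path_segment(data.frame(x = 0, y = 0, z = c(0, 20)))
  seg2 <- as_path_segment(data.frame(x = 0, y = 0, z = c(0, 10)))
  expect_equal(differential_shrinkage(seg1, seg2), 0.5)
})

test_that("vertical segments deformed by a known profile recover its values", {
  cfg <- generator_config(seed = 11)
  segs <- gen_vertical_segments(cfg, n_per_third = 12)
  p <- profile_thirds(0.451, 0.304, 0.443)
  deformed <- lapply(segs$tree, apply_deformation, p = p, slice = sl300)
  per_seg <- mapply(function(a, b) {
    differential_shrinkage(z_extent(as_path_segment(a)),
                           z_extent(as_path_segment(b)))
  }, segs$tree, deformed)
  expected <- c(top = 0.451, middle = 0.304, bottom = 0.443)[segs$third]
  expect_equal(unname(per_seg), unname(expected), tolerance = 1e-12)
})

test_that("depth-thirds table recovers per-third shrinkage exactly", {
  cfg <- generator_config(seed = 12)
  segs <- gen_vertical_segments(cfg, n_per_third = 15)
  # identity: all means zero
  tbl0 <- depth_thirds_table(segs$tree, segs$tree, sl300)
  expect_equal(tbl0$mean_shrinkage, rep(0, 3))
  # thirds profile: exact construction
  p <- profile_thirds(0.451, 0.304, 0.443)
  deformed <- lapply(segs$tree, apply_deformation, p = p, slice = sl300)
  tbl <- depth_thirds_table(segs$tree, deformed, sl300, n_per_third = 15)
  expect_equal(tbl$third, factor(c("top", "middle", "bottom"),
                                 levels = c("top", "middle", "bottom")))
  expect_equal(tbl$n_segments, rep(15L, 3))
  expect_equal(tbl$mean_shrinkage, c(0.451, 0.304, 0.443), tolerance = 1e-12)
  expect_equal(tbl$sd_shrinkage, rep(0, 3), tolerance = 1e-12)
  # uniform profile: all thirds equal
  deformed_u <- lapply(segs$tree, apply_deformation,
                       p = profile_uniform(0.42), slice = sl300)
  tbl_u <- depth_thirds_table(segs$tree, deformed_u, sl300)
  expect_equal(tbl_u$mean_shrinkage, rep(0.42, 3), tolerance = 1e-12)
  # asking for more segments than exist reports the count found
  expect_error(depth_thirds_table(segs$tree, deformed, sl300,
                                  n_per_third = 99),
               "found only")
})

test_that("landmark distance changes detect pure scalings", {
  lm <- tibble::tibble(label = sprintf("L%d", 1:5),
                       x = c(0, 10, -5, 3, 8), y = c(0, 0, 4, -7, 2))
  same <- landmark_distance_change(lm, lm)
  expect_equal(nrow(same), choose(5, 2))
  expect_equal(same$rel_change, rep(0, 10))
  up <- dplyr::mutate(lm, x = x * 1.042, y = y * 1.042)
  expect_equal(landmark_distance_change(lm, up)$rel_change,
               rep(0.042, 10), tolerance = 1e-12)
  down <- dplyr::mutate(lm, x = x * 0.971, y = y * 0.971)
  expect_equal(landmark_distance_change(lm, down)$rel_change,
               rep(-0.029, 10), tolerance = 1e-12)
  bad <- lm; bad$label[1] <- "other"
  expect_error(landmark_distance_change(lm, bad), "labels")
})

test_that("projected spine density counts only resolvable offsets", {
  shaft <- as_path_segment(data.frame(x = 0, y = seq(0, 10, length.out = 5),
                                      z = 100))
  # 10 spines with 1 um lateral (x) offsets: all visible in xy
  spines <- tibble::tibble(spine_id = 1:10, x = 0, y = seq(0.5, 9.5, 1),
                           z = 100, ox = 1, oy = 0, oz = 0)
  expect_equal(spine_density_projection(spines, shaft, "xy", 0.4), 1)
  # threshold above every offset: density 0
  expect_equal(spine_density_projection(spines, shaft, "xy", 1.5), 0)
  expect_error(spine_density_projection(spines, shaft, "xy", 0), "> 0")
  # vertical-offset spines compressed by 0.58: brute-force visibility oracle
  zsp <- tibble::tibble(spine_id = 1:7, x = 0, y = seq(1, 9, length.out = 7),
                        z = 100, ox = 0, oy = 0,
                        oz = c(0.3, 0.5, 0.7, 0.9, 1.1, -0.8, -0.45))
  th <- 0.4
  comp <- apply_deformation_spines(zsp, profile_uniform(0.42), sl300,
                                   center = c(0, 0))
  visible_brute <- sum(abs(comp$oz) >= th)   # shaft is along y in yz view
  expect_equal(spine_density_projection(comp, shaft, "yz", th),
               visible_brute / 10)
  # zero projected length errors
  xshaft <- as_path_segment(data.frame(x = seq(0, 10, 2.5), y = 0, z = 100))
  expect_error(spine_density_projection(spines, xshaft, "yz"), "zero projected")
})

test_that("xy-projected density is invariant under pure z-compression", {
  cfg <- generator_config(seed = 21)
  host <- sliceshrink:::gen_horizontal_shaft(cfg, index = 1)
  sp <- gen_spines(cfg, host, index = 1)
  center <- c(mean(host$x), mean(host$y))
  p <- profile_uniform(0.42)  # g = 1: pure z-deformation
  hostd <- apply_deformation(host, p, sl300, center = center)
  spd <- apply_deformation_spines(sp, p, sl300, center = center)
  seg0 <- as_path_segment(host); segd <- as_path_segment(hostd)
  expect_equal(spine_density_projection(spd, segd, "xy"),
               spine_density_projection(sp, seg0, "xy"), tolerance = 1e-12)
  # yz density is non-increasing under z-compression
  expect_lte(spine_density_projection(spd, segd, "yz"),
             spine_density_projection(sp, seg0, "yz") + 1e-12)
})

test_that("3-D spine counting follows the lateral-OR-axial resolution rule", {
  shaft <- as_path_segment(data.frame(x = 0, y = seq(0, 20, 5), z = 150))
  big <- tibble::tibble(spine_id = 1:10, x = 0, y = 1:10, z = 150,
                        ox = 1, oy = 0, oz = 1)
  expect_equal(spine_density_3d(big, shaft), 10 / 20)
  # z-only offsets between compressed and uncompressed threshold are lost
  zs <- tibble::tibble(spine_id = 1:6, x = 0, y = 1:6, z = 150,
                       ox = 0, oy = 0, oz = c(0.75, 0.8, 0.9, 1.0, 1.15, 1.3))
  expect_equal(spine_density_3d(zs, shaft), 6 / 20)
  comp <- apply_deformation_spines(zs, profile_uniform(0.42), sl300,
                                   center = c(0, 0))
  kept_brute <- sum(abs(zs$oz) * 0.58 >= 0.7)   # per-spine rule oracle
  expect_equal(spine_density_3d(comp, shaft), kept_brute / 20)
  expect_lt(spine_density_3d(comp, shaft), spine_density_3d(zs, shaft))
  # axial resolution -> 0 recovers count / length
  tiny <- spine_density_3d(zs, shaft, axial_resolution = 1e-12)
  expect_equal(tiny, nrow(zs) / 20)
  expect_error(spine_density_3d(zs, shaft, lateral_resolution = 0), "> 0")
})

test_that("kinetics fit recovers noiseless parameters and flags degeneracy", {
  tt <- c(0.5, 1, 2, 4, 8, 16, 40, 75)
  series <- tibble::tibble(day = tt,
                           shrinkage_percent = 50 * (1 - exp(-tt / 5)))
  fit <- summarize_kinetics(series)
  expect_equal(fit$s_inf, 50, tolerance = 1e-6)
  expect_equal(fit$tau, 5, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(tidy(fit)$estimate, c(fit$s_inf, fit$tau))
  expect_equal(glance(fit)$flag, "ok")

  const <- summarize_kinetics(tibble::tibble(day = c(1, 3, 9),
                                             shrinkage_percent = rep(30, 3)))
  expect_equal(const$s_inf, 30, tolerance = 1e-6)
  expect_false(const$converged)
  expect_equal(const$flag, "degenerate_tau")

  expect_error(summarize_kinetics(tibble::tibble(day = c(1, 2),
                                                 shrinkage_percent = c(1, 2))),
               "at least 3")
  expect_error(summarize_kinetics(tibble::tibble(day = c(2, 1, 3),
                                                 shrinkage_percent = 1:3)),
               "increasing")
})

test_that("fitted asymptotes order the packaged embedding methods", {
  kin <- load_kinetics()
  expect_equal(sort(unique(kin$method)), c("agar", "conventional", "metal"))
  fits <- lapply(split(kin, kin$method), summarize_kinetics)
  expect_lt(fits$metal$s_inf, fits$conventional$s_inf)
  expect_lt(fits$conventional$s_inf, fits$agar$s_inf)
})
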