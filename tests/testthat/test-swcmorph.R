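test_that("read_swc parses minimal and chain inputs", {
  m <- read_swc("1 1 0 0 0 1 -1")
  expect_s3_class(m, "morphology")
  expect_equal(nrow(m), 1)
  expect_equal(m$radius, 1)
  expect_equal(unname(unlist(m[1, c("x", "y", "z")])), c(0, 0, 0))

  chain <- read_swc(c("# a header", "1 1 0 0 0 1 -1", "2 3 0 0 5 1 1",
                      "3 3 0 0 10 1 2"))
  expect_equal(total_length(chain), 10)
  expect_equal(attr(chain, "swc_header"), "a header")
})

test_that("read_swc accepts Windows line endings", {
  m <- read_swc(c("1 1 0 0 0 1 -1\r", "2 3 3 4 12 1 1\r"))
  expect_equal(total_length(m), 13)
})

test_that("malformed SWC input raises errors naming the line", {
  expect_error(read_swc(c("1 1 0 0 0 1 -1", "2 3 0 0")), "line 2")
  expect_error(read_swc(c("1 1 0 0 zero 1 -1")), "line 1.*non-numeric")
  expect_error(read_swc(c("1 1 0 0 0 1 -1", "2 3 0 0 5 1 99")), "line 2.*99")
  expect_error(read_swc(c("1 1 0 0 0 1 2", "2 3 0 0 5 1 1")), "cycle")
})

test_that("write/read round trip is the identity on the node table", {
  m <- random_tree(50, seed = 7)
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, f)
  m2 <- read_swc(f)
  expect_equal(tibble::as_tibble(m2), tibble::as_tibble(m))
})

test_that("write_swc orders parents before children", {
  shuffled <- withr::with_seed(3, {
    m <- random_tree(30, seed = 11)
    tibble::as_tibble(m)[sample(nrow(m)), ]
  })
  lines <- write_swc(as_morphology(shuffled))
  recs <- do.call(rbind, lapply(strsplit(lines, " "), as.numeric))
  pos <- match(recs[, 7], recs[, 1])   # line index of each node's parent
  expect_true(all(is.na(pos) | pos < seq_along(lines)))
})

test_that("round trip preserves radii to at least 6 significant digits", {
  m <- random_tree(20, seed = 5)
  m$radius <- m$radius + pi * 1e-7   # irrational radii
  m2 <- read_swc(write_swc(m))
  expect_equal(m2$radius, m$radius, tolerance = 1e-7)
})

test_that("total_length matches brute-force per-edge accumulation", {
  expect_equal(total_length(read_swc(c("1 1 0 0 0 1 -1", "2 3 3 4 12 1 1"))), 13)
  expect_equal(total_length(read_swc("1 1 5 5 5 1 -1")), 0)
  m <- random_tree(101, seed = 13)   # 100 edges
  expect_equal(total_length(m), brute_total_length(m), tolerance = 1e-12)
})

test_that("total_length is invariant under rigid rotation and re-indexing", {
  m <- random_tree(60, seed = 17)
  R <- rotation_matrix(0.3, -1.1, 2.2)
  xyz <- as.matrix(tibble::as_tibble(m)[c("x", "y", "z")]) %*% t(R)
  mr <- m; mr$x <- xyz[, 1]; mr$y <- xyz[, 2]; mr$z <- xyz[, 3]
  expect_equal(total_length(mr), total_length(m), tolerance = 1e-9)

  reindexed <- tibble::as_tibble(m)
  perm <- withr::with_seed(1, sample(1000:2000, nrow(m)))
  reindexed$parent <- ifelse(reindexed$parent == -1L, -1L,
                             perm[match(reindexed$parent, reindexed$id)])
  reindexed$id <- perm
  expect_equal(total_length(as_morphology(reindexed)), total_length(m))
})

test_that("flatten_xy projects lengths onto the xy-plane and is idempotent", {
  expect_equal(total_length(flatten_xy(make_chain(c(0, 10)))), 0)
  diag_edge <- read_swc(c("1 1 0 0 0 1 -1", "2 3 3 4 12 1 1"))
  expect_equal(total_length(flatten_xy(diag_edge)), 5)

  m <- random_tree(80, seed = 23)
  flat <- flatten_xy(m)
  # per-edge projection oracle
  proj <- 0
  for (i in seq_len(nrow(m))) {
    p <- m$parent[i]
    if (p == -1) next
    j <- which(m$id == p)
    proj <- proj + sqrt((m$x[i] - m$x[j])^2 + (m$y[i] - m$y[j])^2)
  }
  expect_equal(total_length(flat), proj, tolerance = 1e-12)
  expect_lte(total_length(flat), total_length(m))
  expect_equal(tibble::as_tibble(flatten_xy(flat)), tibble::as_tibble(flat))
})

test_that("gaussian smoothing: fixed points, closed-form decay, convolution", {
  # collinear equally spaced path is a kernel fixed point
  col <- make_chain(seq(0, 50, by = 5))
  expect_equal(tibble::as_tibble(gaussian_smooth(col, 1, 25)),
               tibble::as_tibble(col))
  # interior of [0, 1, 0] decays as 0.5^k with anchored endpoints
  spike <- make_chain(c(0, 1, 0), x = c(0, 1, 2))
  sm <- gaussian_smooth(spike, xy_iterations = 0, z_iterations = 15)
  expect_equal(sm$z[2], 0.5^15, tolerance = 1e-12)
  expect_equal(sm$z[c(1, 3)], c(0, 0))
  # one iteration equals direct discrete convolution on interior nodes
  m <- withr::with_seed(31, make_chain(runif(12, 0, 40), x = cumsum(runif(12))))
  sm1 <- gaussian_smooth(m, xy_iterations = 0, z_iterations = 1)
  z <- m$z
  expected <- z
  expected[2:11] <- 0.25 * z[1:10] + 0.5 * z[2:11] + 0.25 * z[3:12]
  expect_equal(sm1$z, expected, tolerance = 1e-12)
  # zero iterations is the identity; negatives rejected
  expect_equal(tibble::as_tibble(gaussian_smooth(m, 0, 0)), tibble::as_tibble(m))
  expect_error(gaussian_smooth(m, -1, 0), "non-negative")
})

test_that("smoothing anchors branch points and shrinks noisy paths to chord", {
  # Y-shaped tree: node 2 is a branch point
  y_tree <- as_morphology(data.frame(
    id = 1:5, type = 3L,
    x = c(0, 0, 5, -1, -2), y = c(0, 1, 7, 2, 3), z = c(0, 10, 20, 18, 30),
    radius = 0.5, parent = c(-1L, 1L, 2L, 2L, 4L)
  ))
  sm <- gaussian_smooth(y_tree, 3, 10)
  anchored <- c(1, 2, 3, 5)   # root, branch point, two tips
  expect_equal(tibble::as_tibble(sm)[anchored, c("x", "y", "z")],
               tibble::as_tibble(y_tree)[anchored, c("x", "y", "z")])

  noisy <- withr::with_seed(41, make_chain(
    seq(0, 100, length.out = 21) + rnorm(21, 0, 3),
    x = seq(0, 30, length.out = 21) + rnorm(21, 0, 3)))
  chord <- sqrt(sum((tibble::as_tibble(noisy)[21, c("x", "y", "z")] -
                       tibble::as_tibble(noisy)[1, c("x", "y", "z")])^2))
  lens <- numeric(6)
  cur <- noisy
  for (k in 1:6) {
    lens[k] <- total_length(cur)
    cur <- gaussian_smooth(cur, xy_iterations = 1, z_iterations = 1)
  }
  expect_true(all(diff(lens) <= 1e-12))
  expect_gte(total_length(cur), chord - 1e-9)
})

test_that("extract_segment measures extents along unbranched paths", {
  vert <- make_chain(seq(10, 30, by = 5))
  seg <- extract_segment(vert, 1, 5)
  expect_equal(z_extent(seg), 20)
  expect_equal(xy_length(seg), 0)

  horiz <- as_morphology(data.frame(id = 1:3, type = 3L,
                                    x = c(0, 10, 20), y = 0, z = 50,
                                    radius = 0.5, parent = c(-1L, 1L, 2L)))
  seg2 <- extract_segment(horiz, 1, 3)
  expect_equal(z_extent(seg2), 0)
  expect_equal(xy_length(seg2), 20)

  # helical path: z-extent is the z-range, xy-length the summed projections
  t <- seq(0, 4 * pi, length.out = 40)
  helix <- make_chain(5 * t, x = 10 * cos(t), y = 10 * sin(t))
  seg3 <- extract_segment(helix, 1, 40)
  expect_equal(z_extent(seg3), 5 * (max(t) - min(t)), tolerance = 1e-12)
  expect_equal(xy_length(seg3),
               sum(sqrt(diff(10 * cos(t))^2 + diff(10 * sin(t))^2)),
               tolerance = 1e-12)

  y_tree <- as_morphology(data.frame(
    id = 1:5, type = 3L, x = 0, y = c(0, 0, 1, -1, -2),
    z = c(0, 10, 20, 20, 30), radius = 0.5,
    parent = c(-1L, 1L, 2L, 2L, 4L)
  ))
  expect_error(extract_segment(y_tree, 3, 5), "unbranched")
})

test_that("morphology invariants are enforced", {
  expect_error(as_morphology(data.frame(id = c(1, 1), type = 3, x = 0, y = 0,
                                        z = 0, radius = 1, parent = c(-1, 1))),
               "duplicated")
  expect_error(as_morphology(data.frame(id = 1:2, type = 3, x = 0, y = 0,
                                        z = 0, radius = 1, parent = c(-1, 5))),
               "dangling")
  expect_error(as_morphology(data.frame(id = 1:2, type = 3, x = 0, y = 0,
                                        z = 0, radius = 1, parent = c(-1, -1))),
               "exactly one root")
})
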