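# Fixture builders and independent oracles shared across the suite.

# Simple unbranched chain along z at the given depths.
make_chain <- function(z, x = 0, y = 0, radius = 0.5) {
  n <- length(z)
  as_morphology(data.frame(
    id = seq_len(n), type = 3L,
    x = rep_len(x, n), y = rep_len(y, n), z = z,
    radius = radius, parent = c(-1L, seq_len(n - 1L))
  ))
}

# Random tree with ~4-decimal coordinates (exactly representable at the
# 9 significant digits used by the SWC writer).
random_tree <- function(n, seed = 1, z_range = c(10, 290)) {
  withr::with_seed(seed, {
    parent <- c(-1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
    as_morphology(data.frame(
      id = seq_len(n), type = 3L,
      x = round(stats::runif(n, -100, 100), 4),
      y = round(stats::runif(n, -100, 100), 4),
      z = round(stats::runif(n, z_range[1], z_range[2]), 4),
      radius = round(stats::runif(n, 0.2, 2), 4),
      parent = parent
    ))
  })
}

# Brute-force per-edge accumulation of total length.
brute_total_length <- function(m) {
  s <- 0
  for (i in seq_len(nrow(m))) {
    p <- m$parent[i]
    if (p == -1) next
    j <- which(m$id == p)
    s <- s + sqrt((m$x[i] - m$x[j])^2 + (m$y[i] - m$y[j])^2 + (m$z[i] - m$z[j])^2)
  }
  s
}

# Brute-force exact two-sided Wilcoxon signed-rank p over all 2^n sign
# patterns (independent of the package's convolution implementation).
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p_le <- mean(vs <= v_obs + 1e-9)
  p_ge <- mean(vs >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

rotation_matrix <- function(a, b, c) {
  rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
  rz <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, byrow = TRUE)
  rx %*% ry %*% rz
}
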