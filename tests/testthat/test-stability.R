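test_that("spherical water counting equals a brute-force radius scan", {
  set.seed(81)
  nw <- 1500
  w <- matrix(runif(3 * nw, -70, 70), ncol = 3)
  pw <- particle_set(1:nw, "water", "solvent", w[, 1], w[, 2], w[, 3])
  sh <- shell_geometry(c(0, 0, 0), 50, delta = 5)
  expect_identical(count_interior_waters(pw, sh),
                   sum(sqrt(rowSums(w^2)) < 50))
  # all waters inside
  w2 <- w / 3
  pw2 <- particle_set(1:nw, "water", "solvent", w2[, 1], w2[, 2], w2[, 3])
  expect_identical(count_interior_waters(pw2, sh), as.integer(nw))
  # no waters
  pd <- particle_set(1, "pseudo", "shell", 0, 0, 0)
  expect_identical(count_interior_waters(pd, sh), 0L)
})

test_that("flood-fill volume of a closed 50 A sphere is within 5% of 4/3 pi R^3", {
  ps <- closed_shell_particles(10000, cavity_radius = 50)
  v <- interior_volume(ps, spacing = 1)
  expect_lt(abs(v - 4 / 3 * pi * 50^3) / (4 / 3 * pi * 50^3), 0.05)
})

test_that("volume converges under grid refinement and shrinks with atom radius", {
  ps <- closed_shell_particles(6000, cavity_radius = 30)
  v1 <- interior_volume(ps, spacing = 1)
  v05 <- interior_volume(ps, spacing = 0.5)
  expect_lt(abs(v05 - v1) / v1, 0.02)
  v_fat <- interior_volume(ps, spacing = 1, atom_radius = 4)
  expect_lte(v_fat, v1)
})

test_that("grid and spherical water counts agree for an ideal shell", {
  ps <- closed_shell_particles(10000, cavity_radius = 50)
  res <- interior_volume(ps, spacing = 1, return_grid = TRUE)
  set.seed(82)
  nw <- 4000
  w <- matrix(runif(3 * nw, -60, 60), ncol = 3)
  pw <- particle_set(1:nw, "water", "solvent", w[, 1], w[, 2], w[, 3])
  sh <- shell_geometry(c(0, 0, 0), 50, delta = 5)
  n_sph <- count_interior_waters(pw, sh)
  n_grid <- count_interior_waters(pw, res$grid)
  expect_lt(abs(n_grid - n_sph) / n_sph, 0.05)
})

test_that("degenerate shells are reported, volume still returned", {
  pd <- particle_set(1:20, "pseudo", "cargo",
                     x = runif(20), y = runif(20), z = runif(20),
                     complex_id = 1L)
  expect_warning(v <- interior_volume(pd), "no shell atoms")
  expect_identical(v, 0)
  # an open hemisphere leaks: fill reaches the center
  u <- fib_sphere(6000, 52.4)
  u <- u[u[, 3] > 0, ]
  ph <- particle_set(seq_len(nrow(u)), "pseudo", "shell",
                     u[, 1], u[, 2], u[, 3])
  expect_warning(interior_volume(ph, spacing = 1), "leaky")
})

test_that("ingress rate reproduces hand finite differences", {
  r0 <- ingress_rate(0:10, rep(100, 11))
  expect_equal(r0$rate, rep(0, 10))
  ramp <- ingress_rate(0:10, 100 + 10 * (0:10), window = 2)
  expect_equal(ramp$rate, rep(10, 9))
  expect_equal(ramp$percentage[11], 200)
  set.seed(83)
  t <- seq(0, 5, 0.5)
  c <- cumsum(rpois(length(t), 5))
  w <- 3
  r <- ingress_rate(t, c, window = w)
  i <- seq_len(length(t) - w)
  expect_equal(r$rate, (c[i + w] - c[i]) / (t[i + w] - t[i]))
  expect_error(ingress_rate(1, 5), ">= 2")
})

test_that("water replication adds the exact count and preserves originals", {
  set.seed(84)
  nw <- 1200
  d <- matrix(rnorm(3 * nw), ncol = 3)
  r <- 45 * runif(nw)^(1 / 3)
  d <- d / sqrt(rowSums(d^2)) * r
  pw <- particle_set(1:nw, "water", "solvent", d[, 1], d[, 2], d[, 3])
  sh <- shell_geometry(c(0, 0, 0), 50, delta = 5)
  n_int <- count_interior_waters(pw, sh)
  expect_identical(n_int, as.integer(nw))  # all generated inside
  out <- replicate_interior_waters(pw, sh, fraction = 0.20, seed = 7)
  expect_identical(attr(out, "n_added"), as.integer(floor(0.20 * nw)))
  expect_equal(out[seq_len(nw), ], pw, ignore_attr = TRUE)  # originals verbatim
  expect_false(anyDuplicated(out$particle_id) > 0)
  # every duplicate sits exactly `displacement` from some original water
  added <- out[-(seq_len(nw)), ]
  for (i in seq_len(min(20, nrow(added)))) {
    dmin <- min(sqrt((pw$x - added$x[i])^2 + (pw$y - added$y[i])^2 +
                       (pw$z - added$z[i])^2))
    expect_equal(dmin, 0.5, tolerance = 1e-6)
  }
  # determinism
  out2 <- replicate_interior_waters(pw, sh, fraction = 0.20, seed = 7)
  expect_identical(out, out2)
  expect_error(replicate_interior_waters(pw, sh, fraction = 0), "\\(0, 1]")
  expect_error(replicate_interior_waters(pw, sh, fraction = 1.5), "\\(0, 1]")
})

test_that("clash-free placement fails loudly when impossible", {
  # waters packed so densely that any 0.5 A displacement clashes at 2.0 A
  g <- as.matrix(expand.grid(seq(-2, 2, 1), seq(-2, 2, 1), seq(-2, 2, 1)))
  pw <- particle_set(seq_len(nrow(g)), "water", "solvent",
                     g[, 1], g[, 2], g[, 3])
  sh <- shell_geometry(c(0, 0, 0), 20, delta = 5)
  expect_error(replicate_interior_waters(pw, sh, fraction = 0.5, seed = 2,
                                         min_dist = 2.0), "clash")
})
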