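test_that("the contact kernel hits its landmark values", {
  at <- function(d) coordination_contacts(matrix(0, 1, 3),
                                          matrix(c(d, 0, 0), 1, 3))$value
  expect_equal(at(4), 0.5)                       # logistic midpoint
  expect_equal(at(3), 1 / (1 + exp(-5)), tolerance = 1e-12)
  expect_equal(at(3), 0.99331, tolerance = 1e-4)
  expect_equal(at(200), 0)                       # beyond cutoff: skipped
})

test_that("contact score is symmetric and strictly decreasing in distance", {
  set.seed(71)
  A <- matrix(runif(60, 0, 15), ncol = 3)
  B <- matrix(runif(60, 0, 15), ncol = 3)
  expect_equal(coordination_contacts(A, B)$value,
               coordination_contacts(B, A)$value, tolerance = 1e-12)
  ds <- seq(1, 10, 0.5)
  vals <- vapply(ds, function(d) {
    coordination_contacts(matrix(0, 1, 3), matrix(c(d, 0, 0), 1, 3))$value
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("grid-accelerated search equals brute force on random frames", {
  set.seed(72)
  for (i in 1:100) {
    A <- matrix(runif(3 * sample(5:40, 1), 0, 50), ncol = 3)
    B <- matrix(runif(3 * sample(5:40, 1), 0, 50), ncol = 3)
    expect_equal(coordination_contacts(A, B)$value,
                 coordination_contacts(A, B, method = "brute")$value,
                 tolerance = 1e-9)
  }
})

test_that("contact graph edges respect the C-alpha cutoff", {
  ps <- particle_set(1:4, "pseudo", "cargo",
                     x = c(0, 1, 9, 30), y = 0, z = 0,
                     complex_id = c(1, 1, 2, 3), is_calpha = TRUE)
  coords <- array(0, c(3, 4, 3))
  for (f in 1:3) coords[f, , 1] <- ps$x
  tr <- trajectory(1:3, coords, ps)
  g <- contact_graph(tr, cutoff = 10)
  # only complexes 1-2 touch (nearest Calpha 8 A); 3 is 21 A away
  expect_identical(nrow(g$edges), 1L)
  expect_equal(g$edges[1, c("a", "b")], data.frame(a = 1L, b = 2L))
  expect_equal(g$edges$weight, 1)
  expect_equal(g$edges$mean_min_dist, 8)
})

test_that("clustering cargo grows its contact network over time", {
  spc <- cargo_spec(n_complexes = 20, attraction_strength = 3,
                    n_frames = 90, seed = 73)
  tr <- gen_cargo_frames(spc)
  # snapshot graphs at the start, middle and end of the run
  edge_counts <- vapply(c(1, 45, 90), function(f) {
    sub <- trajectory(tr$times[f], tr$coords[f, , , drop = FALSE],
                      tr$particles)
    nrow(contact_graph(sub)$edges)
  }, numeric(1))
  expect_true(all(diff(edge_counts) >= 0))
  expect_gt(edge_counts[3], edge_counts[1])
})

test_that("contact-graph weights are invariant to relabeling within a complex", {
  spc <- cargo_spec(n_complexes = 8, n_frames = 20, seed = 74)
  tr <- gen_cargo_frames(spc)
  g1 <- contact_graph(tr)
  # permute particles within each complex
  ps <- tr$particles
  perm <- unlist(lapply(split(seq_len(nrow(ps)), ps$complex_id), sample))
  tr2 <- trajectory(tr$times, tr$coords[, perm, , drop = FALSE], ps[perm, ])
  g2 <- contact_graph(tr2)
  expect_equal(g1$edges, g2$edges)
})

test_that("nearest neighbors match hand geometry and a brute-force oracle", {
  # three point complexes on a line at 0, 10, 25
  ps <- particle_set(1:3, "pseudo", "cargo", x = c(0, 10, 25), y = 0, z = 0,
                     complex_id = 1:3, is_calpha = TRUE)
  nn <- nearest_neighbors(ps, k = 2)
  expect_equal(nn$distances[1, ], c(10, 25))
  expect_equal(nn$distances[2, ], c(10, 15))
  expect_equal(nn$distances[3, ], c(15, 25))
  expect_error(nearest_neighbors(ps, k = 3), "k < n")
  # random multi-atom complexes vs an O(n^2) loop oracle
  set.seed(75)
  n <- 8; m <- 4
  coords <- matrix(runif(3 * n * m, 0, 60), ncol = 3)
  psr <- particle_set(seq_len(n * m), "pseudo", "cargo",
                      coords[, 1], coords[, 2], coords[, 3],
                      complex_id = rep(1:n, each = m), is_calpha = TRUE)
  nnr <- nearest_neighbors(psr, k = 3)
  oracle <- matrix(NA_real_, n, 3)
  for (a in 1:n) {
    ds <- numeric(0)
    for (b in setdiff(1:n, a)) {
      best <- Inf
      for (i in which(psr$complex_id == a)) {
        for (j in which(psr$complex_id == b)) {
          best <- min(best, sqrt(sum((coords[i, ] - coords[j, ])^2)))
        }
      }
      ds <- c(ds, best)
    }
    oracle[a, ] <- sort(ds)[1:3]
  }
  expect_equal(nnr$distances, oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(nnr$rank_means, colMeans(oracle), tolerance = 1e-12)
})

test_that("shell/cargo contact series equal brute-force logistic sums", {
  ps <- particle_set(1:5, "pseudo",
                     c("shell", "shell", "cargo", "cargo", "cargo"),
                     x = c(0, 3, 5, 6, 30), y = 0, z = 0,
                     complex_id = c(NA, NA, 1, 1, 2), is_calpha = TRUE)
  coords <- array(0, c(2, 5, 3))
  for (f in 1:2) coords[f, , 1] <- ps$x
  tr <- trajectory(1:2, coords, ps)
  sc <- shell_cargo_contact_series(tr)
  k <- function(d) 1 / (1 + exp(5 * (d - 4)))
  # shell {0,3} x cargo {5,6,30}; 30 is beyond the 12 A cutoff
  expect_equal(sc$shell_cargo, rep(k(5) + k(6) + k(2) + k(3), 2),
               tolerance = 1e-9)
  # cargo/cargo: only cross-complex pairs (5,30), (6,30) - both beyond cutoff
  expect_equal(sc$cargo_cargo, c(0, 0))
  # no cargo at all
  ps2 <- ps[ps$role == "shell", ]
  tr2 <- trajectory(1:2, coords[, 1:2, , drop = FALSE], ps2)
  sc2 <- shell_cargo_contact_series(tr2)
  expect_equal(sc2$cargo_cargo, c(0, 0))
  expect_equal(sc2$shell_cargo, c(0, 0))
})

test_that("graphs round-trip through GEXF and GraphML", {
  spc <- cargo_spec(n_complexes = 10, attraction_strength = 2,
                    n_frames = 30, seed = 76)
  g <- contact_graph(gen_cargo_frames(spc))
  base <- withr::local_tempfile()
  paths <- export_graph(g, base)
  for (p in paths) {
    rt <- read_contact_graph(p)
    expect_equal(nrow(rt$nodes), nrow(g$nodes))
    expect_equal(rt$edges$a, g$edges$a)
    expect_equal(rt$edges$b, g$edges$b)
    expect_equal(rt$edges$weight, g$edges$weight, tolerance = 1e-9)
    expect_equal(rt$edges$mean_min_dist, g$edges$mean_min_dist,
                 tolerance = 1e-9)
  }
  # empty graph still produces valid files
  ps <- particle_set(1:2, "pseudo", "cargo", x = c(0, 50), y = 0, z = 0,
                     complex_id = 1:2, is_calpha = TRUE)
  coords <- array(0, c(1, 2, 3)); coords[1, , 1] <- ps$x
  g0 <- contact_graph(trajectory(1, coords, ps))
  p0 <- export_graph(g0, withr::local_tempfile())
  rt0 <- read_contact_graph(p0[["gexf"]])
  expect_equal(nrow(rt0$nodes), 2L)
  expect_equal(nrow(rt0$edges), 0L)
})
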