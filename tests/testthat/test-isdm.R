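test_that("window diffusivity recovers the OU ground truth within 15%", {
  w <- ou_window()
  D <- window_diffusivity(w)
  expect_lt(abs(D - 70) / 70, 0.15)
  # OU relations: var ~ kBT/k, tau ~ var/D
  expect_equal(var(w$samples), 0.1185, tolerance = 0.1)
})

test_that("doubling the true diffusivity halves the relaxation time", {
  sp <- umbrella_spec(function(x) 0 * x, function(x) rep(140, length(x)),
                      window_centers = 0, k_bias = 5, n_samples = 5e4,
                      seed = 4, sample_interval = 0.1)
  w2 <- gen_umbrella_windows(sp)[[1]]
  D2 <- window_diffusivity(w2)
  expect_lt(abs(D2 - 140) / 140, 0.15)
})

test_that("degenerate windows are rejected with advice", {
  wconst <- umbrella_window(0, 5, samples = rep(1, 2000), interval = 0.2)
  expect_error(window_diffusivity(wconst), "zero variance|constant")
  wshort <- umbrella_window(0, 5, samples = rnorm(500), interval = 0.2)
  expect_error(window_diffusivity(wshort), ">= 1000")
})

test_that("profile splines reproduce lines exactly and denoise a sine", {
  x <- seq(0, 10, 0.5)
  f <- fit_profile_spline(x, 2 * x + 1)
  expect_equal(f(x), 2 * x + 1, tolerance = 1e-6)
  # clamped outside the data range
  expect_equal(f(50), f(10))
  expect_error(fit_profile_spline(c(1, 2, 3), c(1, 2, 3)), "at least 4")
  set.seed(19)
  xs <- seq(0, 2 * pi, length.out = 80)
  noisy <- sin(xs) + rnorm(80, 0, 0.1)
  fs <- fit_profile_spline(xs, noisy)
  expect_lt(sqrt(mean((fs(xs) - sin(xs))^2)), 0.1)
})

test_that("flat-profile ISDM equals D/L to 1e-6 relative", {
  g <- free_energy_profile(seq(-30, 30, 0.5), rep(0, 121))
  d <- diffusivity_profile(seq(-30, 30, 0.5), rep(60, 121))
  est <- isdm_permeability(g, d, -30, 30, n_draws = 0)
  expect_lt(abs(est$P - 10) / 10, 1e-6)
})

test_that("re-anchoring the free energy leaves the permeability invariant", {
  xi <- seq(-30, 30, 0.5)
  G <- 3 * exp(-xi^2 / 18)
  d <- diffusivity_profile(xi, rep(50, length(xi)))
  a <- isdm_permeability(free_energy_profile(xi, G), d, -30, 30, n_draws = 0)
  b <- isdm_permeability(free_energy_profile(xi, G + 7.5), d, -30, 30,
                         n_draws = 0)
  expect_equal(a$P, b$P, tolerance = 1e-9)
})

test_that("a square barrier matches piecewise hand quadrature", {
  xi <- seq(-30, 30, 0.25)
  G <- ifelse(abs(xi) <= 5, 5, 0)
  est <- isdm_permeability(free_energy_profile(xi, G),
                           diffusivity_profile(xi, rep(50, length(xi))),
                           -30, 30, n_draws = 0)
  beta <- thermo_constants(298)$beta
  I_hand <- 50 / 50 + 10 * exp(beta * 5) / 50  # 50 A at G=0, 10 A at 5 kcal/mol
  # spline smoothing rounds the discontinuous corners slightly
  expect_equal(est$P, 10 / I_hand, tolerance = 0.02)
})

test_that("integration bounds must be covered by the profiles", {
  g <- free_energy_profile(seq(-10, 10, 0.5), rep(0, 41))
  d <- diffusivity_profile(seq(-30, 30, 0.5), rep(60, 121))
  expect_error(isdm_permeability(g, d, -30, 30), "covers")
})

test_that("effective permeability is exact tile arithmetic", {
  dhap <- effective_permeability(pore_set(P_H = 23.9, P_T = 13.5))
  g3p <- effective_permeability(pore_set(P_H = 33.7, P_T = 13.3))
  expect_equal(signif(dhap$P, 2), 3.7)
  expect_equal(signif(g3p$P, 2), 5.0)
  expect_equal(signif(cylinder_area_fraction(15, 16166), 3), 0.0437)
  expect_equal(effective_permeability(pore_set(0, 0))$P, 0)
  # linear in the per-pore permeabilities
  expect_equal(effective_permeability(pore_set(2 * 23.9, 2 * 13.5))$P,
               2 * dhap$P)
})

test_that("Boltzmann inversion recovers an analytic Gaussian well", {
  set.seed(42)
  n <- 5e4
  z <- rnorm(n, 0, sqrt(0.5))            # density ~ exp(-z^2)
  rho <- sqrt(runif(n)) * 10
  phi <- runif(n, 0, 2 * pi)
  ps <- particle_set(1:n, "G3P", "metabolite",
                     x = rho * cos(phi), y = rho * sin(phi), z = z + 40)
  coords <- array(NA_real_, c(1, n, 3))
  coords[1, , 1] <- ps$x; coords[1, , 2] <- ps$y; coords[1, , 3] <- ps$z
  tr <- trajectory(1, coords, ps)
  sh <- shell_geometry(c(0, 0, 0), 40, delta = 5,
                       pores = list(list(axis = c(0, 0, 1), radius = 12)))
  fe <- boltzmann_inversion(tr, sh, cylinder_radius = 15, bin_width = 0.25)
  kBT <- thermo_constants(298)$kBT
  truth <- kBT * fe$grid^2
  sel <- abs(fe$grid) < 1.5
  expect_lt(max(abs((fe$G[sel] - min(fe$G[sel])) -
                      (truth[sel] - min(truth[sel])))), 0.1)
  expect_error(boltzmann_inversion(tr, sh, species = "DHAP"), "empty selection")
})

test_that("uniform occupancy inverts to a flat profile within 2 stderr", {
  set.seed(43)
  n <- 4e4
  ps <- particle_set(1:n, "G3P", "metabolite",
                     x = runif(n, -10, 10), y = runif(n, -10, 10),
                     z = runif(n, 30, 50))
  coords <- array(NA_real_, c(1, n, 3))
  coords[1, , 1] <- ps$x; coords[1, , 2] <- ps$y; coords[1, , 3] <- ps$z
  tr <- trajectory(1, coords, ps)
  sh <- shell_geometry(c(0, 0, 0), 40, delta = 5,
                       pores = list(list(axis = c(0, 0, 1), radius = 12)))
  fe <- boltzmann_inversion(tr, sh, cylinder_radius = 10, bin_width = 1)
  core <- abs(fe$grid) < 9
  ref <- mean(fe$G[core])
  expect_true(mean(abs(fe$G[core] - ref) < 2 * fe$stderr[core] + 1e-9) > 0.9)
})

test_that("2D PMF reweighting flattens a uniform density and flags voids", {
  set.seed(44)
  n <- 4e4
  ps <- particle_set(1:n, "DHAP", "metabolite",
                     x = runif(n, -15, 15), y = runif(n, -15, 15),
                     z = runif(n, 25, 55))
  coords <- array(NA_real_, c(1, n, 3))
  coords[1, , 1] <- ps$x; coords[1, , 2] <- ps$y; coords[1, , 3] <- ps$z
  tr <- trajectory(1, coords, ps)
  sh <- shell_geometry(c(0, 0, 0), 40, delta = 5,
                       pores = list(list(axis = c(0, 0, 1), radius = 12)))
  pm <- pmf_2d(tr, sh, species = "DHAP", z_bins = seq(-10, 10, 2),
               r_bins = seq(0, 10, 2))
  dev <- abs(pm$G - mean(pm$G, na.rm = TRUE)) / pm$stderr
  expect_gt(mean(dev < 2, na.rm = TRUE), 0.9)
  # all mass in one bin: that bin 0, all others unreachable
  ps1 <- particle_set(1:10, "DHAP", "metabolite",
                      x = 0.5, y = 0, z = 40.5)
  c1 <- array(NA_real_, c(1, 10, 3))
  c1[1, , 1] <- ps1$x; c1[1, , 2] <- ps1$y; c1[1, , 3] <- ps1$z
  tr1 <- trajectory(1, c1, ps1)
  pm1 <- pmf_2d(tr1, sh, species = "DHAP", z_bins = seq(-2, 2, 1),
                r_bins = seq(0, 2, 1))
  expect_equal(sum(!pm1$unreachable), 1L)
  expect_equal(pm1$G[!pm1$unreachable], 0)
  expect_true(all(is.na(pm1$G[pm1$unreachable])))
})
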