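test_that("immobile particles have zero MSD at every lag", {
  ps <- particle_set(1:4, "water", "solvent", x = 1:4, y = 0, z = 0)
  coords <- array(rep(c(1:4, 0, 0, 0, 0, 0, 0, 0, 0), each = 1), c(10, 4, 3))
  for (f in 1:10) { coords[f, , 1] <- 1:4; coords[f, , 2] <- 0; coords[f, , 3] <- 0 }
  tr <- trajectory(seq(0.1, 1, 0.1), coords, ps)
  res <- msd_lag(tr, lags = c(0.2, 0.5))
  expect_equal(res$MSD, c(0, 0))
  expect_equal(res$D, c(0, 0))
})

test_that("MSD estimator recovers the generator diffusivity within 5%", {
  run <- free_diffusion_run()
  res <- msd_lag(run$traj, lags = 1)
  expect_lt(abs(res$D - 100) / 100, 0.05)
  expect_equal(res$MSD, 600, tolerance = 0.05)
})

test_that("wrapped trajectories are refused", {
  ps <- particle_set(1:2, "water", "solvent", x = 0:1, y = 0, z = 0)
  coords <- array(0, c(3, 2, 3))
  tr <- trajectory(1:3, coords, ps, unwrapped = FALSE)
  expect_error(msd_lag(tr, lags = 1), "wrapped")
  expect_error(radial_diffusion_profile(tr, shell_geometry(c(0, 0, 0), 40),
                                        r_bins = c(0, 10)), "unwrapped")
})

test_that("region labels equal brute-force radius comparison", {
  fx <- canonical_shell_run()
  sh <- fx$shell
  lab <- partition_by_region(fx$run$traj, sh, subset = 1:20)
  for (f in c(1, 100)) {
    for (j in 1:20) {
      r <- sqrt(sum((fx$run$traj$coords[f, j, ] - sh$center)^2))
      expect_identical(lab[f, j], if (r < sh$R_mid) "inside" else "outside")
    }
  }
})

test_that("windows straddling a crossing are excluded from both regions", {
  # particle 1 stays at r=10 (inside); particle 2 crosses mid-window
  ps <- particle_set(1:2, "G3P", "metabolite", x = c(10, 10), y = 0, z = 0)
  coords <- array(0, c(5, 2, 3))
  coords[, 1, 1] <- 10
  coords[, 2, 1] <- c(10, 20, 80, 80, 80)  # crosses R_mid = 40 at frame 3
  tr <- trajectory(1:5, coords, ps)
  sh <- shell_geometry(c(0, 0, 0), 40, delta = 5)
  res_in <- msd_lag(tr, lags = 4, shell = sh, region = "inside")
  # only particle 1's single full window survives, with zero displacement
  expect_identical(res_in$n_pairs, 1L)
  expect_equal(res_in$MSD, 0)
  res_out <- msd_lag(tr, lags = 2, shell = sh, region = "outside")
  # particle 2 is fully outside only for the window starting at frame 3
  expect_identical(res_out$n_pairs, 1L)
})

test_that("confined molecules show sublinear MSD at long lags", {
  p <- shell_bd_params(barrier_height = 8, n_solutes = 400, n_steps = 3e4,
                       seed = 29)
  run <- gen_shell_bd(p, save_every = 15)
  inside0 <- run$traj$particles$init_inside
  res <- msd_lag(run$traj, lags = c(1, 2, 5, 10), subset = inside0,
                 shell = run$shell, region = "inside")
  # D(lag) falls with lag once displacement saturates at the cage size
  expect_lt(res$D[4], res$D[1])
})

test_that("radial diffusion profile is flat for free diffusion and dips in the shell band", {
  run <- free_diffusion_run()
  prof <- radial_diffusion_profile(run$traj, shell_geometry(c(0, 0, 0), 40),
                                   r_bins = seq(30, 150, 20), interval = 1,
                                   n_boot = 30)
  expect_true(all(abs(prof$D - 100) / 100 < 0.1, na.rm = TRUE))
  # a D_shell = D_free/10 band produces a deep dip at the shell radius
  p <- shell_bd_params(barrier_height = 0, n_solutes = 400, n_steps = 2e4,
                       seed = 37)
  runb <- gen_shell_bd(p, save_every = 4)
  profb <- radial_diffusion_profile(runb$traj, runb$shell,
                                    r_bins = seq(20, 58, 2), interval = 0.1,
                                    n_boot = 0)
  band <- profb$r_mid > 37 & profb$r_mid < 43
  free <- profb$r_mid < 26 | profb$r_mid > 54
  expect_lt(min(profb$D[band]), mean(profb$D[free]) / 5)
  # empty bins are flagged missing, not zero
  prof0 <- radial_diffusion_profile(runb$traj, runb$shell,
                                    r_bins = c(0.0, 0.5, 20), interval = 0.1,
                                    n_boot = 0)
  expect_true(is.na(prof0$D[1]))
})

test_that("radial density is flat for uniform occupancy and scales interior bins", {
  set.seed(51)
  n <- 3e4
  d <- matrix(rnorm(3 * n), ncol = 3)
  r <- 80 * runif(n)^(1 / 3)
  d <- d / sqrt(rowSums(d^2)) * r
  ps <- particle_set(1:n, "G3P", "metabolite", d[, 1], d[, 2], d[, 3])
  coords <- array(NA_real_, c(1, n, 3))
  for (k in 1:3) coords[1, , k] <- d[, k]
  tr <- trajectory(1, coords, ps)
  sh <- shell_geometry(c(0, 0, 0), 40, delta = 5)
  bins <- seq(10, 80, 10)
  raw <- radial_density(tr, sh, bins, free_volume_fraction = 0)
  expect_lt(diff(range(raw$density)) / mean(raw$density), 0.15)
  cor <- radial_density(tr, sh, bins, free_volume_fraction = 0.20)
  interior <- raw$r_mid + 5 <= sh$R_mid
  expect_equal(cor$density[interior], raw$density[interior] / 0.8)
  expect_equal(cor$density[!interior], raw$density[!interior])
})

test_that("Stokes-Einstein-Sutherland prediction and scalings", {
  D50 <- predict_diffusion(50)
  expect_equal(D50, 90, tolerance = 0.02)       # ~90 x 1e-8 cm^2/s
  expect_equal(predict_diffusion(50, eta = 9), D50 / 9)
  expect_equal(predict_diffusion(8 * 50), D50 / 2)
})

test_that("viscosity fit inverts the prediction and tolerates noise", {
  MW <- c(15, 30, 60, 120, 250, 500)
  clean <- data.frame(MW = MW, D = predict_diffusion(MW, eta = 10))
  fit <- stokes_einstein_fit(clean)
  expect_lt(abs(fit$eta - 10) / 10, 0.01)
  expect_lt(abs(fit$offset), 1e-8)
  expect_error(stokes_einstein_fit(data.frame(MW = c(10, 20), D = c(1, 2))),
               "3 distinct")
  set.seed(61)
  etas <- replicate(20, {
    noisy <- clean
    noisy$D <- noisy$D * (1 + rnorm(length(MW), 0, 0.05))
    stokes_einstein_fit(noisy)$eta
  })
  expect_lt(abs(mean(etas) - 10) / 10, 0.15)
  expect_true(all(abs(etas - 10) / 10 < 0.5))
})

test_that("diffusion estimates are invariant under rigid translation", {
  run <- free_diffusion_run()
  tr <- run$traj
  shifted <- tr
  shifted$coords <- tr$coords + 123.4
  a <- msd_lag(tr, lags = 1)
  b <- msd_lag(shifted, lags = 1)
  expect_equal(a$MSD, b$MSD)
})
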