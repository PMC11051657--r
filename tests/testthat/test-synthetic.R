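test_that("generator output is bit-reproducible for a fixed scenario seed", {
  sc <- lamella_scenario(n_tomograms = 2, seed = 31)
  a <- simulate_lamella_particles(sc)
  b <- simulate_lamella_particles(sc)
  expect_identical(a, b)
})

test_that("particles lie inside the slab with correct ground-truth depths", {
  sc <- lamella_scenario(n_tomograms = 1, wedge_slope = 0,
                         thickness_front_nm = 150, seed = 32)
  sim <- simulate_lamella_particles(sc)
  expect_true(all(sim$truth$depth_nm >= 0))
  expect_true(all(sim$truth$depth_nm <= 75))
  expect_true(all(sim$truth$thickness_nm == 150))
})

test_that("multi-tomogram scenario reproduces the configured thickness range", {
  sc <- lamella_scenario(seed = 33)      # 12 tomograms spanning 43-255 nm
  sim <- simulate_lamella_particles(sc)
  expect_lt(abs(min(sim$truth$thickness_nm) - 43), 5)
  expect_lt(abs(max(sim$truth$thickness_nm) - 255), 5)
})

test_that("doubling density doubles particle counts within Poisson tolerance", {
  n_of <- function(dens, seed) nrow(simulate_lamella_particles(
    lamella_scenario(n_tomograms = 4, density_per_100nm3 = dens,
                     seed = seed))$particles)
  n1 <- mean(vapply(41:44, function(s) n_of(8, s), numeric(1)))
  n2 <- mean(vapply(51:54, function(s) n_of(16, s), numeric(1)))
  expect_lt(abs(n2 / n1 - 2), 6 / sqrt(n1))   # a few sigma of Poisson noise
})

test_that("geometry module recovers the generator's plane and thickness", {
  sc <- lamella_scenario(n_tomograms = 3, seed = 34)
  sim <- simulate_lamella_particles(sc)
  st <- straighten(sim$particles, sim$meta)
  for (tm in names(st$frames)) {
    fr <- st$frames[[tm]]
    expect_lt(max(abs(fr$plane[1:2] - sc$plane[1:2])), 0.02)
    true_t <- sim$frames[[tm]]$thickness_mean_nm
    expect_lt(abs(fr$thickness_nm - true_t), 2 * fr$bin_width_nm)
  }
})

test_that("simulated CC scores follow the damage model and stay positive", {
  d <- c(0, 10, 30, 60, 90)
  ramp <- list(kind = "ramp", d_break_nm = 30, c_surface = 0.6,
               c_plateau = 0.95, noise_sd = 0)
  expect_equal(simulate_cc_scores(d, ramp),
               c(0.6, 0.6 + 0.35 / 3, 0.95, 0.95, 0.95), tolerance = 1e-12)
  expo <- list(kind = "exponential", lambda_nm = 15, c_surface = 0.6,
               c_plateau = 0.95, noise_sd = 0)
  cc <- simulate_cc_scores(d, expo)
  expect_equal(cc[1], 0.6, tolerance = 1e-12)
  expect_true(all(diff(cc) > 0))
  expect_lt(abs(cc[5] - 0.95), 0.001)
  noisy <- simulate_cc_scores(runif(5000, 0, 90),
                              list(kind = "ramp", d_break_nm = 30,
                                   c_surface = 0.05, c_plateau = 0.2,
                                   noise_sd = 0.3), seed = 35)
  expect_true(all(noisy > 0))
})

test_that("hinge estimator stays near the break under the exponential model too", {
  set.seed(36)
  d <- runif(3000, 0, 90)
  cc <- simulate_cc_scores(d, list(kind = "exponential", lambda_nm = 10,
                                   c_surface = 0.6, c_plateau = 0.95,
                                   noise_sd = 0.03), seed = 37)
  fit <- estimate_damage_depth(d, cc, n_boot = 0)
  expect_false(fit$no_damage)
  # under misspecification the hinge break lands within the decay region
  expect_gt(fit$d_break_nm, 10)
  expect_lt(fit$d_break_nm, 60)
})

test_that("half-map FSC matches the closed-form SNR/(1+SNR) curve", {
  hm <- simulate_halfmaps(box = 64, pixel_size = 4, n_particles = 1000,
                          B = 300, seed = 38)
  fsc <- compute_fsc(hm$map_a, hm$map_b)
  dev <- abs(fsc$fsc - hm$expected_fsc$fsc)
  # per-shell Monte-Carlo tolerance ~ (1 - FSC) / sqrt(n_voxels in shell)
  tol <- pmax(6 * (1 - hm$expected_fsc$fsc) / sqrt(fsc$n_voxels), 0.02)
  expect_true(all(dev < tol))
  expect_lt(max(dev), 0.05)
})

test_that("resolution improves monotonically with particle number at fixed B", {
  res <- vapply(c(250, 1000, 4000), function(n) {
    hm <- simulate_halfmaps(box = 48, pixel_size = 1.5, n_particles = n,
                            B = 300, scale = 0.04, seed = 39)
    resolution_at(compute_fsc(hm$map_a, hm$map_b), 0.143)
  }, numeric(1))
  expect_true(all(diff(res) < 0))   # finer (smaller) resolution with more N
})

test_that("RH fit on simulated resolution series recovers the configured B within 15%", {
  B_true <- 300
  n <- c(250, 500, 1000, 2000, 4000, 8000)
  res <- vapply(seq_along(n), function(i) {
    hm <- simulate_halfmaps(box = 64, pixel_size = 1.5, n_particles = n[i],
                            B = B_true, scale = 0.04, seed = 40 + i)
    resolution_at(compute_fsc(hm$map_a, hm$map_b), 0.143)
  }, numeric(1))
  fit <- rosenthal_henderson_fit(n, res, nyquist_res = 3)
  expect_lt(abs(fit$B - B_true) / B_true, 0.15)
})
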