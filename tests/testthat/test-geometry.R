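test_that("plane fit interpolates exact planes and matches the lm oracle", {
  xy <- expand.grid(x = seq(0, 400, by = 40), y = seq(0, 400, by = 40))
  exact <- cbind(xy, z = 0.1 * xy$x + 0.2 * xy$y + 50)
  expect_equal(unname(fit_reference_plane(exact)), c(0.1, 0.2, 50),
               tolerance = 1e-10)
  flat <- cbind(xy, z = 42)
  expect_equal(unname(fit_reference_plane(flat)), c(0, 0, 42), tolerance = 1e-10)

  set.seed(11)
  noisy <- data.frame(x = runif(500, 0, 900), y = runif(500, 0, 900))
  noisy$z <- 0.05 * noisy$x - 0.1 * noisy$y + 30 + rnorm(500, 0, 2)
  got <- fit_reference_plane(noisy)
  oracle <- unname(coef(lm(z ~ x + y, data = noisy)))  # (c, a, b)
  expect_equal(unname(got), oracle[c(2, 3, 1)], tolerance = 1e-9)
  expect_lt(abs(got[["a"]] - 0.05), 0.01)
  expect_lt(abs(got[["b"]] + 0.10), 0.01)
  expect_lt(abs(got[["c"]] - 30), 1)
})

test_that("plane fit rejects degenerate geometry, naming the tomogram", {
  expect_error(fit_reference_plane(data.frame(x = 1:2, y = 1:2, z = 1:2)),
               "at least 3 points")
  collinear <- data.frame(x = 1:10, y = 2 * (1:10) + 1, z = rnorm(10))
  expect_error(fit_reference_plane(collinear, tomo = "tomo_007"), "tomo_007")
  expect_error(fit_reference_plane(collinear), "collinear")
})

test_that("flatten_z subtracts the plane; refitting flattened data gives the zero plane", {
  tab <- data.frame(x = 100, y = 200, z = 80)
  expect_equal(flatten_z(tab, c(0.1, 0.2, 10))$z_flat, 20)
  expect_equal(flatten_z(tab, c(0, 0, 0))$z_flat, 80)

  set.seed(12)
  cloud <- data.frame(x = runif(400, 0, 800), y = runif(400, 0, 800))
  cloud$z <- 0.07 * cloud$x - 0.03 * cloud$y + 150 + runif(400, -15, 15)
  plane <- fit_reference_plane(cloud)
  flat <- flatten_z(cloud, plane)
  expect_equal(mean(flat$z_flat), 0, tolerance = 1e-9)
  refit <- fit_reference_plane(data.frame(x = flat$x, y = flat$y, z = flat$z_flat))
  expect_equal(unname(refit), c(0, 0, 0), tolerance = 1e-9)
})

test_that("surface estimation matches the histogram-scan oracle and recovers uniform slabs", {
  set.seed(13)
  z_nm <- runif(20000, -75, 75)
  z_vox <- z_nm * 10 / 4.9
  got <- estimate_surfaces(z_vox, pixel_size = 4.9)
  expect_equal(unname(got), oracle_surfaces(z_vox * 0.49))
  expect_lt(abs(got[["z_bottom_nm"]] + 75), 5)
  expect_lt(abs(got[["z_top_nm"]] - 75), 5)

  z2 <- runif(20000, 10, 110)      # off-centre slab
  got2 <- estimate_surfaces(z2 * 10 / 4.9, pixel_size = 4.9)
  expect_lt(abs(diff(got2) - 100), 10)
  expect_equal(unname(got2), oracle_surfaces(z2))
})

test_that("surface estimation needs enough support", {
  expect_error(estimate_surfaces(rnorm(10), 4.9), "insufficient support")
})

test_that("particle depth is distance to the closest surface, negative outside", {
  expect_equal(particle_depth(0, -75, 75), 75)
  expect_equal(particle_depth(75, -75, 75), 0)
  expect_equal(particle_depth(-60, -75, 75), 15)
  expect_equal(particle_depth(90, -75, 75), -15)     # outside the slab
  # reflection invariance and half-thickness bound
  set.seed(14)
  z <- runif(200, -80, 80)
  d <- particle_depth(z, -75, 75)
  expect_equal(d, particle_depth((-75 + 75) - z, -75, 75))
  expect_true(all(d[z > -75 & z < 75] <= 150 / 2))
})

test_that("lamella frames expose thickness and wedge profiles sort front-to-back", {
  fr <- lamella_frame(c(0, 0, 0), -75, 75, pixel_size = 4.9)
  expect_equal(local_thickness(fr), 150)
  expect_error(lamella_frame(c(0, 0, 0), 75, -75, 4.9))

  # wedge: thickness grows 0.02 nm per nm of position over 5 positions
  pos <- seq(0, 4000, length.out = 5)
  frames <- lapply(pos, function(p)
    lamella_frame(c(0, 0, 0), -(100 + 0.02 * p) / 2, (100 + 0.02 * p) / 2, 4.9))
  prof <- wedge_profile(frames[c(3, 1, 5, 2, 4)], pos[c(3, 1, 5, 2, 4)])
  expect_equal(prof$position, pos)
  expect_true(all(diff(prof$thickness_nm) >= 0))
  expect_equal(nrow(wedge_profile(frames[1], 0)), 1)
})

test_that("straighten annotates every particle with depth and local thickness", {
  sc <- lamella_scenario(n_tomograms = 2, seed = 21)
  sim <- simulate_lamella_particles(sc)
  st <- straighten(sim$particles, sim$meta)
  p <- st$particles
  expect_true(all(is.finite(p$depth_nm)))
  expect_true(all(p$thickness_nm > 0))
  expect_identical(p$outside_slab, p$depth_nm < 0)
  expect_length(st$frames, 2)
  # depths approximate ground truth up to surface-estimation error
  expect_lt(median(abs(p$depth_nm - sim$truth$depth_nm)), 5)
})
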