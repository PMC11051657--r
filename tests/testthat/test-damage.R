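test_that("CC normalisation is per tomogram with maximum exactly 1", {
  tab <- data.frame(tomo = c("a", "a", "a", "b", "b"),
                    x = 0, y = 0, z = 0, cc = c(2, 4, 8, 10, 5))
  out <- normalize_cc(tab)
  expect_equal(out$cc_norm, c(0.25, 0.5, 1, 1, 0.5))
  same <- normalize_cc(data.frame(tomo = "a", x = 0, y = 0, z = 0,
                                  cc = rep(3, 4)))
  expect_equal(same$cc_norm, rep(1, 4))
  # invariant under per-tomogram positive rescaling
  tab2 <- tab
  tab2$cc <- tab$cc * ifelse(tab$tomo == "a", 7, 0.3)
  expect_equal(normalize_cc(tab2)$cc_norm, out$cc_norm, tolerance = 1e-12)
  bad <- data.frame(tomo = "t9", x = 0, y = 0, z = 0, cc = c(-1, 0))
  expect_error(normalize_cc(bad), "t9")
})

test_that("hinge regression recovers a noiseless ramp-plateau break exactly", {
  set.seed(17)
  d <- runif(500, 0, 90)
  cc <- 0.6 + (0.95 - 0.6) * pmin(d, 30) / 30
  fit <- estimate_damage_depth(d, cc, n_boot = 0)
  expect_equal(fit$d_break_nm, 30)
  expect_equal(fit$c_surface, 0.6, tolerance = 1e-9)
  expect_equal(fit$c_plateau, 0.95, tolerance = 1e-9)
  expect_false(fit$no_damage)
})

test_that("a flat CC profile raises the no-damage flag", {
  set.seed(18)
  d <- runif(300, 0, 90)
  fit <- estimate_damage_depth(d, rep(0.9, 300) + rnorm(300, 0, 1e-4),
                               n_boot = 0)
  expect_true(fit$no_damage)
  expect_equal(fit$d_break_nm, 5)   # reported at the grid minimum
  expect_error(estimate_damage_depth(runif(10), runif(10)), "at least 50")
})

test_that("breakpoint estimation is consistent as noise vanishes", {
  for (sd in c(0.1, 0.02, 0.001)) {
    set.seed(19)
    d <- runif(3000, 0, 90)
    cc <- simulate_cc_scores(d, list(kind = "ramp", d_break_nm = 30,
                                     c_surface = 0.6, c_plateau = 0.95,
                                     noise_sd = sd), seed = 20)
    fit <- estimate_damage_depth(d, cc, n_boot = 0)
    tol <- c(`0.1` = 5, `0.02` = 2, `0.001` = 1)[[as.character(sd)]]
    expect_lt(abs(fit$d_break_nm - 30), tol + 1e-9)
  }
})

test_that("breakpoint is equivariant under depth shifts covered by the scan window", {
  set.seed(22)
  d <- runif(2000, 0, 90)
  cc <- simulate_cc_scores(d, list(kind = "ramp", d_break_nm = 25,
                                   c_surface = 0.6, c_plateau = 0.95,
                                   noise_sd = 0.03), seed = 23)
  base <- estimate_damage_depth(d, cc, n_boot = 0)$d_break_nm
  shifted <- estimate_damage_depth(d + 10, cc, n_boot = 0)$d_break_nm
  expect_lte(abs(shifted - (base + 10)), 1)   # within grid resolution
})

test_that("bootstrap CI brackets the estimate and is seed-reproducible", {
  set.seed(24)
  d <- runif(1000, 0, 90)
  cc <- simulate_cc_scores(d, list(kind = "ramp", d_break_nm = 30,
                                   c_surface = 0.6, c_plateau = 0.95,
                                   noise_sd = 0.05), seed = 25)
  f1 <- estimate_damage_depth(d, cc, n_boot = 50, seed = 4)
  f2 <- estimate_damage_depth(d, cc, n_boot = 50, seed = 4)
  expect_identical(f1$ci, f2$ci)
  expect_lte(f1$ci[1], f1$d_break_nm)
  expect_gte(f1$ci[2], f1$d_break_nm)
  expect_equal(predict(f1, c(0, f1$d_break_nm, 90)),
               c(f1$c_surface, f1$c_plateau, f1$c_plateau), tolerance = 1e-9)
})

test_that("linear trend fitting matches closed-form OLS", {
  x <- c(1, 2, 3, 4)
  expect_equal(unname(fit_linear_trend(x, 2 * x + 1)), c(2, 1, 1),
               tolerance = 1e-12)
  expect_equal(fit_linear_trend(x, rep(5, 4))[["slope"]], 0)
  set.seed(26)
  thick <- runif(200, 43, 255)
  res <- 0.05 * thick + 4 + rnorm(200, 0, 1)
  got <- fit_linear_trend(thick, res)
  ora <- coef(lm(res ~ thick))
  expect_equal(got[["slope"]], unname(ora[2]), tolerance = 1e-9)
  expect_equal(got[["intercept"]], unname(ora[1]), tolerance = 1e-9)
  expect_lt(abs(got[["slope"]] - 0.05), 0.01)
  expect_error(fit_linear_trend(c(1, 1), c(2, 3)), "degenerate")
})
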