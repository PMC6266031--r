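mk_scores <- function(dose, let = 0, alpha = 0, sqrtbeta = 0, zstar = 0) {
  n <- length(dose)
  arr <- function(x) array(rep(x, length.out = n), c(n, 1, 1))
  structure(list(dims = c(n, 1, 1), spacing = c(1, 1, 1), origin = c(0, 0, 0),
                 dose = arr(dose), sum_d_let = arr(dose * let),
                 sum_d_alpha = arr(dose * alpha),
                 sum_d_sqrtbeta = arr(dose * sqrtbeta),
                 sum_d_zstar = arr(dose * zstar)),
            class = "score_maps")
}

test_that("fixed proton RBE is a pure 1.1 scaling", {
  expect_equal(rbe_fixed_1p1(2), 2.2)
  expect_equal(rbe_fixed_1p1(0), 0)
  d <- c(0.5, 1, 3)
  expect_equal(rbe_fixed_1p1(7 * d), 7 * rbe_fixed_1p1(d))
})

test_that("mixed LEM coefficients are dose-averaged alpha and sqrt(beta)", {
  s <- mk_scores(c(1, 1), alpha = 0.5, sqrtbeta = sqrt(0.05))
  cf <- mixed_lem_coeffs(s)
  expect_equal(as.numeric(cf$alpha_mix), c(0.5, 0.5))
  expect_equal(as.numeric(cf$beta_mix), c(0.05, 0.05))
  # equal doses, alpha 0.2 and 0.6 -> 0.4; beta 0.04 and 0.09 -> 0.0625
  s2 <- structure(list(dims = c(1, 1, 1), spacing = c(1, 1, 1),
                       origin = c(0, 0, 0), dose = array(2, c(1, 1, 1)),
                       sum_d_let = array(0, c(1, 1, 1)),
                       sum_d_alpha = array(0.2 + 0.6, c(1, 1, 1)),
                       sum_d_sqrtbeta = array(0.2 + 0.3, c(1, 1, 1)),
                       sum_d_zstar = array(0, c(1, 1, 1))),
                  class = "score_maps")
  cf2 <- mixed_lem_coeffs(s2)
  expect_equal(as.numeric(cf2$alpha_mix), 0.4)
  expect_equal(as.numeric(cf2$beta_mix), 0.0625)
})

test_that("mixed MKM alpha is alpha0 + beta0 * dose-averaged zstar", {
  p <- mkm_params(alpha0 = 0.13, beta0 = 0.05)
  s0 <- mk_scores(1, zstar = 0)
  expect_equal(as.numeric(mixed_mkm_alpha(s0, p)$alpha_mix), 0.13)
  s2 <- mk_scores(1, zstar = 2)
  expect_equal(as.numeric(mixed_mkm_alpha(s2, p)$alpha_mix), 0.13 + 0.05 * 2)
  # equal doses at zstar 1 and 3 -> dose-averaged 2
  s13 <- structure(list(dims = c(1, 1, 1), spacing = c(1, 1, 1),
                        origin = c(0, 0, 0), dose = array(2, c(1, 1, 1)),
                        sum_d_let = array(0, c(1, 1, 1)),
                        sum_d_alpha = array(0, c(1, 1, 1)),
                        sum_d_sqrtbeta = array(0, c(1, 1, 1)),
                        sum_d_zstar = array(1 + 3, c(1, 1, 1))),
                   class = "score_maps")
  expect_equal(as.numeric(mixed_mkm_alpha(s13, p)$zstar_mix), 2)
})

test_that("the LQ inversion reproduces its closed-form worked example", {
  # alpha_x 0.1, beta_x 0.05, alpha_mix 0.5, beta_mix 0.05, D 2:
  # E = 1.2, D_RBE = (sqrt(0.01 + 0.24) - 0.1)/0.1 = 4
  expect_equal(photon_equivalent_dose(2, 0.5, 0.05, photon_lq(0.1, 0.05)),
               4, tolerance = 1e-15)
  # self-reference identity
  d <- seq(0, 5, by = 0.25)
  expect_equal(photon_equivalent_dose(d, 0.1, 0.05, photon_lq(0.1, 0.05)),
               d, tolerance = 1e-12)
  # low-dose limit: D_RBE / D -> alpha_mix / alpha_x
  eps <- 1e-8
  expect_equal(photon_equivalent_dose(eps, 0.5, 0.05,
                                      photon_lq(0.1, 0.05)) / eps,
               5, tolerance = 1e-6)
  # degenerate photon beta
  expect_equal(photon_equivalent_dose(2, 0.5, 0.05, photon_lq(0.2, 0)),
               1.2 / 0.2)
})

test_that("the LQ inversion is strictly monotone in dose and coefficients", {
  ref <- photon_lq(0.1, 0.05)
  d <- seq(0.1, 6, by = 0.1)
  out <- photon_equivalent_dose(d, 0.4, 0.04, ref)
  expect_true(all(diff(out) > 0))
  a <- seq(0.1, 1, by = 0.05)
  expect_true(all(diff(photon_equivalent_dose(2, a, 0.04, ref)) > 0))
  b <- seq(0.01, 0.2, by = 0.01)
  expect_true(all(diff(photon_equivalent_dose(2, 0.4, b, ref)) > 0))
})

test_that("with depth-constant biology the SOBP D_RBE equals the closed form", {
  # constant alpha/beta tables make the mixed-field averages exact constants,
  # so the engine's LEM dose must equal the LQ inversion of the physical dose
  db <- fx_carbon_db()
  for (key in names(db$ions$carbon$entries)) {
    tab <- db$ions$carbon$entries[[key]]$table
    tab[, "alpha"] <- 0.45
    tab[, "beta"] <- 0.04
    db$ions$carbon$entries[[key]]$table <- tab
  }
  g <- fx_water_grid(c(24, 24, 80))
  spots <- data.frame(energy = c(200, 280), x = c(0, 3), y = c(0, -3),
                      n_particles = c(4e7, 3e7))
  plan <- spot_plan("carbon", list(list(
    direction = c(0, 0, 1), isocenter = c(24, 24, 80),
    range_shifter = range_shifter(0, 0, FALSE), spots = spots)))
  sc <- compute_plan(g, db, plan)
  ref <- photon_lq(0.1, 0.05)
  # engine carries sqrt(beta); with constant tables the average is exact
  d_lem <- biological_dose(sc, "lem", ref = ref)
  oracle <- photon_equivalent_dose(sc$dose, 0.45, 0.04, ref)
  expect_equal(as.numeric(d_lem$values), as.numeric(oracle),
               tolerance = 1e-10)
})

test_that("LEM/MKM ratio map and derived scaling factor", {
  dims <- c(4, 4, 2)
  mk <- function(v) voxel_grid(array(v, dims), c(1, 1, 1), c(0, 0, 0), "RSP")
  roi <- roi_mask("ctv", array(TRUE, dims))
  r1 <- lem_mkm_ratio(mk(3), mk(3), scaling = 1, roi = roi)
  expect_true(all(abs(r1$ratio_values - 1) < 1e-12))
  expect_equal(r1$summary$derived_scaling, 1)
  r2 <- lem_mkm_ratio(mk(3), mk(1.5), scaling = 1, roi = roi)
  expect_equal(r2$summary$derived_scaling, 2)
  r3 <- lem_mkm_ratio(mk(4.3), mk(3.9), scaling = 1, roi = roi)
  expect_equal(r3$summary$derived_scaling, 4.3 / 3.9, tolerance = 1e-12)
  expect_error(lem_mkm_ratio(mk(1), mk(1), 1,
                             roi_mask("e", array(FALSE, dims))), "empty")
})
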