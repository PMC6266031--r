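test_that("dose is linear in fluence and additive over spots", {
  db <- fx_proton_db()
  g <- fx_water_grid(c(30, 30, 90))
  spot <- list(energy = 150, x = 0, y = 0, n_particles = 1e8)
  s1 <- compute_spot_dose(g, db, spot, "proton", c(0, 0, 1), c(30, 30, 90))
  s2 <- compute_spot_dose(g, db, spot, "proton", c(0, 0, 1), c(30, 30, 90))
  s2 <- compute_spot_dose(g, db, spot, "proton", c(0, 0, 1), c(30, 30, 90),
                          scores = s2)
  expect_equal(s2$dose, 2 * s1$dose, tolerance = 1e-12)
})

test_that("the on-axis maximum sits at the database Bragg-peak depth", {
  db <- fx_proton_db()
  g <- fx_water_grid(c(30, 30, 90))
  sc <- compute_spot_dose(g, db, list(energy = 150, x = 0, y = 0,
                                      n_particles = 1e8),
                          "proton", c(0, 0, 1), c(30, 30, 90))
  zpk <- (which.max(sc$dose[15, 15, ]) - 0.5) * 2
  expect_lt(abs(zpk - pencilbeam:::.db_entry(db, "proton", 150)$peak_depth),
            2.01)
})

test_that("single-spot dose matches the brute-force kernel oracle", {
  db <- fx_proton_db()
  g <- fx_water_grid(c(40, 40, 40), c(2, 2, 4))
  sc <- compute_spot_dose(g, db, list(energy = 150, x = 0, y = 0,
                                      n_particles = 1e8),
                          "proton", c(0, 0, 1), c(40, 40, 80),
                          config = engine_config(dose_spacing = c(2, 2, 4)))
  sig_air <- fwhm_to_sigma(pencilbeam:::.db_fwhm_air(db, "proton", 150))
  oracle <- bf_spot_dose_water(g, db, 150, 1e8, c(40, 40), sig_air)
  expect_lt(max(abs(sc$dose - oracle)) / max(oracle), 0.005)
})

test_that("plans compose: empty, single-spot and partitioned plans agree", {
  db <- fx_proton_db()
  g <- fx_water_grid(c(30, 30, 90))
  iso <- c(30, 30, 90)
  mkplan <- function(spots) spot_plan("proton", list(list(
    direction = c(0, 0, 1), isocenter = iso,
    range_shifter = range_shifter(0, 0, FALSE), spots = spots)))
  empty <- compute_plan(g, db, mkplan(data.frame(energy = numeric(0),
                                                 x = numeric(0),
                                                 y = numeric(0),
                                                 n_particles = numeric(0))))
  expect_true(all(empty$dose == 0))
  expect_true(all(empty$sum_d_let == 0))
  one <- compute_plan(g, db, mkplan(data.frame(energy = 150, x = 0, y = 0,
                                               n_particles = 1e8)))
  direct <- compute_spot_dose(g, db, list(energy = 150, x = 0, y = 0,
                                          n_particles = 1e8),
                              "proton", c(0, 0, 1), iso)
  expect_equal(one$dose, direct$dose, tolerance = 1e-14)
  spots <- data.frame(energy = c(148, 150, 152, 150),
                      x = c(0, -6, 6, 0), y = c(0, 0, -6, 6),
                      n_particles = c(2e7, 3e7, 1e7, 2e7))
  full <- compute_plan(g, db, mkplan(spots))
  half1 <- compute_plan(g, db, mkplan(spots[1:2, ]))
  half2 <- compute_plan(g, db, mkplan(spots[3:4, ]))
  expect_equal(full$dose, half1$dose + half2$dose, tolerance = 1e-10)
  expect_equal(full$sum_d_let, half1$sum_d_let + half2$sum_d_let,
               tolerance = 1e-10)
})

test_that("plans with energies outside the database are rejected by name", {
  db <- fx_proton_db()
  g <- fx_water_grid(c(20, 20, 40))
  plan <- spot_plan("proton", list(list(
    direction = c(0, 0, 1), isocenter = c(20, 20, 40),
    range_shifter = range_shifter(0, 0, FALSE),
    spots = data.frame(energy = c(150, 210), x = 0, y = 0,
                       n_particles = 1))))
  expect_error(compute_plan(g, db, plan), "beam 1 spot 2")
})

test_that("deposited energy matches the depth-dose integral", {
  db <- fx_proton_db()
  g <- fx_water_grid(c(60, 60, 100))   # wide enough to catch the halo
  sc <- compute_spot_dose(g, db, list(energy = 150, x = 0, y = 0,
                                      n_particles = 1e8),
                          "proton", c(0, 0, 1), c(60, 60, 100))
  edep <- sum(sc$dose) * prod(sc$spacing)
  e <- pencilbeam:::.db_entry(db, "proton", 150)
  zc <- seq(1, 199, by = 2)
  idd <- db_lookup(db, "proton", 150, zc)$idd
  expect_equal(edep, 1e8 * sum(idd * 2), tolerance = 0.01)
})

test_that("an air gap shifts the Bragg peak deeper by its missing WET", {
  db <- fx_proton_db()
  n <- c(30, 30, 100)
  g_w <- fx_water_grid(n)
  v <- array(1, n)
  v[, , 11:20] <- 0.001            # 20 mm air-like slab from z=20 to 40
  g_a <- voxel_grid(v, c(2, 2, 2), c(0, 0, 0), "RSP")
  spot <- list(energy = 150, x = 0, y = 0, n_particles = 1e8)
  sw <- compute_spot_dose(g_w, db, spot, "proton", c(0, 0, 1), c(30, 30, 100))
  sa <- compute_spot_dose(g_a, db, spot, "proton", c(0, 0, 1), c(30, 30, 100))
  shift <- (which.max(sa$dose[15, 15, ]) - which.max(sw$dose[15, 15, ])) * 2
  expect_lte(abs(shift - 20), 2.01)
})

test_that("dose-averaged LET is the dose-weighted mean of contributions", {
  sc <- structure(list(dims = c(2, 1, 1), spacing = c(1, 1, 1),
                       origin = c(0, 0, 0),
                       dose = array(c(4, 0), c(2, 1, 1)),
                       sum_d_let = array(c(1 * 1 + 3 * 3, 0), c(2, 1, 1)),
                       sum_d_alpha = array(0, c(2, 1, 1)),
                       sum_d_sqrtbeta = array(0, c(2, 1, 1)),
                       sum_d_zstar = array(0, c(2, 1, 1))),
                  class = "score_maps")
  lm <- let_d_map(sc)
  expect_equal(lm$values[1, 1, 1], 2.5)   # (1*1 + 3*3)/(1 + 3)
  expect_equal(lm$values[2, 1, 1], 0)     # zero dose -> zero LET
  sc$dose <- array(c(2, 1), c(2, 1, 1))
  sc$sum_d_let <- array(c(2 * 3, 1 * 3), c(2, 1, 1))
  expect_equal(let_d_map(sc)$values[, 1, 1], c(3, 3))
})

test_that("score maps accumulate nothing where dose is zero", {
  db <- fx_proton_db()
  g <- fx_water_grid(c(30, 30, 90))
  sc <- compute_spot_dose(g, db, list(energy = 150, x = 0, y = 0,
                                      n_particles = 1e8),
                          "proton", c(0, 0, 1), c(30, 30, 90))
  zero <- sc$dose == 0
  expect_true(all(sc$sum_d_let[zero] == 0))
  expect_true(all(sc$sum_d_alpha[zero] == 0))
  expect_true(all(sc$sum_d_zstar[zero] == 0))
})
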