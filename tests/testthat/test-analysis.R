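mk_map <- function(v, dims = NULL, spacing = c(2, 2, 2)) {
  if (is.null(dims)) dims <- dim(v) else v <- array(v, dims)
  voxel_grid(v, spacing, c(0, 0, 0), "RSP")
}

test_that("the cumulative DVH steps where the dose does", {
  dims <- c(4, 4, 2)
  roi <- roi_mask("t", array(TRUE, dims))
  h <- dvh(mk_map(2, dims), roi)
  expect_equal(d_metric(h, 50), 2)
  expect_equal(d_metric(h, 2), 2)
  expect_equal(d_metric(h, 98), 2)
  f <- h$curve$volume_fraction
  expect_equal(f[1], 1)
  expect_equal(tail(f, 1), 0)
  # half at 1 Gy, half at 3 Gy -> fraction 0.5 on (1, 3]
  v <- array(rep(c(1, 3), each = 16), dims)
  h2 <- dvh(mk_map(v), roi, bin_width = 0.5)
  at2 <- h2$curve$volume_fraction[h2$curve$dose == 2]
  expect_equal(at2, 0.5)
  expect_true(all(diff(h2$curve$volume_fraction) <= 0))
  expect_error(dvh(mk_map(2, dims), roi_mask("e", array(FALSE, dims))),
               "empty")
})

test_that("D_x follows the stated interpolation convention", {
  v <- array(1:100, c(100, 1, 1))
  h <- dvh(mk_map(v), roi_mask("t", array(TRUE, c(100, 1, 1))))
  expect_equal(d_metric(h, 50), 50.5)
  expect_equal(d_metric(h, 2), 98.5)
  expect_gte(d_metric(h, 2), d_metric(h, 50))
  expect_gte(d_metric(h, 50), d_metric(h, 98))
})

test_that("D_x equals the sort-based oracle on random regions", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(20:400, 1)
    vals <- switch(1 + rep %% 3,
                   rgamma(n, 2, 1), runif(n, 0, 5), rnorm(n, 10, 2))
    x <- runif(1, 1, 99)
    expect_equal(d_metric(vals, x), bf_percentile(vals, x),
                 tolerance = 1e-12)
  }
})

test_that("the DVH integral recovers the mean dose", {
  set.seed(7)
  dims <- c(10, 10, 5)
  v <- array(rgamma(prod(dims), 3, 2), dims)
  h <- dvh(mk_map(v), roi_mask("t", array(TRUE, dims)),
           bin_width = max(v) / 5000)
  int <- sum(h$curve$volume_fraction) * h$bin_width
  expect_equal(int, mean(v), tolerance = 1e-3)
})

test_that("LET metrics reduce correctly", {
  dims <- c(5, 5, 2)
  lm <- let_metrics(mk_map(3, dims), roi_mask("t", array(TRUE, dims)))
  expect_equal(lm$mean, 3)
  expect_equal(lm$let_d2, 3)
  set.seed(1)
  v <- array(rgamma(prod(dims), 2, 1), dims)
  lm2 <- let_metrics(mk_map(v), roi_mask("t", array(TRUE, dims)))
  expect_gte(lm2$let_d2, stats::median(v))
})

test_that("identical distributions give gamma zero and full pass", {
  set.seed(2)
  cx <- 1:14 - 7.5
  v <- array(outer(outer(exp(-cx^2 / 40), exp(-cx^2 / 40)),
                   exp(-cx^2 / 60)), c(14, 14, 14))
  g <- mk_map(v)
  r <- gamma_index(g, g)
  expect_equal(r$pass_rate, 100)
  expect_true(all(r$gamma[!is.na(r$gamma)] < 1e-12))
  # voxels below the threshold are excluded
  expect_true(anyNA(r$gamma))
  expect_equal(sum(!is.na(r$gamma)), r$n_eval)
})

test_that("a uniform 3% offset yields gamma 1.5 in gradient-free regions", {
  u <- mk_map(1, c(10, 10, 10))
  u3 <- mk_map(1.03, c(10, 10, 10))
  r <- gamma_index(u, u3, dta = 2, dose_crit = 2, threshold = 10)
  expect_equal(max(abs(r$gamma - 1.5)), 0, tolerance = 1e-9)
  expect_equal(r$pass_rate, 0)
})

test_that("a 1 mm shift in a linear gradient scores gamma about 0.5", {
  # dose rises linearly along x; shifting by 1 mm with 2 mm DTA gives
  # gamma <= 0.5 plus interpolation error
  nx <- 20
  v <- array(rep((1:nx) / nx, times = 400), c(nx, 20, 1))
  ref <- voxel_grid(v, c(2, 2, 2), c(0, 0, 0), "RSP")
  shift <- array(rep(((1:nx) - 0.5) / nx, times = 400), c(nx, 20, 1))
  ev <- voxel_grid(shift, c(2, 2, 2), c(0, 0, 0), "RSP")
  r <- gamma_index(ref, ev, dta = 2, dose_crit = 2, threshold = 10)
  interior <- r$gamma[5:15, 5:15, 1]
  expect_true(all(interior <= 0.5 + 0.05))
})

test_that("gamma agrees with the dense brute-force search", {
  set.seed(4)
  cx <- 1:8 - 4.5
  v <- array(outer(outer(exp(-cx^2 / 30), exp(-cx^2 / 30)),
                   exp(-cx^2 / 45)), c(8, 8, 8))
  ref <- mk_map(v)
  ev <- mk_map(v * 1.02 + 0.01 * max(v))
  r <- gamma_index(ref, ev, dta = 2, dose_crit = 2, threshold = 10)
  win <- list(4:5, 4:5, 4:5)
  gbf <- bf_gamma(ref$values, ev$values, c(2, 2, 2), dta = 2,
                  crit_abs = 0.02 * max(v), thresh_abs = 0.1 * max(v),
                  step_frac = 20, window = win)
  sel <- !is.na(gbf)
  # the package searches at dta/10, the oracle at dta/20: bounded offset error
  expect_lt(max(abs(r$gamma[sel] - gbf[sel])), 0.06)
})

test_that("the QA statistic follows the chamber protocol arithmetic", {
  dims <- c(10, 10, 10)
  comp <- mk_map(2, dims)
  pts <- expand.grid(x = c(5, 9, 13), y = c(5, 9), z = c(5, 9))
  pts$measured <- 2
  q <- qa_compare(comp, pts)
  expect_equal(q$mean, 0)
  expect_equal(q$sd, 0)
  expect_true(q$verdict)
  # flat field measured 3% high: mean +3% on the max-normalised scale
  pts3 <- pts; pts3$measured <- 2 * 1.03
  q3 <- qa_compare(comp, pts3)
  expect_equal(q3$mean, 0.03, tolerance = 1e-12)
  expect_true(q3$verdict)
  # one +20%-of-max outlier among 12 exact points: mean 1.67%, sd 5.77%, fail
  pts12 <- pts
  pts12$measured <- 2
  pts12$measured[1] <- 2 + 0.20 * 2
  q12 <- qa_compare(comp, pts12)
  expect_equal(q12$n, 12)
  expect_equal(q12$mean, 0.2 / 12, tolerance = 1e-12)
  expect_equal(q12$sd, stats::sd(c(0.2, rep(0, 11))), tolerance = 1e-12)
  expect_equal(round(100 * q12$mean, 2), 1.67)
  expect_equal(round(100 * q12$sd, 2), 5.77)
  expect_false(q12$verdict)
  # a point outside the grid is reported by index
  bad <- rbind(pts, data.frame(x = 100, y = 5, z = 5, measured = 1))
  expect_error(qa_compare(comp, bad), "outside the computed grid: index 13")
})
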