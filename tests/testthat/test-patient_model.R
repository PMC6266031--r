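test_that("HU to RSP conversion honors the calibration anchors", {
  hu <- array(c(0, -1024, 3000, -512, 50), c(5, 1, 1))
  g <- voxel_grid(hu, c(1, 1, 1), value_kind = "HU")
  r <- hu_to_rsp(g)
  cal <- default_hu_calibration()
  expect_identical(r$values[1, 1, 1], 1.0)                     # water anchor
  expect_equal(r$values[2, 1, 1], cal$rsp[1])                  # air endpoint
  expect_equal(r$values[3, 1, 1], cal$rsp[nrow(cal)])
  # midway between the -1024 and -700 nodes -> mean of node RSPs
  gmid <- voxel_grid(array(-862, c(1, 1, 1)), c(1, 1, 1), value_kind = "HU")
  expect_equal(hu_to_rsp(gmid)$values[1, 1, 1],
               mean(cal$rsp[1:2]))
  # out-of-range values clamp (and are reported)
  gout <- voxel_grid(array(5000, c(1, 1, 1)), c(1, 1, 1), value_kind = "HU")
  expect_message(r2 <- hu_to_rsp(gout), "clamped")
  expect_equal(r2$values[1, 1, 1], cal$rsp[nrow(cal)])
})

test_that("raytracing reproduces closed-form chords and WEPL", {
  g <- voxel_grid(array(1, c(10, 10, 50)), c(10, 10, 2), c(0, 0, 0), "RSP")
  r <- raytrace_wepl(g, c(50, 50, -5), c(0, 0, 1))
  expect_equal(sum(r$length), 100, tolerance = 1e-9)
  expect_equal(tail(r$wepl, 1), 100, tolerance = 1e-9)
  g$values[] <- 0.5
  r <- raytrace_wepl(g, c(50, 50, -5), c(0, 0, 1))
  expect_equal(tail(r$wepl, 1), 50, tolerance = 1e-9)
  # diagonal across a single cubic voxel of side 2 mm
  g1 <- voxel_grid(array(1, c(1, 1, 1)), c(2, 2, 2), c(0, 0, 0), "RSP")
  r1 <- raytrace_wepl(g1, c(-1, -1, -1), c(1, 1, 1))
  expect_equal(sum(r1$length), 2 * sqrt(3), tolerance = 1e-9)
  expect_error(raytrace_wepl(g1, c(0, 0, 0), c(0, 0, 0)), "nonzero")
})

test_that("traversal matches a fine-step line integral on random grids", {
  set.seed(42)
  for (rep in 1:5) {
    dm <- sample(8:20, 3, replace = TRUE)
    sp <- runif(3, 0.7, 2.0)
    g <- voxel_grid(array(runif(prod(dm), 0, 2), dm), sp, runif(3, -5, 5),
                    "RSP")
    src <- g$origin - runif(3, 1, 4)
    # aim through the grid interior so the chord is not a corner clip
    center <- g$origin + dm * sp / 2
    dir <- center - src + runif(3, -1, 1)
    r <- raytrace_wepl(g, src, dir)
    w_bf <- bf_wepl(g, src, dir, step = 0.005, tmax = 120)
    expect_equal(tail(r$wepl, 1), w_bf, tolerance = 1.5e-3)
  }
})

test_that("a ray along a voxel boundary is counted once", {
  g <- voxel_grid(array(1, c(4, 4, 10)), c(2, 2, 2), c(0, 0, 0), "RSP")
  r <- raytrace_wepl(g, c(4, 4, -1), c(0, 0, 1))  # x=4 is a voxel boundary
  expect_equal(sum(r$length), 20, tolerance = 1e-9)
  expect_equal(tail(r$wepl, 1), 20, tolerance = 1e-9)
  # every z-slab appears exactly once
  expect_equal(nrow(r), 10)
})

test_that("dose-grid resampling averages exactly and conserves the integral", {
  v <- array(1:16 / 4, c(4, 4, 1))
  g <- voxel_grid(v, c(1, 1, 1), c(0, 0, 0), "RSP")
  same <- resample_to_dose_grid(g, 1)
  expect_equal(same$values, v)
  # 2x2x1 block of (1,1,3,3) -> 2
  vb <- array(c(1, 1, 3, 3), c(2, 2, 1))
  gb <- voxel_grid(vb, c(1, 1, 1), c(0, 0, 0), "RSP")
  merged <- resample_to_dose_grid(gb, c(2, 2, 1))
  expect_equal(as.numeric(merged$values), 2)
  # uniform stays uniform under non-commensurate spacing
  gu <- voxel_grid(array(0.7, c(9, 9, 9)), c(1, 1, 1), c(0, 0, 0), "RSP")
  ru <- resample_to_dose_grid(gu, 2)
  expect_true(all(abs(ru$values - 0.7) < 1e-12))
  # integral over covered volume is conserved
  set.seed(1)
  gr <- voxel_grid(array(runif(27 * 8), c(6, 6, 6)), c(1, 1, 1), c(0, 0, 0),
                   "RSP")
  rr <- resample_to_dose_grid(gr, 1.7)
  cov <- attr(rr, "covered_volume")
  expect_equal(sum(rr$values * cov), sum(gr$values), tolerance = 1e-3)
  expect_error(resample_to_dose_grid(gr, 0.5), ">= CT spacing")
})

test_that("water-tank targets have the prescribed cubic volumes", {
  ph3 <- make_phantom("water_tank", size = c(100, 100, 160),
                      spacing = c(2, 2, 2), target_side = 30,
                      target_depth = 60)
  expect_equal(roi_volume(ph3$rois$target, ph3$grid), 27)
  ph6 <- make_phantom("water_tank", size = c(120, 120, 200),
                      spacing = c(2, 2, 2), target_side = 60,
                      target_depth = 60)
  expect_equal(roi_volume(ph6$rois$target, ph6$grid), 216)
  expect_error(make_phantom("water_tank", size = c(100, 100, 100),
                            target_depth = 90, target_side = 30),
               "beyond")
})

test_that("an air insert reduces WEPL behind it", {
  ph <- make_phantom("slab_with_insert", size = c(100, 100, 150),
                     spacing = c(2, 2, 2))
  rsp <- hu_to_rsp(ph$grid)
  behind_air <- raytrace_wepl(rsp, c(75, 50, -1), c(0, 0, 1))
  behind_bone <- raytrace_wepl(rsp, c(25, 50, -1), c(0, 0, 1))
  expect_lt(tail(behind_air$wepl, 1), 150)
  expect_gt(tail(behind_bone$wepl, 1), 150)
  expect_lt(tail(behind_air$wepl, 1), tail(behind_bone$wepl, 1))
})

test_that("grid and ROI round trip through their text formats", {
  set.seed(5)
  g <- voxel_grid(array(runif(60), c(3, 4, 5)), c(1, 2, 3), c(-1, 0, 1),
                  "RSP")
  base <- file.path(withr::local_tempdir(), "g")
  write_grid(g, base, units = "Gy")
  g2 <- read_grid(base)
  expect_identical(g2$values, g$values)
  expect_equal(g2$spacing, g$spacing)
  expect_identical(attr(g2, "units"), "Gy")
  roi <- roi_mask("t", array(runif(60) > 0.5, c(3, 4, 5)))
  rp <- file.path(withr::local_tempdir(), "roi.json")
  write_roi(roi, rp)
  roi2 <- read_roi(rp)
  expect_identical(roi2$mask, roi$mask)
  expect_identical(roi2$name, "t")
})
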