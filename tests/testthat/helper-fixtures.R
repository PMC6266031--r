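# Shared fixtures (built once per run) and independent brute-force oracles.

.fx <- new.env(parent = emptyenv())

fx_proton_db <- function() {
  if (is.null(.fx$pdb))
    .fx$pdb <- synthesize_proton_database(c(100, 110, 148, 150, 152),
                                          seed = 11)
  .fx$pdb
}

fx_carbon_db <- function() {
  if (is.null(.fx$cdb))
    .fx$cdb <- synthesize_carbon_database(c(115, 200, 280, 400), seed = 12)
  .fx$cdb
}

fx_water_grid <- function(n = c(40, 40, 90), spacing = c(2, 2, 2)) {
  voxel_grid(array(1, n), spacing, c(0, 0, 0), "RSP")
}

fx_one_spot_plan <- function(energy = 150, n_particles = 1e8,
                             iso = c(40, 40, 90), rs = range_shifter(0, 0, FALSE)) {
  spot_plan("proton", list(list(
    direction = c(0, 0, 1), isocenter = iso, range_shifter = rs,
    spots = data.frame(energy = energy, x = 0, y = 0,
                       n_particles = n_particles))))
}

# brute-force WEPL: fine-step sampling of the line integral
bf_wepl <- function(grid, source, direction, step = 0.01, tmax = 500) {
  d <- direction / sqrt(sum(direction^2))
  ts <- seq(0, tmax, by = step)
  pts <- sweep(outer(ts, d), 2, source, "+")
  ij <- floor(sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, "/")) + 1
  dm <- dim(grid$values)
  ok <- ij[, 1] >= 1 & ij[, 1] <= dm[1] & ij[, 2] >= 1 & ij[, 2] <= dm[2] &
    ij[, 3] >= 1 & ij[, 3] <= dm[3]
  sum(grid$values[ij[ok, , drop = FALSE]]) * step
}

# brute-force single-spot dose in uniform water along +z: direct kernel
# evaluation at every voxel center, no lateral cutoff, depth from the
# entrance face
bf_spot_dose_water <- function(grid, db, energy, n_particles, iso_xy,
                               sigma_air, rs_wet = 0, sigma_rs_fun = NULL) {
  dm <- dim(grid$values)
  cx <- grid$origin[1] + (seq_len(dm[1]) - 0.5) * grid$spacing[1]
  cy <- grid$origin[2] + (seq_len(dm[2]) - 0.5) * grid$spacing[2]
  cz <- grid$origin[3] + (seq_len(dm[3]) - 0.5) * grid$spacing[3]
  out <- array(0, dm)
  r2_lat <- outer((cx - iso_xy[1])^2, (cy - iso_xy[2])^2, "+")
  lk <- db_lookup(db, "proton", energy, pmax(cz - grid$origin[3], 0) + rs_wet)
  for (k in seq_len(dm[3])) {
    if (lk$idd[k] <= 0) next
    srs <- if (is.null(sigma_rs_fun)) 0 else sigma_rs_fun(cz[k] - grid$origin[3])
    s <- sqrt(c(lk$s1[k], lk$s2[k], lk$s3[k])^2 + sigma_air^2 + srs^2)
    w <- c(lk$w1[k], lk$w2[k], lk$w3[k])
    out[, , k] <- n_particles * lk$idd[k] *
      triple_gaussian(sqrt(r2_lat), s, w)
  }
  out
}

# sort-based percentile oracle: linear interpolation of the inverse survival
# function through the points (v_(i), (n - i + 0.5)/n)
bf_percentile <- function(values, x) {
  v <- sort(values)
  n <- length(v)
  frac <- (n - seq_len(n) + 0.5) / n        # fraction >= v_(i)
  p <- x / 100
  if (p >= frac[1]) return(v[1])
  if (p <= frac[n]) return(v[n])
  i <- max(which(frac >= p))
  v[i] + (v[i + 1] - v[i]) * (frac[i] - p) / (frac[i] - frac[i + 1])
}

# independent trilinear interpolation at a point (mm)
bf_trilinear <- function(vals, spacing, origin, p) {
  f <- (p - origin) / spacing - 0.5
  d <- dim(vals)
  if (any(f < 0) || any(f > d - 1)) return(NA_real_)
  i0 <- pmin(pmax(floor(f), 0), d - 2)
  a <- f - i0
  acc <- 0
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
    w <- (if (bx) a[1] else 1 - a[1]) * (if (by) a[2] else 1 - a[2]) *
      (if (bz) a[3] else 1 - a[3])
    acc <- acc + w * vals[i0[1] + bx + 1, i0[2] + by + 1, i0[3] + bz + 1]
  }
  acc
}

# vectorised independent trilinear interpolation at many points (rows of P)
bf_trilinear_vec <- function(vals, spacing, origin, P) {
  d <- dim(vals)
  f <- sweep(sweep(P, 2, origin), 2, spacing, "/") - 0.5
  out <- rep(NA_real_, nrow(P))
  ok <- f[, 1] >= 0 & f[, 2] >= 0 & f[, 3] >= 0 &
    f[, 1] <= d[1] - 1 & f[, 2] <= d[2] - 1 & f[, 3] <= d[3] - 1
  if (!any(ok)) return(out)
  ff <- f[ok, , drop = FALSE]
  i0 <- pmin(pmax(floor(ff), 0), matrix(d - 2, nrow(ff), 3, byrow = TRUE))
  a <- ff - i0
  acc <- numeric(nrow(ff))
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
    w <- (if (bx) a[, 1] else 1 - a[, 1]) *
      (if (by) a[, 2] else 1 - a[, 2]) *
      (if (bz) a[, 3] else 1 - a[, 3])
    acc <- acc + w * vals[cbind(i0[, 1] + bx + 1, i0[, 2] + by + 1,
                                i0[, 3] + bz + 1)]
  }
  out[ok] <- acc
  out
}

# brute-force gamma: exhaustive offset enumeration (radius 3*dta, step
# dta/step_frac) with independent interpolation and no early exit; `window`
# (list of index vectors per axis) limits which voxels are evaluated --
# interpolation always sees the full map
bf_gamma <- function(ref, ev, spacing, dta, crit_abs, thresh_abs,
                     step_frac = 10, window = NULL) {
  d <- dim(ref)
  if (is.null(window)) window <- lapply(d, seq_len)
  st <- dta / step_frac
  off1 <- seq(-3 * dta, 3 * dta, by = st)
  offs <- as.matrix(expand.grid(off1, off1, off1))
  offs <- offs[rowSums(offs^2) <= (3 * dta)^2 + 1e-12, , drop = FALSE]
  r2 <- rowSums(offs^2)
  g <- array(NA_real_, d)
  for (iz in window[[3]]) for (iy in window[[2]]) for (ix in window[[1]]) {
    rv <- ref[ix, iy, iz]
    if (rv < thresh_abs) next
    p0 <- (c(ix, iy, iz) - 0.5) * spacing
    e <- bf_trilinear_vec(ev, spacing, c(0, 0, 0),
                          sweep(offs, 2, p0, "+"))
    cand <- r2 / dta^2 + ((e - rv) / crit_abs)^2
    g[ix, iy, iz] <- sqrt(min(cand, na.rm = TRUE))
  }
  g
}

fx_opt_db <- function() {
  if (is.null(.fx$odb))
    .fx$odb <- synthesize_proton_database(seq(120, 160, by = 2), seed = 11)
  .fx$odb
}

# full-scale SOBP study case: 3 cm cubic target, proximal face at 12 cm in
# water, fixed-RBE proton optimization to 2 Gy (RBE) on a 2 mm dose grid
fx_sobp <- function() {
  if (!is.null(.fx$sobp)) return(.fx$sobp)
  db <- synthesize_proton_database(seed = 1)
  ph <- make_phantom("water_tank", size = c(160, 160, 200),
                     spacing = c(2, 2, 2), target_side = 30,
                     target_depth = 120)
  spots <- layout_spots(ph$rois$target, ph$grid, db, "proton",
                        lateral_spacing = 3)
  plan <- optimize_sobp(spots, ph$rois$target, ph$grid, db, "proton",
                        prescription = 2, model = "rbe1.1")
  scores <- compute_plan(ph$grid, db, plan, engine_config(dose_spacing = 2))
  .fx$sobp <- list(db = db, ph = ph, plan = plan, scores = scores,
                   target = roi_on_dose_grid(ph$rois$target, ph$grid,
                                             scores))
  .fx$sobp
}
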