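## Pencil-beam superposition engine. Radiological depth is computed on the
## CT-resolution ray; dose and the dose-weighted accumulators are scored at
## the dose-grid voxel centers. Summation order is fixed (beam, spot,
## sub-beam, voxel-linear) so results are bit-reproducible and independent of
## how a plan is partitioned.

#' Engine configuration
#'
#' @param dose_spacing dose-grid spacing in mm (scalar or length 3); the
#'   clinical defaults are 2 mm (head) and 3 mm (pelvic sites).
#' @param n_splits sub-pencil-beams per spot (1 = no splitting, the water
#'   phantom setting; ~350 for heterogeneous head cases, ~100 pelvic).
#' @param cutoff_sigma lateral cutoff in units of the largest composed
#'   Gaussian sigma (default 3.5, mirroring the splitting bound).
#' @param split_bound truncation bound of the sub-beam grid in sigmas.
#' @return list of class `engine_config`.
#' @export
engine_config <- function(dose_spacing = 2, n_splits = 1,
                          cutoff_sigma = 3.5, split_bound = 3.5) {
  stopifnot(all(dose_spacing > 0), n_splits >= 1, cutoff_sigma > 0)
  structure(list(dose_spacing = rep(dose_spacing, length.out = 3),
                 n_splits = as.integer(n_splits),
                 cutoff_sigma = cutoff_sigma, split_bound = split_bound),
            class = "engine_config")
}

#' Create empty score maps on the dose grid derived from a CT grid
#'
#' @param grid the CT-resolution `voxel_grid`.
#' @param dose_spacing dose-grid spacing in mm (scalar or length 3).
#' @return an object of class `score_maps` holding the physical dose (Gy)
#'   and the dose-weighted accumulators for LET, alpha, sqrt(beta) and
#'   z*_mix on the dose grid (same origin as the CT grid).
#' @export
score_maps_new <- function(grid, dose_spacing = 2) {
  hs <- rep(dose_spacing, length.out = 3)
  ext <- dim(grid$values) * grid$spacing
  nd <- pmax(1L, as.integer(ceiling(ext / hs - 1e-9)))
  z <- function() array(0, nd)
  structure(list(dims = nd, spacing = hs, origin = grid$origin,
                 dose = z(), sum_d_let = z(), sum_d_alpha = z(),
                 sum_d_sqrtbeta = z(), sum_d_zstar = z()),
            class = "score_maps")
}

#' @export
print.score_maps <- function(x, ...) {
  cat(sprintf("<score_maps> %d x %d x %d @ %g x %g x %g mm, max dose %.4g Gy\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing[1], x$spacing[2],
              x$spacing[3], max(x$dose)))
  invisible(x)
}

#' Extract one score map as a voxel grid
#'
#' @param scores a `score_maps`.
#' @param what one of `"dose"`, `"sum_d_let"`, `"sum_d_alpha"`,
#'   `"sum_d_sqrtbeta"`, `"sum_d_zstar"`.
#' @return a `voxel_grid` on the dose grid.
#' @export
score_grid <- function(scores, what = "dose") {
  stopifnot(inherits(scores, "score_maps"), what %in% names(scores))
  voxel_grid(scores[[what]], scores$spacing, scores$origin, "RSP")
}

# deterministic orthonormal transverse basis (u, v) for a beam direction
.beam_basis <- function(d) {
  d <- d / sqrt(sum(d^2))
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(d[2] * ref[3] - d[3] * ref[2],
         d[3] * ref[1] - d[1] * ref[3],
         d[1] * ref[2] - d[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(d = d, u = u, v = v)
}

# per-energy table cache keyed by ion/energy; prepares the deposit table,
# which carries sqrt(beta) so the engine accumulates the Zaider-Rossi
# dose-weighted sqrt(beta) sum
.entry_cache <- function(db) {
  env <- new.env(parent = emptyenv())
  function(ion, energy) {
    key <- paste0(ion, "_", .energy_key(energy))
    if (is.null(env[[key]])) {
      e <- .db_entry(db, ion, energy)
      dt <- e$table
      dt[, "beta"] <- sqrt(dt[, "beta"])
      e$deposit_table <- dt
      env[[key]] <- e
    }
    env[[key]]
  }
}

# Deposit a single (sub-)beam axis. `axis_point` is any point on the axis,
# `sigma_air_kernel` the in-air sigma composed onto the kernel (0 for
# sub-beams of a split spot). Writes into `scores` in place, or into
# `subset_out` (rows given by `subset_map`) when building influence columns.
.deposit_axis <- function(ct_grid, scores, entry, axis_point, basis, n_eff,
                          sigma_air_kernel, theta, rs, cutoff,
                          subset_map = NULL, subset_out = NULL) {
  d <- basis$d
  ext <- dim(ct_grid$values) * ct_grid$spacing
  diagl <- sqrt(sum(ext^2))
  src <- axis_point - d * (diagl + sqrt(sum((axis_point - ct_grid$origin)^2)) + 10)
  ray <- raytrace_wepl(ct_grid, src, d)
  if (nrow(ray) == 0) {
    message("spot axis misses the grid; no dose deposited")
    return(invisible(FALSE))
  }
  t0 <- attr(ray, "t_entry")
  tb <- ray$t_end - t0
  wdt <- min(ct_grid$spacing) / 2
  t_u <- seq(0, max(tb), by = wdt)
  W <- stats::approx(c(0, tb), c(0, ray$wepl), xout = t_u, rule = 2)$y
  mat <- which(c(0, head(ray$wepl, -1)) < ray$wepl - 1e-12)
  t_skin <- if (length(mat)) tb[mat[1]] - ray$length[mat[1]] else Inf
  A <- src + t0 * d
  t_exit <- attr(ray, "t_exit") - t0
  rs_wet <- if (rs$present) rs$wet else 0
  s3max <- max(entry$table[, "s3"])
  rmax <- cutoff * sqrt(s3max^2 + sigma_air_kernel^2 +
                          (theta * (rs$air_gap + t_exit))^2)
  tab <- entry$deposit_table
  if (is.null(tab)) {
    tab <- entry$table
    tab[, "beta"] <- sqrt(tab[, "beta"])
  }
  deposit_spot_cpp(scores$dims, scores$spacing, scores$origin, A, d,
                   W, wdt, t_skin, t_exit, tab,
                   diff(entry$depths[1:2]),
                   n_eff, sigma_air_kernel, theta, rs$air_gap, rs_wet,
                   cutoff, rmax, scores$dose, scores$sum_d_let,
                   scores$sum_d_alpha, scores$sum_d_sqrtbeta,
                   scores$sum_d_zstar, subset_map, subset_out)
  invisible(TRUE)
}

#' Compute the dose of a single spot and accumulate score maps
#'
#' Deposits `n_particles x idd(z_wed) x L(r)` at every dose-grid voxel within
#' the lateral cutoff, where `z_wed` is the water-equivalent depth along the
#' spot axis (raytraced at CT resolution, plus the range-shifter
#' water-equivalent thickness) and `L` the triple-Gaussian kernel with the
#' in-air and range-shifter widths composed in quadrature onto each
#' component. Simultaneously accumulates dose-weighted LET, alpha,
#' sqrt(beta) and z*_mix.
#'
#' @param grid CT-resolution `voxel_grid` (RSP; HU grids are converted with
#'   the database calibration).
#' @param db a `beam_db`.
#' @param spot list or one-row data.frame with `energy` (MeV/u), `x`, `y`
#'   (mm, transverse offsets at the isocenter plane) and `n_particles`;
#'   optional `fwhm_air` overrides the database FWHM-in-air table.
#' @param ion `"proton"` or `"carbon"`.
#' @param direction beam direction (length-3, any norm).
#' @param isocenter isocenter position in mm.
#' @param rs a [range_shifter()].
#' @param scores a `score_maps` to accumulate into (created from `grid` when
#'   `NULL`).
#' @param config an [engine_config()].
#' @return the updated `score_maps` (also modified in place).
#' @export
compute_spot_dose <- function(grid, db, spot, ion = "proton",
                              direction = c(0, 0, 1),
                              isocenter = NULL, rs = range_shifter(0, 0, FALSE),
                              scores = NULL, config = engine_config()) {
  grid <- .as_rsp(grid, db)
  if (is.null(scores)) scores <- score_maps_new(grid, config$dose_spacing)
  if (is.null(isocenter))
    isocenter <- grid$origin + dim(grid$values) * grid$spacing / 2
  basis <- .beam_basis(direction)
  cache <- .entry_cache(db)
  entry <- cache(ion, spot$energy)
  fw <- if (!is.null(spot$fwhm_air) && !is.na(spot$fwhm_air)) spot$fwhm_air
        else .db_fwhm_air(db, ion, spot$energy)
  sigma_air <- fwhm_to_sigma(fw)
  theta <- if (rs$present) .db_rs_theta(db, ion, spot$energy, rs$wet) else 0
  P <- isocenter + spot$x * basis$u + spot$y * basis$v
  .deposit_axis(grid, scores, entry, P, basis, spot$n_particles, sigma_air,
                theta, rs, config$cutoff_sigma)
  scores
}

.as_rsp <- function(grid, db) {
  if (grid$value_kind == "HU") hu_to_rsp(grid, db$hu_calibration) else grid
}

#' Compute the score maps of a full spot-scanning plan
#'
#' Iterates beams, spots and (when `config$n_splits > 1`) sub-pencil beams in
#' a fixed order; the result is a pure sum and therefore independent of how
#' the plan is partitioned.
#'
#' @param grid CT-resolution `voxel_grid` (HU or RSP).
#' @param db a `beam_db`.
#' @param plan a `spot_plan` (see [spot_plan()]).
#' @param config an [engine_config()].
#' @return a `score_maps` on the dose grid.
#' @export
compute_plan <- function(grid, db, plan, config = engine_config()) {
  stopifnot(inherits(plan, "spot_plan"))
  validate_plan(plan, db)
  grid <- .as_rsp(grid, db)
  scores <- score_maps_new(grid, config$dose_spacing)
  cache <- .entry_cache(db)
  for (beam in plan$beams) {
    basis <- .beam_basis(beam$direction)
    rs <- beam$range_shifter
    spots <- beam$spots
    for (si in seq_len(nrow(spots))) {
      sp <- spots[si, ]
      entry <- cache(plan$ion, sp$energy)
      fw <- if (!is.null(sp$fwhm_air) && !is.na(sp$fwhm_air)) sp$fwhm_air
            else .db_fwhm_air(db, plan$ion, sp$energy)
      sigma_air <- fwhm_to_sigma(fw)
      theta <- if (rs$present) .db_rs_theta(db, plan$ion, sp$energy, rs$wet)
               else 0
      P <- beam$isocenter + sp$x * basis$u + sp$y * basis$v
      if (config$n_splits > 1) {
        sub <- split_spot(config$n_splits, sigma_air, config$split_bound)
        s_sub <- attr(sub, "sub_sigma")
        for (k in seq_len(nrow(sub))) {
          Pk <- P + sub$dx[k] * basis$u + sub$dy[k] * basis$v
          .deposit_axis(grid, scores, entry, Pk, basis,
                        sp$n_particles * sub$weight[k], s_sub, theta, rs,
                        config$cutoff_sigma)
        }
      } else {
        .deposit_axis(grid, scores, entry, P, basis, sp$n_particles,
                      sigma_air, theta, rs, config$cutoff_sigma)
      }
    }
  }
  scores
}

#' Dose-averaged LET map
#'
#' `LET_d(v) = sum_d_let(v) / dose(v)` where dose is positive, 0 elsewhere.
#' The restriction of the proton LET to the proton/deuteron/triton component
#' is a property of the database tables, honoured upstream by the generator.
#'
#' @param scores a populated `score_maps`.
#' @return a `voxel_grid` of LET_d in keV/um on the dose grid.
#' @export
let_d_map <- function(scores) {
  stopifnot(inherits(scores, "score_maps"))
  v <- array(0, scores$dims)
  pos <- scores$dose > 0
  v[pos] <- scores$sum_d_let[pos] / scores$dose[pos]
  voxel_grid(v, scores$spacing, scores$origin, "RSP")
}
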