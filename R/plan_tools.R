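## Plan data model and generators: spot-grid layout over a target and a
## dose-ratio spot-weight optimizer producing homogeneous spread-out Bragg
## peaks. The optimizer is deliberately a simple damped fixed point -- its
## job is to produce SOBP test plans, not to replace a treatment planning
## system's constrained optimization.

#' Construct a spot-scanning plan
#'
#' @param ion `"proton"` or `"carbon"`.
#' @param beams list of beams; each beam is a list with `direction`
#'   (length 3), `isocenter` (mm), `range_shifter` (a [range_shifter()]) and
#'   `spots` (data.frame with `energy`, `x`, `y`, `n_particles`, optional
#'   `fwhm_air`).
#' @param prescription prescribed D_RBE per fraction in Gy (RBE), `> 0`.
#' @param fractions number of fractions.
#' @return an object of class `spot_plan`.
#' @export
spot_plan <- function(ion, beams, prescription = 2, fractions = 1L) {
  stopifnot(length(beams) >= 1, prescription > 0, fractions >= 1)
  for (b in beams) {
    stopifnot(is.list(b), length(b$direction) == 3,
              length(b$isocenter) == 3, inherits(b$range_shifter,
                                                 "range_shifter"),
              is.data.frame(b$spots))
    if (any(b$spots$n_particles < 0))
      stop("spot particle numbers must be nonnegative")
  }
  structure(list(ion = ion, beams = beams, prescription = prescription,
                 fractions = as.integer(fractions), schema_version = "1.0"),
            class = "spot_plan")
}

#' @export
print.spot_plan <- function(x, ...) {
  ns <- vapply(x$beams, function(b) nrow(b$spots), integer(1))
  cat(sprintf("<spot_plan %s> %d beam(s), %d spots, prescription %g Gy (RBE)\n",
              x$ion, length(x$beams), sum(ns), x$prescription))
  invisible(x)
}

#' Validate a plan against a beam database
#'
#' @param plan a `spot_plan`.
#' @param db a `beam_db`.
#' @return `plan` invisibly; errors list every offending spot.
#' @export
validate_plan <- function(plan, db) {
  stopifnot(inherits(plan, "spot_plan"))
  slot <- db$ions[[plan$ion]]
  if (is.null(slot))
    stop(sprintf("ion '%s' not present in database", plan$ion))
  rng <- range(slot$energies)
  bad <- character(0)
  for (bi in seq_along(plan$beams)) {
    en <- plan$beams[[bi]]$spots$energy
    out <- which(en < rng[1] - 1e-9 | en > rng[2] + 1e-9)
    if (length(out))
      bad <- c(bad, sprintf("beam %d spot %d (%.6g MeV/u)", bi, out, en[out]))
  }
  if (length(bad))
    stop("spot energies outside database grid: ", paste(bad, collapse = "; "))
  invisible(plan)
}

#' Lay out spots over a target for one beam
#'
#' Energy layers are the database energies whose Bragg peaks fall inside the
#' target's water-equivalent depth extent along the beam axis (evaluated on
#' the central ray), extended one layer proximally and distally. Each layer
#' carries a square lattice of spots covering the target's lateral projection
#' plus a one-sigma margin. Deterministic given its inputs.
#'
#' @param target an `roi_mask` on `grid`, non-empty.
#' @param grid CT-resolution `voxel_grid` (HU or RSP).
#' @param db a `beam_db`.
#' @param ion `"proton"` or `"carbon"`.
#' @param lateral_spacing lattice spacing in mm, `> 0` (default 3).
#' @param direction beam direction.
#' @param isocenter isocenter in mm; defaults to the target centroid.
#' @param rs a [range_shifter()]; its water-equivalent thickness shifts the
#'   usable energy window.
#' @return data.frame of spots (`energy`, `x`, `y`, `n_particles = 1`) plus
#'   attributes `isocenter` and `direction`.
#' @export
layout_spots <- function(target, grid, db, ion, lateral_spacing = 3,
                         direction = c(0, 0, 1), isocenter = NULL,
                         rs = range_shifter(0, 0, FALSE)) {
  if (!any(target$mask)) stop("target region is empty")
  if (lateral_spacing <= 0) stop("lateral_spacing must be positive")
  grid <- .as_rsp(grid, db)
  basis <- .beam_basis(direction)
  idx <- which(target$mask, arr.ind = TRUE)
  ctr <- grid$origin + (colMeans(idx) - 0.5) * grid$spacing
  if (is.null(isocenter)) isocenter <- ctr
  # WET extent of the target along the central axis
  ray <- raytrace_wepl(grid, isocenter - basis$d * 1e4, basis$d)
  if (nrow(ray) == 0) stop("central axis misses the grid")
  t0 <- attr(ray, "t_entry")
  tb <- ray$t_end - t0
  pts <- t(t(idx - 0.5) * grid$spacing) + matrix(grid$origin, nrow(idx), 3,
                                                 byrow = TRUE)
  rel <- sweep(pts, 2, isocenter - basis$d * 1e4)
  tproj <- as.numeric(rel %*% basis$d) - t0
  wet_rng <- range(stats::approx(c(0, tb), c(0, ray$wepl), xout = tproj,
                                 rule = 2)$y)
  rs_wet <- if (rs$present) rs$wet else 0
  slot <- db$ions[[ion]]
  if (is.null(slot)) stop(sprintf("ion '%s' not present in database", ion))
  peaks <- vapply(slot$entries, function(e) e$peak_depth, numeric(1))
  need <- wet_rng + rs_wet
  if (max(peaks) < need[2])
    stop(sprintf(paste0("target WET extent reaches %.1f mm but the deepest ",
                        "database energy peaks at %.1f mm"),
                 need[2], max(peaks)))
  inside <- which(peaks >= need[1] & peaks <= need[2])
  if (!length(inside)) inside <- which.min(abs(peaks - mean(need)))
  lo <- max(1L, min(inside) - 1L)
  hi <- min(length(peaks), max(inside) + 1L)
  energies <- slot$energies[lo:hi]
  # lateral lattice covering the projected target plus one sigma margin
  uproj <- as.numeric(sweep(pts, 2, isocenter) %*% basis$u)
  vproj <- as.numeric(sweep(pts, 2, isocenter) %*% basis$v)
  sigma <- fwhm_to_sigma(.db_fwhm_air(db, ion, stats::median(energies)))
  half_u <- max(abs(uproj)) + sigma
  half_v <- max(abs(vproj)) + sigma
  gu <- seq(-half_u, half_u, by = lateral_spacing)
  gu <- gu - mean(gu)
  gv <- seq(-half_v, half_v, by = lateral_spacing)
  gv <- gv - mean(gv)
  spots <- expand.grid(x = gu, y = gv, energy = energies,
                       KEEP.OUT.ATTRS = FALSE)
  spots <- spots[, c("energy", "x", "y")]
  spots$n_particles <- 1
  attr(spots, "isocenter") <- isocenter
  attr(spots, "direction") <- basis$d
  spots
}

# nearest dose-grid voxel (linear index) to each point, NA when outside
.point_to_voxel <- function(pts, dims, spacing, origin) {
  ij <- floor(sweep(sweep(pts, 2, origin), 2, spacing, "/")) + 1
  ij <- pmin(pmax(ij, 1), matrix(dims, nrow(ij), 3, byrow = TRUE))
  as.integer(ij[, 1] + dims[1] * (ij[, 2] - 1) +
               dims[1] * dims[2] * (ij[, 3] - 1))
}

#' Optimize spot weights to a homogeneous target D_RBE
#'
#' Damped dose-ratio fixed point: each sweep rescales every spot weight by
#' `(prescription / D_RBE at the spot's Bragg-peak voxel)^gamma`, recomputing
#' the mixed-field D_RBE from the (linear) spot-influence accumulators, until
#' the target's median D_RBE is within tolerance of the prescription. The
#' objective `max |D_RBE - prescription|` over the target is non-increasing
#' over accepted sweeps (a sweep that would worsen it is retried with halved
#' damping and the iteration stops when no progress is possible).
#'
#' @param spots data.frame from [layout_spots()] (or equivalent) with the
#'   `isocenter`/`direction` attributes, or a `spot_plan` whose single beam
#'   provides them.
#' @param target an `roi_mask` on `grid`.
#' @param grid CT-resolution `voxel_grid`.
#' @param db a `beam_db`.
#' @param ion `"proton"` or `"carbon"`.
#' @param prescription D_RBE per fraction in Gy (RBE).
#' @param model `"rbe1.1"`, `"lem"` or `"mkm"`.
#' @param rs a [range_shifter()].
#' @param config an [engine_config()]; splitting is not used during
#'   optimization (water-phantom geometry).
#' @param ref,mkm biological parameters for the LEM/MKM models.
#' @param max_iter,tol stopping rule: relative deviation of the target median
#'   D_RBE from the prescription.
#' @param damping exponent `gamma <= 1` of the ratio update.
#' @return a `spot_plan` with optimized `n_particles`, carrying the
#'   convergence `trace` and the influence diagnostics as attributes.
#' @export
optimize_sobp <- function(spots, target, grid, db, ion = "proton",
                          prescription = 2,
                          model = c("rbe1.1", "lem", "mkm"),
                          rs = range_shifter(0, 0, FALSE),
                          config = engine_config(), ref = photon_lq(),
                          mkm = mkm_params(), max_iter = 80, tol = 0.003,
                          damping = 0.7) {
  model <- match.arg(model)
  grid <- .as_rsp(grid, db)
  isocenter <- attr(spots, "isocenter")
  direction <- attr(spots, "direction")
  if (is.null(isocenter) || is.null(direction))
    stop("spots must carry isocenter/direction attributes (see layout_spots)")
  basis <- .beam_basis(direction)
  scores0 <- score_maps_new(grid, config$dose_spacing)
  dims <- scores0$dims; spacing <- scores0$spacing; origin <- scores0$origin

  # rows of the influence matrices: target voxels plus every spot's peak voxel
  tgt_on_dose <- .mask_on_dose_grid(target, grid, dims, spacing, origin)
  tgt_lin <- which(tgt_on_dose)
  if (!length(tgt_lin)) stop("target region is empty on the dose grid")
  cache <- .entry_cache(db)
  nspot <- nrow(spots)
  rs_wet <- if (rs$present) rs$wet else 0
  ray <- raytrace_wepl(grid, isocenter - basis$d * 1e4, basis$d)
  t0 <- attr(ray, "t_entry")
  tb <- ray$t_end - t0
  # control point of each spot: its Bragg-peak position, clamped into the
  # target's bounding box so margin spots and the proximal/distal extension
  # layers are steered by the coverage they provide at the target edge
  tidx <- which(target$mask, arr.ind = TRUE)
  t_lo <- grid$origin + (apply(tidx, 2, min) - 1) * grid$spacing
  t_hi <- grid$origin + apply(tidx, 2, max) * grid$spacing
  peak_pts <- matrix(0, nspot, 3)
  for (i in seq_len(nspot)) {
    pk_wet <- cache(ion, spots$energy[i])$peak_depth - rs_wet
    t_pk <- stats::approx(c(0, ray$wepl), c(0, tb), xout = pk_wet,
                          rule = 2, ties = "ordered")$y
    A <- isocenter - basis$d * 1e4 + t0 * basis$d
    p <- A + t_pk * basis$d + spots$x[i] * basis$u + spots$y[i] * basis$v
    peak_pts[i, ] <- pmin(pmax(p, t_lo + 0.5 * spacing),
                          t_hi - 0.5 * spacing)
  }
  peak_lin <- .point_to_voxel(peak_pts, dims, spacing, origin)
  rows <- sort(unique(c(tgt_lin, peak_lin)))
  smap <- integer(prod(dims)); smap[] <- -1L
  smap[rows] <- seq_along(rows) - 1L
  tgt_rows <- match(tgt_lin, rows)
  peak_rows <- match(peak_lin, rows)

  # influence: columns are per-spot unit-weight scores at the selected rows
  Idose <- matrix(0, length(rows), nspot)
  Iacc <- if (model == "lem") {
    list(alpha = matrix(0, length(rows), nspot),
         sqrtbeta = matrix(0, length(rows), nspot))
  } else if (model == "mkm") {
    list(zstar = matrix(0, length(rows), nspot))
  } else NULL
  for (i in seq_len(nspot)) {
    sub_out <- matrix(0, length(rows), 5)
    entry <- cache(ion, spots$energy[i])
    fw <- .db_fwhm_air(db, ion, spots$energy[i])
    theta <- if (rs$present) .db_rs_theta(db, ion, spots$energy[i], rs$wet)
             else 0
    P <- isocenter + spots$x[i] * basis$u + spots$y[i] * basis$v
    .deposit_axis(grid, scores0, entry, P, basis, 1, fwhm_to_sigma(fw),
                  theta, rs, config$cutoff_sigma,
                  subset_map = smap, subset_out = sub_out)
    Idose[, i] <- sub_out[, 1]
    if (model == "lem") {
      Iacc$alpha[, i] <- sub_out[, 3]
      Iacc$sqrtbeta[, i] <- sub_out[, 4]
    } else if (model == "mkm") {
      Iacc$zstar[, i] <- sub_out[, 5]
    }
  }

  drbe_rows <- function(w) {
    d <- as.numeric(Idose %*% w)
    if (model == "rbe1.1") return(rbe_fixed_1p1(d))
    pos <- d > 0
    out <- numeric(length(d))
    if (model == "lem") {
      am <- ifelse(pos, as.numeric(Iacc$alpha %*% w) / d, 0)
      bm <- ifelse(pos, (as.numeric(Iacc$sqrtbeta %*% w) / d)^2, 0)
      out <- photon_equivalent_dose(d, am, bm, ref)
    } else {
      zs <- ifelse(pos, as.numeric(Iacc$zstar %*% w) / d, 0)
      out <- photon_equivalent_dose(d, mkm$alpha0 + mkm$beta0 * zs, mkm$beta0,
                                    ref)
    }
    out
  }

  w <- rep(1, nspot)
  dr <- drbe_rows(w)
  d50 <- .percentile_sorted(dr[tgt_rows], 50)
  if (d50 > 0) {
    w <- w * prescription / d50          # analytic first guess
    dr <- drbe_rows(w)
  }
  obj <- max(abs(dr[tgt_rows] - prescription))
  trace <- data.frame(iter = 0L,
                      d50 = .percentile_sorted(dr[tgt_rows], 50), obj = obj)
  converged <- FALSE
  it <- 0L
  while (!converged && it < max_iter) {
    it <- it + 1L
    g <- damping
    repeat {
      ratio <- ifelse(dr[peak_rows] > 0, prescription / dr[peak_rows], 1)
      w_new <- w * ratio^g
      dr_new <- drbe_rows(w_new)
      # pin the target median back onto the prescription (exact for the
      # fixed-RBE model, one extra evaluation for the LQ models)
      d50_new <- .percentile_sorted(dr_new[tgt_rows], 50)
      if (d50_new > 0) {
        w_new <- w_new * (prescription / d50_new)
        dr_new <- drbe_rows(w_new)
      }
      obj_new <- max(abs(dr_new[tgt_rows] - prescription))
      if (obj_new <= obj || g < 1e-3) break
      g <- g / 2
    }
    stalled <- obj_new > obj - 2e-4 * prescription
    if (obj_new > obj) {                 # no acceptable step remains
      converged <- abs(tail(trace$d50, 1) - prescription) <= tol * prescription
      break
    }
    w <- w_new; dr <- dr_new; obj <- obj_new
    d50 <- .percentile_sorted(dr[tgt_rows], 50)
    trace <- rbind(trace, data.frame(iter = it, d50 = d50, obj = obj))
    # run until the homogeneity objective stagnates, then require the median
    # to sit within tolerance of the prescription
    converged <- stalled && abs(d50 - prescription) <= tol * prescription
  }
  if (!converged) {
    cond <- structure(class = c("sobp_no_convergence", "error", "condition"),
                      list(message = sprintf(
                        paste0("SOBP optimization did not reach %.3g Gy (RBE) ",
                               "within %d sweeps (last D50 %.4g)"),
                        prescription, max_iter, tail(trace$d50, 1)),
                        call = sys.call(), trace = trace))
    stop(cond)
  }
  out_spots <- spots
  out_spots$n_particles <- w
  plan <- spot_plan(ion, list(list(direction = basis$d, isocenter = isocenter,
                                   range_shifter = rs, spots = out_spots)),
                    prescription = prescription)
  attr(plan, "trace") <- trace
  attr(plan, "model") <- model
  plan
}

#' Transfer a region of interest onto the dose grid of a score map
#'
#' Marks every dose-grid voxel whose center falls inside the CT-grid mask.
#'
#' @param roi an `roi_mask` on the CT grid.
#' @param ct_grid the CT-resolution `voxel_grid` the mask lives on.
#' @param scores a `score_maps` defining the dose grid.
#' @return an `roi_mask` on the dose grid.
#' @export
roi_on_dose_grid <- function(roi, ct_grid, scores) {
  stopifnot(inherits(scores, "score_maps"))
  roi_mask(roi$name, .mask_on_dose_grid(roi, ct_grid, scores$dims,
                                        scores$spacing, scores$origin))
}

# mark dose-grid voxels whose centers fall inside a CT-grid mask
.mask_on_dose_grid <- function(roi, ct_grid, dims, spacing, origin) {
  cx <- origin[1] + (seq_len(dims[1]) - 0.5) * spacing[1]
  cy <- origin[2] + (seq_len(dims[2]) - 0.5) * spacing[2]
  cz <- origin[3] + (seq_len(dims[3]) - 0.5) * spacing[3]
  dct <- dim(ct_grid$values)
  fx <- pmin(pmax(floor((cx - ct_grid$origin[1]) / ct_grid$spacing[1]) + 1, 1), dct[1])
  fy <- pmin(pmax(floor((cy - ct_grid$origin[2]) / ct_grid$spacing[2]) + 1, 1), dct[2])
  fz <- pmin(pmax(floor((cz - ct_grid$origin[3]) / ct_grid$spacing[3]) + 1, 1), dct[3])
  roi$mask[fx, fy, fz, drop = FALSE]
}

# linear interpolation between order statistics with the midpoint plotting
# position (n - i + 0.5)/n: the dose exceeded by x% of the volume
.percentile_sorted <- function(values, x) {
  as.numeric(stats::quantile(values, probs = 1 - x / 100, type = 5,
                             names = FALSE))
}

#' Write a plan to JSON
#'
#' @param plan a `spot_plan`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "spot_plan"))
  beams <- lapply(plan$beams, function(b) {
    sp <- b$spots[, intersect(c("energy", "x", "y", "n_particles",
                                "fwhm_air"), names(b$spots))]
    list(direction = b$direction, isocenter = b$isocenter,
         range_shifter = list(wet = b$range_shifter$wet,
                              air_gap = b$range_shifter$air_gap,
                              present = b$range_shifter$present),
         spots = sp)
  })
  jsonlite::write_json(
    list(schema_version = plan$schema_version, ion = plan$ion,
         prescription = plan$prescription, fractions = plan$fractions,
         beams = beams),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.PLAN_FIELDS <- c("schema_version", "ion", "prescription", "fractions",
                  "beams")
.BEAM_FIELDS <- c("direction", "isocenter", "range_shifter", "spots")
.SPOT_FIELDS <- c("energy", "x", "y", "n_particles", "fwhm_air")

#' Read a plan from JSON
#'
#' Strict: unknown fields are rejected, required fields are checked per spot
#' (errors name the beam and spot index), negative particle numbers fail.
#'
#' @param path JSON file written by [write_plan()] (schema version 1.0).
#' @return a `spot_plan`.
#' @export
read_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- setdiff(names(x), .PLAN_FIELDS)
  if (length(extra))
    stop("unknown plan field(s): ", paste(extra, collapse = ", "))
  miss <- setdiff(.PLAN_FIELDS, names(x))
  if (length(miss))
    stop("missing plan field(s): ", paste(miss, collapse = ", "))
  if (!identical(x$schema_version, "1.0"))
    stop("unsupported plan schema version: ", x$schema_version)
  beams <- x$beams
  if (is.data.frame(beams)) beams <- split(beams, seq_len(nrow(beams)))
  beams <- lapply(seq_along(beams), function(bi) {
    b <- as.list(beams[[bi]])
    if (is.data.frame(b$range_shifter)) b$range_shifter <- as.list(b$range_shifter)
    extra <- setdiff(names(b), .BEAM_FIELDS)
    if (length(extra))
      stop(sprintf("beam %d: unknown field(s) %s", bi,
                   paste(extra, collapse = ", ")))
    sp <- b$spots
    if (is.list(sp) && !is.data.frame(sp)) sp <- as.data.frame(sp)
    if (is.matrix(sp)) sp <- as.data.frame(sp)
    extra <- setdiff(names(sp), .SPOT_FIELDS)
    if (length(extra))
      stop(sprintf("beam %d: unknown spot field(s) %s", bi,
                   paste(extra, collapse = ", ")))
    for (f in c("energy", "x", "y", "n_particles")) {
      if (is.null(sp[[f]]) || any(is.na(sp[[f]])))
        stop(sprintf("beam %d: spot %d is missing field '%s'", bi,
                     if (is.null(sp[[f]])) 1L else which(is.na(sp[[f]]))[1], f))
    }
    if (any(sp$n_particles < 0))
      stop(sprintf("beam %d: negative particle number at spot %d", bi,
                   which(sp$n_particles < 0)[1]))
    rsl <- b$range_shifter
    list(direction = as.numeric(unlist(b$direction)),
         isocenter = as.numeric(unlist(b$isocenter)),
         range_shifter = range_shifter(rsl$wet, rsl$air_gap, rsl$present),
         spots = sp)
  })
  spot_plan(x$ion, beams, prescription = x$prescription,
            fractions = x$fractions)
}
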