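## Synthetic per-energy beam database: analytic Bragg curves, triple-Gaussian
## lateral parameters vs depth, LET_d and mixed-field radiobiological tables.
## The analytic models and their constants are part of this package's
## contract; they emulate the qualitative shapes of facility Monte-Carlo
## tables (single Bragg peak, fragmentation tail for carbon, distal LET/alpha
## maxima) without any transport calculation.

# range-energy power law R = a * E^p (mm, E in MeV/u); the carbon coefficient
# follows the A/Z^2 scaling of stopping power (factor 1/3 vs protons)
.ION_CONST <- list(
  proton = list(a = 0.022, p = 1.77, A = 1, Z = 1, m_MeV = 938.272,
                e_min = 60, e_max = 250),
  carbon = list(a = 0.022 / 3, p = 1.77, A = 12, Z = 6, m_MeV = 931.494,
                e_min = 115, e_max = 400)
)

.MEV_PER_MM_TO_GY_MM2 <- 1.602e-4  # 1 MeV/mm deposited in water, per primary

.TABLE_COLS <- c("idd", "s1", "s2", "s3", "w1", "w2", "w3",
                 "let_d", "alpha", "beta", "zstar")

#' Water range of an ion beam under the package's range-energy power law
#'
#' @param ion `"proton"` or `"carbon"`.
#' @param energy kinetic energy in MeV/u (vectorised).
#' @return range in mm of water.
#' @export
ion_range <- function(ion, energy) {
  k <- .ion_const(ion)
  k$a * energy^k$p
}

.ion_const <- function(ion) {
  ion <- match.arg(ion, c("proton", "carbon"))
  .ION_CONST[[ion]]
}

# power-law stopping dE/dz (MeV/mm) convolved with a Gaussian range-straggling
# kernel, evaluated on `depths`; returns the integrated depth dose in
# Gy*mm^2 per primary
.bragg_idd <- function(ion, energy, depths) {
  k <- .ion_const(ion)
  R0 <- ion_range(ion, energy)
  sigma <- if (ion == "proton") 0.012 * R0^0.935 else
    pmax(0.0045 * R0^0.935, 0.25)
  h <- min(0.25, if (length(depths) > 1) diff(depths[1:2]) else 0.25)
  zf <- seq(0, max(depths) + 5 * sigma, by = h)
  u <- R0 - (zf + h / 2)                       # midpoints avoid the u=0 pole
  S <- ifelse(u > 0, k$A * u^(1 / k$p - 1) / (k$p * k$a^(1 / k$p)), 0)
  m <- ceiling(4 * sigma / h)
  kern <- stats::dnorm(seq(-m, m) * h, sd = sigma) * h
  Spad <- c(numeric(m), S, numeric(m))
  idd_f <- as.numeric(stats::filter(Spad, kern, sides = 2))[(m + 1):(m + length(zf))]
  idd <- stats::approx(zf + h / 2, idd_f, xout = depths, rule = 2)$y
  if (ion == "carbon") {
    # parametric fragmentation tail switched on around the primary range
    pk <- max(idd)
    tail_frac <- 0.12
    idd <- idd + tail_frac * pk * stats::plogis((depths - R0) / 2) *
      exp(-pmax(depths - R0, 0) / 20)
  }
  idd * .MEV_PER_MM_TO_GY_MM2
}

# Highland-flavoured in-water multiple-Coulomb-scattering growth of the core
# sigma; nondecreasing in depth, saturating past the range
.mcs_sigma <- function(ion, R0, depths) {
  s_end <- if (ion == "proton") 0.0205 * R0 else 0.0065 * R0
  u <- pmin(depths / R0, 1)
  s <- s_end * u^1.8
  past <- depths > R0
  s[past] <- s_end * (1 + 0.25 * (depths[past] - R0) / R0)
  s
}

# momentum*velocity (MeV) for kinetic energy T per nucleon
.pv_total <- function(ion, energy) {
  k <- .ion_const(ion)
  k$A * energy * (energy + 2 * k$m_MeV) / (energy + k$m_MeV)
}

# Highland angular spread (rad) for a water-equivalent degrader of `wet` mm
.highland_theta <- function(ion, energy, wet) {
  k <- .ion_const(ion)
  x_over_X0 <- wet / 360.8
  pv <- .pv_total(ion, energy)
  th <- 14.1 * k$Z / pv * sqrt(x_over_X0) * (1 + 0.038 * log(x_over_X0))
  pmax(th, 0)
}

#' Default piecewise-linear HU to relative-stopping-power calibration
#'
#' Nodes at air, lung, adipose, water (HU 0 maps to RSP 1 exactly), soft
#' tissue and bone; covers HU -1024 to 3000.
#'
#' @return data.frame with columns `hu` and `rsp`.
#' @export
default_hu_calibration <- function() {
  data.frame(
    hu  = c(-1024, -700, -98, 0, 100, 1000, 3000),
    rsp = c(0.00102, 0.290, 0.930, 1.000, 1.060, 1.550, 2.400)
  )
}

.make_entry <- function(ion, energy, depth_step, halo_frac) {
  R0 <- ion_range(ion, energy)
  zmax <- R0 + if (ion == "proton") 40 else 70
  depths <- seq(0, zmax, by = depth_step)
  idd <- .bragg_idd(ion, energy, depths)
  mcs <- .mcs_sigma(ion, R0, depths)
  s1 <- sqrt(0.8^2 + mcs^2)
  s2 <- 1.8 * s1 + 1.5
  s3 <- 3.5 * s1 + 5.0
  u <- pmin(depths / R0, 1.3) / 1.3
  w1 <- if (ion == "proton") 0.92 - 0.15 * u else 0.95 - 0.12 * u
  w2 <- halo_frac * (1 - w1)
  w3 <- (1 - halo_frac) * (1 - w1)
  ures <- pmax(R0 - depths, 0)
  if (ion == "proton") {
    let <- 0.3 + 7.7 * (ures + 1)^-0.45
    past <- depths > R0
    let[past] <- let[past][1] * exp(-(depths[past] - R0) / 3) + 0.1
    alpha <- 0.10 + 0.005 * let
    beta <- rep(0.05, length(depths))
    zstar <- 0.1 * let
  } else {
    let <- 10 + 190 * (ures + 1)^-0.45
    past <- depths > R0
    let[past] <- (let[!past][sum(!past)] - 15) * exp(-(depths[past] - R0) / 8) + 15
    alpha <- 0.15 + (1.10 - 0.15) * exp(-ures / 30)
    alpha[past] <- 0.35 + (1.10 - 0.35) * exp(-(depths[past] - R0) / 15)
    beta <- 0.050 + 0.012 * exp(-ures / 40)
    beta[past] <- 0.050 + 0.012 * exp(-(depths[past] - R0) / 30)
    zstar <- 0.3 + (2.8 - 0.3) * exp(-ures / 25)
    zstar[past] <- 0.6 + (2.8 - 0.6) * exp(-(depths[past] - R0) / 15)
  }
  tab <- cbind(idd = idd, s1 = s1, s2 = s2, s3 = s3, w1 = w1, w2 = w2,
               w3 = w3, let_d = let, alpha = alpha, beta = beta,
               zstar = zstar)
  list(ion = ion, energy = energy, depths = depths, table = tab,
       peak_depth = depths[which.max(idd)])
}

.energy_key <- function(energy) sprintf("%.6g", energy)

.synthesize_db <- function(ion, energies, depth_step, seed) {
  k <- .ion_const(ion)
  if (length(energies) == 0 || any(!is.finite(energies)))
    stop("energies must be a non-empty finite numeric vector")
  if (any(energies < k$e_min | energies > k$e_max))
    stop(sprintf("%s energies must lie within [%g, %g] MeV/u", ion,
                 k$e_min, k$e_max))
  if (depth_step <= 0) stop("depth_step must be > 0")
  energies <- sort(unique(energies))
  rng <- .with_seed(seed, {
    list(halo = stats::runif(1, 0.65, 0.75),
         fwhm_jit = stats::runif(length(energies), -0.02, 0.02))
  })
  entries <- lapply(energies, .make_entry, ion = ion,
                    depth_step = depth_step, halo_frac = rng$halo)
  names(entries) <- .energy_key(energies)
  fwhm0 <- if (ion == "proton") 6 + 1200 / energies else 3.5 + 350 / energies
  db <- list(
    ions = setNames(list(list(energies = energies, entries = entries)), ion),
    fwhm_air = data.frame(ion = ion, energy = energies,
                          fwhm = fwhm0 * (1 + rng$fwhm_jit)),
    rs_widening = data.frame(ion = ion, energy = energies,
                             theta = .highland_theta(ion, energies, 30)),
    hu_calibration = default_hu_calibration(),
    rs_reference_wet = 30,
    depth_step = depth_step,
    seed = seed
  )
  class(db) <- "beam_db"
  validate_beam_database(db)
  db
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthesize a proton beam database
#'
#' Builds the complete depth-dependent database the dose engine consumes:
#' integrated depth dose from a power-law stopping model convolved with
#' Gaussian range straggling, triple-Gaussian lateral parameters with a
#' Highland-based scattering growth, an LET_d table (restricted by
#' construction to the proton/deuteron/triton component) and benign LQ
#' tables (the proton biological path applies a fixed RBE and never reads
#' them). Also carries the FWHM-in-air table, the range-shifter widening
#' table and the default HU calibration.
#'
#' @param energies beam energies in MeV, within \[60, 250\].
#' @param depth_step depth grid step in mm (default 0.5).
#' @param seed integer seed for the small emulated measurement scatter in the
#'   FWHM-in-air table and the halo weight split.
#' @return an object of class `beam_db`.
#' @examples
#' db <- synthesize_proton_database(c(100, 150), seed = 1)
#' db_lookup(db, "proton", 150, 50)
#' @export
synthesize_proton_database <- function(energies = seq(70, 230, by = 2),
                                       depth_step = 0.5, seed = 1L) {
  .synthesize_db("proton", energies, depth_step, seed)
}

#' Synthesize a carbon-ion beam database
#'
#' As [synthesize_proton_database()], plus a parametric fragmentation tail
#' beyond the Bragg peak and carbon radiobiological tables: dose-averaged
#' LEM alpha/beta and the MKM saturation-corrected specific energy z*_mix,
#' all rising into the peak with a distal maximum, with entrance alpha a
#' decreasing function of residual range.
#'
#' @param energies beam energies in MeV/u, within \[115, 400\].
#' @inheritParams synthesize_proton_database
#' @return an object of class `beam_db`.
#' @export
synthesize_carbon_database <- function(energies = seq(120, 400, by = 5),
                                       depth_step = 0.5, seed = 1L) {
  .synthesize_db("carbon", energies, depth_step, seed)
}

#' Validate a beam database against its structural invariants
#'
#' Checks completeness of every entry, weight normalisation, sigma ordering
#' and monotonicity, positivity, and that peak depth increases with energy.
#'
#' @param db a `beam_db`.
#' @param context optional label (e.g. a file name) used in error messages.
#' @return `db`, invisibly; errors describe the offending entry and row.
#' @export
validate_beam_database <- function(db, context = NULL) {
  where <- function(msg, ...) {
    pre <- if (is.null(context)) "" else paste0(context, ": ")
    stop(pre, sprintf(msg, ...), call. = FALSE)
  }
  if (!all(c("ions", "fwhm_air", "rs_widening", "hu_calibration") %in% names(db)))
    where("database is missing top-level tables")
  for (ion in names(db$ions)) {
    slot <- db$ions[[ion]]
    if (is.unsorted(slot$energies, strictly = TRUE))
      where("%s energy grid is not strictly increasing", ion)
    peaks <- numeric(0)
    for (key in names(slot$entries)) {
      e <- slot$entries[[key]]
      tab <- e$table
      if (!all(.TABLE_COLS %in% colnames(tab)))
        where("%s %s MeV: missing columns", ion, key)
      if (is.unsorted(e$depths, strictly = TRUE))
        where("%s %s MeV: depth grid not strictly increasing", ion, key)
      if (any(tab < -1e-12))
        where("%s %s MeV: negative table values (first at row %d)",
              ion, key, which(apply(tab < -1e-12, 1, any))[1])
      wsum <- tab[, "w1"] + tab[, "w2"] + tab[, "w3"]
      bad <- which(abs(wsum - 1) > 1e-9)
      if (length(bad))
        where("%s %s MeV: lateral weights do not sum to 1 at row %d (sum %.6g)",
              ion, key, bad[1], wsum[bad[1]])
      if (any(tab[, "s1"] > tab[, "s2"] + 1e-12) ||
          any(tab[, "s2"] > tab[, "s3"] + 1e-12))
        where("%s %s MeV: sigma ordering violated", ion, key)
      if (any(diff(tab[, "s1"]) < -1e-9))
        where("%s %s MeV: sigma1 decreases with depth", ion, key)
      ipk <- which.max(tab[, "idd"])
      if (tab[length(e$depths), "idd"] >= 0.05 * tab[ipk, "idd"])
        where("%s %s MeV: depth dose does not fall below 5%% of peak", ion, key)
      peaks <- c(peaks, e$depths[ipk])
    }
    if (is.unsorted(peaks, strictly = TRUE))
      where("%s: Bragg-peak depth not monotone in energy", ion)
  }
  invisible(db)
}

#' @export
print.beam_db <- function(x, ...) {
  cat("<beam_db>\n")
  for (ion in names(x$ions)) {
    e <- x$ions[[ion]]$energies
    cat(sprintf("  %s: %d energies, %.6g - %.6g MeV/u, depth step %g mm\n",
                ion, length(e), min(e), max(e), x$depth_step))
  }
  invisible(x)
}

# full depth tables at an arbitrary energy; off-grid energies are linearly
# blended between the bracketing entries after aligning their depth axes on
# the Bragg-peak position (avoids the double-peak artifact of naive blending)
.db_entry <- function(db, ion, energy) {
  slot <- db$ions[[ion]]
  if (is.null(slot))
    stop(sprintf("ion '%s' not present in database", ion))
  eg <- slot$energies
  if (energy < min(eg) - 1e-9 || energy > max(eg) + 1e-9)
    stop(sprintf("energy %g outside tabulated grid [%g, %g] for %s",
                 energy, min(eg), max(eg), ion))
  hit <- which(abs(eg - energy) < 1e-6)
  if (length(hit)) return(slot$entries[[hit[1]]])
  i2 <- findInterval(energy, eg) + 1L
  i1 <- i2 - 1L
  e1 <- slot$entries[[i1]]; e2 <- slot$entries[[i2]]
  f <- (energy - eg[i1]) / (eg[i2] - eg[i1])
  p1 <- e1$peak_depth; p2 <- e2$peak_depth
  pk <- (1 - f) * p1 + f * p2
  zmax <- pk + max(max(e1$depths) - p1, max(e2$depths) - p2)
  depths <- seq(0, zmax, by = db$depth_step)
  sample_shift <- function(e, pshift) {
    z <- depths - pk + pshift
    vapply(.TABLE_COLS, function(cn) {
      # idd/let vanish beyond the table end but clamp at the entrance
      rule <- if (cn %in% c("idd", "let_d")) c(2L, 1L) else c(2L, 2L)
      v <- stats::approx(e$depths, e$table[, cn], xout = z, rule = rule)$y
      v[is.na(v)] <- 0
      v
    }, numeric(length(depths)))
  }
  tab <- (1 - f) * sample_shift(e1, p1) + f * sample_shift(e2, p2)
  colnames(tab) <- .TABLE_COLS
  list(ion = ion, energy = energy, depths = depths, table = tab,
       peak_depth = depths[which.max(tab[, "idd"])])
}

#' Look up beam data at a given depth
#'
#' Linear interpolation in depth; for untabulated energies the bracketing
#' entries are blended after aligning depth axes on the Bragg-peak position.
#' Beyond the last tabulated depth the integrated depth dose and LET_d are
#' zero while lateral and biological values hold their last tabulated value.
#'
#' @param db a `beam_db`.
#' @param ion `"proton"` or `"carbon"`.
#' @param energy MeV/u, inside the tabulated grid.
#' @param depth water-equivalent depth in mm (vectorised), `>= 0`.
#' @return data.frame with one row per depth: `idd`, `s1..s3`, `w1..w3`,
#'   `let_d`, `alpha`, `beta`, `zstar`.
#' @export
db_lookup <- function(db, ion, energy, depth) {
  stopifnot(all(depth >= 0))
  e <- .db_entry(db, ion, energy)
  out <- vapply(.TABLE_COLS, function(cn) {
    rule <- if (cn %in% c("idd", "let_d")) c(2L, 1L) else c(2L, 2L)
    v <- stats::approx(e$depths, e$table[, cn], xout = depth, rule = rule)$y
    v[is.na(v)] <- 0
    v
  }, numeric(length(depth)))
  out <- as.data.frame(matrix(out, nrow = length(depth),
                              dimnames = list(NULL, .TABLE_COLS)))
  out
}

# FWHM in air at isocenter (mm) for a spot energy
.db_fwhm_air <- function(db, ion, energy) {
  t <- db$fwhm_air[db$fwhm_air$ion == ion, ]
  if (!nrow(t)) stop(sprintf("no FWHM-in-air table for ion '%s'", ion))
  stats::approx(t$energy, t$fwhm, xout = energy, rule = 2)$y
}

# range-shifter angular spread (rad) at a spot energy, scaled from the
# tabulated reference water-equivalent thickness by the Highland sqrt(x) law
.db_rs_theta <- function(db, ion, energy, wet) {
  t <- db$rs_widening[db$rs_widening$ion == ion, ]
  if (!nrow(t)) stop(sprintf("no range-shifter table for ion '%s'", ion))
  th <- stats::approx(t$energy, t$theta, xout = energy, rule = 2)$y
  th * sqrt(wet / db$rs_reference_wet)
}
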