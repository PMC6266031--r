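## Evaluation suite: cumulative DVH / LET-volume histograms, D_x metrics,
## global gamma-index analysis and the multi-chamber patient-QA statistic.

#' Cumulative dose-volume histogram over a region of interest
#'
#' Exact evaluation on the sorted voxel values; binning is applied only for
#' export. The curve starts at volume fraction 1, is non-increasing, and
#' reaches 0 beyond the maximum value.
#'
#' @param map a `voxel_grid` (dose, D_RBE or LET map).
#' @param roi an `roi_mask` on the same grid, non-empty.
#' @param bin_width bin width for the exported curve (same units as the map);
#'   default 1/500 of the maximum value.
#' @return an object of class `dvh_curve` holding the sorted values and the
#'   binned export curve (`dose`, `volume_fraction`).
#' @export
dvh <- function(map, roi, bin_width = NULL) {
  stopifnot(inherits(map, "voxel_grid"), inherits(roi, "roi_mask"))
  if (!all(dim(map$values) == dim(roi$mask)))
    stop("map and region of interest are on different grids")
  if (!any(roi$mask)) stop("region of interest is empty")
  vals <- sort(as.numeric(map$values[roi$mask]))
  vmax <- max(vals)
  if (is.null(bin_width)) bin_width <- if (vmax > 0) vmax / 500 else 1
  edges <- seq(0, vmax + bin_width, by = bin_width)
  frac <- vapply(edges, function(d) mean(vals >= d), numeric(1))
  structure(list(values = vals, n = length(vals),
                 curve = data.frame(dose = edges, volume_fraction = frac),
                 bin_width = bin_width),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %d voxels, D50 %.4g, D2 %.4g, D98 %.4g\n",
              x$n, d_metric(x, 50), d_metric(x, 2), d_metric(x, 98)))
  invisible(x)
}

#' @export
plot.dvh_curve <- function(x, ..., xlab = "dose", ylab = "volume fraction") {
  plot(x$curve$dose, x$curve$volume_fraction, type = "s", xlab = xlab,
       ylab = ylab, ylim = c(0, 1), ...)
  invisible(x)
}

#' D_x: the value received by x% of the volume
#'
#' Linear interpolation between order statistics with the midpoint plotting
#' position `(n - i + 0.5)/n` (the convention is fixed here; planning systems
#' differ). Guarantees `D_2 >= D_50 >= D_98`.
#'
#' @param curve a `dvh_curve` (or numeric vector of voxel values).
#' @param x percentage of the volume, `0 < x < 100`.
#' @return the interpolated value.
#' @export
d_metric <- function(curve, x) {
  if (x <= 0 || x >= 100) stop("x must be strictly between 0 and 100")
  vals <- if (inherits(curve, "dvh_curve")) curve$values else
    sort(as.numeric(curve))
  .percentile_sorted(vals, x)
}

#' Mean LET and LET_d,2 over a region of interest
#'
#' @param let_map a `voxel_grid` of LET_d in keV/um.
#' @param roi an `roi_mask` on the same grid.
#' @return list with `mean` and `let_d2` (the LET_d received by 2% of the
#'   volume).
#' @export
let_metrics <- function(let_map, roi) {
  h <- dvh(let_map, roi)
  list(mean = mean(h$values), let_d2 = d_metric(h, 2))
}

#' Global gamma-index comparison of two dose distributions
#'
#' Globally normalised to the maximum of the reference. For each reference
#' voxel at or above the low-dose threshold, the evaluated distribution is
#' searched over a sphere of radius `3 x dta` at step `dta/10` with trilinear
#' interpolation:
#' `gamma = min sqrt(dr^2/dta^2 + dD^2/(crit x max_ref)^2)`.
#' The pass rate counts evaluated voxels with `gamma <= 1`.
#'
#' @param reference,evaluated `voxel_grid`s on the same grid.
#' @param dta distance-to-agreement criterion in mm (default 2).
#' @param dose_crit dose-difference criterion in percent of the reference
#'   maximum (default 2).
#' @param threshold low-dose threshold in percent of the reference maximum
#'   (default 10); voxels below it are excluded from the pass rate.
#' @return an object of class `gamma_result` with the gamma map (`NA` below
#'   threshold), the pass rate in percent, the number of evaluated voxels and
#'   the criteria.
#' @export
gamma_index <- function(reference, evaluated, dta = 2, dose_crit = 2,
                        threshold = 10) {
  stopifnot(inherits(reference, "voxel_grid"),
            inherits(evaluated, "voxel_grid"),
            all(dim(reference$values) == dim(evaluated$values)),
            dta > 0, dose_crit > 0)
  maxref <- max(reference$values)
  if (maxref <= 0) stop("reference distribution is empty")
  thr <- threshold / 100 * maxref
  if (all(reference$values < thr))
    stop("all reference voxels lie below the low-dose threshold")
  res <- gamma_index_cpp(dim(reference$values), reference$spacing,
                         as.numeric(reference$values),
                         as.numeric(evaluated$values), dta,
                         dose_crit / 100 * maxref, thr)
  gmap <- array(res$gamma, dim(reference$values))
  structure(list(gamma = gmap, pass_rate = 100 * res$n_pass / res$n_eval,
                 n_eval = res$n_eval,
                 criteria = list(dta = dta, dose_crit = dose_crit,
                                 threshold = threshold)),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm (threshold %g%%): pass rate %.1f%% over %d voxels\n",
              x$criteria$dose_crit, x$criteria$dta, x$criteria$threshold,
              x$pass_rate, x$n_eval))
  invisible(x)
}

# trilinear interpolation of a grid map at arbitrary points (mm); NA outside
.trilinear <- function(grid, pts) {
  d <- dim(grid$values)
  f <- sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, "/") - 0.5
  out <- rep(NA_real_, nrow(pts))
  ok <- f[, 1] >= 0 & f[, 2] >= 0 & f[, 3] >= 0 &
    f[, 1] <= d[1] - 1 & f[, 2] <= d[2] - 1 & f[, 3] <= d[3] - 1
  if (!any(ok)) return(out)
  f0 <- pmin(floor(f[ok, , drop = FALSE]), matrix(d - 2, sum(ok), 3,
                                                  byrow = TRUE))
  f0 <- pmax(f0, 0)
  a <- f[ok, , drop = FALSE] - f0
  i0 <- f0 + 1
  val <- numeric(sum(ok))
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
    w <- (if (bx) a[, 1] else 1 - a[, 1]) *
         (if (by) a[, 2] else 1 - a[, 2]) *
         (if (bz) a[, 3] else 1 - a[, 3])
    val <- val + w * grid$values[cbind(i0[, 1] + bx, i0[, 2] + by,
                                       i0[, 3] + bz)]
  }
  out[ok] <- val
  out
}

#' Patient-QA point comparison statistic
#'
#' Per-point differences `(measured - calculated) / max(calculated field)`,
#' their mean and sample standard deviation (n-1 denominator), and the
#' protocol verdict: pass when `|mean| <= 5%` and `sd < 5%`.
#'
#' @param computed a `voxel_grid` of calculated dose.
#' @param points data.frame with chamber positions `x`, `y`, `z` (mm) and
#'   `measured` dose (Gy); the clinical protocol uses 12 chambers.
#' @return an object of class `qa_stat` with per-point differences
#'   (unitless fractions), `mean`, `sd` and `verdict`.
#' @export
qa_compare <- function(computed, points) {
  stopifnot(inherits(computed, "voxel_grid"),
            all(c("x", "y", "z", "measured") %in% names(points)),
            nrow(points) >= 1)
  pts <- as.matrix(points[, c("x", "y", "z")])
  calc <- .trilinear(computed, pts)
  if (anyNA(calc))
    stop("point(s) outside the computed grid: index ",
         paste(which(is.na(calc)), collapse = ", "))
  dmax <- max(computed$values)
  if (dmax <= 0) stop("computed field is empty")
  diffs <- (points$measured - calc) / dmax
  m <- mean(diffs)
  s <- if (length(diffs) > 1) stats::sd(diffs) else 0
  structure(list(differences = diffs, mean = m, sd = s,
                 n = length(diffs),
                 verdict = (abs(m) <= 0.05) && (s < 0.05),
                 calculated = calc),
            class = "qa_stat")
}

#' @export
print.qa_stat <- function(x, ...) {
  cat(sprintf("<qa_stat> %d points: mean %.2f%%, sd %.2f%% -> %s\n", x$n,
              100 * x$mean, 100 * x$sd, if (x$verdict) "PASS" else "FAIL"))
  invisible(x)
}
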