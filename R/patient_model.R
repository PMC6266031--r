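## Voxel phantom / CT-like grid, HU -> relative stopping power conversion,
## water-equivalent-path-length raytracing and dose-grid resampling.
##
## Conventions (fixed to avoid half-voxel drift): right-handed coordinates in
## mm, 0-based voxel indices in C++ (1-based in R outputs), the grid origin is
## the corner of voxel (1,1,1), voxel extents are half-open [lower, upper),
## voxel centers sit at origin + (i - 0.5) * spacing.

#' Construct a voxel grid
#'
#' @param values 3-D numeric array (nx x ny x nz), x varying fastest.
#' @param spacing voxel spacing in mm, length-3, all `> 0`.
#' @param origin position in mm of the corner of voxel (1,1,1).
#' @param value_kind `"HU"` or `"RSP"`.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing, origin = c(0, 0, 0),
                       value_kind = c("HU", "RSP")) {
  value_kind <- match.arg(value_kind)
  stopifnot(is.array(values), length(dim(values)) == 3,
            length(spacing) == 3, all(spacing > 0), length(origin) == 3,
            all(is.finite(values)))
  if (value_kind == "RSP" && any(values < 0))
    stop("relative stopping power must be nonnegative")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), value_kind = value_kind),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid %s> %d x %d x %d voxels, spacing %g x %g x %g mm\n",
              x$value_kind, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

# voxel-center coordinates along one axis
.grid_centers <- function(grid, axis) {
  n <- dim(grid$values)[axis]
  grid$origin[axis] + (seq_len(n) - 0.5) * grid$spacing[axis]
}

#' Construct a named binary region-of-interest mask
#'
#' @param name label of the region.
#' @param mask logical 3-D array on the grid it refers to.
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(name, mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  structure(list(name = name, mask = mask), class = "roi_mask")
}

#' Volume of a region of interest in cm^3
#'
#' @param roi an `roi_mask`.
#' @param grid the `voxel_grid` the mask lives on.
#' @return volume in cm^3 (voxel count times voxel volume).
#' @export
roi_volume <- function(roi, grid) {
  stopifnot(all(dim(roi$mask) == dim(grid$values)))
  sum(roi$mask) * prod(grid$spacing) / 1000
}

#' Convert an HU grid to relative stopping power
#'
#' Per-voxel linear interpolation on a piecewise-linear calibration curve.
#' HU = 0 maps to RSP = 1 exactly with the default calibration. Values
#' outside the node range are clamped to the end values (reported once).
#'
#' @param grid a `voxel_grid` with `value_kind = "HU"`.
#' @param calibration data.frame with strictly increasing `hu` covering
#'   \[-1024, 3000\] and the corresponding `rsp`.
#' @return a `voxel_grid` with `value_kind = "RSP"`.
#' @export
hu_to_rsp <- function(grid, calibration = default_hu_calibration()) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (grid$value_kind != "HU") stop("grid does not hold HU values")
  if (is.unsorted(calibration$hu, strictly = TRUE))
    stop("calibration nodes must be strictly increasing in HU")
  if (min(calibration$hu) > -1024 || max(calibration$hu) < 3000)
    stop("calibration must cover HU [-1024, 3000]")
  v <- grid$values
  n_out <- sum(v < min(calibration$hu) | v > max(calibration$hu))
  if (n_out > 0)
    message(sprintf("hu_to_rsp: %d voxel(s) outside calibration range clamped",
                    n_out))
  rsp <- stats::approx(calibration$hu, calibration$rsp, xout = as.numeric(v),
                       rule = 2)$y
  voxel_grid(array(rsp, dim(v)), grid$spacing, grid$origin, "RSP")
}

#' Trace a ray through an RSP grid and accumulate water-equivalent path length
#'
#' Exact Siddon-style voxel traversal at the grid's own resolution with the
#' half-open voxel convention. The summed geometric lengths equal the chord
#' length of the ray inside the grid; cumulative WEPL is the prefix sum of
#' geometric length times RSP.
#'
#' @param grid a `voxel_grid` with `value_kind = "RSP"`.
#' @param source ray origin in mm (length 3).
#' @param direction direction vector (length 3, need not be unit; zero fails).
#' @return data.frame with 1-based voxel indices `ix, iy, iz`, the geometric
#'   `length` (mm) in each voxel, cumulative `wepl` (mm) and the distance
#'   `t_end` from `source` to each segment end. Attributes `t_entry` and
#'   `t_exit` give the chord parameters; zero rows if the ray misses the grid.
#' @export
raytrace_wepl <- function(grid, source, direction) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (grid$value_kind != "RSP") stop("raytracing needs an RSP grid")
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("ray direction must be nonzero")
  d <- direction / nrm
  res <- raytrace_wepl_cpp(dim(grid$values), grid$spacing, grid$origin,
                           as.numeric(grid$values), as.numeric(source),
                           as.numeric(d))
  if (res$n == 0) {
    out <- data.frame(ix = integer(0), iy = integer(0), iz = integer(0),
                      length = numeric(0), wepl = numeric(0),
                      t_end = numeric(0))
    attr(out, "t_entry") <- NA_real_
    attr(out, "t_exit") <- NA_real_
    return(out)
  }
  out <- data.frame(ix = res$vox[, 1] + 1L, iy = res$vox[, 2] + 1L,
                    iz = res$vox[, 3] + 1L, length = res$length,
                    wepl = res$wepl, t_end = res$t_end)
  attr(out, "t_entry") <- res$t_entry
  attr(out, "t_exit") <- res$t_exit
  out
}

# per-axis interval-overlap matrix between source voxel edges and target
# voxel edges (rows: target, cols: source), lengths in mm
.overlap_matrix <- function(n_src, h_src, n_dst, h_dst) {
  M <- matrix(0, n_dst, n_src)
  for (j in seq_len(n_dst)) {
    lo <- (j - 1) * h_dst; hi <- j * h_dst
    i0 <- max(1L, floor(lo / h_src) + 1L)
    i1 <- min(n_src, ceiling(hi / h_src))
    for (i in seq.int(i0, i1)) {
      ov <- min(hi, i * h_src) - max(lo, (i - 1) * h_src)
      if (ov > 1e-12) M[j, i] <- ov
    }
  }
  M
}

#' Resample a map from the CT grid onto a coarser dose grid
#'
#' Volume-weighted averaging with exact box overlap: each dose-grid voxel
#' value is the mean of the CT-grid samples it contains, weighted by overlap
#' volume, so the total integral (value times covered volume) is conserved.
#'
#' @param grid a `voxel_grid` (any value kind) or a `score map` array wrapped
#'   in a `voxel_grid`.
#' @param dose_spacing target spacing in mm (scalar or length 3), at least the
#'   CT spacing on every axis.
#' @return a `voxel_grid` on the dose grid (same origin); attribute
#'   `covered_volume` holds the per-voxel covered volume in mm^3.
#' @export
resample_to_dose_grid <- function(grid, dose_spacing) {
  stopifnot(inherits(grid, "voxel_grid"))
  hs <- rep(dose_spacing, length.out = 3)
  if (any(hs < grid$spacing - 1e-9))
    stop("dose_spacing must be >= CT spacing on every axis")
  d <- dim(grid$values)
  ext <- d * grid$spacing
  nd <- pmax(1L, as.integer(ceiling(ext / hs - 1e-9)))
  Ms <- lapply(1:3, function(a) .overlap_matrix(d[a], grid$spacing[a],
                                                nd[a], hs[a]))
  # contract axis by axis: numerator carries value * overlap volume
  v <- grid$values
  # axis 1
  v <- array(Ms[[1]] %*% matrix(v, d[1], d[2] * d[3]), c(nd[1], d[2], d[3]))
  # axis 2
  v <- aperm(array(Ms[[2]] %*% matrix(aperm(v, c(2, 1, 3)), d[2],
                                      nd[1] * d[3]),
                   c(nd[2], nd[1], d[3])), c(2, 1, 3))
  # axis 3
  v <- aperm(array(Ms[[3]] %*% matrix(aperm(v, c(3, 1, 2)), d[3],
                                      nd[1] * nd[2]),
                   c(nd[3], nd[1], nd[2])), c(2, 3, 1))
  covx <- rowSums(Ms[[1]]); covy <- rowSums(Ms[[2]]); covz <- rowSums(Ms[[3]])
  cov <- outer(outer(covx, covy), covz)   # covered volume per dose voxel
  out <- voxel_grid(v / cov, hs, grid$origin,
                    if (grid$value_kind == "RSP") "RSP" else grid$value_kind)
  attr(out, "covered_volume") <- cov
  out
}

#' Build a test phantom with region-of-interest masks
#'
#' * `water_tank`: uniform RSP-1 grid with a cubic target of side
#'   `target_side` mm whose proximal face sits at `target_depth` mm along +z.
#' * `slab_with_insert`: water tank with a bone-like and an air-like slab
#'   inserted side by side at depth (HU grid).
#' * `head_like`: ellipsoidal soft-tissue body with a bone shell and an air
#'   cavity, plus cubic PTV and OAR masks (HU grid).
#'
#' @param kind phantom type.
#' @param size grid extent in mm (length 3).
#' @param spacing voxel spacing in mm (length 3).
#' @param target_side side of the cubic target in mm (water tank).
#' @param target_depth proximal depth of the target along +z in mm.
#' @param insert_hu HU values of the two inserts (bone-like, air-like).
#' @return list with `grid` (a `voxel_grid`) and `rois` (named `roi_mask`s).
#' @export
make_phantom <- function(kind = c("water_tank", "slab_with_insert",
                                  "head_like"),
                         size = c(160, 160, 200), spacing = c(2, 2, 2),
                         target_side = 30, target_depth = 120,
                         insert_hu = c(800, -1000)) {
  kind <- match.arg(kind)
  n <- as.integer(round(size / spacing))
  cx <- (seq_len(n[1]) - 0.5) * spacing[1]
  cy <- (seq_len(n[2]) - 0.5) * spacing[2]
  cz <- (seq_len(n[3]) - 0.5) * spacing[3]
  mid <- size / 2
  # half-open on every axis so an s-mm cube holds exactly (s/spacing)^3 voxels
  cube_mask <- function(center, side) {
    mx <- cx > center[1] - side / 2 & cx <= center[1] + side / 2
    my <- cy > center[2] - side / 2 & cy <= center[2] + side / 2
    mz <- cz > center[3] - side / 2 & cz <= center[3] + side / 2
    outer(outer(mx, my, "&"), mz, "&")
  }
  if (kind == "water_tank") {
    if (target_depth + target_side > size[3])
      stop(sprintf("target (%g-%g mm) extends beyond the %g mm grid",
                   target_depth, target_depth + target_side, size[3]))
    g <- voxel_grid(array(1, n), spacing, c(0, 0, 0), "RSP")
    tgt <- cube_mask(c(mid[1], mid[2], target_depth + target_side / 2),
                     target_side)
    return(list(grid = g,
                rois = list(target = roi_mask("target", tgt))))
  }
  if (kind == "slab_with_insert") {
    hu <- array(0, n)
    zsl <- cz > 40 & cz <= 70
    bone <- outer(outer(cx <= mid[1], rep(TRUE, n[2]), "&"), zsl, "&")
    air <- outer(outer(cx > mid[1], rep(TRUE, n[2]), "&"), zsl, "&")
    hu[bone] <- insert_hu[1]
    hu[air] <- insert_hu[2]
    g <- voxel_grid(hu, spacing, c(0, 0, 0), "HU")
    tgt <- cube_mask(c(mid[1], mid[2], target_depth + target_side / 2),
                     target_side)
    return(list(grid = g, rois = list(target = roi_mask("target", tgt))))
  }
  # head_like
  hu <- array(-1000, n)
  a <- mid * c(0.85, 0.85, 0.9)
  X <- outer(outer((cx - mid[1])^2 / a[1]^2, (cy - mid[2])^2 / a[2]^2, "+"),
             (cz - mid[3])^2 / a[3]^2, "+")
  hu[X <= 1] <- 40                              # soft tissue
  hu[X <= 1 & X >= 0.80] <- 700                 # bone shell
  cav <- cube_mask(mid + c(0, 0, -a[3] * 0.45), 24)
  hu[cav & X < 0.75] <- -990                    # air cavity
  g <- voxel_grid(hu, spacing, c(0, 0, 0), "HU")
  ptv <- cube_mask(mid, target_side)
  oar <- cube_mask(mid + c(target_side, 0, 0), 16)
  list(grid = g, rois = list(ptv = roi_mask("ptv", ptv),
                             oar = roi_mask("oar", oar)))
}
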