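## RBE-weighted dose: fixed RBE 1.1 for protons; mixed-field LEM and modified
## MKM for carbon ions via the dose-weighted accumulators, followed by the
## standard linear-quadratic iso-effect inversion against a photon reference.

#' Photon reference linear-quadratic parameters
#'
#' @param alpha_x linear coefficient in 1/Gy, `> 0`.
#' @param beta_x quadratic coefficient in 1/Gy^2, `>= 0` (0 selects the
#'   degenerate linear branch of the inversion).
#' @param name tissue label.
#' @return list of class `photon_lq`. The defaults are test/configuration
#'   values, not clinical commissioning data.
#' @export
photon_lq <- function(alpha_x = 0.1, beta_x = 0.05, name = "default") {
  stopifnot(alpha_x > 0, beta_x >= 0)
  structure(list(alpha_x = alpha_x, beta_x = beta_x, name = name),
            class = "photon_lq")
}

#' Modified-MKM parameters
#'
#' The mixed-field MKM linear coefficient is
#' `alpha_mix = alpha0 + beta0 * z*_mix` with constant `beta_mix = beta0`.
#'
#' @param alpha0 1/Gy, `> 0`.
#' @param beta0 1/Gy^2, `> 0`.
#' @return list of class `mkm_params` (configuration defaults, not clinical
#'   values).
#' @export
mkm_params <- function(alpha0 = 0.13, beta0 = 0.05) {
  stopifnot(alpha0 > 0, beta0 > 0)
  structure(list(alpha0 = alpha0, beta0 = beta0), class = "mkm_params")
}

#' Fixed-RBE proton biological dose
#'
#' `D_RBE = 1.1 x dose`, voxel-wise. The proton path never touches the
#' alpha/beta/z* accumulators; variable-RBE schemes are a deliberate
#' extension point, not a default.
#'
#' @param dose numeric array/vector of physical dose in Gy, `>= 0`.
#' @return RBE-weighted dose in Gy (RBE), same shape.
#' @export
rbe_fixed_1p1 <- function(dose) {
  stopifnot(all(dose >= 0))
  1.1 * dose
}

#' Mixed-field LEM coefficients from score maps
#'
#' Dose-averaged alpha and dose-averaged sqrt(beta) (Zaider-Rossi style):
#' `alpha_mix = sum_d_alpha / dose`, `beta_mix = (sum_d_sqrtbeta / dose)^2`,
#' zeros where dose is zero.
#'
#' @param scores a populated `score_maps`.
#' @return list with arrays `alpha_mix` (1/Gy) and `beta_mix` (1/Gy^2).
#' @export
mixed_lem_coeffs <- function(scores) {
  stopifnot(inherits(scores, "score_maps"))
  pos <- scores$dose > 0
  a <- array(0, scores$dims); b <- array(0, scores$dims)
  a[pos] <- scores$sum_d_alpha[pos] / scores$dose[pos]
  b[pos] <- (scores$sum_d_sqrtbeta[pos] / scores$dose[pos])^2
  list(alpha_mix = a, beta_mix = b)
}

#' Mixed-field modified-MKM coefficients from score maps
#'
#' `z*_mix,voxel = sum_d_zstar / dose`; `alpha_mix = alpha0 + beta0 * z*`;
#' `beta_mix = beta0` (constant).
#'
#' @param scores a populated `score_maps`.
#' @param p an [mkm_params()].
#' @return list with arrays `alpha_mix`, `beta_mix` and `zstar_mix`.
#' @export
mixed_mkm_alpha <- function(scores, p = mkm_params()) {
  stopifnot(inherits(scores, "score_maps"), inherits(p, "mkm_params"))
  pos <- scores$dose > 0
  z <- array(0, scores$dims)
  z[pos] <- scores$sum_d_zstar[pos] / scores$dose[pos]
  a <- array(0, scores$dims)
  a[pos] <- p$alpha0 + p$beta0 * z[pos]
  b <- array(0, scores$dims)
  b[pos] <- p$beta0
  list(alpha_mix = a, beta_mix = b, zstar_mix = z)
}

#' Photon-equivalent (RBE-weighted) dose by LQ iso-effect inversion
#'
#' Effect `E = alpha_mix D + beta_mix D^2`; the photon dose producing the
#' same effect is `D_RBE = (sqrt(alpha_x^2 + 4 beta_x E) - alpha_x) /
#' (2 beta_x)`, with the linear branch `E / alpha_x` when `beta_x = 0`.
#' `D_RBE = 0` where `D = 0`.
#'
#' @param dose physical dose array (Gy), per fraction.
#' @param alpha_mix,beta_mix mixed-field LQ coefficient arrays (scalars are
#'   recycled).
#' @param ref a [photon_lq()].
#' @return RBE-weighted dose in Gy (RBE), same shape as `dose`.
#' @export
photon_equivalent_dose <- function(dose, alpha_mix, beta_mix,
                                   ref = photon_lq()) {
  stopifnot(all(dose >= 0), inherits(ref, "photon_lq"))
  E <- alpha_mix * dose + beta_mix * dose^2
  if (ref$beta_x == 0) {
    out <- E / ref$alpha_x
  } else {
    out <- (sqrt(ref$alpha_x^2 + 4 * ref$beta_x * E) - ref$alpha_x) /
      (2 * ref$beta_x)
  }
  out[dose == 0] <- 0
  out
}

#' Biological dose map from score maps
#'
#' Convenience dispatcher over the three supported models.
#'
#' @param scores a populated `score_maps`.
#' @param model `"rbe1.1"`, `"lem"` or `"mkm"`.
#' @param ref photon reference ([photon_lq()]), used by `"lem"`/`"mkm"`.
#' @param mkm [mkm_params()], used by `"mkm"`.
#' @return a `voxel_grid` of D_RBE in Gy (RBE) on the dose grid.
#' @export
biological_dose <- function(scores, model = c("rbe1.1", "lem", "mkm"),
                            ref = photon_lq(), mkm = mkm_params()) {
  model <- match.arg(model)
  d <- scores$dose
  v <- switch(model,
    "rbe1.1" = rbe_fixed_1p1(d),
    "lem" = {
      cf <- mixed_lem_coeffs(scores)
      photon_equivalent_dose(d, cf$alpha_mix, cf$beta_mix, ref)
    },
    "mkm" = {
      cf <- mixed_mkm_alpha(scores, mkm)
      photon_equivalent_dose(d, cf$alpha_mix, cf$beta_mix, ref)
    })
  g <- voxel_grid(array(v, scores$dims), scores$spacing, scores$origin, "RSP")
  attr(g, "units") <- "Gy (RBE)"
  g
}

#' LEM/MKM biological-dose ratio map and derived scaling factor
#'
#' `ratio = scaling x D_MKM / D_LEM` inside the region of interest where the
#' LEM dose is positive. The summary carries the derived scaling factor
#' `D_RBE,LEM,50 / D_RBE,MKM,50` over the region.
#'
#' @param d_lem,d_mkm `voxel_grid`s of LEM and MKM D_RBE on the same grid.
#' @param scaling clinical scaling value multiplying the ratio map.
#' @param roi an `roi_mask` on the same grid, non-empty.
#' @return list with `ratio` (a `voxel_grid`, NA outside the region) and
#'   `summary` (derived factor and ratio range inside the region).
#' @export
lem_mkm_ratio <- function(d_lem, d_mkm, scaling = 1, roi) {
  stopifnot(inherits(d_lem, "voxel_grid"), inherits(d_mkm, "voxel_grid"),
            all(dim(d_lem$values) == dim(d_mkm$values)))
  if (!any(roi$mask)) stop("region of interest is empty")
  stopifnot(all(dim(roi$mask) == dim(d_lem$values)))
  sel <- roi$mask & d_lem$values > 0
  r <- array(NA_real_, dim(d_lem$values))
  r[sel] <- scaling * d_mkm$values[sel] / d_lem$values[sel]
  d50_lem <- d_metric(dvh(d_lem, roi), 50)
  d50_mkm <- d_metric(dvh(d_mkm, roi), 50)
  list(ratio = voxel_grid(replace(r, is.na(r), 0), d_lem$spacing,
                          d_lem$origin, "RSP"),
       ratio_values = r,
       summary = list(derived_scaling = d50_lem / d50_mkm,
                      scaling_applied = scaling,
                      ratio_range = range(r[sel])))
}
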