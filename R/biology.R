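#' McNamara RBE model parameters
#'
#' Phenomenological fit coefficients of the linear-quadratic-based proton
#' RBE model: p0 = 0.99, p1 = 0.36, p2 = 1.101, p3 = -0.0039.
#'
#' @param p0,p1,p2,p3 fit coefficients.
#' @return object of class `rbe_params`.
#' @export
rbe_params <- function(p0 = 0.99, p1 = 0.36, p2 = 1.101, p3 = -0.0039) {
  structure(list(p0 = p0, p1 = p1, p2 = p2, p3 = p3), class = "rbe_params")
}

#' McNamara variable RBE
#'
#' Evaluates, exactly as published,
#' \deqn{RBE = \frac{1}{2 D_p}\left(\sqrt{(\alpha/\beta)_x^2
#'   + 4 D_p (\alpha/\beta)_x \left(p_0 + \frac{p_1}{(\alpha/\beta)_x}
#'     LET_d\right)
#'   + 4 D_p^2 \left(p_2 + p_3 \sqrt{(\alpha/\beta)_x} LET_d\right)^2}
#'   - (\alpha/\beta)_x\right)}
#' as a function of the proton physical dose per fraction, the
#' dose-averaged LET, and the tissue (alpha/beta)_x ratio of the photon
#' linear-quadratic model. With p0 = p2 = 1 and p1 = p3 = 0 the model
#' reduces to RBE = 1 for all inputs.
#'
#' @param dose_per_fx physical proton dose per fraction, Gy (> 0; the
#'   formula is singular at zero dose — callers mask zero-dose voxels).
#' @param letd dose-averaged LET in keV/um (>= 0).
#' @param alpha_beta (alpha/beta)_x in Gy (> 0).
#' @param params an [rbe_params()].
#' @return dimensionless RBE (vectorized over the three inputs).
#' @export
mcnamara_rbe <- function(dose_per_fx, letd, alpha_beta,
                         params = rbe_params()) {
  if (any(dose_per_fx <= 0))
    stop("mcnamara_rbe: dose per fraction must be > 0 (mask zero-dose voxels)")
  if (any(letd < 0) || any(alpha_beta <= 0))
    stop("mcnamara_rbe: need LET_d >= 0 and (alpha/beta)_x > 0")
  ab <- alpha_beta
  amax <- params$p0 + (params$p1 / ab) * letd
  bterm <- params$p2 + params$p3 * sqrt(ab) * letd
  (sqrt(ab^2 + 4 * dose_per_fx * ab * amax +
          4 * dose_per_fx^2 * bterm^2) - ab) / (2 * dose_per_fx)
}

#' RBE-weighted dose grid
#'
#' Converts a physical dose / LET_d pair into Gy(RBE): per voxel the dose
#' per fraction is `total dose / fractions` (uniform fractionation), the
#' (alpha/beta)_x comes from the highest-priority structure containing the
#' voxel (target > OAR > body; uncovered voxels get the body value, counted
#' in attribute `n_unassigned`), and
#' `D_RBE = fractions x RBE(D_p, LET_d, (alpha/beta)_x) x D_p`.
#' Zero-dose voxels map to 0. Voxels below the LET validity threshold use
#' LET_d = 0 (their RBE is then the LET-free value; they carry negligible
#' dose by construction).
#'
#' @param dose_let a `dose_let` (normalized dose grid).
#' @param fractions number of fractions (>= 1).
#' @param structures a `structure_set` providing the (alpha/beta)_x map.
#' @param params an [rbe_params()].
#' @return numeric array of RBE-weighted dose in Gy(RBE).
#' @export
rbe_weighted_dose <- function(dose_let, fractions, structures,
                              params = rbe_params()) {
  stopifnot(inherits(dose_let, "dose_let"), fractions >= 1)
  ab <- alpha_beta_grid(structures)
  dose <- dose_let$dose
  out <- array(0, dim = dim(dose))
  pos <- dose > 0
  letd <- dose_let$letd
  letd[!is.finite(letd)] <- 0
  dp <- dose[pos] / fractions
  out[pos] <- fractions * dp *
    mcnamara_rbe(dp, letd[pos], ab[pos], params)
  attr(out, "n_unassigned") <- attr(ab, "n_unassigned")
  out
}
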