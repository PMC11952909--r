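#' Isotropic elasticity identities
#'
#' For an isotropic linear-elastic solid the four engineering constants are
#' mutually determined: the bulk modulus is `k = E / (3 (1 - 2 nu))` and the
#' shear modulus is `mu = E / (2 (1 + nu))`. Both identities are
#' unit-invariant, so `E` may be given in Pa, MPa or GPa and `k`, `mu` are
#' returned in the same unit.
#'
#' @param E Young's modulus (any pressure unit), strictly positive.
#' @param nu Poisson's ratio, strictly inside (-1, 0.5).
#' @return A list with components `k` (bulk modulus) and `mu` (shear
#'   modulus), vectorised over the inputs.
#' @seealso [isotropic_inverse()] for the reverse mapping.
#' @examples
#' isotropic_relations(14.88, 0.25) # bone-like, GPa
#' isotropic_relations(1.23, 0.47)  # disc-like, MPa
#' @export
isotropic_relations <- function(E, nu) {
  stopifnot(is.numeric(E), is.numeric(nu))
  if (any(!is.finite(E)) || any(!is.finite(nu)))
    stop("E and nu must be finite")
  if (any(E <= 0))
    stop("Young's modulus must be strictly positive")
  if (any(nu >= 0.5))
    stop("nu >= 0.5: material is incompressible, bulk modulus diverges")
  if (any(nu <= -1))
    stop("nu <= -1 is outside the thermodynamically admissible range")
  list(k = E / (3 * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

#' Invert the isotropic elasticity identities
#'
#' Recovers `(E, nu)` from the bulk and shear moduli via
#' `E = 9 k mu / (3 k + mu)` and `nu = (3 k - 2 mu) / (2 (3 k + mu))`.
#' Composing with [isotropic_relations()] round-trips to machine precision.
#'
#' @param k Bulk modulus, strictly positive.
#' @param mu Shear modulus, strictly positive.
#' @return A list with components `E` and `nu`, vectorised.
#' @export
isotropic_inverse <- function(k, mu) {
  stopifnot(is.numeric(k), is.numeric(mu))
  if (any(k <= 0) || any(mu <= 0))
    stop("bulk and shear moduli must be strictly positive")
  denom <- 3 * k + mu
  list(E = 9 * k * mu / denom, nu = (3 * k - 2 * mu) / (2 * denom))
}

#' Bundle material properties for a bone/disc model
#'
#' Builds the full ten-parameter property set used throughout the package:
#' Young's modulus, Poisson's ratio, bulk modulus, shear modulus and density
#' for the (single) bone material and the (single) disc material. Bulk and
#' shear moduli are always derived through [isotropic_relations()], so the
#' set is consistent by construction.
#'
#' @param E_bone,E_disc Young's moduli in Pa.
#' @param nu_bone,nu_disc Poisson's ratios, strictly inside (-1, 0.5).
#' @param rho_bone,rho_disc Densities in kg/m^3.
#' @return An object of class `material_properties`: a named list of the ten
#'   scalars (all SI) with a `consistent = TRUE` flag.
#' @examples
#' material_properties(E_bone = 15e9, nu_bone = 0.3,
#'                     E_disc = 2e6, nu_disc = 0.45)
#' @export
material_properties <- function(E_bone, nu_bone, E_disc, nu_disc,
                                rho_bone = 1500, rho_disc = 1100) {
  bone <- isotropic_relations(E_bone, nu_bone)
  disc <- isotropic_relations(E_disc, nu_disc)
  if (rho_bone <= 0 || rho_disc <= 0) stop("densities must be positive")
  structure(list(
    E_bone = E_bone, nu_bone = nu_bone,
    E_disc = E_disc, nu_disc = nu_disc,
    k_bone = bone$k, mu_bone = bone$mu,
    k_disc = disc$k, mu_disc = disc$mu,
    rho_bone = rho_bone, rho_disc = rho_disc,
    consistent = TRUE
  ), class = "material_properties")
}

#' @export
print.material_properties <- function(x, ...) {
  cat("Material properties (SI units)\n")
  cat(sprintf("  bone: E = %.4g Pa, nu = %.3f, k = %.4g Pa, mu = %.4g Pa, rho = %.0f kg/m^3\n",
              x$E_bone, x$nu_bone, x$k_bone, x$mu_bone, x$rho_bone))
  cat(sprintf("  disc: E = %.4g Pa, nu = %.3f, k = %.4g Pa, mu = %.4g Pa, rho = %.0f kg/m^3\n",
              x$E_disc, x$nu_disc, x$k_disc, x$mu_disc, x$rho_disc))
  invisible(x)
}

# Lame parameters from (E, nu); used by the FEA stiffness split
# K = lambda * K_lam + mu * K_mu.
lame_parameters <- function(E, nu) {
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
       mu = E / (2 * (1 + nu)))
}

#' One-term incompressible Ogden uniaxial response
#'
#' Nominal (first Piola-Kirchhoff) stress for uniaxial extension/compression
#' of an incompressible one-term Ogden solid with strain energy
#' `W = (2 mu_o / alpha^2) (l1^alpha + l2^alpha + l3^alpha - 3)`.
#' Under uniaxial stretch `l` with `l2 = l3 = l^(-1/2)` this gives
#' `P(l) = (2 mu_o / alpha) (l^(alpha - 1) - l^(-alpha/2 - 1))`.
#' In this convention `mu_o` is the small-strain shear modulus: the tangent
#' stiffness at `l = 1` is `3 mu_o`, the incompressible uniaxial modulus.
#' With `alpha = 2` the model reduces to incompressible neo-Hookean,
#' `P = mu_o (l - l^-2)`.
#'
#' @param mu_o Ogden shear modulus (Pa), positive.
#' @param alpha Ogden exponent, non-zero.
#' @param stretch Principal stretch `l > 0`; vectorised.
#' @return Nominal stress in the same pressure unit as `mu_o`.
#' @export
ogden_uniaxial <- function(mu_o, alpha, stretch) {
  if (mu_o <= 0) stop("mu_o must be positive")
  if (alpha == 0) stop("alpha must be non-zero")
  if (any(!is.finite(stretch)) || any(stretch <= 0))
    stop("stretch must be strictly positive")
  (2 * mu_o / alpha) * (stretch^(alpha - 1) - stretch^(-alpha / 2 - 1))
}

# Strain energy density of the same one-term incompressible Ogden solid
# under uniaxial stretch; exported for finite-difference verification.
#' @rdname ogden_uniaxial
#' @export
ogden_uniaxial_energy <- function(mu_o, alpha, stretch) {
  if (mu_o <= 0) stop("mu_o must be positive")
  if (alpha == 0) stop("alpha must be non-zero")
  if (any(stretch <= 0)) stop("stretch must be strictly positive")
  (2 * mu_o / alpha^2) * (stretch^alpha + 2 * stretch^(-alpha / 2) - 3)
}

#' Classify a CT attenuation value into bone-tissue bands
#'
#' Cortical bone attenuates in roughly +700 to +2000 Hounsfield units and
#' cancellous (trabecular) bone in +100 to +300 HU; values outside both
#' bands are reported as indeterminate. Band edges are inclusive.
#'
#' @param hu Hounsfield units; vectorised, must be finite.
#' @return Character vector with values `"cortical"`, `"cancellous"` or
#'   `"indeterminate"`.
#' @examples
#' hu_classify(c(1500, 200, 500))
#' @export
hu_classify <- function(hu) {
  if (any(!is.finite(hu))) stop("HU values must be finite")
  out <- rep("indeterminate", length(hu))
  out[hu >= 700 & hu <= 2000] <- "cortical"
  out[hu >= 100 & hu <= 300] <- "cancellous"
  out
}

#' Empirical Hounsfield-unit to bone property relations
#'
#' Evaluates the standard empirical calibration forms
#' `E (MPa) = a * HU^b` and `rho (kg/m^3) = c + d * HU`. The coefficients
#' are scanner- and cohort-specific and must be supplied by the user.
#'
#' @param hu Hounsfield units; must be positive when `b` is non-integer.
#' @param a,b Power-law coefficients for Young's modulus (MPa).
#' @param c,d Affine coefficients for density (kg/m^3).
#' @return A list with components `E_MPa` and `rho` (kg/m^3), vectorised
#'   over `hu`.
#' @export
hu_to_properties <- function(hu, a, b, c, d) {
  if (any(!is.finite(hu))) stop("HU values must be finite")
  if (any(hu <= 0) && b != round(b))
    stop("hu <= 0 with non-integer exponent b: power law undefined")
  list(E_MPa = a * hu^b, rho = c + d * hu)
}
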