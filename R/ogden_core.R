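#' One-term modified Ogden parameters
#'
#' Constructs and validates the parameter pair of the incompressible one-term
#' modified Ogden strain-energy function
#' \deqn{\psi_O = \frac{2\mu}{\alpha^2}\left(\lambda_1^\alpha + \lambda_2^\alpha +
#'   \lambda_3^\alpha - 3\right)}{psi = (2 mu / alpha^2) (l1^a + l2^a + l3^a - 3)}
#' with classical shear modulus `mu` (Pa, > 0) and dimensionless nonlinearity
#' parameter `alpha`. The model reduces to neo-Hookean uniaxial behaviour at
#' `alpha = 2`. Values of `|alpha| < 0.01` are rejected: the energy divides by
#' `alpha^2` and the limit `alpha -> 0` is a removable parameterization
#' boundary that the calibration never needs to cross.
#'
#' @param mu Shear modulus in Pa, must be positive and finite.
#' @param alpha Nonlinearity parameter, finite, `|alpha| >= 0.01`. Negative
#'   values are common for ultrasoft brain-like tissues.
#' @return An object of class `ogden_parameters` (a named list).
#' @examples
#' ogden_parameters(mu = 1000, alpha = 2)
#' @export
ogden_parameters <- function(mu, alpha) {
  check_number(mu, "mu", positive = TRUE)
  check_number(alpha, "alpha")
  if (abs(alpha) < 0.01) {
    nq_abort("`alpha` is inside the singular band |alpha| < 0.01", field = "alpha")
  }
  structure(list(mu = mu, alpha = alpha), class = "ogden_parameters")
}

#' @export
print.ogden_parameters <- function(x, ...) {
  cat(sprintf("<ogden_parameters> mu = %g Pa, alpha = %g\n", x$mu, x$alpha))
  invisible(x)
}

as_ogden_parameters <- function(params) {
  if (inherits(params, "ogden_parameters")) return(params)
  if (is.list(params) && all(c("mu", "alpha") %in% names(params))) {
    return(ogden_parameters(params$mu, params$alpha))
  }
  nq_abort("`params` must be an ogden_parameters object or a list with mu and alpha")
}

check_stretch <- function(lambda, name = "lambda") {
  if (!is.numeric(lambda) || any(!is.finite(lambda)) || any(lambda <= 0)) {
    nq_abort(sprintf("`%s` must be finite and > 0", name), field = name)
  }
  invisible(lambda)
}

#' Ogden strain-energy density
#'
#' Evaluates the incompressible one-term modified Ogden strain energy for a
#' principal-stretch triple. The function is symmetric in its stretch
#' arguments and vanishes in the undeformed reference configuration
#' (all stretches 1).
#'
#' @param lambda1,lambda2,lambda3 Principal stretches (> 0); vectors recycle.
#' @param params An [ogden_parameters()] object.
#' @return Strain energy in J m^-3 (equivalently Pa).
#' @examples
#' p <- ogden_parameters(1000, 2)
#' ogden_strain_energy(0.85^-0.5, 0.85^-0.5, 0.85, p)
#' @export
ogden_strain_energy <- function(lambda1, lambda2, lambda3, params) {
  params <- as_ogden_parameters(params)
  check_stretch(lambda1, "lambda1")
  check_stretch(lambda2, "lambda2")
  check_stretch(lambda3, "lambda3")
  a <- params$alpha
  (2 * params$mu / a^2) * (lambda1^a + lambda2^a + lambda3^a - 3)
}

# Uniaxial incompressible energy psi(lambda) = (2 mu/a^2)(2 lambda^(-a/2) + lambda^a - 3);
# its derivative is the uniaxial nominal stress. Used by tests as the finite-
# difference oracle; kept exported for transparency.

#' Uniaxial strain energy under incompressibility
#'
#' The Ogden energy restricted to uniaxial stretch `lambda` with lateral
#' stretches `lambda^(-1/2)` imposed by incompressibility. Its derivative with
#' respect to `lambda` is the uniaxial nominal (Piola) stress.
#'
#' @param lambda Axial stretch (> 0), vectorized.
#' @inheritParams ogden_strain_energy
#' @return Energy density in J m^-3.
#' @export
ogden_uniaxial_energy <- function(lambda, params) {
  params <- as_ogden_parameters(params)
  check_stretch(lambda)
  a <- params$alpha
  (2 * params$mu / a^2) * (2 * lambda^(-a / 2) + lambda^a - 3)
}

#' Hydrostatic pressure in uniaxial compression
#'
#' The Lagrange multiplier enforcing incompressibility, determined by the
#' lateral traction-free boundary condition of unconfined uniaxial
#' compression: `p = (2 mu / alpha) * lambda^(-alpha/2)`.
#'
#' @inheritParams ogden_uniaxial_energy
#' @return Pressure in Pa.
#' @examples
#' ogden_pressure(0.85, ogden_parameters(1000, 2))
#' @export
ogden_pressure <- function(lambda, params) {
  params <- as_ogden_parameters(params)
  check_stretch(lambda)
  (2 * params$mu / params$alpha) * lambda^(-params$alpha / 2)
}

#' Uniaxial nominal (Piola) stress
#'
#' Analytic axial nominal stress of the incompressible one-term modified Ogden
#' model under homogeneous uniaxial deformation:
#' \deqn{P_{zz} = \frac{2\mu}{\alpha}\left(\lambda^{\alpha-1} -
#'   \lambda^{-\alpha/2-1}\right)}{Pzz = (2 mu/alpha) (l^(a-1) - l^(-a/2-1))}
#' Negative in compression (`lambda < 1`) for `mu > 0`; at `alpha = 2` it
#' reduces to the neo-Hookean form `mu * (lambda - lambda^-2)`.
#'
#' @inheritParams ogden_uniaxial_energy
#' @return Nominal stress in Pa, same length as `lambda`.
#' @examples
#' ogden_stress(0.85, ogden_parameters(1000, 2)) # -534.08 Pa
#' @export
ogden_stress <- function(lambda, params) {
  params <- as_ogden_parameters(params)
  check_stretch(lambda)
  a <- params$alpha
  (2 * params$mu / a) * (lambda^(a - 1) - lambda^(-a / 2 - 1))
}

#' Apparent Young's modulus from the shear modulus
#'
#' Under incompressibility the initial Poisson ratio is 0.5 and the
#' small-strain stiffness summary is `E_app = 2 mu (1 + nu) = 3 mu`. This is
#' the per-condition stiffness number reported for soft tissue constructs.
#'
#' @param mu Shear modulus in Pa (> 0).
#' @return A tibble with columns `E_app` (Pa), `mu` (Pa) and `nu` (0.5).
#' @examples
#' apparent_young_modulus(118) # 354 Pa, brainstem-like
#' @export
apparent_young_modulus <- function(mu) {
  check_number(mu, "mu", positive = TRUE)
  tibble(E_app = 3 * mu, mu = mu, nu = 0.5)
}

#' Tabulate the Ogden stress over a stretch grid
#'
#' Convenience predictor: evaluates the uniaxial nominal stress on a stretch
#' grid and returns a tidy table, handy for plotting model curves next to
#' data.
#'
#' @inheritParams ogden_uniaxial_energy
#' @param lambda Stretch grid (defaults to 100 points spanning 15% compression).
#' @return Tibble with columns `lambda`, `stress` (Pa).
#' @export
ogden_predict <- function(params, lambda = seq(0.85, 1, length.out = 100)) {
  params <- as_ogden_parameters(params)
  check_stretch(lambda)
  tibble(lambda = lambda, stress = ogden_stress(lambda, params))
}
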