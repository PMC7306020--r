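#' Construct an Ogden parameter set
#'
#' Bundles the constitutive constants of an N-term incompressible Ogden
#' hyperelastic material. The convention used throughout this package is the
#' \eqn{2\mu_j/\alpha_j} prefactor form of the strain-energy density,
#' \deqn{W = \sum_{i=1}^{3}\sum_{j=1}^{N} \frac{2\mu_j}{\alpha_j}
#'       \left((J^{-1/3}\lambda_i)^{\alpha_j} - 1\right)
#'       + \frac{K}{2}(J - 1)^2,}
#' which differs by a factor of two from the classical Ogden form (see
#' [to_classical_ogden()]). All stresses are in MPa.
#'
#' A parameter set is *stable* when \eqn{\sum_j \mu_j \alpha_j > 0}, which is
#' equivalent to a positive small-strain shear modulus. Construction does not
#' require stability (unstable sets are useful for testing), but the fitting
#' routines enforce it.
#'
#' @param mu Numeric vector of shear-like moduli \eqn{\mu_j} (MPa).
#' @param alpha Numeric vector of dimensionless exponents \eqn{\alpha_j},
#'   same length as `mu`. No \eqn{\alpha_j} may be zero (it divides the
#'   energy prefactor).
#' @param bulk_k Volumetric penalty modulus K (MPa). Irrelevant on the
#'   incompressible path (J = 1) and kept only as metadata; default 0.
#' @return An object of class `ogden_params` with fields `mu`, `alpha`,
#'   `n_terms`, `bulk_k`.
#' @examples
#' p <- ogden_params(mu = c(0.0029, 0.0584), alpha = c(0.2267, 14.055))
#' uniaxial_nominal_stress(p, 1.2)
#' @export
ogden_params <- function(mu, alpha, bulk_k = 0) {
  if (length(mu) < 1L || length(mu) != length(alpha))
    stop("'mu' and 'alpha' must be non-empty vectors of equal length")
  if (!all(is.finite(mu)) || !all(is.finite(alpha)) || !is.finite(bulk_k))
    stop("Ogden parameters must be finite")
  if (any(alpha == 0))
    stop("alpha_j = 0 is not admissible: the 2*mu_j/alpha_j prefactor divides by alpha_j")
  structure(
    list(mu = as.numeric(mu), alpha = as.numeric(alpha),
         n_terms = length(mu), bulk_k = as.numeric(bulk_k)),
    class = "ogden_params"
  )
}

#' @export
print.ogden_params <- function(x, ...) {
  cat(sprintf("Ogden material (%d term%s, 2*mu/alpha convention, MPa)\n",
              x$n_terms, if (x$n_terms > 1L) "s" else ""))
  for (j in seq_len(x$n_terms))
    cat(sprintf("  term %d: mu = %.6g MPa, alpha = %.6g\n",
                j, x$mu[j], x$alpha[j]))
  cat(sprintf("  bulk K = %g MPa; sum(mu*alpha) = %.6g MPa (%s)\n",
              x$bulk_k, sum(x$mu * x$alpha),
              if (is_stable(x)) "stable" else "UNSTABLE"))
  invisible(x)
}

#' Stability of an Ogden parameter set
#'
#' Checks the inequality \eqn{\sum_j \mu_j \alpha_j > 0} that every admissible
#' parameter set must satisfy (positive ground-state shear modulus).
#'
#' @param params An [ogden_params()] object.
#' @return `TRUE` or `FALSE`.
#' @export
is_stable <- function(params) {
  stopifnot(inherits(params, "ogden_params"))
  sum(params$mu * params$alpha) > 0
}

#' Convert between the 2*mu/alpha and classical Ogden conventions
#'
#' The classical Ogden strain energy uses a \eqn{\mu_j/\alpha_j} prefactor;
#' this package's convention uses \eqn{2\mu_j/\alpha_j}. The two describe the
#' same material when classical \eqn{\mu = 2 \times} package \eqn{\mu}
#' (exponents are unchanged).
#'
#' @param params An [ogden_params()] object in this package's convention
#'   (for `to_classical_ogden`) or a list/object with classical `mu`, `alpha`
#'   (for `from_classical_ogden`).
#' @return For `to_classical_ogden`, a list with classical `mu` and `alpha`.
#'   For `from_classical_ogden`, an [ogden_params()] object.
#' @export
to_classical_ogden <- function(params) {
  stopifnot(inherits(params, "ogden_params"))
  list(mu = 2 * params$mu, alpha = params$alpha)
}

#' @rdname to_classical_ogden
#' @param mu,alpha Classical-convention constants (used by
#'   `from_classical_ogden`).
#' @param bulk_k Volumetric penalty modulus (MPa).
#' @export
from_classical_ogden <- function(mu, alpha, bulk_k = 0) {
  ogden_params(mu = mu / 2, alpha = alpha, bulk_k = bulk_k)
}

#' Construct a principal-stretch deformation state
#'
#' Represents a homogeneous deformation by its principal stretches, i.e. a
#' diagonal deformation gradient `F = diag(l1, l2, l3)` with volume ratio
#' `J = l1*l2*l3`.
#'
#' @param stretches Numeric length-3 vector of principal stretches, all > 0.
#' @return Object of class `deformation_state` with fields `stretches` and `J`.
#' @export
deformation_state <- function(stretches) {
  stretches <- as.numeric(stretches)
  if (length(stretches) != 3L || !all(is.finite(stretches)) || any(stretches <= 0))
    stop("'stretches' must be three finite positive principal stretches")
  structure(list(stretches = stretches, J = prod(stretches)),
            class = "deformation_state")
}

#' Incompressible uniaxial deformation state
#'
#' The uniaxial-tension path under exact incompressibility:
#' \eqn{\lambda_2 = \lambda_3 = \lambda^{-1/2}}, so \eqn{J = 1}.
#'
#' @param stretch Axial stretch \eqn{\lambda > 0}.
#' @return A [deformation_state()].
#' @export
uniaxial_state <- function(stretch) {
  if (!is.finite(stretch) || stretch <= 0) stop("'stretch' must be positive")
  deformation_state(c(stretch, stretch^-0.5, stretch^-0.5))
}

#' Ogden strain-energy density
#'
#' Evaluates the N-term Ogden strain energy in the 2*mu/alpha convention with
#' a quadratic volumetric penalty,
#' \deqn{W = \sum_{i=1}^{3}\sum_{j=1}^{N} \frac{2\mu_j}{\alpha_j}
#'       \left((J^{-1/3}\lambda_i)^{\alpha_j} - 1\right)
#'       + \frac{K}{2}(J-1)^2 .}
#' On incompressible states (J = 1) the penalty term vanishes identically,
#' so K plays no role on the uniaxial identification path.
#'
#' @param params An [ogden_params()] object.
#' @param state A [deformation_state()].
#' @return Energy density in MPa (scalar).
#' @export
strain_energy <- function(params, state) {
  stopifnot(inherits(params, "ogden_params"), inherits(state, "deformation_state"))
  lam_iso <- state$J^(-1 / 3) * state$stretches   # deviatoric stretches
  dev <- 0
  for (j in seq_len(params$n_terms)) {
    a <- params$alpha[j]
    # expm1 keeps lam^a - 1 accurate when a*log(lam) is small; the naive
    # power loses ~eps/a absolute accuracy for small exponents
    dev <- dev + 2 * params$mu[j] / a * sum(expm1(a * log(lam_iso)))
  }
  dev + params$bulk_k / 2 * (state$J - 1)^2
}

#' Uniaxial nominal (first Piola) stress of an incompressible Ogden material
#'
#' Closed-form nominal stress on the incompressible uniaxial path,
#' \eqn{P(\lambda) = dW/d\lambda} with
#' \eqn{\lambda_2=\lambda_3=\lambda^{-1/2}}:
#' \deqn{P(\lambda) = \sum_j 2\mu_j\left(\lambda^{\alpha_j - 1}
#'       - \lambda^{-\alpha_j/2 - 1}\right).}
#' The reference state is stress-free: P(1) = 0 for any parameter set, and the
#' initial tangent stiffness is \eqn{dP/d\lambda|_{\lambda=1} =
#' 3\sum_j \mu_j\alpha_j}.
#'
#' @param params An [ogden_params()] object.
#' @param stretch Axial stretch(es) \eqn{\lambda > 0}; vectorized.
#' @return Nominal stress in MPa, same length as `stretch`.
#' @export
uniaxial_nominal_stress <- function(params, stretch) {
  stopifnot(inherits(params, "ogden_params"))
  if (any(!is.finite(stretch)) || any(stretch <= 0))
    stop("'stretch' must be finite and positive")
  P <- numeric(length(stretch))
  for (j in seq_len(params$n_terms)) {
    a <- params$alpha[j]
    P <- P + 2 * params$mu[j] * (stretch^(a - 1) - stretch^(-a / 2 - 1))
  }
  P
}

# Gradient of the uniaxial nominal stress with respect to (mu_j, alpha_j),
# used as the analytic Jacobian of the least-squares residuals.
# d P / d mu_j    = 2 (l^(a-1) - l^(-a/2-1))
# d P / d alpha_j = 2 mu_j ln(l) (l^(a-1) + l^(-a/2-1)/2)
uniaxial_stress_grad <- function(params, stretch) {
  n <- params$n_terms
  J <- matrix(0, nrow = length(stretch), ncol = 2 * n)
  ll <- log(stretch)
  for (j in seq_len(n)) {
    a <- params$alpha[j]
    up <- stretch^(a - 1)
    dn <- stretch^(-a / 2 - 1)
    J[, j] <- 2 * (up - dn)
    J[, n + j] <- 2 * params$mu[j] * ll * (up + dn / 2)
  }
  J
}

#' von Mises equivalent stress from principal stresses
#'
#' Collapses a triaxial principal stress state to the scalar
#' \deqn{\sigma_{vM} = \sqrt{\tfrac12\left[(\sigma_1-\sigma_2)^2 +
#'   (\sigma_2-\sigma_3)^2 + (\sigma_3-\sigma_1)^2\right]},}
#' which is non-negative, zero exactly for hydrostatic states, invariant under
#' permutation of the principal stresses and under addition of a common
#' hydrostatic offset.
#'
#' @param s1,s2,s3 Principal stresses (MPa); vectorized.
#' @return von Mises stress (MPa).
#' @examples
#' von_mises(3, 1, 1)  # 2
#' @export
von_mises <- function(s1, s2, s3) {
  if (any(!is.finite(c(s1, s2, s3)))) stop("principal stresses must be finite")
  sqrt(0.5 * ((s1 - s2)^2 + (s2 - s3)^2 + (s3 - s1)^2))
}

#' Serialize Ogden parameters to/from JSON
#'
#' The JSON layout is
#' `{"terms": [{"mu_mpa": .., "alpha": ..}, ...], "bulk_k_mpa": ..}`.
#' Round-tripping is lossless at full double precision (17 significant
#' digits are written).
#'
#' @param params An [ogden_params()] object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `ogden_to_json`: JSON string (invisibly, if written to a file).
#'   `ogden_from_json`: an [ogden_params()] object.
#' @export
ogden_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "ogden_params"))
  obj <- list(
    terms = lapply(seq_len(params$n_terms), function(j)
      list(mu_mpa = params$mu[j], alpha = params$alpha[j])),
    bulk_k_mpa = params$bulk_k
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(as.character(txt))
}

#' @rdname ogden_to_json
#' @param json JSON string or path to a JSON file.
#' @export
ogden_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (is.null(obj$terms) || length(obj$terms) < 1L)
    stop("JSON does not contain an Ogden 'terms' array")
  ogden_params(
    mu = vapply(obj$terms, function(t) as.numeric(t$mu_mpa), numeric(1)),
    alpha = vapply(obj$terms, function(t) as.numeric(t$alpha), numeric(1)),
    bulk_k = if (is.null(obj$bulk_k_mpa)) 0 else as.numeric(obj$bulk_k_mpa)
  )
}
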