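# Closed-form partial derivatives of the constrained free energy
# f~(phi_0, phi_v) = f(xi*(phi_0 - phi_v), phi_v).
#
# With h = xi*(phi_0 - phi_v) (horizontal coverage), u = 1 - h (free
# sublattice fraction) and w = 1 - h - phi_v (empty-site fraction), every
# partial derivative is a sum of logarithms or reciprocals of {h, u, w,
# phi_v}, so arbitrary-order derivatives are available exactly. All terms
# that involve u carry a factor (xi - 1), so the expressions remain valid
# at xi = 1 without special-casing.

# Exact product with error term (Dekker/Veltkamp splitting); used to form
# u = 1 - xi*phi_0 + xi*phi_v without cancellation noise. Near a full
# sublattice u is O(phi_v) while 1 - h loses all significant digits, which
# would otherwise cap the accuracy of the pressure at ~1e-8 for strongly
# penalized reorientation.
two_prod <- function(a, b) {
  p <- a * b
  s <- 134217729  # 2^27 + 1
  aa <- a * s; ah <- aa - (aa - a); al <- a - ah
  bb <- b * s; bh <- bb - (bb - b); bl <- b - bh
  e <- ((ah * bh - p) + ah * bl + al * bh) + al * bl
  list(p = p, e = e)
}

# Compensated u = 1 - h and w = 1 - h - phi_v along the conservation line.
comp_uw <- function(xi, phi_0, phi_v) {
  t1 <- two_prod(xi, phi_0)
  t2 <- two_prod(xi, phi_v)
  u <- ((1 - t1$p) + t2$p) + (t2$e - t1$e)
  list(u = u, w = u - phi_v)
}

ftilde_value <- function(phi_0, phi_v, p) {
  p <- as_model_params(p)
  free_energy_per_site(p$xi * (phi_0 - phi_v), phi_v, p)
}

#' Partial derivatives of the constrained free energy
#'
#' Closed-form first, second and third partial derivatives of
#' `f~(phi_0, phi_v) = f(xi*(phi_0 - phi_v), phi_v)` with respect to the
#' scaled molecule number `phi_0` and the vertical fraction `phi_v`. These
#' feed the implicit-differentiation route to the lateral pressure and the
#' inflection-point condition, so that only the numerical values of the
#' equilibrium distribution are ever needed — never its numerical
#' derivative.
#'
#' @param phi_0 Scaled molecule number(s) in (0, 1).
#' @param phi_v Vertical fraction(s), strictly inside the feasible interval.
#' @param p A [model_params()].
#' @return A list of numeric vectors: `f` (the value), `f_0`, `f_v` (first
#'   partials), `f_00`, `f_v0`, `f_vv` (second), and `f_000`, `f_00v`,
#'   `f_0vv`, `f_vvv` (third), subscripts counting derivatives in `phi_0`
#'   and `phi_v`.
#' @export
ftilde_partials <- function(phi_0, phi_v, p) {
  p <- as_model_params(p)
  xi <- p$xi; lam <- p$lam
  h <- xi * (phi_0 - phi_v)
  uw <- comp_uw(xi, phi_0, phi_v)
  u <- uw$u
  w <- uw$w
  if (any(h <= 0) || any(u <= 0) || any(w <= 0) || any(phi_v <= 0))
    stop("interior feasible point required for the partial derivatives",
         call. = FALSE)
  xm1 <- xi - 1
  list(
    f     = lam * phi_v + h * log(h) / xi + (1 / xi - 1) * u * log(u) +
            w * log(w) + phi_v * log(phi_v),
    f_0   = log(h) + xm1 * log(u) - xi * log(w),
    f_v   = lam + log(phi_v / h) + xm1 * log(w / u),
    f_00  = xi / h - xi * xm1 / u + xi^2 / w,
    f_v0  = -xi / h + xi * xm1 / u - xi * xm1 / w,
    f_vv  = 1 / phi_v + xi / h - xi * xm1 / u + xm1^2 / w,
    f_000 = -xi^2 / h^2 - xi^2 * xm1 / u^2 + xi^3 / w^2,
    f_00v = xi^2 / h^2 + xi^2 * xm1 / u^2 - xi^2 * xm1 / w^2,
    f_0vv = -xi^2 / h^2 - xi^2 * xm1 / u^2 + xi * xm1^2 / w^2,
    f_vvv = -1 / phi_v^2 + xi^2 / h^2 + xi^2 * xm1 / u^2 - xm1^3 / w^2
  )
}
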