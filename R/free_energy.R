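# x*log(x) with the boundary convention 0*log(0) = 0
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Mixing entropy per lattice site
#'
#' Stirling-approximation entropy (as -S/(kB*M), so it is the quantity that
#' enters the free energy with a plus sign) of arranging horizontal molecules
#' on the sublattice and vertical molecules on the remaining lattice sites:
#'
#' (phi_h/xi) ln phi_h + (1/xi - 1)(1 - phi_h) ln(1 - phi_h)
#'   + (1 - phi_h - phi_v) ln(1 - phi_h - phi_v) + phi_v ln phi_v
#'
#' @param phi_h,phi_v Fractions of sites covered by horizontal / vertical
#'   molecules; `phi_h + phi_v <= 1`.
#' @param xi Area ratio `>= 1`.
#' @return Dimensionless entropy contribution per site (non-positive terms
#'   sum; 0 for an empty lattice). Vectorized over `phi_h`, `phi_v`.
#' @export
entropy_per_site <- function(phi_h, phi_v, xi) {
  check_fractions(phi_h, phi_v)
  xlogx(phi_h) / xi + (1 / xi - 1) * xlogx(1 - phi_h) +
    xlogx(1 - phi_h - phi_v) + xlogx(phi_v)
}

#' Free energy per lattice site
#'
#' `f(phi_h, phi_v) = lam*phi_v + entropy_per_site(phi_h, phi_v, xi)`,
#' in kT units. The internal energy counts only the reorientation cost of
#' the vertical molecules; inter-molecular interactions beyond steric
#' exclusion are ignored.
#'
#' @inheritParams entropy_per_site
#' @param p A [model_params()].
#' @return Free energy per site in kT units; 0 for the empty monolayer.
#' @examples
#' free_energy_per_site(0.3, 0.2, model_params(4, 7))
#' @export
free_energy_per_site <- function(phi_h, phi_v, p) {
  p <- as_model_params(p)
  p$lam * phi_v + entropy_per_site(phi_h, phi_v, p$xi)
}

check_fractions <- function(phi_h, phi_v) {
  if (any(phi_h < 0) || any(phi_v < 0) || any(phi_h + phi_v > 1 + 1e-12))
    stop("infeasible occupancy fractions: need phi_h, phi_v >= 0 and ",
         "phi_h + phi_v <= 1", call. = FALSE)
  invisible(NULL)
}

#' Feasible range of the vertical fraction at fixed molecule number
#'
#' For fixed `phi_0`, the vertical fraction is constrained by
#' `phi_h = xi*(phi_0 - phi_v) <= 1` (sublattice capacity), by
#' `phi_h + phi_v <= 1` (no overlap), and by `0 <= phi_v <= phi_0`.
#' The active lower bound is `max(0, (xi*phi_0 - 1)/(xi - 1))` for `xi > 1`.
#'
#' @param phi_0 Scaled molecule number, strictly inside (0, 1). Vectorized.
#' @param xi Area ratio `>= 1`.
#' @return A list with numeric vectors `lo` and `hi` (`lo < hi`).
#' @export
feasible_phi_v_range <- function(phi_0, xi) {
  if (any(phi_0 <= 0) || any(phi_0 >= 1))
    stop("'phi_0' must lie strictly inside (0, 1)", call. = FALSE)
  lo <- if (xi > 1) pmax(0, (xi * phi_0 - 1) / (xi - 1)) else rep(0, length(phi_0))
  list(lo = lo, hi = phi_0)
}

#' Stationarity residual of the constrained free energy
#'
#' Partial derivative of `f~(phi_0, phi_v) = f(xi*(phi_0 - phi_v), phi_v)`
#' with respect to `phi_v`:
#'
#' `lam + ln(phi_v/phi_h) + (xi - 1) ln((1 - phi_h - phi_v)/(1 - phi_h))`
#'
#' with `phi_h = xi*(phi_0 - phi_v)`. Its unique zero on the feasible
#' interval is the equilibrium orientational distribution. The residual
#' diverges to -Inf at the lower end of the interval and to +Inf as
#' `phi_v -> phi_0`.
#'
#' @param phi_v Vertical fraction, strictly inside [feasible_phi_v_range()].
#' @param phi_0 Scaled molecule number in (0, 1).
#' @param p A [model_params()].
#' @return Residual in kT units. Vectorized over `phi_v`/`phi_0`.
#' @export
stationarity_residual <- function(phi_v, phi_0, p) {
  p <- as_model_params(p)
  r <- feasible_phi_v_range(phi_0, p$xi)
  if (any(phi_v <= r$lo) || any(phi_v >= r$hi))
    stop("'phi_v' must lie strictly inside the feasible interval",
         call. = FALSE)
  phi_h <- p$xi * (phi_0 - phi_v)
  p$lam + log(phi_v / phi_h) +
    (p$xi - 1) * log((1 - phi_h - phi_v) / (1 - phi_h))
}

# Unchecked residual used internally by the vectorized solver; u and w are
# formed by compensated products so that the bracket end points keep their
# analytic signs even within rounding distance of the packing constraints.
resid_raw <- function(phi_v, phi_0, xi, lam) {
  phi_h <- xi * (phi_0 - phi_v)
  uw <- comp_uw(xi, phi_0, phi_v)
  lam + log(phi_v / phi_h) + (xi - 1) * log(uw$w / uw$u)
}

#' Equilibrium vertical fraction
#'
#' Solves the stationarity condition for the vertical fraction at fixed
#' scaled molecule number, i.e. minimizes the constrained free energy
#' `f~(phi_0, .)` over the feasible interval. The root is bracketed by the
#' sign structure of the residual (-Inf at the lower end, +Inf at the upper
#' end), located by bisection, and polished by safeguarded Newton steps
#' using the closed-form second partial derivative.
#'
#' @param phi_0 Scaled molecule number(s) in (0, 1). Vectorized.
#' @param p A [model_params()].
#' @param tol Tolerance on the stationarity residual (kT units).
#' @return Equilibrium `phi_v` values, same length as `phi_0`.
#' @examples
#' solve_phi_v(0.25, model_params(4, 7))
#' @export
solve_phi_v <- function(phi_0, p, tol = 1e-12) {
  p <- as_model_params(p)
  stopifnot(tol > 0)
  r <- feasible_phi_v_range(phi_0, p$xi)
  lo <- r$lo; hi <- r$hi
  xi <- p$xi; lam <- p$lam
  width <- hi - lo

  # Bracket ends shrunk into the open interval; pushed geometrically toward
  # the boundary for any element whose root lies beyond the initial shrink
  # (extreme lam puts the root within ~exp(-|lam|) of an end point).
  a <- lo + width * 1e-6
  b <- hi - width * 1e-6
  for (k in seq_len(120)) {
    fa <- resid_raw(a, phi_0, xi, lam)
    bad <- is.finite(fa) & fa > 0
    if (!any(bad)) break
    a[bad] <- lo[bad] + (a[bad] - lo[bad]) / 16
  }
  for (k in seq_len(120)) {
    fb <- resid_raw(b, phi_0, xi, lam)
    bad <- is.finite(fb) & fb < 0
    if (!any(bad)) break
    b[bad] <- hi[bad] - (hi[bad] - b[bad]) / 16
  }
  fa <- resid_raw(a, phi_0, xi, lam)
  fb <- resid_raw(b, phi_0, xi, lam)
  if (any(!(fa < 0 & fb > 0)))
    stop("failed to bracket the stationarity root; this indicates a coding ",
         "error or parameters at the edge of numerical range", call. = FALSE)

  for (k in seq_len(80)) {
    m <- 0.5 * (a + b)
    fm <- resid_raw(m, phi_0, xi, lam)
    up <- fm < 0
    a[up] <- m[up]
    b[!up] <- m[!up]
  }
  x <- 0.5 * (a + b)

  # Newton polish on the residual; second partial of f~ wrt phi_v.
  for (k in seq_len(4)) {
    fx <- resid_raw(x, phi_0, xi, lam)
    if (all(abs(fx) < tol)) break
    d <- tryCatch(ftilde_partials(phi_0, x, p)$f_vv,
                  error = function(e) NULL)
    if (is.null(d)) break
    xn <- x - fx / d
    ok <- is.finite(xn) & xn > lo & xn < hi
    x[ok] <- xn[ok]
  }
  x
}

#' Closed-form equilibrium vertical fraction at phi_0 = 1/xi
#'
#' At the special molecule number `phi_0 = 1/xi` (scaled area per molecule
#' equal to `xi`) the stationarity condition has the analytic solution
#' `phi_v* = 1 / (exp(lam) * ((xi-1)/xi)^(xi-1) + xi)`, continuous at
#' `xi -> 1` where it becomes `1/(1 + exp(lam))`.
#'
#' @param p A [model_params()].
#' @return `phi_v*` in (0, 1/xi).
#' @examples
#' phi_v_star(model_params(4, 0))  # 1/((3/4)^3 + 4)
#' @export
phi_v_star <- function(p) {
  p <- as_model_params(p)
  if (p$xi == 1) return(1 / (1 + exp(p$lam)))
  1 / (exp(p$lam) * ((p$xi - 1) / p$xi)^(p$xi - 1) + p$xi)
}
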