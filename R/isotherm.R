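#' Slope of the equilibrium orientational distribution
#'
#' Derivative `d phi_v^opt / d phi_0` of the equilibrium vertical fraction
#' with respect to the scaled molecule number, obtained from the implicit
#' function theorem applied to the stationarity condition:
#' `-(d2f/dphi_v dphi_0) / (d2f/dphi_v^2)` evaluated at equilibrium.
#'
#' @param phi_0 Scaled molecule number(s) in (0, 1).
#' @param p A [model_params()].
#' @return Numeric vector of slopes; equals `1/(1 + exp(lam))` for `xi = 1`.
#' @export
dphi_v_dphi_0 <- function(phi_0, p) {
  p <- as_model_params(p)
  phi_v <- solve_phi_v(phi_0, p)
  d <- ftilde_partials(phi_0, phi_v, p)
  if (any(abs(d$f_vv) < 1e-300))
    stop("vanishing curvature of the free energy in phi_v; cannot apply ",
         "the implicit function theorem", call. = FALSE)
  -d$f_v0 / d$f_vv
}

#' Scaled lateral pressure of the monolayer
#'
#' Dimensionless surface pressure `a0*Pi` (in kT units) at scaled molecule
#' number `phi_0 = a0/a`. Computed from the closed-form partial derivatives
#' of the constrained free energy evaluated at the equilibrium orientational
#' distribution:
#'
#' `a0*Pi = phi_0 * (df/dphi_0 - df/dphi_v * (d2f/dphi_v dphi_0) /
#'          (d2f/dphi_v^2)) - f`
#'
#' At exact equilibrium the correction term vanishes (envelope property) and
#' the expression reduces to the Legendre-type form `phi_0 * df_opt' - f_opt`.
#' For `xi = 1` the result is the lattice-gas pressure `-ln(1 - phi_0)`,
#' independent of the reorientation energy.
#'
#' @param phi_0 Scaled molecule number(s); values `>= 1` yield `Inf`
#'   (closest packing).
#' @param p A [model_params()].
#' @param phi_v Optional orientational distribution to impose instead of the
#'   equilibrium one (used by the piecewise-linear approximation).
#' @return `a0*Pi` in kT units, non-negative.
#' @examples
#' scaled_pressure(0.25, model_params(4, 7))  # analytic point, phi_0 = 1/xi
#' @export
scaled_pressure <- function(phi_0, p, phi_v = NULL) {
  p <- as_model_params(p)
  out <- rep(NA_real_, length(phi_0))
  out[phi_0 >= 1] <- Inf
  ok <- phi_0 > 0 & phi_0 < 1
  if (!any(ok)) return(out)
  ph0 <- phi_0[ok]
  pv <- if (is.null(phi_v)) solve_phi_v(ph0, p) else {
    stopifnot(length(phi_v) == length(phi_0))
    phi_v[ok]
  }
  # Clamp an imposed distribution into the open feasible interval so the
  # logarithmic terms stay finite at the end points of approximations.
  r <- feasible_phi_v_range(ph0, p$xi)
  eps <- 1e-13 * (r$hi - r$lo)
  pv <- pmin(pmax(pv, r$lo + eps), r$hi - eps)
  d <- ftilde_partials(ph0, pv, p)
  out[ok] <- ph0 * (d$f_0 - d$f_v * d$f_v0 / d$f_vv) - d$f
  out
}

#' Closed-form pressure at the analytic point phi_0 = 1/xi
#'
#' At scaled area per molecule `a/a0 = xi` the model pressure has the closed
#' form `a0*Pi = -ln(xi - 1) + (1/xi) * ln(exp(lam)*(xi-1)^(xi-1) + xi^xi)`.
#' This is the landmark the reorientation-energy estimator inverts. Evaluated
#' in log-space so that large `lam` or `xi` do not overflow.
#'
#' @param p A [model_params()] with `xi > 1`.
#' @return `a0*Pi` in kT units.
#' @export
pressure_at_star <- function(p) {
  p <- as_model_params(p)
  if (p$xi <= 1)
    stop("'pressure_at_star' requires xi > 1; for xi = 1 the pressure is ",
         "-log(1 - phi_0) at any phi_0", call. = FALSE)
  xi <- p$xi
  # log(exp(lam)*(xi-1)^(xi-1) + xi^xi) via logsumexp
  t1 <- p$lam + (xi - 1) * log(xi - 1)
  t2 <- xi * log(xi)
  m <- pmax(t1, t2)
  -log(xi - 1) + (m + log(exp(t1 - m) + exp(t2 - m))) / xi
}

#' Second and third derivatives of the optimized free energy
#'
#' Total derivatives `d2 f_opt/dphi_0^2` and `d3 f_opt/dphi_0^3` of the
#' free energy along the equilibrium path `phi_v = phi_v^opt(phi_0)`. Two
#' independent routes are provided: `"implicit"` (default) eliminates the
#' derivatives of the unknown equilibrium function through the implicit
#' function theorem, leaving only closed-form partials of the constrained
#' free energy; `"fd"` applies 5-point central finite-difference stencils
#' to `f_opt` values obtained from the solver.
#'
#' @param phi_0 Scaled molecule number(s) in (0, 1).
#' @param p A [model_params()].
#' @param method `"implicit"` or `"fd"`.
#' @param step Base stencil spacing for the finite-difference route (halved
#'   once for Richardson extrapolation; shrunk automatically near the
#'   domain ends).
#' @return A list with numeric vectors `d2` and `d3`.
#' @export
fopt_derivatives <- function(phi_0, p, method = c("implicit", "fd"),
                             step = 1e-3) {
  p <- as_model_params(p)
  method <- match.arg(method)
  if (method == "fd") {
    fopt <- function(x) ftilde_value(x, solve_phi_v(x, p), p)
    stencil <- function(h) {
      vals <- vapply(-2:2, function(j) fopt(phi_0 + j * h),
                     numeric(length(phi_0)))
      vals <- matrix(vals, nrow = length(phi_0))
      list(d2 = (-vals[, 1] + 16 * vals[, 2] - 30 * vals[, 3] +
                   16 * vals[, 4] - vals[, 5]) / (12 * h^2),
           d3 = (vals[, 5] - 2 * vals[, 4] + 2 * vals[, 2] - vals[, 1]) /
             (2 * h^3))
    }
    h <- pmin(step, pmin(phi_0, 1 - phi_0) / 8)
    full <- stencil(h)
    half <- stencil(h / 2)
    # Richardson: the 5-point d2 is O(h^4), the d3 stencil O(h^2)
    return(list(d2 = (16 * half$d2 - full$d2) / 15,
                d3 = (4 * half$d3 - full$d3) / 3))
  }
  phi_v <- solve_phi_v(phi_0, p)
  d <- ftilde_partials(phi_0, phi_v, p)
  dpv <- -d$f_v0 / d$f_vv
  # d2 f_opt = Schur complement of the Hessian of f~
  d2 <- d$f_00 - d$f_v0^2 / d$f_vv
  # d3 f_opt: differentiate the Schur complement along the path
  dF2_d0 <- d$f_000 - 2 * d$f_v0 * d$f_00v / d$f_vv +
    d$f_v0^2 * d$f_0vv / d$f_vv^2
  dF2_dv <- d$f_00v - 2 * d$f_v0 * d$f_0vv / d$f_vv +
    d$f_v0^2 * d$f_vvv / d$f_vv^2
  d3 <- dF2_d0 + dF2_dv * dpv
  list(d2 = d2, d3 = d3)
}

#' Inflection-point condition for the isotherm in area coordinates
#'
#' When the pressure is plotted against the scaled area per molecule
#' `a/a0 = 1/phi_0`, its inflection points are the zeros of
#' `3 * d2f_opt/dphi_0^2 + phi_0 * d3f_opt/dphi_0^3`. Working in `phi_0`
#' coordinates through this combination avoids numerically differentiating
#' the pressure curve itself.
#'
#' @inheritParams fopt_derivatives
#' @return Numeric vector: the condition value (sign changes locate
#'   inflections).
#' @export
inflection_condition <- function(phi_0, p) {
  d <- fopt_derivatives(phi_0, p)
  3 * d$d2 + phi_0 * d$d3
}

#' Locate the inflection points of an isotherm
#'
#' Scans the inflection condition on a uniform `phi_0` grid, refines every
#' sign change by bisection, and maps the roots to area coordinates. The
#' member with the largest `a/a0` is the first inflection met on
#' compression — the landmark used to estimate the reorientation energy.
#' An empty set is a valid result (isotherms without a shoulder).
#'
#' @param p A [model_params()].
#' @param grid_size Number of grid points (>= 200).
#' @param phi0_range Interval scanned; end points stay off 0 and 1.
#' @param tol Bisection tolerance in `phi_0`.
#' @return An object of class `inflection_set`: list with `params`, a
#'   data frame `inflections` (columns `phi_0`, `area_ratio`,
#'   `scaled_pressure`, largest area first) and `first_on_compression`
#'   (one-row data frame or `NULL`).
#' @examples
#' find_inflections(model_params(4, 7))
#' @export
find_inflections <- function(p, grid_size = 2001,
                             phi0_range = c(1e-3, 1 - 1e-3), tol = 1e-10) {
  p <- as_model_params(p)
  stopifnot(grid_size >= 200)
  grid <- seq(phi0_range[1], phi0_range[2], length.out = grid_size)
  g <- inflection_condition(grid, p)
  s <- sign(g)
  idx <- which(s[-1] * s[-length(s)] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(function(x) inflection_condition(x, p),
                   lower = grid[i], upper = grid[i + 1], tol = tol)$root
  }, numeric(1))
  infl <- data.frame(phi_0 = roots,
                     area_ratio = 1 / roots,
                     scaled_pressure = if (length(roots))
                       scaled_pressure(roots, p) else numeric(0))
  infl <- infl[order(-infl$area_ratio), , drop = FALSE]
  rownames(infl) <- NULL
  structure(list(params = p, inflections = infl,
                 first_on_compression = if (nrow(infl)) infl[1, ] else NULL),
            class = "inflection_set")
}

#' @export
print.inflection_set <- function(x, ...) {
  cat(sprintf("Isotherm inflection points (xi = %g, lam = %g kT)\n",
              x$params$xi, x$params$lam))
  if (!nrow(x$inflections)) {
    cat("  none (no shoulder in this isotherm)\n")
  } else {
    print(x$inflections, row.names = FALSE)
  }
  invisible(x)
}

#' Smallest reorientation energy that produces a shoulder
#'
#' For fixed area ratio, inflection points of the isotherm (in `a/a0`
#' coordinates) only exist above a threshold reorientation energy. The
#' threshold is found by bisection on the existence indicator of
#' [find_inflections()].
#'
#' @param xi Area ratio `> 1`.
#' @param tol Bisection tolerance on the threshold (kT units), `<= 0.01`.
#' @param lam_range Initial search range; expanded upward if needed.
#' @param grid_size Grid used inside the existence test.
#' @return The critical reorientation energy in kT units.
#' @examples
#' \donttest{critical_lambda(4)}  # about 3.85 kT
#' @export
critical_lambda <- function(xi, tol = 0.005, lam_range = c(0, 10),
                            grid_size = 801) {
  stopifnot(xi > 1, tol > 0, tol <= 0.01)
  exists_at <- function(lam) {
    g <- inflection_condition(seq(1e-3, 1 - 1e-3, length.out = grid_size),
                              model_params(xi, lam))
    any(g[-1] * g[-length(g)] < 0)
  }
  lo <- lam_range[1]; hi <- lam_range[2]
  if (exists_at(lo))
    stop("inflections already exist at the lower end of 'lam_range'",
         call. = FALSE)
  tries <- 0
  while (!exists_at(hi)) {
    hi <- hi + diff(lam_range)
    tries <- tries + 1
    if (tries > 10)
      stop("no inflection regime found when expanding 'lam_range'",
           call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- 0.5 * (lo + hi)
    if (exists_at(mid)) hi <- mid else lo <- mid
  }
  0.5 * (lo + hi)
}

#' Piecewise-linear approximation of the equilibrium distribution
#'
#' Interpolates the equilibrium vertical fraction linearly between its exact
#' end points (0 at `phi_0 = 0`, 1 at `phi_0 = 1`) through the analytically
#' known value `phi_v*` at `phi_0 = 1/xi`:
#' `phi_v = xi * phi_v* * phi_0` below the kink and
#' `phi_v* + (1 - phi_v*)/(1 - 1/xi) * (phi_0 - 1/xi)` above it.
#'
#' @param phi_0 Scaled molecule number(s) in `[0, 1]`. Vectorized.
#' @param p A [model_params()] with `xi > 1`.
#' @return Approximate vertical fraction(s).
#' @export
piecewise_linear_phi_v <- function(phi_0, p) {
  p <- as_model_params(p)
  if (p$xi <= 1)
    stop("the piecewise-linear approximation requires xi > 1", call. = FALSE)
  if (any(phi_0 < 0) || any(phi_0 > 1))
    stop("'phi_0' must lie in [0, 1]", call. = FALSE)
  pv_star <- phi_v_star(p)
  kink <- 1 / p$xi
  ifelse(phi_0 <= kink,
         p$xi * pv_star * phi_0,
         pv_star + (1 - pv_star) / (1 - kink) * (phi_0 - kink))
}

#' Compute a surface pressure-area isotherm
#'
#' Tabulates the equilibrium vertical fraction and the scaled lateral
#' pressure on a uniform grid of the scaled molecule number `phi_0`, i.e.
#' along a compression path `a/a0 = 1/phi_0`. In `approximate` mode the
#' piecewise-linear orientational distribution is inserted into the pressure
#' expression instead of the exact equilibrium solution.
#'
#' @param p A [model_params()].
#' @param n_points Number of grid points.
#' @param phi0_min,phi0_max Grid limits, `0 < phi0_min < phi0_max < 1`.
#' @param approximate Use the piecewise-linear distribution (`xi > 1` only).
#' @return An object of class `isotherm_curve`: a data frame with columns
#'   `phi_0`, `area_ratio`, `phi_v`, `a0Pi` and attribute `params`.
#' @examples
#' crv <- compute_isotherm(model_params(4, 7), n_points = 101)
#' head(as.data.frame(crv))
#' @export
compute_isotherm <- function(p, n_points = 2001, phi0_min = 1e-3,
                             phi0_max = 1 - 1e-3, approximate = FALSE) {
  p <- as_model_params(p)
  stopifnot(n_points >= 2, phi0_min > 0, phi0_max < 1, phi0_min < phi0_max)
  phi_0 <- seq(phi0_min, phi0_max, length.out = n_points)
  phi_v <- if (approximate) piecewise_linear_phi_v(phi_0, p)
           else solve_phi_v(phi_0, p)
  a0Pi <- if (approximate) scaled_pressure(phi_0, p, phi_v = phi_v)
          else scaled_pressure(phi_0, p)
  out <- data.frame(phi_0 = phi_0, area_ratio = 1 / phi_0,
                    phi_v = phi_v, a0Pi = a0Pi)
  structure(out, params = p, approximate = approximate,
            class = c("isotherm_curve", "data.frame"))
}

#' @export
print.isotherm_curve <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Surface pressure-area isotherm (xi = %g, lam = %g kT, %d points%s)\n",
              p$xi, p$lam, nrow(x),
              if (isTRUE(attr(x, "approximate"))) ", piecewise-linear" else ""))
  print(utils::head(as.data.frame(x)), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Quick base-graphics preview of one or more isotherms
#'
#' @param x An `isotherm_curve`.
#' @param xlim Area-ratio window.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.isotherm_curve <- function(x, xlim = c(1, 10), ...) {
  keep <- x$area_ratio >= xlim[1] & x$area_ratio <= xlim[2] &
    is.finite(x$a0Pi)
  graphics::plot(x$area_ratio[keep], x$a0Pi[keep], type = "l",
                 xlab = expression(a / a[0]),
                 ylab = expression(a[0] * Pi / k[B] * T), ...)
  invisible(x)
}
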