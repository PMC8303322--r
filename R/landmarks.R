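KB_J_PER_K <- 1.380649e-23
AVOGADRO <- 6.02214076e23

#' Experimental isotherm landmarks
#'
#' The three numbers the reorientation-energy estimator needs, read off a
#' recorded surface pressure-area isotherm: the limiting (collapse) area per
#' molecule `a0`, and the area and pressure at the first inflection met on
#' compression. `a0` is identified with the vertical-orientation
#' cross-section; the inflection sits close to the area ratio `a/a0 = xi`.
#'
#' @param a0 Limiting area per molecule, nm^2.
#' @param a_infl Mean molecular area at the first inflection, nm^2
#'   (`> a0`).
#' @param pi_infl Lateral pressure at that inflection, mN/m (`> 0`).
#' @param kBT Thermal energy in J (default 4.14e-21, about 300 K).
#' @return An object of class `isotherm_landmarks`.
#' @examples
#' isotherm_landmarks(a0 = 0.4, a_infl = 2.7, pi_infl = 27)
#' @export
isotherm_landmarks <- function(a0, a_infl, pi_infl, kBT = 4.14e-21) {
  stopifnot(length(a0) == 1L, length(a_infl) == 1L, length(pi_infl) == 1L,
            length(kBT) == 1L)
  if (!(a0 > 0 && a_infl > a0))
    stop("need a_infl > a0 > 0 (inflection area above the limiting area)",
         call. = FALSE)
  if (pi_infl <= 0) stop("'pi_infl' must be positive", call. = FALSE)
  if (kBT <= 0) stop("'kBT' must be positive", call. = FALSE)
  structure(list(a0 = a0, a_infl = a_infl, pi_infl = pi_infl, kBT = kBT),
            class = "isotherm_landmarks")
}

#' Dimensionless scaled pressure from experimental units
#'
#' Converts a pressure in mN/m and a molecular area in nm^2 into the
#' dimensionless combination `a0*Pi/kBT` used throughout the model
#' (1 nm^2 * mN/m = 1e-21 J).
#'
#' @param a0_nm2 Area per molecule, nm^2.
#' @param pi_mN_per_m Lateral pressure, mN/m.
#' @param kBT_J Thermal energy, J.
#' @return Dimensionless `a0*Pi`.
#' @examples
#' dimensionless_pressure(0.4, 27)  # 2.61 for cyclosporin A
#' @export
dimensionless_pressure <- function(a0_nm2, pi_mN_per_m, kBT_J = 4.14e-21) {
  if (any(a0_nm2 <= 0) || any(kBT_J <= 0) || any(pi_mN_per_m < 0))
    stop("areas and thermal energy must be positive, pressure non-negative",
         call. = FALSE)
  (a0_nm2 * 1e-18) * (pi_mN_per_m * 1e-3) / kBT_J
}

#' Reorientation energy from the dimensionless landmark pressure
#'
#' Inverts the closed-form pressure at the analytic point `a/a0 = xi`
#' for the reorientation energy:
#'
#' `lam = ln(((xi-1)^xi * exp(xi*a0Pi) - xi^xi) / (xi-1)^(xi-1))`
#'
#' evaluated in log-space so that large `xi*a0Pi` cannot overflow. A real
#' solution exists only when `xi > 1/(1 - exp(-a0Pi))`; outside that region
#' an estimation error is raised.
#'
#' @param a0Pi Dimensionless scaled pressure at the inflection landmark.
#' @param xi Area ratio `> 1`.
#' @return Reorientation energy in kT units.
#' @examples
#' lambda_from_dimensionless(2.61, 6.75)  # about 19 kT (cyclosporin A)
#' @export
lambda_from_dimensionless <- function(a0Pi, xi) {
  stopifnot(length(a0Pi) == 1L, length(xi) == 1L)
  if (xi <= 1)
    stop("'xi' must exceed 1 for the landmark inversion", call. = FALSE)
  t1 <- xi * log(xi - 1) + xi * a0Pi
  t2 <- xi * log(xi)
  if (t1 <= t2)
    stop(sprintf(paste0("no real-valued reorientation energy: requires xi > ",
                        "1/(1 - exp(-a0Pi)) = %.4g but xi = %.4g"),
                 1 / (1 - exp(-a0Pi)), xi),
         call. = FALSE)
  t1 + log1p(-exp(t2 - t1)) - (xi - 1) * log(xi - 1)
}

#' Estimate the reorientation energy from isotherm landmarks
#'
#' Implements the landmark recipe: the area ratio is `xi = a_infl/a0`, the
#' dimensionless pressure is `a0*pi_infl/kBT`, and the reorientation energy
#' follows from the closed-form inversion at the analytic point. When the
#' validity condition `xi > 1/(1 - exp(-a0Pi))` fails, the estimate is
#' returned with `valid = FALSE` and no energy value.
#'
#' @param landmarks An [isotherm_landmarks()] object.
#' @return An object of class `lambda_estimate`: list with `xi`, `a0Pi`,
#'   `lam` (kT units; `NA` if invalid), `valid`, and the echoed `landmarks`.
#' @examples
#' estimate_lambda(isotherm_landmarks(0.4, 2.7, 27))
#' @export
estimate_lambda <- function(landmarks) {
  stopifnot(inherits(landmarks, "isotherm_landmarks"))
  xi <- landmarks$a_infl / landmarks$a0
  a0Pi <- dimensionless_pressure(landmarks$a0, landmarks$pi_infl,
                                 landmarks$kBT)
  lam <- tryCatch(lambda_from_dimensionless(a0Pi, xi),
                  error = function(e) NA_real_)
  structure(list(xi = xi, a0Pi = a0Pi, lam = lam, valid = is.finite(lam),
                 landmarks = landmarks),
            class = "lambda_estimate")
}

#' @export
print.lambda_estimate <- function(x, ...) {
  cat("Reorientation-energy estimate from isotherm landmarks\n")
  lm <- x$landmarks
  cat(sprintf("  inputs : a0 = %g nm^2, a_infl = %g nm^2, Pi_infl = %g mN/m, kBT = %g J\n",
              lm$a0, lm$a_infl, lm$pi_infl, lm$kBT))
  cat(sprintf("  xi     = %g  (area ratio a_infl/a0)\n", x$xi))
  cat(sprintf("  a0*Pi  = %.4g  (dimensionless landmark pressure)\n", x$a0Pi))
  if (x$valid) {
    cat(sprintf("  lambda = %.4g kT  (reorientation energy)\n", x$lam))
  } else {
    cat("  lambda : no real solution; requires xi > 1/(1 - exp(-a0Pi))\n")
  }
  invisible(x)
}

#' Convert a reorientation energy from kT units to kJ/mol
#'
#' @param lam_kBT Energy in units of kT.
#' @param T_kelvin Absolute temperature, K.
#' @return Energy in kJ/mol (`lam * kB * T * NA / 1000`).
#' @examples
#' lambda_to_kj_per_mol(19, 300)  # about 47.4 kJ/mol
#' @export
lambda_to_kj_per_mol <- function(lam_kBT, T_kelvin = 300) {
  stopifnot(all(T_kelvin > 0))
  lam_kBT * KB_J_PER_K * T_kelvin * AVOGADRO / 1000
}

#' Detect the first inflection of a digitized isotherm
#'
#' Automates the visual identification of the landmark inflection: the
#' pressure curve is smoothed by local quadratic regression over a sliding
#' window of points and the local curvature (second derivative of pressure
#' with respect to area) is read off the quadratic coefficient. The
#' shoulder shows up as a concave lobe (negative curvature); the detector
#' anchors at the strongest concave point and walks toward larger areas to
#' the curvature sign change that bounds the lobe, refining it by linear
#' interpolation. Anchoring at the dominant lobe rather than at the first
#' raw sign change keeps small-amplitude noise wiggles in flat regions of
#' the isotherm from masquerading as the landmark; for noisy data, choose a
#' `window` wide enough that the smoothed curvature of the flat regions
#' stays clear of zero.
#'
#' @param data An `experimental_isotherm` (see [read_isotherm_csv()] or
#'   [generate_synthetic_isotherm()]), at least 15 records.
#' @param window Odd window length (points) for the local quadratic fit.
#' @return A list with `a_infl` (nm^2) and `pi_infl` (mN/m).
#' @export
detect_first_inflection <- function(data, window = 7) {
  data <- as_experimental_isotherm(data)
  n <- nrow(data)
  if (n < 15)
    stop("need at least 15 records spanning the shoulder", call. = FALSE)
  window <- as.integer(window)
  if (window < 5 || window %% 2 == 0)
    stop("'window' must be an odd integer >= 5", call. = FALSE)
  half <- window %/% 2
  a <- data$area_nm2
  pr <- data$pressure_mN_per_m
  centers <- (half + 1):(n - half)
  fits <- vapply(centers, function(i) {
    x <- a[(i - half):(i + half)] - a[i]
    y <- pr[(i - half):(i + half)]
    cf <- stats::coef(stats::lm(y ~ x + I(x^2)))
    c(smooth = unname(cf[1]), curv = 2 * unname(cf[3]))
  }, numeric(2))
  smooth <- fits[1, ]
  curv <- fits[2, ]
  # centers run from largest to smallest area (compression direction);
  # anchor at the strongest concave point of the shoulder
  anchor <- which.min(curv)
  if (curv[anchor] >= 0)
    stop("no concave region found; the isotherm has no detectable ",
         "inflection - supply the landmark manually", call. = FALSE)
  j <- anchor
  while (j > 1 && curv[j - 1] < 0) j <- j - 1
  if (j == 1)
    stop("the concave shoulder is not bounded at large areas within the ",
         "data; extend the isotherm or supply the landmark manually",
         call. = FALSE)
  i <- j - 1
  a1 <- a[centers[i]]; a2 <- a[centers[i + 1]]
  c1 <- curv[i]; c2 <- curv[i + 1]
  t <- c1 / (c1 - c2)
  a_infl <- a1 + t * (a2 - a1)
  pi_infl <- smooth[i] + t * (smooth[i + 1] - smooth[i])
  list(a_infl = a_infl, pi_infl = pi_infl)
}

#' Fit the full two-state model to a digitized isotherm
#'
#' Least-squares refinement of the landmark method: minimizes the sum of
#' squared pressure residuals between the recorded isotherm and the
#' dimensionalized model curve `Pi(a) = a0Pi(phi_0 = a0/a) * kBT / a0`
#' over `(a0, xi, lam)`, using Levenberg-Marquardt. When the fitted area
#' ratio collapses onto `xi = 1` the reorientation energy does not affect
#' the pressure at all; the same degeneracy appears as `lam -> -Inf` with
#' any `xi` (every molecule vertical) and as `lam -> +Inf` with `a0*xi`
#' fixed (every molecule horizontal - only the horizontal cross-section
#' `a0*xi` is then identifiable). The fit probes the sensitivity of the
#' residual to `lam` at the solution and flags `lam` as unidentifiable
#' instead of reporting an arbitrary value.
#'
#' @param data An `experimental_isotherm`.
#' @param init Named list or vector with starting values `a0` (nm^2), `xi`,
#'   `lam` (kT) — typically from [estimate_lambda()] landmarks.
#' @param kBT Thermal energy, J.
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return An object of class `isotherm_fit`: list with fitted `a0`, `xi`,
#'   `lam`, `residual_norm` (mN/m), `lambda_degenerate`, `converged`,
#'   `message`, and `fitted` pressures.
#' @export
fit_isotherm <- function(data, init, kBT = 4.14e-21,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)) {
  data <- as_experimental_isotherm(data)
  init <- as.list(init)
  stopifnot(all(c("a0", "xi", "lam") %in% names(init)))
  a <- data$area_nm2
  pr <- data$pressure_mN_per_m
  a_min <- min(a)
  model_pressure <- function(a0, xi, lam, areas) {
    phi_0 <- pmin(a0 / areas, 1 - 1e-9)
    scaled_pressure(phi_0, model_params(xi, lam)) * kBT / (a0 * 1e-18) * 1e3
  }
  resid_fn <- function(par) {
    pr - model_pressure(par[["a0"]], par[["xi"]], par[["lam"]], a)
  }
  lower <- c(a0 = 1e-4, xi = 1, lam = -50)
  upper <- c(a0 = 0.999 * a_min, xi = 100, lam = 500)
  par0 <- pmin(pmax(unlist(init[c("a0", "xi", "lam")]), lower), upper)
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            lower = lower, upper = upper, control = control)
  est <- as.list(stats::coef(fit))
  rn <- function(lam) sqrt(sum(resid_fn(c(a0 = est$a0, xi = est$xi,
                                          lam = lam))^2))
  base_norm <- rn(est$lam)
  lam_sens <- max(abs(rn(est$lam + 1) - base_norm),
                  abs(rn(est$lam - 1) - base_norm))
  degenerate <- est$xi < 1 + 1e-3 || lam_sens < 1e-6 * (1 + base_norm)
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("least-squares fit did not converge: ", fit$message,
            call. = FALSE)
  structure(list(a0 = est$a0, xi = est$xi,
                 lam = if (degenerate) NA_real_ else est$lam,
                 residual_norm = sqrt(sum(fit$fvec^2)),
                 lambda_degenerate = degenerate,
                 converged = converged, message = fit$message,
                 fitted = model_pressure(est$a0, est$xi, est$lam, a),
                 data = data),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat("Two-state model fit to a digitized isotherm\n")
  cat(sprintf("  a0  = %.4g nm^2\n  xi  = %.4g\n", x$a0, x$xi))
  if (x$lambda_degenerate) {
    cat("  lam : unidentifiable (xi at 1; pressure independent of lam)\n")
  } else {
    cat(sprintf("  lam = %.4g kT\n", x$lam))
  }
  cat(sprintf("  residual norm = %.3g mN/m (%s)\n", x$residual_norm,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
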