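#' Model parameters for the two-state monolayer
#'
#' The model is fully specified by two dimensionless numbers: the area ratio
#' `xi` between the horizontal and vertical cross-sections of the molecule,
#' and the reorientation energy `lam` (cost to switch one molecule from
#' horizontal to vertical), measured in units of the thermal energy kT.
#'
#' @param xi Area ratio, dimensionless, `>= 1`. `xi = 1` is the degenerate
#'   case in which reorientation decouples from the lateral pressure.
#' @param lam Reorientation energy per molecule in kT units; any finite real
#'   (negative values mean the vertical orientation is favored).
#' @return An object of class `model_params`.
#' @examples
#' model_params(xi = 4, lam = 7)
#' @export
model_params <- function(xi, lam) {
  stopifnot(is.numeric(xi), length(xi) == 1L, is.finite(xi),
            is.numeric(lam), length(lam) == 1L, is.finite(lam))
  if (xi < 1)
    stop("'xi' must be >= 1 (horizontal cross-section cannot be smaller ",
         "than vertical)", call. = FALSE)
  structure(list(xi = as.numeric(xi), lam = as.numeric(lam)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Two-state monolayer model parameters\n")
  cat(sprintf("  xi  (area ratio)          : %g\n", x$xi))
  cat(sprintf("  lam (reorientation energy): %g kT\n", x$lam))
  invisible(x)
}

as_model_params <- function(p) {
  if (inherits(p, "model_params")) return(p)
  if (is.list(p) && all(c("xi", "lam") %in% names(p)))
    return(model_params(p$xi, p$lam))
  stop("expected a 'model_params' object", call. = FALSE)
}

#' Integer lattice configuration
#'
#' Bookkeeping for the discrete lattice-sublattice picture: a lattice of `M`
#' unit cells (one vertical molecule each) partitioned into `M/xi` super-cells
#' (one horizontal molecule each). Used for the combinatorial demonstrations;
#' the continuum model takes real `xi`.
#'
#' @param M Total number of lattice sites (positive integer).
#' @param xi Integer sublattice factor `>= 1`; `M` must be divisible by `xi`.
#' @param Nh Number of horizontal molecules (each blocks `xi` sites).
#' @param Nv Number of vertical molecules (each blocks one site).
#' @return An object of class `lattice_config`.
#' @examples
#' lattice_config(M = 64, xi = 4, Nh = 5, Nv = 15)
#' @export
lattice_config <- function(M, xi, Nh, Nv) {
  stopifnot(length(M) == 1L, length(xi) == 1L, length(Nh) == 1L,
            length(Nv) == 1L)
  M <- as.integer(M); xi <- as.integer(xi)
  Nh <- as.integer(Nh); Nv <- as.integer(Nv)
  if (M <= 0L) stop("'M' must be a positive integer", call. = FALSE)
  if (xi < 1L) stop("'xi' must be an integer >= 1", call. = FALSE)
  if (M %% xi != 0L) stop("'M' must be divisible by 'xi'", call. = FALSE)
  if (Nh < 0L || Nv < 0L)
    stop("molecule counts must be non-negative", call. = FALSE)
  if (Nh > M %/% xi)
    stop("'Nh' exceeds the number of sublattice cells M/xi", call. = FALSE)
  if (xi * Nh + Nv > M)
    stop("steric overlap: xi*Nh + Nv exceeds the number of lattice sites M",
         call. = FALSE)
  structure(list(M = M, xi = xi, Nh = Nh, Nv = Nv), class = "lattice_config")
}

#' Fractional occupancies from molecule counts
#'
#' Converts an integer lattice configuration into the fractions of lattice
#' sites covered by horizontal molecules (`phi_h = xi*Nh/M`), by vertical
#' molecules (`phi_v = Nv/M`), their sum `phi_tot`, and the scaled molecule
#' number `phi_0 = phi_h/xi + phi_v` (the coverage if every molecule stood
#' vertically; `phi_0 <= phi_tot`).
#'
#' @param cfg A [lattice_config()].
#' @return A list of class `occupancy_state` with elements `phi_h`, `phi_v`,
#'   `phi_tot`, `phi_0`.
#' @examples
#' occupancy_from_counts(lattice_config(64, 4, Nh = 5, Nv = 15))
#' @export
occupancy_from_counts <- function(cfg) {
  stopifnot(inherits(cfg, "lattice_config"))
  phi_h <- cfg$xi * cfg$Nh / cfg$M
  phi_v <- cfg$Nv / cfg$M
  structure(list(phi_h = phi_h, phi_v = phi_v,
                 phi_tot = phi_h + phi_v,
                 phi_0 = phi_h / cfg$xi + phi_v),
            class = "occupancy_state")
}

#' @export
print.occupancy_state <- function(x, ...) {
  cat("Lattice occupancies\n")
  cat(sprintf("  phi_h = %g, phi_v = %g, phi_tot = %g, phi_0 = %g\n",
              x$phi_h, x$phi_v, x$phi_tot, x$phi_0))
  invisible(x)
}
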