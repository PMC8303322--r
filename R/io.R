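#' Construct / validate a digitized experimental isotherm
#'
#' A digitized surface pressure-area record set, ordered in the compression
#' direction (strictly decreasing area). Pressures must be finite and
#' non-negative.
#'
#' @param area_nm2 Areas per molecule, nm^2.
#' @param pressure_mN_per_m Lateral pressures, mN/m.
#' @return A data frame of class `experimental_isotherm` with columns
#'   `area_nm2`, `pressure_mN_per_m`.
#' @export
experimental_isotherm <- function(area_nm2, pressure_mN_per_m) {
  stopifnot(length(area_nm2) == length(pressure_mN_per_m))
  if (any(!is.finite(area_nm2)) || any(!is.finite(pressure_mN_per_m)))
    stop("areas and pressures must be finite", call. = FALSE)
  if (any(area_nm2 <= 0))
    stop("areas must be positive", call. = FALSE)
  bad <- which(pressure_mN_per_m < 0)
  if (length(bad))
    stop("negative pressure in record ", bad[1], call. = FALSE)
  ord <- order(-area_nm2)
  area_nm2 <- area_nm2[ord]
  pressure_mN_per_m <- pressure_mN_per_m[ord]
  if (anyDuplicated(area_nm2))
    stop("duplicate area values; areas must be strictly monotone",
         call. = FALSE)
  structure(data.frame(area_nm2 = area_nm2,
                       pressure_mN_per_m = pressure_mN_per_m),
            class = c("experimental_isotherm", "data.frame"))
}

as_experimental_isotherm <- function(x) {
  if (inherits(x, "experimental_isotherm")) return(x)
  if (is.data.frame(x) &&
      all(c("area_nm2", "pressure_mN_per_m") %in% names(x)))
    return(experimental_isotherm(x$area_nm2, x$pressure_mN_per_m))
  stop("expected an 'experimental_isotherm'", call. = FALSE)
}

#' Read a digitized isotherm from CSV
#'
#' Expects two numeric columns `area_nm2,pressure_mN_per_m` with a header
#' row; lines starting with `#` are treated as comments. Records are
#' validated and sorted by decreasing area (compression direction).
#'
#' @param path Path to a CSV file.
#' @return An `experimental_isotherm`.
#' @export
read_isotherm_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, comment.char = "#",
                         colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) < 2)
    stop("expected 2 columns (area_nm2, pressure_mN_per_m) in ", path,
         call. = FALSE)
  area <- suppressWarnings(as.numeric(raw[[1]]))
  pres <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(is.na(area) | is.na(pres))
  if (length(bad))
    stop("malformed row ", bad[1], " in ", path,
         " (non-numeric area or pressure)", call. = FALSE)
  experimental_isotherm(area, pres)
}

#' Write an isotherm (experimental records or model curve) to CSV
#'
#' Experimental records are written with the standard two-column header.
#' Model curves ([compute_isotherm()]) are written with columns
#' `phi0,area_ratio,phi_v,a0Pi` preceded by `#`-prefixed metadata lines
#' recording the model parameters and the grid.
#'
#' @param x An `experimental_isotherm` or `isotherm_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isotherm_csv <- function(x, path) {
  if (inherits(x, "isotherm_curve")) {
    p <- attr(x, "params")
    meta <- c(sprintf("# xi = %.17g", p$xi),
              sprintf("# lam = %.17g", p$lam),
              sprintf("# grid = %d points, phi0 in [%.17g, %.17g]",
                      nrow(x), min(x$phi_0), max(x$phi_0)),
              if (isTRUE(attr(x, "approximate")))
                "# phi_v: piecewise-linear approximation")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(meta, con)
    writeLines("phi0,area_ratio,phi_v,a0Pi", con)
    writeLines(sprintf("%.17g,%.17g,%.17g,%.17g",
                       x$phi_0, x$area_ratio, x$phi_v, x$a0Pi), con)
  } else {
    x <- as_experimental_isotherm(x)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("area_nm2,pressure_mN_per_m", con)
    writeLines(sprintf("%.17g,%.17g", x$area_nm2, x$pressure_mN_per_m), con)
  }
  invisible(path)
}

#' Generate a synthetic digitized isotherm from the model
#'
#' Dimensionalizes a model isotherm (`a = a0 * (a/a0)`;
#' `Pi = a0Pi * kBT / a0`, reported in mN/m) on a uniform grid of the area
#' ratio, and optionally adds seeded Gaussian pressure noise. Intended as a
#' stand-in for plot-digitized experimental curves when testing landmark
#' detection and model fitting: it reproduces the model exactly (plus
#' noise) and therefore contains none of the hysteresis, molecule loss or
#' phase-transition features of real monolayer data.
#'
#' @param a0 Limiting area per molecule, nm^2.
#' @param xi,lam Model parameters (see [model_params()]).
#' @param n_points Number of records (`>= 2`).
#' @param area_ratio_range Sampled interval of `a/a0`, within (1, 50].
#' @param noise_sd Gaussian pressure noise standard deviation, mN/m.
#' @param seed Integer seed; identical seeds give identical output.
#' @param kBT Thermal energy, J.
#' @return An `experimental_isotherm` (areas in decreasing order).
#' @examples
#' generate_synthetic_isotherm(0.4, 6.75, 19, n_points = 30, seed = 1)
#' @export
generate_synthetic_isotherm <- function(a0, xi, lam, n_points = 60,
                                        area_ratio_range = c(1.2, 10),
                                        noise_sd = 0, seed = NULL,
                                        kBT = 4.14e-21) {
  stopifnot(a0 > 0, n_points >= 2, noise_sd >= 0,
            area_ratio_range[1] > 1, area_ratio_range[2] <= 50,
            area_ratio_range[1] < area_ratio_range[2])
  p <- model_params(xi, lam)
  ratio <- seq(area_ratio_range[2], area_ratio_range[1],
               length.out = n_points)
  a0Pi <- scaled_pressure(1 / ratio, p)
  pressure <- a0Pi * kBT / (a0 * 1e-18) * 1e3
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    pressure <- pmax(0, pressure + stats::rnorm(n_points, sd = noise_sd))
  }
  experimental_isotherm(a0 * ratio, pressure)
}
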