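test_that("closed-form partial derivatives match finite differences", {
  tr <- random_triples(12, seed = 99)
  for (k in seq_len(nrow(tr))) {
    p <- model_params(tr$xi[k], tr$lam[k])
    phi_0 <- tr$phi_0[k]
    r <- feasible_phi_v_range(phi_0, p$xi)
    phi_v <- r$lo + 0.5 * (r$hi - r$lo)
    d <- ftilde_partials(phi_0, phi_v, p)
    # first partials from the value, second from the first, third from the
    # second - each step an independent central difference
    expect_equal(d$f_0,
                 fd1(function(x) ftilde_value(x, phi_v, p), phi_0),
                 tolerance = 1e-6)
    expect_equal(d$f_v,
                 fd1(function(y) ftilde_value(phi_0, y, p), phi_v),
                 tolerance = 1e-6)
    expect_equal(d$f_00,
                 fd1(function(x) ftilde_partials(x, phi_v, p)$f_0, phi_0),
                 tolerance = 1e-5)
    expect_equal(d$f_v0,
                 fd1(function(y) ftilde_partials(phi_0, y, p)$f_0, phi_v),
                 tolerance = 1e-5)
    expect_equal(d$f_vv,
                 fd1(function(y) ftilde_partials(phi_0, y, p)$f_v, phi_v),
                 tolerance = 1e-5)
    expect_equal(d$f_000,
                 fd1(function(x) ftilde_partials(x, phi_v, p)$f_00, phi_0),
                 tolerance = 1e-4)
    expect_equal(d$f_00v,
                 fd1(function(y) ftilde_partials(phi_0, y, p)$f_00, phi_v),
                 tolerance = 1e-4)
    expect_equal(d$f_0vv,
                 fd1(function(y) ftilde_partials(phi_0, y, p)$f_v0, phi_v),
                 tolerance = 1e-4)
    expect_equal(d$f_vvv,
                 fd1(function(y) ftilde_partials(phi_0, y, p)$f_vv, phi_v),
                 tolerance = 1e-4)
  }
})

test_that("the equilibrium point is a stationary minimum of the free energy", {
  tr <- random_triples(15, seed = 5)
  for (k in seq_len(nrow(tr))) {
    p <- model_params(tr$xi[k], tr$lam[k])
    pv <- solve_phi_v(tr$phi_0[k], p)
    d <- ftilde_partials(tr$phi_0[k], pv, p)
    expect_lt(abs(d$f_v), 1e-9)
    expect_gt(d$f_vv, 0)
  }
})

test_that("slope of the equilibrium distribution matches its numerical derivative", {
  # decoupled case: constant slope 1/(1 + e^lam)
  for (lam in c(-1, 0, 2)) {
    expect_equal(dphi_v_dphi_0(c(0.2, 0.5, 0.8), model_params(1, lam)),
                 rep(1 / (1 + exp(lam)), 3), tolerance = 1e-10)
  }
  # numerical differentiation of the solver
  tr <- random_triples(10, seed = 31)
  for (k in seq_len(nrow(tr))) {
    p <- model_params(tr$xi[k], tr$lam[k])
    phi_0 <- tr$phi_0[k]
    slope_fd <- (solve_phi_v(phi_0 + 1e-5, p) - solve_phi_v(phi_0 - 1e-5, p)) / 2e-5
    expect_equal(dphi_v_dphi_0(phi_0, p), slope_fd, tolerance = 1e-5)
  }
  # strongly penalized reorientation: nothing stands up below full sublattice
  expect_lt(dphi_v_dphi_0(0.2, model_params(4, 30)), 1e-8)
})

test_that("scaled pressure reduces to the lattice gas in the decoupled case", {
  phi_0 <- seq(0.05, 0.95, by = 0.1)
  for (lam in c(0, 5)) {
    expect_equal(scaled_pressure(phi_0, model_params(1, lam)),
                 lattice_gas_pressure(phi_0), tolerance = 1e-10)
  }
})

test_that("pressure from implicit differentiation matches the thermodynamic definition", {
  # a0*Pi = phi_0 * dfopt/dphi_0 - fopt with the derivative taken numerically
  for (par in list(c(4, 7), c(2.5, 1), c(6.75, 19))) {
    p <- model_params(par[1], par[2])
    fopt <- function(x) ftilde_value(x, solve_phi_v(x, p), p)
    for (phi_0 in c(0.12, 0.3, 0.55, 0.8)) {
      expect_equal(scaled_pressure(phi_0, p),
                   phi_0 * fd1(fopt, phi_0) - fopt(phi_0),
                   tolerance = 1e-6)
    }
  }
})

test_that("envelope property: the correction term vanishes at equilibrium", {
  tr <- random_triples(12, seed = 77)
  for (k in seq_len(nrow(tr))) {
    p <- model_params(tr$xi[k], tr$lam[k])
    phi_0 <- tr$phi_0[k]
    pv <- solve_phi_v(phi_0, p)
    d <- ftilde_partials(phi_0, pv, p)
    with_corr <- phi_0 * (d$f_0 - d$f_v * d$f_v0 / d$f_vv) - d$f
    without <- phi_0 * d$f_0 - d$f
    expect_lt(abs(with_corr - without), 1e-9)
    expect_equal(scaled_pressure(phi_0, p), with_corr, tolerance = 1e-12)
  }
})

test_that("pressure at the analytic point equals its closed form", {
  # the closed form answers for exact phi_0 = 1/xi; the numeric pipeline
  # sees its floating-point representation, which matters where the curve
  # is steep (large lam), hence an absolute comparison at 1e-8
  for (xi in c(1.5, 2, 4, 8, 11.5)) {
    for (lam in c(-2, 0, 1, 7, 19)) {
      p <- model_params(xi, lam)
      expect_lt(abs(scaled_pressure(1 / xi, p) - pressure_at_star(p)), 1e-8)
    }
  }
  expect_equal(pressure_at_star(model_params(4, 0)),
               -log(3) + log((3 / 4)^3 * 4^3 + 4^4) / 4, tolerance = 1e-14)
  expect_equal(pressure_at_star(model_params(4, 0)), 0.3127494,
               tolerance = 1e-6)
  expect_equal(pressure_at_star(model_params(4, 7)), 1.477499,
               tolerance = 1e-6)
  expect_error(pressure_at_star(model_params(1, 3)), "xi > 1")
})

test_that("pressure approaches the one-component lattice-gas limits", {
  # reorientation frozen out: horizontal molecules on the sublattice
  p_h <- model_params(4, 30)
  phi_0 <- seq(0.05, 0.95 / 4, length.out = 7)
  expect_equal(scaled_pressure(phi_0, p_h),
               -(1 / 4) * log(1 - 4 * phi_0), tolerance = 1e-3)
  # reorientation free: all molecules vertical
  p_v <- model_params(4, -30)
  phi_0 <- seq(0.1, 0.9, by = 0.2)
  expect_equal(scaled_pressure(phi_0, p_v), -log(1 - phi_0),
               tolerance = 1e-3)
})

test_that("compression always raises the pressure", {
  phi_0 <- seq(0.02, 0.98, length.out = 300)
  for (par in list(c(1, 2), c(4, 0), c(4, 7), c(8, 3), c(11.5, 0.7))) {
    a0Pi <- scaled_pressure(phi_0, model_params(par[1], par[2]))
    expect_true(all(diff(a0Pi) > 0))
  }
  expect_identical(scaled_pressure(1, model_params(4, 2)), Inf)
})

test_that("both derivative routes of the optimized free energy agree", {
  tr <- random_triples(10, seed = 13)
  for (k in seq_len(nrow(tr))) {
    p <- model_params(tr$xi[k], tr$lam[k])
    phi_0 <- tr$phi_0[k]
    impl <- fopt_derivatives(phi_0, p)
    fd <- fopt_derivatives(phi_0, p, method = "fd")
    expect_equal(impl$d2, fd$d2, tolerance = 1e-4)
    expect_equal(impl$d3, fd$d3, tolerance = 1e-4)
    expect_gt(impl$d2, 0)  # optimized free energy is convex
  }
  # decoupled case: analytic derivatives of the optimal free energy
  p1 <- model_params(1, 2.5)
  for (phi_0 in c(0.2, 0.5, 0.7)) {
    d <- fopt_derivatives(phi_0, p1)
    expect_equal(d$d2, 1 / (phi_0 * (1 - phi_0)), tolerance = 1e-9)
    expect_equal(d$d3, (2 * phi_0 - 1) / (phi_0 * (1 - phi_0))^2,
                 tolerance = 1e-8)
  }
})

test_that("inflection condition is strictly positive for the decoupled case", {
  phi_0 <- seq(0.02, 0.98, length.out = 50)
  # closed form: 3/(x(1-x)) + x(2x-1)/(x(1-x))^2 > 0 on (0,1)
  closed <- 3 / (phi_0 * (1 - phi_0)) +
    phi_0 * (2 * phi_0 - 1) / (phi_0 * (1 - phi_0))^2
  expect_true(all(closed > 0))
  expect_equal(inflection_condition(phi_0, model_params(1, 4)), closed,
               tolerance = 1e-8)
})

test_that("shoulder isotherms carry exactly two inflection points", {
  g <- seq(0.01, 0.99, length.out = 400)
  v <- inflection_condition(g, model_params(4, 7))
  expect_identical(sum(v[-1] * v[-length(v)] < 0), 2L)

  res <- find_inflections(model_params(4, 7))
  expect_s3_class(res, "inflection_set")
  expect_identical(nrow(res$inflections), 2L)
  # first inflection on compression sits close to a/a0 = xi
  expect_gt(res$first_on_compression$area_ratio, 0.8 * 4)
  expect_lt(res$first_on_compression$area_ratio, 1.3 * 4)
  # refined roots actually satisfy the condition
  expect_true(all(abs(inflection_condition(res$inflections$phi_0,
                                           model_params(4, 7))) < 1e-3))

  expect_identical(nrow(find_inflections(model_params(1, 6))$inflections), 0L)
  expect_null(find_inflections(model_params(1, 6))$first_on_compression)
})

test_that("inflection existence threshold is sharp and scan-independent", {
  lc <- critical_lambda(4)
  # definition probe: inflections appear just above, vanish just below
  expect_identical(nrow(find_inflections(model_params(4, lc + 0.1))$inflections), 2L)
  expect_identical(nrow(find_inflections(model_params(4, lc - 0.1))$inflections), 0L)
  # stable under grid refinement
  expect_equal(lc, critical_lambda(4, grid_size = 2001), tolerance = 0.02)

  # cross-check against direct curvature of the pressure-area curve,
  # computed by plain finite differences with no shared machinery
  direct_has_inflection <- function(lam) {
    x <- seq(1.5, 8, length.out = 1200)
    Pi <- scaled_pressure(1 / x, model_params(4, lam))
    d2 <- diff(diff(Pi)) / diff(x)[1]^2
    any(d2[-1] * d2[-length(d2)] < 0)
  }
  expect_true(direct_has_inflection(lc + 0.2))
  expect_false(direct_has_inflection(lc - 0.2))
})

test_that("piecewise-linear distribution interpolates the analytic point", {
  p <- model_params(4, 7)
  expect_identical(piecewise_linear_phi_v(0, p), 0)
  expect_identical(piecewise_linear_phi_v(1, p), 1)
  expect_equal(piecewise_linear_phi_v(1 / 4, p), phi_v_star(p))
  # continuity at the kink
  expect_equal(piecewise_linear_phi_v(1 / 4 - 1e-12, p),
               piecewise_linear_phi_v(1 / 4 + 1e-12, p), tolerance = 1e-9)
  expect_error(piecewise_linear_phi_v(0.5, model_params(1, 2)), "xi > 1")
})

test_that("isotherm families are ordered in the reorientation energy", {
  probe <- c(0.15, 0.3, 0.6)
  curves <- lapply(0:9, function(l)
    scaled_pressure(probe, model_params(4, l)))
  for (j in seq_along(probe)) {
    at_fixed_area <- vapply(curves, `[[`, numeric(1), j)
    expect_true(all(diff(at_fixed_area) > 0))
  }
  # decoupled case: the family collapses onto a single curve
  c0 <- compute_isotherm(model_params(1, 0), n_points = 51)
  c5 <- compute_isotherm(model_params(1, 5), n_points = 51)
  expect_equal(c0$a0Pi, c5$a0Pi, tolerance = 1e-12)
})

test_that("piecewise-linear approximation tracks the exact isotherm", {
  p <- model_params(4, 7)
  phi_0 <- 1 / seq(1.2, 10, length.out = 120)
  exact <- scaled_pressure(phi_0, p)
  approx <- scaled_pressure(phi_0, p, phi_v = piecewise_linear_phi_v(phi_0, p))
  expect_lt(max(abs(approx - exact) / exact), 0.15)
})

test_that("computed curves satisfy their structural invariants", {
  crv <- compute_isotherm(model_params(4, 7), n_points = 201)
  expect_s3_class(crv, "isotherm_curve")
  expect_equal(crv$area_ratio * crv$phi_0, rep(1, nrow(crv)), tolerance = 1e-14)
  expect_true(all(crv$a0Pi >= 0))
  expect_true(all(diff(crv$phi_0) > 0))
  # pressure strictly decreasing in area
  ord <- order(crv$area_ratio)
  expect_true(all(diff(crv$a0Pi[ord]) < 0))

  appr <- compute_isotherm(model_params(4, 7), n_points = 201,
                           approximate = TRUE)
  expect_equal(appr$phi_v, piecewise_linear_phi_v(appr$phi_0, model_params(4, 7)),
               tolerance = 1e-12)
})
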