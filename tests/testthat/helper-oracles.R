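# Independent oracles used across the test files. These deliberately avoid
# the code paths they check.

# Brute-force minimizer of the free energy along the conservation line
# phi_h = xi*(phi_0 - phi_v), on a dense phi_v grid.
grid_min_phi_v <- function(phi_0, p, n = 200000) {
  r <- feasible_phi_v_range(phi_0, p$xi)
  pv <- seq(r$lo, r$hi, length.out = n + 2)[-c(1, n + 2)]
  f <- free_energy_per_site(p$xi * (phi_0 - pv), pv, p)
  list(phi_v = pv[which.min(f)], resolution = (r$hi - r$lo) / (n + 1))
}

# Exact number of arrangements: Nh molecules on the M/xi sublattice cells
# times Nv molecules on the M - xi*Nh remaining sites.
exact_neg_lnOmega_per_site <- function(M, xi, Nh, Nv) {
  -(lchoose(M / xi, Nh) + lchoose(M - xi * Nh, Nv)) / M
}

# Explicit lattice placement: occupy xi sites per horizontal molecule
# (whole sublattice cells) and one per vertical molecule, then count.
placement_fractions <- function(M, xi, Nh, Nv) {
  sites <- integer(M)                       # 0 empty, 1 horizontal, 2 vertical
  cells <- split(seq_len(M), rep(seq_len(M / xi), each = xi))
  for (c_id in seq_len(Nh)) sites[cells[[c_id]]] <- 1L
  free <- which(sites == 0L)
  sites[free[seq_len(Nv)]] <- 2L
  list(phi_h = sum(sites == 1L) / M, phi_v = sum(sites == 2L) / M,
       phi_tot = sum(sites != 0L) / M)
}

# Closed forms of the decoupled xi = 1 case.
decoupled_phi_v <- function(phi_0, lam) phi_0 / (1 + exp(lam))
lattice_gas_pressure <- function(phi_0) -log(1 - phi_0)

# Random interior model/state triples under a fixed seed.
random_triples <- function(n, seed = 4372) {
  set.seed(seed)
  data.frame(xi = runif(n, 1.05, 9),
             lam = runif(n, -4, 10),
             phi_0 = runif(n, 0.05, 0.92))
}

# Central finite difference of a scalar function.
fd1 <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)
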