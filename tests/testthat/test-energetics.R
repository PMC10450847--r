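params1 <- default_parameter_set("CALVADOS1")

test_that("Lennard-Jones potential has its textbook zero and minimum", {
  expect_equal(lj_potential(0.6, 0.6, 0.8368), 0)
  rmin <- 2^(1 / 6) * 0.6
  expect_equal(lj_potential(rmin, 0.6, 0.8368), -0.8368)
  # minimum: values on either side are higher
  expect_gt(lj_potential(rmin * 0.99, 0.6, 0.8368), -0.8368)
  expect_gt(lj_potential(rmin * 1.01, 0.6, 0.8368), -0.8368)
  expect_error(lj_potential(-1, 0.6), "positive")
})

test_that("stickiness potential is continuous and vanishes at the cutoff for all pairs", {
  aa <- rownames(params1$residues)
  rc <- 2.0
  for (i in seq_along(aa)) {
    for (j in seq(i, length(aa))) {
      pp <- pair_params(aa[i], aa[j], params1)
      sig <- pp[["sigma_nm"]]; lam <- pp[["lambda"]]
      expect_equal(ah_potential(rc, sig, lam, rc), 0)
      # branch point: both branch expressions agree at 2^(1/6) sigma
      rmin <- 2^(1 / 6) * sig
      ulj_rc <- lj_potential(rc, sig, 0.8368)
      expect_equal(ah_potential(rmin, sig, lam, rc),
                   -lam * 0.8368 - lam * ulj_rc, tolerance = 1e-12)
      # dense grid: no jumps larger than expected from the local slope
      r <- seq(0.8 * rmin, rc + 0.2, length.out = 400)
      u <- ah_potential(r, sig, lam, rc)
      du <- abs(diff(u))
      slope_scale <- max(abs(diff(lj_potential(r[r < rc], sig, 0.8368))))
      expect_lt(max(du), 2 * slope_scale + 1e-10)
    }
  }
})

test_that("stickiness limits: lambda = 1 is shifted LJ, lambda = 0 is purely repulsive", {
  sig <- 0.62; rc <- 2
  r <- seq(0.5, 2.5, by = 0.01)
  u1 <- ah_potential(r, sig, 1, rc)
  ulj_ts <- ifelse(r <= rc, lj_potential(r, sig, 0.8368) -
                     lj_potential(rc, sig, 0.8368), 0)
  expect_equal(u1, ulj_ts, tolerance = 1e-12)
  # lambda = 0: outer branch identically zero (shifted form)
  router <- r[r > 2^(1 / 6) * sig]
  expect_equal(ah_potential(router, sig, 0, rc), rep(0, length(router)))
  # inner branch non-negative in the infinite-cutoff limit
  rinner <- seq(0.9 * sig, 2^(1 / 6) * sig, length.out = 50)
  expect_true(all(ah_potential(rinner, sig, 0, rc = 1e6) >= 0))
  expect_error(ah_potential(1, sig, 0.5, rc = 0.5), "cutoff")
})

test_that("dielectric constant matches the liquid-water polynomial and decreases with T", {
  expect_equal(dielectric_constant(293.15), 80.3, tolerance = 0.001)
  expect_equal(dielectric_constant(298.15), 78.4, tolerance = 0.001)
  ts <- seq(277.15, 323.15, by = 1)
  expect_true(all(diff(dielectric_constant(ts)) < 0))
  expect_error(dielectric_constant(200), "valid")
})

test_that("Debye length follows the inverse-root salt scaling", {
  d10 <- debye_length(293.15, 0.010)
  d150 <- debye_length(293.15, 0.150)
  expect_equal(d10 / d150, sqrt(15), tolerance = 1e-12)
  expect_equal(debye_length(298.15, 0.15), 0.785, tolerance = 0.005)
  expect_identical(debye_length(298.15, 0), Inf)
  # 4 -> 50 C relative change is about -3%
  rel <- (debye_length(323.15, 0.15) - debye_length(277.15, 0.15)) /
    debye_length(277.15, 0.15)
  expect_equal(rel, -0.03, tolerance = 0.002)
})

test_that("screened electrostatics decay and truncate correctly", {
  ctx <- electrostatics_context(293.15, 0.15)
  r <- seq(0.5, 3.9, by = 0.1)
  u <- dh_potential(r, 1, 1, ctx, rc = 4)
  expect_true(all(diff(u) < 0))          # monotonic decay, like charges
  expect_true(all(u > 0))
  expect_equal(dh_potential(c(4, 4.5, 10), 1, 1, ctx, rc = 4),
               c(0, 0, 0))
  # opposite charges: attractive mirror image
  expect_equal(dh_potential(1, 1, -1, ctx, rc = 4),
               -dh_potential(1, 1, 1, ctx, rc = 4))
})

test_that("harmonic bond energy is quadratic and symmetric", {
  expect_equal(bond_potential(0.38), 0)
  expect_equal(bond_potential(0.48, 8033, 0.38), 40.165)
  expect_equal(bond_potential(0.38 + 0.07), bond_potential(0.38 - 0.07))
})

test_that("system energy matches an independent 27-image brute-force oracle", {
  sys <- random_test_system(n_chains = 2, chain_length = 15, seed = 3)
  got <- system_energy(sys$config, sys$topology, sys$params, sys$ctx)
  want <- oracle_energy(sys$config$positions, sys$config$box, sys$topology,
                        sys$params, sys$ctx)
  expect_equal(got$bonded, want$bonded, tolerance = 1e-9)
  expect_equal(got$nonionic, want$nonionic, tolerance = 1e-9)
  expect_equal(got$ionic, want$ionic, tolerance = 1e-9)
  expect_equal(got$per_chain_nonionic, want$per_chain_nonionic,
               tolerance = 1e-9)
  # attribution rule: per-chain halves sum back to the total
  expect_equal(sum(got$per_chain_nonionic), got$nonionic, tolerance = 1e-12)
  # compiled backend agrees with the reference path
  comp <- system_energy(sys$config, sys$topology, sys$params, sys$ctx,
                        backend = "compiled")
  expect_equal(comp$nonionic, got$nonionic, tolerance = 1e-9)
  expect_equal(comp$ionic, got$ionic, tolerance = 1e-9)
  expect_equal(comp$bonded, got$bonded, tolerance = 1e-9)
})

test_that("system energy is invariant under translations and lattice shifts", {
  sys <- random_test_system(n_chains = 2, chain_length = 12, seed = 8)
  e0 <- system_energy(sys$config, sys$topology, sys$params, sys$ctx)
  shift <- c(1.7, -0.3, 5.1)
  cfg2 <- cg_configuration(sweep(sys$config$positions, 2, shift, "+"),
                           sys$config$box)
  e1 <- system_energy(cfg2, sys$topology, sys$params, sys$ctx)
  expect_equal(e1$nonionic, e0$nonionic, tolerance = 1e-9)
  expect_equal(e1$ionic, e0$ionic, tolerance = 1e-9)
  # move one bead by a full lattice vector
  pos3 <- sys$config$positions
  pos3[5, ] <- pos3[5, ] + sys$config$box * c(1, -2, 1)
  e2 <- system_energy(cg_configuration(pos3, sys$config$box),
                      sys$topology, sys$params, sys$ctx)
  expect_equal(e2$nonionic, e0$nonionic, tolerance = 1e-9)
  expect_equal(e2$ionic, e0$ionic, tolerance = 1e-9)
})

test_that("distant beads contribute nothing and small boxes are refused", {
  cond <- solution_conditions(298, 0.15, 7)
  p <- default_parameter_set("CALVADOS2")
  topo <- build_topology(c("K", "E"), p, cond)
  cfg <- cg_configuration(rbind(c(1, 1, 1), c(1, 1, 6.5)), c(20, 20, 20))
  ctx <- electrostatics_context(cond$temperature_K, cond$ionic_strength_M)
  e <- system_energy(cfg, topo, p, ctx)
  expect_equal(e$nonionic, 0)
  expect_equal(e$ionic, 0)
  expect_error(system_energy(cg_configuration(rbind(c(1, 1, 1), c(1, 1, 2)),
                                              c(5, 5, 5)),
                             topo, p, electrostatics_context(298, 0.15)),
               "twice")
})

test_that("cutoff-difference accounting equals the restricted-pair oracle", {
  sys <- random_test_system(n_chains = 2, chain_length = 15, seed = 5,
                            box = rep(16, 3))
  e2 <- system_energy(sys$config, sys$topology, sys$params, sys$ctx,
                      rc_nonionic = 2, shifted = FALSE)
  e4 <- system_energy(sys$config, sys$topology, sys$params, sys$ctx,
                      rc_nonionic = 4, shifted = FALSE)
  want <- oracle_energy(sys$config$positions, sys$config$box, sys$topology,
                        sys$params, sys$ctx, rc_nonionic = 4,
                        shifted = FALSE, rc_window = c(2, 4))
  expect_equal(e4$nonionic - e2$nonionic, want$nonionic, tolerance = 1e-9)
})
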