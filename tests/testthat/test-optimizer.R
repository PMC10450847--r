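test_that("scale normalization maps to [0,1], flips reversed scales, deduplicates", {
  set.seed(1)
  base <- runif(20)
  names(base) <- rownames(default_parameter_set()$residues)
  scales <- cbind(s1 = base, s2 = 3 * base + 2, s3 = rnorm(20),
                  s4 = -1 * base, s5 = runif(20))
  out <- normalize_scales(scales, reversed = c(FALSE, FALSE, FALSE, TRUE,
                                               FALSE))
  expect_true(all(apply(out, 2, min) >= 0 & apply(out, 2, max) <= 1))
  expect_true(all(apply(out, 2, function(x) any(x == 0) || any(x == 1))))
  # s2 is an affine transform of s1 -> deduplicated; s4 reversed equals s1
  # after flipping (-(base) normalized is 1 - normalized(base), flipped back)
  expect_equal(ncol(out), 3)
  expect_error(normalize_scales(cbind(rep(1, 20))), "degenerate")
})

test_that("5 affine-duplicated scales collapse to the distinct survivors", {
  set.seed(2)
  a <- runif(20); b <- runif(20); c <- runif(20)
  scales <- cbind(a, 2 * a + 1, b, 0.1 * b - 3, c)
  out <- normalize_scales(scales)
  expect_equal(ncol(out), 3)
})

test_that("KDE prior integrates to one and peaks near training data", {
  # reduced-dimension fixture: 2 'residues', handful of scales
  set.seed(3)
  train <- matrix(runif(2 * 6), nrow = 2,
                  dimnames = list(c("A", "G"), NULL))
  prior <- build_prior(train, bandwidth = 0.1)
  g <- seq(-0.6, 1.6, length.out = 120)
  dz <- diff(g)[1]
  dens <- outer(g, g, Vectorize(function(x, y)
    exp(log_prior(prior, c(A = x, G = y)))))
  expect_equal(sum(dens) * dz^2, 1, tolerance = 0.01)
  # training point vs far point
  lp_in <- log_prior(prior, train[, 1])
  lp_out <- log_prior(prior, c(A = 5, G = -5))
  expect_true(is.finite(lp_in))
  expect_gt(lp_in, lp_out)
  expect_error(build_prior(train, bandwidth = 0), "bandwidth")
})

test_that("KDE samples reproduce the moment identity cov + h^2 I", {
  set.seed(4)
  train <- matrix(runif(3 * 40), nrow = 3,
                  dimnames = list(c("A", "G", "Y"), NULL))
  h <- 0.05
  prior <- build_prior(train, bandwidth = h)
  s <- sample_prior(prior, 40000)
  n <- ncol(train)
  want <- stats::cov(t(train)) * (n - 1) / n + h^2 * diag(3)
  expect_equal(stats::cov(s), want, tolerance = 0.15)
})

test_that("reweighting identities hold at the uniform and single-support limits", {
  u <- rnorm(200)
  rw <- reweight_frames(u, u, 298)
  expect_equal(rw$weights, rep(1 / 200, 200))
  expect_equal(rw$phi_eff, 1)
  # one frame vastly lower trial energy dominates
  u2 <- u; u2[7] <- u2[7] - 1000
  rw2 <- reweight_frames(u, u2, 298)
  expect_equal(rw2$weights[7], 1)
  expect_equal(rw2$phi_eff, 1 / 200, tolerance = 1e-6)
  expect_error(reweight_frames(u, c(u2[-1], NA), 298), "finite")
  # phi_eff decreases as concentration grows
  u3 <- u; u3[7] <- u3[7] - 2
  expect_lt(reweight_frames(u, u3, 298)$phi_eff, 1)
})

test_that("energy coefficients linearize the stickiness dependence exactly", {
  sys <- random_test_system(n_chains = 1, chain_length = 14, seed = 6,
                            box = rep(12, 3))
  traj <- structure(list(positions = array(sys$config$positions,
                                           dim = c(14, 3, 1)),
                         box = sys$config$box, save_interval_ps = 1,
                         topology = sys$topology),
                    class = "cg_trajectory")
  co <- lambda_energy_coefficients(traj, sys$params)
  lam <- sys$params$residues[co$codes, "lambda"]
  names(lam) <- co$codes
  u_lin <- co$const + drop(co$M %*% lam)
  e <- system_energy(sys$config, sys$topology, sys$params, sys$ctx)
  expect_equal(u_lin, e$nonionic, tolerance = 1e-9, ignore_attr = TRUE)
  # and for a perturbed lambda vector
  lam2 <- pmin(lam + 0.13, 1)
  res2 <- sys$params$residues
  res2[co$codes, "lambda"] <- lam2
  p3 <- parameter_set(res2, rc_nonionic = sys$params$rc_nonionic)
  topo2 <- build_topology(
    vapply(sys$topology$chains, paste, character(1), collapse = ""),
    p3, solution_conditions(298, 0.15, 7))
  e2 <- system_energy(sys$config, topo2, p3, sys$ctx)
  expect_equal(co$const + drop(co$M %*% lam2[co$codes]), e2$nonionic,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("reweighted observables agree with direct simulation for small moves", {
  p0 <- default_parameter_set("CALVADOS2")
  p0 <- parameter_set(p0$residues, name = "toy-base", epsilon = 2,
                      rc_nonionic = 2)
  cond <- solution_conditions(298, 0.15, 7)
  spec <- protein_spec("x", "GYAYGAYGAYAGYA", cond)
  run_at <- function(lam, seed) {
    res <- p0$residues; res[names(lam), "lambda"] <- lam
    pp <- parameter_set(res, epsilon = 2, rc_nonionic = 2)
    sys <- build_single_chain_system(spec, pp)
    st <- simulation_settings(298, seed = seed)
    tr <- run_langevin(sys$topology, sys$configuration, pp, st,
                       n_steps = 400000, save_every = 1000)
    tr$positions <- tr$positions[, , -(1:50), drop = FALSE]
    list(traj = tr, params = pp, rg = trajectory_rg(tr))
  }
  lam0 <- c(A = 0.35, G = 0.6, Y = 0.8)
  lam1 <- lam0 + c(A = 0.05, G = -0.05, Y = 0.05)
  ref <- run_at(lam0, 31)
  direct <- run_at(lam1, 32)
  co <- lambda_energy_coefficients(ref$traj, ref$params)
  full0 <- ref$params$residues[co$codes, "lambda"]
  names(full0) <- co$codes
  full1 <- full0
  full1[names(lam1)] <- lam1
  rw <- reweight_frames(co$const + drop(co$M %*% full0),
                        co$const + drop(co$M %*% full1), 298)
  rg_rw <- sum(rw$weights * ref$rg)
  tol <- 2 * sqrt(blocking_error(ref$rg)^2 + blocking_error(direct$rg)^2)
  expect_lt(abs(rg_rw - mean(direct$rg)), tol)
  expect_gt(rw$phi_eff, 0.5)
})

test_that("cost function combines its three terms as stated", {
  expect_equal(cost_function(c(0, 0), NULL, 0)$total, 0)
  got <- cost_function(c(1, 3), c(2, 4), log_prior_value = -10,
                       eta = 0.1, theta = 0.05)
  expect_equal(got$chi2_rg, 2)
  expect_equal(got$chi2_pre, 3)
  expect_equal(got$prior_term, 0.5)
  expect_equal(got$total, 2 + 0.3 + 0.5)
  # larger prior density -> lower cost, everything else fixed
  expect_lt(cost_function(1, NULL, -1)$total,
            cost_function(1, NULL, -5)$total)
})

test_that("trial moves perturb exactly five coordinates with the stated scale", {
  lam <- rep(0.5, 20)
  names(lam) <- rownames(default_parameter_set()$residues)
  set.seed(8)
  nchanged <- replicate(400, sum(propose_lambda(lam) != lam))
  expect_true(all(nchanged == 5))
  # per-coordinate selection frequency ~ 5/20
  hits <- rowSums(replicate(2000, propose_lambda(lam) != lam))
  expect_true(all(abs(hits / 2000 - 0.25) < 0.05))
  # perturbation scale
  dev <- replicate(4000, {
    tr <- propose_lambda(lam)
    tr[tr != lam] - 0.5
  })
  expect_equal(sd(as.numeric(dev)), 0.05, tolerance = 0.05)
  short <- c(A = 0.5, G = 0.5)
  expect_equal(sum(propose_lambda(short) != short), 2)
})

test_that("the annealing schedule runs 1604 iterations per micro-cycle", {
  expect_equal(annealing_length(0.1, 0.99, 1e-8), 1604L)
  expect_equal(0.1 * 0.99^1603 >= 1e-8, TRUE)
  expect_equal(0.1 * 0.99^1604 < 1e-8, TRUE)
})

# a tiny frozen training problem with an analytically controllable optimum
frozen_toy_training <- function(seed = 9, n_frames = 400) {
  set.seed(seed)
  rg <- runif(n_frames, 0.6, 1.1)
  # energies linear in (A, Y); compact frames favoured by larger lambda
  M <- cbind(A = -25 * (1.1 - rg), Y = -35 * (1.1 - rg))
  coeffs <- list(const = rep(0, n_frames), M = M, codes = c("A", "Y"))
  lam_ref <- c(A = 0.5, Y = 0.5)
  target <- function(lam) {
    u_ref <- drop(M %*% lam_ref)
    w <- exp(-(drop(M %*% lam) - u_ref) / (0.008314462618 * 298))
    w <- w / sum(w)
    sum(w * rg)
  }
  lam_true <- c(A = 0.62, Y = 0.41)
  list(training = list(list(name = "frozen", coeffs = coeffs, rg = rg,
                            lambda_ref = lam_ref, temperature_K = 298,
                            rg_exp = target(lam_true), rg_sigma = 0.005)),
       target = target, lam_true = lam_true, lam_ref = lam_ref)
}

test_that("on a frozen ensemble the optimizer finds the grid-scan cost minimum", {
  ft <- frozen_toy_training()
  # independent grid scan of chi^2 over the two free coordinates
  g <- seq(0.3, 0.7, by = 0.02)
  grid <- expand.grid(A = g, Y = g)
  cost_grid <- vapply(seq_len(nrow(grid)), function(k) {
    lam <- c(A = grid$A[k], Y = grid$Y[k])
    ((ft$target(lam) - ft$training[[1]]$rg_exp) /
       ft$training[[1]]$rg_sigma)^2
  }, numeric(1))
  gm <- grid[which.min(cost_grid), ]
  cfg <- optimizer_config(theta = 0, n_microcycles = 3, n_cycles = 1,
                          phi_min = 0.2, seed = 10)
  res <- optimize_lambda(ft$training, ft$lam_ref, prior = NULL, config = cfg)
  # reweighting makes the minimum a ridge; the optimizer must land on it
  expect_lt(res$cost_best, min(cost_grid) + 1)
  best_chi <- ((ft$target(res$lambda_best) - ft$training[[1]]$rg_exp) /
                 ft$training[[1]]$rg_sigma)^2
  expect_lt(best_chi, 1)
  expect_equal(ft$target(res$lambda_best), ft$target(unlist(gm)),
               tolerance = 0.02)
})

test_that("accepted costs are non-increasing in the greedy small-xi limit", {
  ft <- frozen_toy_training(seed = 11)
  cfg <- optimizer_config(theta = 0, xi0 = 1e-7, n_microcycles = 1,
                          n_cycles = 1, phi_min = 0.2, seed = 12)
  res <- optimize_lambda(ft$training, ft$lam_ref, prior = NULL, config = cfg)
  acc <- res$audit$cost[res$audit$accepted]
  expect_true(all(diff(acc) <= 1e-9))
})

test_that("the stochastic search is reproducible for a fixed seed", {
  ft <- frozen_toy_training(seed = 13)
  cfg <- optimizer_config(theta = 0, xi0 = 1e-4, n_microcycles = 1,
                          n_cycles = 1, phi_min = 0.2, seed = 14)
  r1 <- optimize_lambda(ft$training, ft$lam_ref, prior = NULL, config = cfg)
  r2 <- optimize_lambda(ft$training, ft$lam_ref, prior = NULL, config = cfg)
  expect_identical(r1$audit$accepted, r2$audit$accepted)
  expect_identical(r1$lambda_best, r2$lambda_best)
})

test_that("the phi_eff gate vetoes distant trial sets", {
  ft <- frozen_toy_training(seed = 15)
  tr <- ft$training
  lam_far <- c(A = 1, Y = 1)
  ev_far <- reweight_frames(
    drop(tr[[1]]$coeffs$M %*% ft$lam_ref),
    drop(tr[[1]]$coeffs$M %*% lam_far), 298)
  expect_lt(ev_far$phi_eff, 0.6)
})
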