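#' Synthetic tanh-shaped density profile
#'
#' Generates a density profile following the interface model exactly,
#' optionally with multiplicative Gaussian noise, and optionally a
#' bead-level configuration realizing it (bead z-coordinates sampled from
#' the profile, uniform x, y).
#'
#' @param rho_dense,rho_dilute Plateau densities, mg/mL
#'   (`rho_dense > rho_dilute >= 0`).
#' @param z_interface Dividing-surface position, nm.
#' @param width Interface width, nm.
#' @param box Box edges, nm.
#' @param bin_width Bin width, nm.
#' @param noise Multiplicative noise level (0 = exact profile).
#' @param seed Optional seed.
#' @param n_beads If non-`NULL`, also return `positions` (n x 3) sampled
#'   from the profile.
#' @return A `density_profile` (with `positions` attached when requested).
#' @export
generate_tanh_fixture <- function(rho_dense, rho_dilute, z_interface, width,
                                  box = c(15, 15, 150), bin_width = 1,
                                  noise = 0, seed = NULL, n_beads = NULL) {
  if (rho_dense < rho_dilute || rho_dilute < 0) {
    stop("need rho_dense >= rho_dilute >= 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  Lz <- box[3]
  nbins <- max(4L, round(Lz / bin_width))
  dz <- Lz / nbins
  z <- (seq_len(nbins) - 0.5) * dz - Lz / 2
  rho <- (rho_dense + rho_dilute) / 2 +
    (rho_dilute - rho_dense) / 2 * tanh((abs(z) - z_interface) / width)
  if (noise > 0) rho <- rho * (1 + noise * stats::rnorm(nbins))
  prof <- structure(list(z_centers = z, density = pmax(rho, 0),
                         per_frame = NULL, n_frames_averaged = 1L,
                         bin_width = dz, box = box),
                    class = "density_profile")
  if (!is.null(n_beads)) {
    zi <- sample.int(nbins, n_beads, replace = TRUE,
                     prob = pmax(rho, 0))
    prof$positions <- cbind(stats::runif(n_beads, 0, box[1]),
                            stats::runif(n_beads, 0, box[2]),
                            z[zi] + stats::runif(n_beads, -dz / 2, dz / 2))
  }
  prof
}

#' Stationary AR(1) series
#'
#' \eqn{x_t = \phi x_{t-1} + \epsilon_t} with
#' \eqn{\epsilon_t \sim N(0, \sigma^2(1-\phi^2))}, so the marginal standard
#' deviation is `sd` and the lag-1 autocorrelation is \eqn{\phi}. Used as a
#' fixture with a known correlation structure for testing autocorrelation
#' and blocking-error estimators.
#'
#' @param phi AR coefficient, |phi| < 1.
#' @param sd Marginal standard deviation.
#' @param n Length.
#' @param seed Optional seed.
#' @return Numeric vector.
#' @export
generate_ar1_series <- function(phi, sd = 1, n = 1000, seed = NULL) {
  stopifnot(abs(phi) < 1)
  if (!is.null(seed)) set.seed(seed)
  innov_sd <- sd * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, sd = sd)
  for (t in seq_len(n - 1)) {
    x[t + 1] <- phi * x[t] + stats::rnorm(1, sd = innov_sd)
  }
  x
}

#' Toy training set with known ground-truth stickiness
#'
#' Builds random small-alphabet sequences, simulates each at a known
#' stickiness vector `lambda_star`, and records the resulting ensemble
#' mean radius of gyration plus stated noise as pseudo-experimental data.
#' The output is ready for [optimize_lambda()] together with the returned
#' `make_training` closure, which (re)simulates ensembles at any reference
#' vector - so the optimizer can be exercised end-to-end against a known
#' answer without any external data.
#'
#' @param alphabet Character vector of canonical residue codes.
#' @param n_proteins Number of sequences.
#' @param chain_length Residues per chain.
#' @param sequences Optional explicit sequences (length `n_proteins`);
#'   by default each sequence is biased towards one letter of the alphabet
#'   in turn (cycling), which keeps the per-letter responses of the
#'   training set well separated.
#' @param lambda_star Named ground-truth stickiness vector over `alphabet`.
#' @param params Base `parameter_set` (sigma, masses, bonds; its lambda
#'   column is overridden per simulation).
#' @param conditions A [solution_conditions()].
#' @param noise_sigma Pseudo-experimental Rg uncertainty, nm.
#' @param n_steps,save_every,n_discard Simulation schedule per protein.
#' @param seed Master seed.
#' @return List with `specs`, `rg_exp` (data frame), `lambda_star`, and
#'   `make_training(lambda_ref)`.
#' @export
generate_toy_training_set <- function(alphabet, n_proteins = 4,
                                      chain_length = 14, lambda_star,
                                      params, conditions,
                                      noise_sigma = 0.015,
                                      sequences = NULL,
                                      n_steps = 600000, save_every = 1000,
                                      n_discard = 100, seed = 1) {
  stopifnot(all(alphabet %in% .CANONICAL_AA),
            all(alphabet %in% names(lambda_star)))
  set.seed(seed)
  if (is.null(sequences)) {
    sequences <- vapply(seq_len(n_proteins), function(k) {
      fav <- alphabet[(k - 1) %% length(alphabet) + 1]
      w <- ifelse(alphabet == fav, 4, 1)
      paste(sample(alphabet, chain_length, replace = TRUE, prob = w),
            collapse = "")
    }, character(1))
  }
  stopifnot(length(sequences) == n_proteins)
  specs <- lapply(seq_len(n_proteins), function(k) {
    protein_spec(paste0("toy", k), sequences[k], conditions)
  })
  with_lambda <- function(lam) {
    res <- params$residues
    res[names(lam), "lambda"] <- lam
    parameter_set(res, name = "toy", epsilon = params$epsilon,
                  bond_k = params$bond_k, bond_r0 = params$bond_r0,
                  rc_nonionic = params$rc_nonionic,
                  rc_ionic = params$rc_ionic,
                  termini_charges = params$termini_charges)
  }
  simulate_one <- function(spec, lam, run_seed) {
    p <- with_lambda(lam)
    sys <- build_single_chain_system(spec, p)
    st <- simulation_settings(conditions$temperature_K, seed = run_seed)
    traj <- run_langevin(sys$topology, sys$configuration, p, st,
                         n_steps = n_steps, save_every = save_every)
    keep <- (n_discard + 1):n_frames(traj)
    traj$positions <- traj$positions[, , keep, drop = FALSE]
    traj
  }
  base_seeds <- replica_seeds(seed * 1000L, n_proteins)
  trajs_star <- lapply(seq_len(n_proteins), function(k) {
    simulate_one(specs[[k]], lambda_star, base_seeds[k])
  })
  rg_true <- vapply(trajs_star, function(tr) mean(trajectory_rg(tr)),
                    numeric(1))
  rg_exp <- data.frame(protein = vapply(specs, `[[`, character(1), "name"),
                       rg_nm = rg_true,
                       rg_sigma_nm = noise_sigma)
  make_training <- function(lambda_ref, hook_seed = seed * 2000L) {
    seeds <- replica_seeds(hook_seed, n_proteins)
    lapply(seq_len(n_proteins), function(k) {
      tr <- simulate_one(specs[[k]], lambda_ref, seeds[k])
      p <- with_lambda(lambda_ref)
      list(name = specs[[k]]$name,
           coeffs = lambda_energy_coefficients(tr, p),
           rg = trajectory_rg(tr),
           lambda_ref = lambda_ref,
           temperature_K = conditions$temperature_K,
           rg_exp = rg_exp$rg_nm[k], rg_sigma = rg_exp$rg_sigma_nm[k])
    })
  }
  list(specs = specs, rg_exp = rg_exp, lambda_star = lambda_star,
       make_training = make_training)
}
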