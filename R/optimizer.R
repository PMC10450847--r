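#' Min-max normalize and deduplicate hydrophobicity scales
#'
#' Each scale (column) is mapped to \[0, 1\] by min-max normalization;
#' scales flagged as reversed (hydrophilicity-type orientation) are flipped
#' as \eqn{1 - x} after normalization. Scales that become identical after
#' normalization (e.g. affine transforms of one another) are collapsed to a
#' single representative.
#'
#' @param scales Numeric matrix (residues x scales) with residue one-letter
#'   rownames, or a data frame with a `one_letter` column.
#' @param reversed Logical vector, one entry per scale.
#' @param tol Comparison tolerance for deduplication.
#' @return Matrix of normalized scale vectors (residues x surviving scales).
#' @export
normalize_scales <- function(scales, reversed = rep(FALSE, ncol(scales)),
                             tol = 1e-9) {
  if (is.data.frame(scales) && "one_letter" %in% names(scales)) {
    rn <- scales$one_letter
    scales <- as.matrix(scales[, setdiff(names(scales), "one_letter")])
    rownames(scales) <- rn
  }
  scales <- as.matrix(scales)
  stopifnot(length(reversed) == ncol(scales))
  norm <- apply(scales, 2, function(x) {
    rng <- range(x)
    if (diff(rng) == 0) {
      stop("degenerate scale: all values equal", call. = FALSE)
    }
    (x - rng[1]) / diff(rng)
  })
  norm[, reversed] <- 1 - norm[, reversed]
  keep <- !duplicated(lapply(seq_len(ncol(norm)),
                             function(j) round(norm[, j] / tol)))
  norm[, keep, drop = FALSE]
}

#' Gaussian kernel-density prior over stickiness vectors
#'
#' A multivariate kernel density estimate over normalized hydrophobicity
#' scale vectors: an isotropic Gaussian kernel of bandwidth `bandwidth` is
#' placed on each training scale, defining a smooth prior
#' \eqn{P(\lambda)} over the d-dimensional stickiness space (d = 20 for the
#' full alphabet) that encodes both the per-residue marginal distributions
#' and the covariance across residues implied by the scale collection.
#'
#' @param scales Matrix of normalized scales (residues x scales), e.g. from
#'   [normalize_scales()].
#' @param bandwidth Kernel standard deviation (default 0.05).
#' @return Object of class `prior_model` with `training` (scales x
#'   residues matrix), `bandwidth`, `dim`.
#' @export
build_prior <- function(scales, bandwidth = 0.05) {
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  x <- t(as.matrix(scales))   # points x dims
  if (nrow(x) < 2) stop("need at least 2 scales", call. = FALSE)
  structure(list(training = x, bandwidth = bandwidth, dim = ncol(x),
                 codes = colnames(x)),
            class = "prior_model")
}

#' @rdname build_prior
#' @param prior A `prior_model`.
#' @param lambda Stickiness vector (named or in the prior's residue order).
#' @return `log_prior`: log density \eqn{\ln P(\lambda)} (finite; severe
#'   underflow is clamped to a large negative value with a warning).
#' @export
log_prior <- function(prior, lambda) {
  if (!is.null(prior$codes) && !is.null(names(lambda))) {
    lambda <- lambda[prior$codes]
  }
  stopifnot(length(lambda) == prior$dim)
  h <- prior$bandwidth
  d2 <- rowSums(sweep(prior$training, 2, lambda)^2)
  lk <- -d2 / (2 * h^2)
  m <- max(lk)
  lp <- m + log(mean(exp(lk - m))) - prior$dim / 2 * log(2 * pi * h^2)
  if (!is.finite(lp) || lp < -1e8) {
    warning("prior underflow; clamping log-density")
    lp <- -1e8
  }
  lp
}

#' @rdname build_prior
#' @param n Number of samples.
#' @return `sample_prior`: n x d matrix of draws from the KDE.
#' @export
sample_prior <- function(prior, n) {
  idx <- sample.int(nrow(prior$training), n, replace = TRUE)
  prior$training[idx, , drop = FALSE] +
    matrix(stats::rnorm(n * prior$dim, sd = prior$bandwidth), n, prior$dim)
}

#' Thermodynamic reweighting of a frozen ensemble
#'
#' Boltzmann reweighting from the simulated (reference) stickiness set to a
#' trial set: \eqn{w_i \propto \exp\{-[U(r_i, \lambda_k) - U(r_i,
#' \lambda_0)]/k_B T\}}, normalized to sum to one. The effective fraction
#' of frames \eqn{\phi_{eff} = \exp[-\sum_i w_i \ln(w_i N_{frames})]} is 1
#' for uniform weights and approaches \eqn{1/N_{frames}} when a single
#' frame dominates; it gates how far trial parameters may stray from the
#' reference ensemble.
#'
#' @param u_ref Per-frame nonionic energies at the reference set, kJ/mol.
#' @param u_trial Per-frame nonionic energies at the trial set, kJ/mol.
#' @param temperature_K Temperature, K.
#' @return Object of class `reweight_result`: `weights`, `phi_eff`.
#' @export
reweight_frames <- function(u_ref, u_trial, temperature_K) {
  stopifnot(length(u_ref) == length(u_trial))
  if (!all(is.finite(u_ref)) || !all(is.finite(u_trial))) {
    stop("non-finite frame energies", call. = FALSE)
  }
  lw <- -(u_trial - u_ref) / (.kB * temperature_K)
  lw <- lw - max(lw)
  w <- exp(lw) / sum(exp(lw))
  n <- length(w)
  lw_n <- ifelse(w > 0, log(w * n), 0)
  structure(list(weights = w, phi_eff = exp(-sum(w * lw_n))),
            class = "reweight_result")
}

#' Per-frame stickiness-energy coefficients
#'
#' The nonionic pair energy is affine in each pair stickiness
#' \eqn{\lambda_{ij} = (\lambda_a + \lambda_b)/2}, so the total nonionic
#' energy of a frame is affine in the per-residue stickiness vector:
#' \eqn{U(\lambda) = c + M\lambda}. This function accumulates, per frame,
#' the constant `c` and the coefficient vector `M` over the residue
#' alphabet, after which reweighting to any trial \eqn{\lambda} is a
#' matrix-vector product instead of an energy recomputation.
#'
#' @param traj A `cg_trajectory` with topology.
#' @param params A `parameter_set` (supplies sigma, epsilon).
#' @param rc Nonionic cutoff, nm.
#' @param shifted Use truncated-and-shifted pair energies.
#' @param frames Frame indices.
#' @return List with `const` (length n_frames) and `M` (n_frames x
#'   n_codes matrix, columns named by residue code); for a stickiness
#'   vector `lam`, per-frame energies are `const + M %*% lam`.
#' @export
lambda_energy_coefficients <- function(traj, params, rc = params$rc_nonionic,
                                       shifted = TRUE,
                                       frames = seq_len(n_frames(traj))) {
  topo <- traj$topology
  b <- topo$beads
  codes <- sort(unique(b$code))
  n <- nrow(b)
  ij <- which(upper.tri(diag(n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  excl <- paste(topo$bonds[, 1], topo$bonds[, 2])
  keep <- !(paste(i, j) %in% excl)
  i <- i[keep]; j <- j[keep]
  sij <- (b$sigma_nm[i] + b$sigma_nm[j]) / 2
  rmin <- 2^(1 / 6) * sij
  eps <- params$epsilon
  const <- numeric(length(frames))
  M <- matrix(0, length(frames), length(codes),
              dimnames = list(NULL, codes))
  ci <- match(b$code[i], codes); cj <- match(b$code[j], codes)
  for (f in seq_along(frames)) {
    pos <- get_frame(traj, frames[f])
    d <- pos[i, , drop = FALSE] - pos[j, , drop = FALSE]
    d <- sweep(d, 2, traj$box, function(x, L) .min_image(x, L))
    r <- sqrt(rowSums(d^2))
    within <- r <= rc
    ulj <- lj_potential(pmax(r, 1e-9), sij, eps)
    uljrc <- lj_potential(rc, sij, eps)
    inner <- r <= rmin
    # u = A + lambda_ij * B per pair
    if (shifted) {
      A <- ifelse(inner, ulj + eps, 0)
      B <- ifelse(inner, -(uljrc + eps), ulj - uljrc)
    } else {
      A <- ifelse(inner, ulj + eps, 0)
      B <- ifelse(inner, -eps, ulj)
    }
    A[!within] <- 0; B[!within] <- 0
    const[f] <- sum(A)
    # lambda_ij = (lambda_a + lambda_b)/2 -> each residue gets B/2
    hb <- B / 2
    for (k in seq_along(codes)) {
      M[f, k] <- sum(hb[ci == k]) + sum(hb[cj == k])
    }
  }
  list(const = const, M = M, codes = codes)
}

#' Cost function of the stickiness optimization
#'
#' \deqn{\mathcal{L}(\lambda) = \langle\chi^2_{Rg}\rangle +
#'   \eta\langle\chi^2_{PRE}\rangle - \theta\ln P(\lambda)}
#' where the angle brackets average over the proteins of each data class
#' (uniform weights).
#'
#' @param chi2_rg_values Per-protein reweighted Rg chi-squared values.
#' @param chi2_pre_values Per-protein PRE chi-squared values (may be
#'   `NULL` if no PRE data).
#' @param log_prior_value \eqn{\ln P(\lambda)} (0 with a flat prior).
#' @param eta PRE weight (default 0.1).
#' @param theta Prior weight (default 0.05).
#' @return List with `total` and components `chi2_rg`, `chi2_pre`,
#'   `prior_term`.
#' @export
cost_function <- function(chi2_rg_values, chi2_pre_values = NULL,
                          log_prior_value = 0, eta = 0.1, theta = 0.05) {
  c_rg <- mean(chi2_rg_values)
  c_pre <- if (length(chi2_pre_values)) mean(chi2_pre_values) else 0
  pr <- -theta * log_prior_value
  list(total = c_rg + eta * c_pre + pr,
       chi2_rg = c_rg, chi2_pre = c_pre, prior_term = pr)
}

#' Trial move of the stickiness vector
#'
#' Nudges a random selection of `n_perturb` distinct residues by Gaussian
#' increments of standard deviation `sd`; all other coordinates are left
#' unchanged.
#'
#' @param lambda Named stickiness vector.
#' @param n_perturb Number of coordinates to perturb (5 in the standard
#'   protocol; capped at the vector length).
#' @param sd Perturbation standard deviation.
#' @param clamp Clamp the result to \[0, 1\] (the normalized stickiness
#'   range); default `TRUE`.
#' @return Perturbed vector.
#' @export
propose_lambda <- function(lambda, n_perturb = 5, sd = 0.05, clamp = TRUE) {
  k <- min(n_perturb, length(lambda))
  idx <- sample.int(length(lambda), k)
  lambda[idx] <- lambda[idx] + stats::rnorm(k, sd = sd)
  if (clamp) lambda[idx] <- pmin(1, pmax(0, lambda[idx]))
  lambda
}

#' Length of one annealing micro-cycle
#'
#' Number of iterations until the control parameter, starting at `xi0` and
#' scaled by `decay` each iteration, first drops below `xi_min`.
#'
#' @param xi0 Initial control parameter.
#' @param decay Per-iteration scale factor.
#' @param xi_min Termination threshold.
#' @return Integer iteration count.
#' @export
annealing_length <- function(xi0 = 0.1, decay = 0.99, xi_min = 1e-8) {
  as.integer(ceiling(log(xi_min / xi0) / log(decay)))
}

#' Optimizer configuration
#'
#' @param eta,theta Cost-function weights.
#' @param xi0,xi_decay,xi_min Annealing schedule of the control parameter:
#'   reset to `xi0` at each micro-cycle start, multiplied by `xi_decay`
#'   each iteration, micro-cycle ends when below `xi_min`.
#' @param n_microcycles Micro-cycles per optimization cycle.
#' @param n_cycles Outer cycles (each re-simulates at the current best).
#' @param phi_min Effective-fraction gate: trial sets whose worst-protein
#'   \eqn{\phi_{eff}} falls below this are rejected without evaluation.
#' @param n_perturb,perturb_sd Trial-move parameters.
#' @param seed Integer seed for the stochastic search.
#' @return List of class `optimizer_config`.
#' @export
optimizer_config <- function(eta = 0.1, theta = 0.05, xi0 = 0.1,
                             xi_decay = 0.99, xi_min = 1e-8,
                             n_microcycles = 10, n_cycles = 1,
                             phi_min = 0.6, n_perturb = 5,
                             perturb_sd = 0.05, seed = 1) {
  structure(as.list(environment()), class = "optimizer_config")
}

.eval_lambda <- function(lambda, training, prior, config) {
  chi_rg <- numeric(0)
  chi_pre <- numeric(0)
  phi <- 1
  for (p in training) {
    lam <- lambda[colnames(p$coeffs$M)]
    u_trial <- p$coeffs$const + drop(p$coeffs$M %*% lam)
    lam0 <- p$lambda_ref[colnames(p$coeffs$M)]
    u_ref <- p$coeffs$const + drop(p$coeffs$M %*% lam0)
    rw <- reweight_frames(u_ref, u_trial, p$temperature_K)
    phi <- min(phi, rw$phi_eff)
    if (!is.null(p$rg_exp)) {
      rg_hat <- sum(rw$weights * p$rg)
      chi_rg <- c(chi_rg, chi2_rg(rg_hat, p$rg_exp, p$rg_sigma))
    }
    if (!is.null(p$pre)) {
      y_hat <- colSums(rw$weights * p$pre$Y_frames)
      chi_pre <- c(chi_pre,
                   chi2_pre(matrix(y_hat, nrow = nrow(p$pre$Y_exp)),
                            p$pre$Y_exp, p$pre$sigma))
    }
  }
  lp <- if (is.null(prior)) 0 else log_prior(prior, lambda)
  cost <- cost_function(chi_rg, chi_pre, lp, config$eta, config$theta)
  list(cost = cost, phi_eff = phi)
}

#' Annealed Bayesian optimization of the stickiness scale
#'
#' Stochastic minimization of [cost_function()] on reweighted frozen
#' ensembles. Each cycle runs `n_microcycles` annealing sweeps: the control
#' parameter starts at `xi0`, trial vectors from [propose_lambda()] are
#' first gated on the effective fraction of frames (rejected untested if
#' the worst-protein \eqn{\phi_{eff}} is below `phi_min`), then accepted
#' with Metropolis probability \eqn{\min\{1, \exp[(\mathcal{L}_{k-1} -
#' \mathcal{L}_k)/\xi_k]\}}, and \eqn{\xi} shrinks by `xi_decay` each
#' iteration until `xi_min`. The lowest-cost vector of the cycle is
#' retained; with a `resimulate` hook, subsequent cycles rebuild the
#' ensembles at the current best vector.
#'
#' Each training entry is a list with elements `coeffs` (from
#' [lambda_energy_coefficients()]), `rg` (per-frame Rg), `lambda_ref`
#' (stickiness vector the frames were simulated at), `temperature_K`,
#' `rg_exp`, `rg_sigma`, and optionally `pre` (list `Y_frames`
#' (frames x observables), `Y_exp`, `sigma` matrices).
#'
#' @param training List of per-protein training entries (see Details).
#' @param lambda0 Named starting stickiness vector.
#' @param prior A `prior_model`, or `NULL` for a flat prior.
#' @param config An [optimizer_config()].
#' @param resimulate Optional hook `function(lambda) -> training` used to
#'   regenerate ensembles between cycles.
#' @param verbose Print per-cycle progress.
#' @return List with `lambda_best`, `cost_best`, and an `audit` data frame
#'   (one row per iteration: cycle, microcycle, iteration, xi, phi_eff,
#'   accepted, total cost and components).
#' @export
optimize_lambda <- function(training, lambda0, prior = NULL,
                            config = optimizer_config(),
                            resimulate = NULL, verbose = FALSE) {
  set.seed(config$seed)
  n_iter <- annealing_length(config$xi0, config$xi_decay, config$xi_min)
  lambda_best <- lambda0
  cost_best <- Inf
  n_rows <- config$n_cycles * config$n_microcycles * n_iter
  audit <- data.frame(cycle = integer(n_rows), microcycle = integer(n_rows),
                      iteration = integer(n_rows), xi = numeric(n_rows),
                      phi_eff = numeric(n_rows), accepted = logical(n_rows),
                      cost = numeric(n_rows), chi2_rg = numeric(n_rows),
                      chi2_pre = numeric(n_rows), prior_term = numeric(n_rows))
  row <- 0
  for (cyc in seq_len(config$n_cycles)) {
    if (cyc > 1 && !is.null(resimulate)) {
      training <- resimulate(lambda_best)
    }
    lambda_cur <- lambda_best
    ev <- .eval_lambda(lambda_cur, training, prior, config)
    cost_cur <- ev$cost$total
    cyc_best <- lambda_cur
    cyc_cost <- cost_cur
    for (mc in seq_len(config$n_microcycles)) {
      xi <- config$xi0
      for (it in seq_len(n_iter)) {
        trial <- propose_lambda(lambda_cur, config$n_perturb,
                                config$perturb_sd)
        ev <- .eval_lambda(trial, training, prior, config)
        accepted <- FALSE
        if (ev$phi_eff >= config$phi_min) {
          dL <- cost_cur - ev$cost$total
          if (dL >= 0 || stats::runif(1) < exp(dL / xi)) {
            lambda_cur <- trial
            cost_cur <- ev$cost$total
            accepted <- TRUE
            if (cost_cur < cyc_cost) { cyc_cost <- cost_cur; cyc_best <- trial }
          }
        }
        row <- row + 1
        audit$cycle[row] <- cyc; audit$microcycle[row] <- mc
        audit$iteration[row] <- it; audit$xi[row] <- xi
        audit$phi_eff[row] <- ev$phi_eff; audit$accepted[row] <- accepted
        audit$cost[row] <- ev$cost$total
        audit$chi2_rg[row] <- ev$cost$chi2_rg
        audit$chi2_pre[row] <- ev$cost$chi2_pre
        audit$prior_term[row] <- ev$cost$prior_term
        xi <- xi * config$xi_decay
      }
    }
    if (cyc_cost < cost_best) { cost_best <- cyc_cost; lambda_best <- cyc_best }
    if (verbose) {
      message("cycle ", cyc, ": best cost ", signif(cost_best, 5))
    }
  }
  list(lambda_best = lambda_best, cost_best = cost_best,
       audit = audit[seq_len(row), ])
}
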