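# Independent brute-force oracles. Formulas are written out inline (not via
# the package's potential functions) so the reference path is fully
# independent of the implementation it checks.

# nearest-image distance found by explicit search over the 27 neighbour cells
oracle_min_image_dist <- function(pi, pj, box) {
  best <- Inf
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    d <- pi - (pj + c(sx, sy, sz) * box)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

oracle_pair_nonionic <- function(r, sig, lam, rc, eps, shifted) {
  ulj <- function(rr) 4 * eps * ((sig / rr)^12 - (sig / rr)^6)
  rmin <- 2^(1 / 6) * sig
  if (shifted) {
    if (r > rc) return(0)
    if (r <= rmin) ulj(r) - lam * ulj(rc) + (1 - lam) * eps
    else lam * (ulj(r) - ulj(rc))
  } else {
    if (r <= rmin) ulj(r) + (1 - lam) * eps else lam * ulj(r)
  }
}

oracle_pair_ionic <- function(r, qi, qj, debye, coul, rc, shifted) {
  u <- function(rr) qi * qj * coul * exp(-rr / debye) / rr
  if (shifted) {
    if (r > rc) return(0)
    u(r) - u(rc)
  } else u(r)
}

# full O(N^2) energy with explicit image search and 1-2 exclusions
oracle_energy <- function(pos, box, topology, params, ctx,
                          rc_nonionic = params$rc_nonionic, shifted = TRUE,
                          rc_window = NULL) {
  n <- nrow(pos)
  b <- topology$beads
  bonded <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(topology$bonds))) {
    bonded[topology$bonds[k, 1], topology$bonds[k, 2]] <- TRUE
    bonded[topology$bonds[k, 2], topology$bonds[k, 1]] <- TRUE
  }
  e_bond <- 0
  for (k in seq_len(nrow(topology$bonds))) {
    i <- topology$bonds[k, 1]; j <- topology$bonds[k, 2]
    r <- oracle_min_image_dist(pos[i, ], pos[j, ], box)
    e_bond <- e_bond + 0.5 * params$bond_k * (r - params$bond_r0)^2
  }
  e_nb <- 0; e_ion <- 0
  per_chain <- numeric(length(topology$chains))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (bonded[i, j]) next
    r <- oracle_min_image_dist(pos[i, ], pos[j, ], box)
    in_window <- if (is.null(rc_window)) r <= rc_nonionic
      else (r > rc_window[1] & r <= rc_window[2])
    if (in_window) {
      u <- oracle_pair_nonionic(r, (b$sigma_nm[i] + b$sigma_nm[j]) / 2,
                                (b$lambda[i] + b$lambda[j]) / 2,
                                rc_nonionic, params$epsilon, shifted)
      e_nb <- e_nb + u
      per_chain[b$chain[i]] <- per_chain[b$chain[i]] + u / 2
      per_chain[b$chain[j]] <- per_chain[b$chain[j]] + u / 2
    }
    if (b$charge[i] * b$charge[j] != 0 && r <= params$rc_ionic) {
      e_ion <- e_ion + oracle_pair_ionic(r, b$charge[i], b$charge[j],
                                         ctx$debye_nm, ctx$coulomb_kJnm,
                                         params$rc_ionic, shifted)
    }
  }
  list(bonded = e_bond, nonionic = e_nb, ionic = e_ion,
       per_chain_nonionic = per_chain)
}

# direct-sum radius of gyration
oracle_rg <- function(pos, masses) {
  w <- masses / sum(masses)
  com <- c(sum(w * pos[, 1]), sum(w * pos[, 2]), sum(w * pos[, 3]))
  s <- 0
  for (i in seq_len(nrow(pos))) s <- s + w[i] * sum((pos[i, ] - com)^2)
  sqrt(s)
}

# random multi-chain configuration with no overlapping beads
random_test_system <- function(n_chains = 2, chain_length = 15,
                               box = rep(12, 3), seed = 1,
                               params = default_parameter_set("CALVADOS2"),
                               conditions = solution_conditions(298, 0.15, 7)) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_chains), function(k) {
    paste(sample(c("A", "G", "K", "E", "Y", "F", "S"), chain_length,
                 replace = TRUE), collapse = "")
  }, character(1))
  topo <- build_topology(seqs, params, conditions)
  pos <- NULL
  min_image_d <- function(a, b) {
    d <- a - b
    d <- d - box * round(d / box)
    sqrt(sum(d^2))
  }
  for (k in seq_len(n_chains)) {
    repeat {
      cur <- runif(3, 2, box - 2)
      if (is.null(pos) ||
          min(apply(pos, 1, min_image_d, b = cur)) > 0.42) break
    }
    chain_pos <- matrix(cur, 1, 3)
    while (nrow(chain_pos) < chain_length) {
      prev <- chain_pos[nrow(chain_pos), ]
      for (try in 1:500) {
        step <- rnorm(3)
        cand <- prev + step / sqrt(sum(step^2)) * 0.38
        others <- rbind(pos, chain_pos[-nrow(chain_pos), , drop = FALSE])
        ok <- is.null(others) || nrow(others) == 0 ||
          min(apply(others, 1, min_image_d, b = cand)) > 0.42
        if (ok) break
      }
      chain_pos <- rbind(chain_pos, cand)
    }
    pos <- rbind(pos, chain_pos)
  }
  list(topology = topo, config = cg_configuration(pos, box),
       params = params,
       ctx = electrostatics_context(conditions$temperature_K,
                                    conditions$ionic_strength_M))
}
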