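#' Build a bead-chain topology
#'
#' One bead per residue; consecutive beads within each chain are connected
#' by harmonic bonds. Per-bead charges are assigned at the conditions' pH
#' (histidine via Henderson-Hasselbalch); if the parameter set's
#' `termini_charges` flag is on, the first bead of each chain gains +1 and
#' the last -1.
#'
#' @param sequences Character vector of one-letter sequences, or a list of
#'   [protein_spec()] objects (all chains share `conditions`).
#' @param params A `parameter_set`.
#' @param conditions A [solution_conditions()]; defaults to the first
#'   spec's conditions.
#' @return Object of class `cg_topology`: `chains` (list of residue-code
#'   vectors), `bonds` (two-column matrix of 1-based bead indices), and
#'   `beads` (data frame with `code`, `chain`, `sigma_nm`, `lambda`,
#'   `charge`, `mass_Da`).
#' @export
build_topology <- function(sequences, params, conditions = NULL) {
  if (inherits(sequences, "protein_spec")) sequences <- list(sequences)
  if (is.list(sequences)) {
    if (is.null(conditions)) conditions <- sequences[[1]]$conditions
    sequences <- vapply(sequences, function(s) s$sequence, character(1))
  }
  if (is.null(conditions)) {
    stop("solution conditions are required to assign charges", call. = FALSE)
  }
  chains <- lapply(sequences, function(s) strsplit(s, "")[[1]])
  codes <- unlist(chains)
  .check_codes(codes, params)
  lens <- lengths(chains)
  chain_id <- rep(seq_along(chains), lens)
  q <- residue_charge(codes, conditions$pH, params)
  if (isTRUE(params$termini_charges)) {
    first <- cumsum(c(1, lens[-length(lens)]))
    last <- cumsum(lens)
    q[first] <- q[first] + 1
    q[last] <- q[last] - 1
  }
  tab <- params$residues[codes, ]
  beads <- data.frame(code = codes, chain = chain_id,
                      sigma_nm = tab$sigma_nm, lambda = tab$lambda,
                      charge = q, mass_Da = tab$mass_Da,
                      row.names = NULL)
  bonds <- do.call(rbind, lapply(seq_along(chains), function(ci) {
    off <- sum(lens[seq_len(ci - 1)])
    if (lens[ci] < 2) return(matrix(integer(0), ncol = 2))
    cbind(off + seq_len(lens[ci] - 1), off + seq_len(lens[ci] - 1) + 1L)
  }))
  structure(list(chains = chains, bonds = bonds, beads = beads,
                 conditions = conditions),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("<cg_topology>", length(x$chains), "chain(s),", nrow(x$beads),
      "beads,", nrow(x$bonds), "bonds\n")
  invisible(x)
}

#' Configuration container
#'
#' @param positions N x 3 matrix of coordinates, nm.
#' @param box Periodic box edge lengths `c(Lx, Ly, Lz)`, nm.
#' @return Object of class `cg_configuration`.
#' @export
cg_configuration <- function(positions, box) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, all(is.finite(positions)),
            length(box) == 3, all(box > 0))
  structure(list(positions = positions, box = as.numeric(box)),
            class = "cg_configuration")
}

#' Single-chain starting system
#'
#' A fully extended linear conformation with 0.38 nm spacing, centered in a
#' cubic box of side \eqn{0.38 (N - 1) + 4} nm.
#'
#' @param spec A [protein_spec()].
#' @param params A `parameter_set`.
#' @return List with `topology` and `configuration`.
#' @export
build_single_chain_system <- function(spec, params) {
  topo <- build_topology(spec, params)
  n <- nrow(topo$beads)
  side <- 0.38 * (n - 1) + 4
  z <- 0.38 * (seq_len(n) - 1) - 0.38 * (n - 1) / 2
  pos <- cbind(rep(side / 2, n), rep(side / 2, n), z + side / 2)
  list(topology = topo,
       configuration = cg_configuration(pos, rep(side, 3)))
}

#' Direct-coexistence (slab) starting system
#'
#' `n_chains` copies of the chain, extended along z and centered on the box
#' midplane, with middle beads placed at random (x, y) positions all more
#' than `min_sep` apart (rejection sampling).
#'
#' @param spec A [protein_spec()].
#' @param n_chains Number of chains (100 in the standard protocol).
#' @param params A `parameter_set`.
#' @param box Box edge lengths, nm; `c(15, 15, 150)` for typical chains,
#'   `c(17, 17, 300)` and `c(25, 25, 300)` for the largest systems.
#' @param min_sep Minimum xy distance between middle beads, nm.
#' @param seed Optional integer seed for the placement.
#' @param max_tries Rejection-sampling attempts per chain.
#' @return List with `topology` and `configuration`.
#' @export
build_slab_system <- function(spec, n_chains = 100, params,
                              box = c(15, 15, 150), min_sep = 0.7,
                              seed = NULL, max_tries = 10000) {
  topo <- build_topology(rep(spec$sequence, n_chains), params,
                         conditions = spec$conditions)
  n <- length(topo$chains[[1]])
  if (0.38 * (n - 1) >= box[3]) {
    stop("extended chain (", 0.38 * (n - 1),
         " nm) does not fit the box z-extent; use a larger box", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  xy <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(n_chains)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- stats::runif(2, 0, box[1:2])
      if (nrow(xy) == 0) { ok <- TRUE } else {
        d <- sweep(xy, 2, cand)
        d <- cbind(.min_image(d[, 1], box[1]), .min_image(d[, 2], box[2]))
        ok <- all(rowSums(d^2) > min_sep^2)
      }
      if (ok) { xy <- rbind(xy, cand); placed <- TRUE; break }
    }
    if (!placed) {
      stop("could not place chain ", k, " with min separation ", min_sep,
           " nm; use a larger box cross-section", call. = FALSE)
    }
  }
  z <- 0.38 * (seq_len(n) - 1) - 0.38 * (n - 1) / 2 + box[3] / 2
  pos <- do.call(rbind, lapply(seq_len(n_chains), function(k) {
    cbind(rep(xy[k, 1], n), rep(xy[k, 2], n), z)
  }))
  list(topology = topo, configuration = cg_configuration(pos, box))
}

#' Single-chain sampling schedule
#'
#' Conformations are saved every \eqn{\Delta t \approx 3 N^2} fs for
#' \eqn{N > 100} and every 30 ps otherwise; each chain is run in
#' `n_replicas` replicas of 600 saved frames, the first 100 of which are
#' discarded, yielding 5,000 weakly correlated conformations with the
#' default ten replicas.
#'
#' @param N Sequence length.
#' @param n_replicas Number of replicas.
#' @return Object of class `sampling_schedule`: `save_interval_ps`,
#'   `n_frames_saved`, `n_discard` (both per replica), `n_replicas`, and
#'   `n_retained_total`.
#' @export
sampling_schedule <- function(N, n_replicas = 10) {
  stopifnot(N >= 1)
  save_ps <- if (N > 100) 3 * N^2 * 1e-3 else 30
  structure(list(save_interval_ps = save_ps, n_frames_saved = 600L,
                 n_discard = 100L, n_replicas = as.integer(n_replicas),
                 n_retained_total = as.integer((600 - 100) * n_replicas)),
            class = "sampling_schedule")
}

#' Integrator settings
#'
#' @param temperature_K Thermostat temperature, K.
#' @param timestep_fs Time step, fs.
#' @param friction_ps Langevin friction coefficient, ps^-1.
#' @param seed Optional integer seed.
#' @return Object of class `simulation_settings`.
#' @export
simulation_settings <- function(temperature_K, timestep_fs = 10,
                                friction_ps = 0.01, seed = NULL) {
  stopifnot(timestep_fs > 0, friction_ps > 0)
  structure(list(temperature_K = temperature_K, timestep_fs = timestep_fs,
                 friction_ps = friction_ps, seed = seed),
            class = "simulation_settings")
}

#' Run Langevin dynamics
#'
#' NVT dynamics with a BAOAB-splitting Langevin integrator acting on the
#' truncated-and-shifted Ashbaugh-Hatch + Debye-Hueckel + harmonic-bond
#' force field, with 1-2 nonbonded exclusions and minimum-image periodic
#' boundaries. Runs are bitwise reproducible for a fixed seed.
#'
#' @param topology A `cg_topology`.
#' @param config A `cg_configuration`.
#' @param params A `parameter_set`.
#' @param settings A [simulation_settings()].
#' @param n_steps Number of integration steps.
#' @param save_every Save a frame every this many steps (0 = none).
#' @param ctx Optional [electrostatics_context()]; defaults to the
#'   topology's solution conditions at the thermostat temperature.
#' @return Object of class `cg_trajectory`: `positions` (N x 3 x n_frames
#'   array, nm), `box`, `save_interval_ps`, per-frame `potential` and
#'   `kinetic` energies (kJ/mol), and the final phase-space point.
#' @export
run_langevin <- function(topology, config, params, settings, n_steps,
                         save_every = 100, ctx = NULL) {
  if (is.null(ctx)) {
    cond <- topology$conditions
    ctx <- electrostatics_context(settings$temperature_K,
                                  cond$ionic_strength_M)
  }
  if (any(config$box < 2 * max(params$rc_nonionic, params$rc_ionic))) {
    stop("box must be at least twice the largest cutoff", call. = FALSE)
  }
  if (n_steps == 0) {
    return(structure(list(
      positions = array(config$positions,
                        dim = c(nrow(config$positions), 3, 1)),
      box = config$box, save_interval_ps = 0,
      potential = NA_real_, kinetic = NA_real_,
      final_positions = config$positions, final_velocities = NULL,
      topology = topology), class = "cg_trajectory"))
  }
  if (!is.null(settings$seed)) set.seed(settings$seed)
  out <- cpp_run_langevin(config$positions, config$box, topology$bonds - 1L,
                          topology$beads$sigma_nm, topology$beads$lambda,
                          topology$beads$charge, topology$beads$mass_Da,
                          topology$beads$chain,
                          params$epsilon, params$bond_k, params$bond_r0,
                          params$rc_nonionic, params$rc_ionic,
                          ctx$debye_nm, ctx$coulomb_kJnm,
                          settings$temperature_K, settings$timestep_fs * 1e-3,
                          settings$friction_ps, as.integer(n_steps),
                          as.integer(save_every))
  structure(list(positions = out$frames, box = config$box,
                 save_interval_ps = save_every * settings$timestep_fs * 1e-3,
                 potential = out$potential, kinetic = out$kinetic,
                 final_positions = out$final_positions,
                 final_velocities = out$final_velocities,
                 topology = topology),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  nf <- n_frames(x)
  cat("<cg_trajectory>", dim(x$positions)[1], "beads,", nf, "frame(s),",
      "saved every", x$save_interval_ps, "ps\n")
  invisible(x)
}

#' Number of saved frames in a trajectory
#' @param traj A `cg_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  if (length(traj$positions) == 0) 0L else dim(traj$positions)[3]
}

#' Extract one frame of a trajectory
#' @param traj A `cg_trajectory`.
#' @param i Frame index.
#' @return N x 3 position matrix, nm.
#' @export
get_frame <- function(traj, i) {
  traj$positions[, , i, drop = TRUE]
}

#' Replica seeds from a master seed
#'
#' Deterministic counter scheme: replica k receives `master + k - 1`
#' (kept below 2^31).
#'
#' @param master Integer master seed.
#' @param n Number of replicas.
#' @return Integer vector of seeds.
#' @export
replica_seeds <- function(master, n) {
  as.integer((as.numeric(master) + seq_len(n) - 1) %% .Machine$integer.max)
}

#' Kinetic temperature of a trajectory
#'
#' Mean kinetic energy per degree of freedom, expressed as a temperature:
#' \eqn{T_{kin} = 2\langle KE\rangle / (3 N k_B)}.
#'
#' @param traj A `cg_trajectory`.
#' @return Temperature, K.
#' @export
kinetic_temperature <- function(traj) {
  n <- dim(traj$positions)[1]
  mean(traj$kinetic) * 2 / (3 * n * .kB)
}

#' Write/read a trajectory in a plain-text frame format
#'
#' Whitespace-delimited text: a header line `n_beads n_frames Lx Ly Lz
#' save_interval_ps`, then frames as N lines of `x y z`.
#'
#' @param traj A `cg_trajectory`.
#' @param path Output file.
#' @return `path` (write) or a `cg_trajectory` (read).
#' @export
write_trajectory_txt <- function(traj, path) {
  nf <- n_frames(traj)
  n <- dim(traj$positions)[1]
  con <- file(path, "w")
  on.exit(close(con))
  cat(n, nf, traj$box, traj$save_interval_ps, "\n", file = con)
  for (i in seq_len(nf)) {
    utils::write.table(format(get_frame(traj, i), digits = 10), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_trajectory_txt
#' @export
read_trajectory_txt <- function(path) {
  hdr <- scan(path, nlines = 1, quiet = TRUE)
  n <- hdr[1]; nf <- hdr[2]; box <- hdr[3:5]; dt <- hdr[6]
  dat <- as.matrix(utils::read.table(path, skip = 1))
  stopifnot(nrow(dat) == n * nf)
  pos <- array(NA_real_, dim = c(n, 3, nf))
  for (i in seq_len(nf)) pos[, , i] <- dat[(i - 1) * n + seq_len(n), ]
  structure(list(positions = pos, box = box, save_interval_ps = dt,
                 potential = NULL, kinetic = NULL, topology = NULL),
            class = "cg_trajectory")
}
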