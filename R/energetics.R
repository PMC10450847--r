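# Physical constants (CODATA 2018), in the nm / kJ/mol / ps / Da unit system.
.kB <- 0.008314462618      # kJ mol^-1 K^-1
.NA_AVOGADRO <- 6.02214076e23
# e^2 / (4 pi eps0 kB), in nm * K: lambda_B = .BJERRUM_NMK / (eps_r * T)
.BJERRUM_NMK <- (1.602176634e-19)^2 /
  (4 * pi * 8.8541878128e-12 * 1.380649e-23) * 1e9

#' Temperature-dependent dielectric constant of water
#'
#' Empirical polynomial for the relative permittivity of liquid water,
#' \deqn{\epsilon_r(T) = 5321/T + 233.76 - 0.9297 T + 1.417\times10^{-3} T^2
#'   - 8.292\times10^{-7} T^3,} with \eqn{T} in kelvin. Only valid in the
#' liquid range; temperatures outside (250, 400) K are refused.
#'
#' @param temperature_K Temperature, K.
#' @return Dimensionless relative permittivity.
#' @export
dielectric_constant <- function(temperature_K) {
  if (any(temperature_K <= 250 | temperature_K >= 400)) {
    stop("dielectric polynomial is only valid for T in (250, 400) K",
         call. = FALSE)
  }
  T <- temperature_K
  5321 / T + 233.76 - 0.9297 * T + 1.417e-3 * T^2 - 8.292e-7 * T^3
}

#' Bjerrum length
#'
#' Distance at which the unscreened Coulomb energy between unit charges
#' equals the thermal energy: \eqn{\lambda_B = e^2/(4\pi\epsilon_0\epsilon_r
#' k_B T)}.
#'
#' @param temperature_K Temperature, K.
#' @param dielectric Relative permittivity; defaults to
#'   [dielectric_constant()] at the same temperature.
#' @return Bjerrum length, nm.
#' @export
bjerrum_length <- function(temperature_K,
                           dielectric = dielectric_constant(temperature_K)) {
  .BJERRUM_NMK / (dielectric * temperature_K)
}

#' Debye screening length
#'
#' \eqn{D = 1/\sqrt{8\pi \lambda_B n_s}} with \eqn{n_s} the salt number
#' density obtained from the molar ionic strength (monovalent salt assumed).
#' At zero ionic strength the screening length diverges and `Inf` is
#' returned.
#'
#' @param temperature_K Temperature, K.
#' @param ionic_strength_M Ionic strength, mol/L.
#' @return Debye length, nm (`Inf` for `ionic_strength_M = 0`).
#' @export
debye_length <- function(temperature_K, ionic_strength_M) {
  if (any(ionic_strength_M < 0)) stop("ionic strength must be >= 0", call. = FALSE)
  ns <- ionic_strength_M * .NA_AVOGADRO * 1e-24   # nm^-3
  lb <- bjerrum_length(temperature_K)
  ifelse(ns == 0, Inf, 1 / sqrt(8 * pi * lb * ns))
}

#' Electrostatics context
#'
#' Precomputes the temperature- and salt-dependent quantities entering the
#' Debye-Hueckel potential.
#'
#' @param temperature_K Temperature, K.
#' @param ionic_strength_M Ionic strength, mol/L.
#' @return Object of class `electrostatics_context` with fields
#'   `temperature_K`, `ionic_strength_M`, `dielectric`, `bjerrum_nm`,
#'   `debye_nm`, and `coulomb_kJnm` (the molar prefactor
#'   \eqn{k_B T \lambda_B} in kJ nm / mol).
#' @export
electrostatics_context <- function(temperature_K, ionic_strength_M) {
  er <- dielectric_constant(temperature_K)
  lb <- bjerrum_length(temperature_K, er)
  structure(list(temperature_K = temperature_K,
                 ionic_strength_M = ionic_strength_M,
                 dielectric = er, bjerrum_nm = lb,
                 debye_nm = debye_length(temperature_K, ionic_strength_M),
                 coulomb_kJnm = .kB * temperature_K * lb),
            class = "electrostatics_context")
}

#' Lennard-Jones pair potential
#'
#' \deqn{u_{LJ}(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]}
#'
#' @param r Separation, nm (> 0).
#' @param sigma Pair diameter, nm.
#' @param epsilon Energy scale, kJ/mol.
#' @return Energy, kJ/mol.
#' @export
lj_potential <- function(r, sigma, epsilon = 0.8368) {
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  s6 <- (sigma / r)^6
  4 * epsilon * (s6^2 - s6)
}

#' Ashbaugh-Hatch stickiness potential
#'
#' Lennard-Jones-based pair potential whose attractive tail is scaled by the
#' pair stickiness \eqn{\lambda}. In the truncated-and-shifted form
#' (`shifted = TRUE`):
#' \deqn{u(r) = \begin{cases}
#'   u_{LJ}(r) - \lambda u_{LJ}(r_c) + (1-\lambda)\epsilon & r \le 2^{1/6}\sigma\\
#'   \lambda [u_{LJ}(r) - u_{LJ}(r_c)] & 2^{1/6}\sigma < r \le r_c\\
#'   0 & r > r_c \end{cases}}
#' With `shifted = FALSE` the bare pair energy (no cutoff shift, no
#' truncation) is returned; this form is used for cutoff-loss accounting.
#' At \eqn{\lambda = 1} the shifted form reduces to the truncated-shifted
#' Lennard-Jones potential; at \eqn{\lambda = 0} it is purely repulsive.
#'
#' @param r Separation, nm (> 0).
#' @param sigma Pair diameter, nm.
#' @param lambda Pair stickiness.
#' @param rc Cutoff, nm; must exceed \eqn{2^{1/6}\sigma}.
#' @param epsilon Energy scale, kJ/mol.
#' @param shifted Truncate and shift at `rc` (default) or return the bare
#'   pair energy.
#' @return Energy, kJ/mol.
#' @export
ah_potential <- function(r, sigma, lambda, rc, epsilon = 0.8368,
                         shifted = TRUE) {
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  rmin <- 2^(1 / 6) * sigma
  if (any(rc <= rmin)) stop("cutoff rc must exceed 2^(1/6)*sigma", call. = FALSE)
  ulj <- lj_potential(r, sigma, epsilon)
  inner <- r <= rmin
  if (shifted) {
    uljrc <- lj_potential(rc, sigma, epsilon)
    u <- ifelse(inner, ulj - lambda * uljrc + (1 - lambda) * epsilon,
                lambda * (ulj - uljrc))
    u[r > rc] <- 0
  } else {
    u <- ifelse(inner, ulj + (1 - lambda) * epsilon, lambda * ulj)
  }
  u
}

#' Debye-Hueckel pair potential
#'
#' Salt-screened electrostatic interaction between average residue charges:
#' \deqn{u_{DH}(r) = q_i q_j \frac{e^2}{4\pi\epsilon_0\epsilon_r}
#'   \frac{\exp(-r/D)}{r}.}
#' With `shifted = TRUE` the value at the cutoff is subtracted and the
#' potential is zero beyond it.
#'
#' @param r Separation, nm.
#' @param q_i,q_j Charges, elementary-charge units.
#' @param ctx An [electrostatics_context()].
#' @param rc Cutoff, nm.
#' @param shifted Truncate and shift at `rc`.
#' @return Energy, kJ/mol.
#' @export
dh_potential <- function(r, q_i, q_j, ctx, rc = 4.0, shifted = TRUE) {
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  pref <- q_i * q_j * ctx$coulomb_kJnm
  u <- pref * exp(-r / ctx$debye_nm) / r
  if (shifted) {
    u <- u - pref * exp(-rc / ctx$debye_nm) / rc
    u[r > rc] <- 0
  }
  u
}

#' Harmonic bond potential
#'
#' \deqn{u(r) = \tfrac{1}{2} k (r - r_0)^2}
#'
#' @param r Bond length, nm (>= 0).
#' @param k Force constant, kJ mol^-1 nm^-2.
#' @param r0 Equilibrium length, nm.
#' @return Energy, kJ/mol.
#' @export
bond_potential <- function(r, k = 8033, r0 = 0.38) {
  if (any(r < 0)) stop("r must be non-negative", call. = FALSE)
  0.5 * k * (r - r0)^2
}

# minimum-image displacement components, vectorized
.min_image <- function(d, L) d - L * round(d / L)

#' Total potential energy of a configuration
#'
#' Sums harmonic bond terms over all bonds and the nonbonded pair terms over
#' all pairs not directly bonded (1-2 exclusions), under the minimum-image
#' convention. Nonionic (Ashbaugh-Hatch) and ionic (Debye-Hueckel)
#' contributions are reported separately, and the nonionic energy is also
#' attributed per chain, half of each pair energy to each participating
#' chain.
#'
#' This is the pure-R reference path; the compiled engine
#' (`backend = "compiled"`) must agree with it to within numerical roundoff
#' and is faster for large systems.
#'
#' @param config A `cg_configuration` (positions + box).
#' @param topology A `cg_topology`.
#' @param params A `parameter_set`.
#' @param ctx An [electrostatics_context()].
#' @param rc_nonionic Nonionic cutoff, nm (defaults to the parameter set's).
#' @param shifted Use the truncated-and-shifted potentials (default); with
#'   `FALSE`, bare pair energies are summed over pairs within the cutoff
#'   (the accounting convention for cutoff-difference analysis).
#' @param backend `"reference"` (pure R) or `"compiled"`.
#' @return Object of class `energy_breakdown`: list with `bonded`,
#'   `nonionic`, `ionic` (kJ/mol) and `per_chain_nonionic`.
#' @export
system_energy <- function(config, topology, params, ctx,
                          rc_nonionic = params$rc_nonionic, shifted = TRUE,
                          backend = c("reference", "compiled")) {
  backend <- match.arg(backend)
  pos <- config$positions
  box <- config$box
  if (any(box < 2 * max(rc_nonionic, params$rc_ionic))) {
    stop("box must be at least twice the largest cutoff for minimum-image validity",
         call. = FALSE)
  }
  if (backend == "compiled") {
    e <- cpp_system_energy(pos, box, topology$bonds - 1L,
                           topology$beads$sigma_nm, topology$beads$lambda,
                           topology$beads$charge, topology$beads$chain,
                           params$epsilon, params$bond_k, params$bond_r0,
                           rc_nonionic, params$rc_ionic,
                           ctx$debye_nm, ctx$coulomb_kJnm, shifted)
    return(structure(e, class = "energy_breakdown"))
  }
  n <- nrow(pos)
  bonds <- topology$bonds
  rb <- if (nrow(bonds)) {
    d <- pos[bonds[, 1], , drop = FALSE] - pos[bonds[, 2], , drop = FALSE]
    d <- sweep(d, 2, box, function(x, L) .min_image(x, L))
    sqrt(rowSums(d^2))
  } else numeric(0)
  bonded <- sum(bond_potential(rb, params$bond_k, params$bond_r0))

  per_chain <- numeric(length(topology$chains))
  nonionic <- 0
  ionic <- 0
  if (n > 1) {
    ij <- which(upper.tri(diag(n)), arr.ind = TRUE)
    i <- ij[, 1]; j <- ij[, 2]  # i < j, matching bond ordering
    excl <- paste(bonds[, 1], bonds[, 2])
    keep <- !(paste(i, j) %in% excl)
    i <- i[keep]; j <- j[keep]
    d <- pos[i, , drop = FALSE] - pos[j, , drop = FALSE]
    d <- sweep(d, 2, box, function(x, L) .min_image(x, L))
    r <- sqrt(rowSums(d^2))
    b <- topology$beads
    sij <- (b$sigma_nm[i] + b$sigma_nm[j]) / 2
    lij <- (b$lambda[i] + b$lambda[j]) / 2
    in_nb <- r <= rc_nonionic
    u_nb <- numeric(length(r))
    if (any(in_nb)) {
      u_nb[in_nb] <- ah_potential(r[in_nb], sij[in_nb], lij[in_nb],
                                  rc = rc_nonionic, epsilon = params$epsilon,
                                  shifted = shifted)
    }
    nonionic <- sum(u_nb)
    qq <- b$charge[i] * b$charge[j]
    in_ion <- qq != 0 & r <= params$rc_ionic
    if (any(in_ion)) {
      ionic <- sum(dh_potential(r[in_ion], b$charge[i][in_ion],
                                b$charge[j][in_ion], ctx,
                                rc = params$rc_ionic, shifted = shifted))
    }
    half <- u_nb / 2
    per_chain <- vapply(seq_along(topology$chains), function(ch) {
      sum(half[b$chain[i] == ch]) + sum(half[b$chain[j] == ch])
    }, numeric(1))
  }
  structure(list(bonded = bonded, nonionic = nonionic, ionic = ionic,
                 per_chain_nonionic = per_chain),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy_breakdown> (kJ/mol)\n")
  cat("  bonded:  ", format(x$bonded), "\n")
  cat("  nonionic:", format(x$nonionic), "\n")
  cat("  ionic:   ", format(x$ionic), "\n")
  invisible(x)
}
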