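# 1 Da/nm^3 in mg/mL
.DA_NM3_TO_MG_ML <- 1.66053906892

.wrap_z <- function(z, Lz) z - Lz * round(z / Lz)  # into [-Lz/2, Lz/2)

.frame_mass_hist <- function(z, masses, Lz, nbins) {
  zb <- .wrap_z(z, Lz) + Lz / 2
  idx <- pmin(nbins, floor(zb / (Lz / nbins)) + 1L)
  as.numeric(tapply(masses, factor(idx, levels = seq_len(nbins)), sum,
                    default = 0))
}

#' Center the condensed slab at z = 0
#'
#' For each frame, a coarse mass histogram along z is computed and the
#' circular shift that maximizes the mass inside a central window of width
#' Lz/2 is applied; the shift is then refined to sub-bin accuracy by
#' subtracting the mass-weighted mean z of the window content. Translation
#' along a periodic axis is a pure gauge, so the operation is idempotent up
#' to bin resolution and a no-op (up to noise) on a homogeneous system.
#'
#' @param traj A `cg_trajectory` (slab geometry, periodic z).
#' @param masses Per-bead masses; defaults to the topology's.
#' @param bin_width Coarse histogram bin width, nm.
#' @return The trajectory with shifted z coordinates.
#' @export
center_slab <- function(traj, masses = NULL, bin_width = 1) {
  if (is.null(masses)) {
    masses <- if (!is.null(traj$topology)) traj$topology$beads$mass_Da
      else rep(1, dim(traj$positions)[1])
  }
  Lz <- traj$box[3]
  nbins <- max(8L, round(Lz / bin_width))
  centers <- (seq_len(nbins) - 0.5) * (Lz / nbins) - Lz / 2
  half_win <- Lz / 4
  win <- round(nbins / 2)
  for (f in seq_len(n_frames(traj))) {
    z <- traj$positions[, 3, f]
    h <- .frame_mass_hist(z, masses, Lz, nbins)
    # circular windowed sums of width ~Lz/2 centered on each bin
    hh <- c(h, h)
    cs <- cumsum(c(0, hh))
    wsum <- vapply(seq_len(nbins), function(b) {
      lo <- b - floor(win / 2); hi <- lo + win - 1
      lo <- lo + nbins * (lo < 1)
      hi2 <- lo + win - 1
      cs[hi2 + 1] - cs[lo]
    }, numeric(1))
    shift <- centers[which.max(wsum)]
    z2 <- .wrap_z(z - shift, Lz)
    inwin <- abs(z2) <= half_win
    if (any(inwin)) {
      shift <- shift + sum(z2[inwin] * masses[inwin]) / sum(masses[inwin])
    }
    traj$positions[, 3, f] <- .wrap_z(z - shift, Lz)
  }
  traj
}

#' Mass density profile along z
#'
#' Time-averaged mass concentration per z-bin, in mg/mL. The per-frame bin
#' integral times the box cross-section recovers the total system mass
#' exactly (mass conservation).
#'
#' @param traj A `cg_trajectory` (ideally centered with [center_slab()]).
#' @param masses Per-bead masses, Da; defaults to the topology's.
#' @param bin_width Bin width, nm.
#' @param frames Frame indices to average over (default all; use this to
#'   discard equilibration).
#' @return Object of class `density_profile`: `z_centers` (nm), `density`
#'   (mg/mL, time average), `per_frame` (bins x frames matrix),
#'   `n_frames_averaged`, `bin_width`, `box`.
#' @export
density_profile <- function(traj, masses = NULL, bin_width = 1,
                            frames = seq_len(n_frames(traj))) {
  if (is.null(masses)) {
    masses <- if (!is.null(traj$topology)) traj$topology$beads$mass_Da
      else rep(1, dim(traj$positions)[1])
  }
  Lz <- traj$box[3]
  nbins <- max(4L, round(Lz / bin_width))
  dz <- Lz / nbins
  vol <- traj$box[1] * traj$box[2] * dz
  per_frame <- vapply(frames, function(f) {
    .frame_mass_hist(traj$positions[, 3, f], masses, Lz, nbins) / vol *
      .DA_NM3_TO_MG_ML
  }, numeric(nbins))
  per_frame <- matrix(per_frame, nrow = nbins)
  structure(list(z_centers = (seq_len(nbins) - 0.5) * dz - Lz / 2,
                 density = rowMeans(per_frame), per_frame = per_frame,
                 n_frames_averaged = length(frames), bin_width = dz,
                 box = traj$box),
            class = "density_profile")
}

.fit_semiprofile <- function(za, rho) {
  ra0 <- max(mean(rho[za <= stats::quantile(za, 0.1)]), max(rho) * 0.5)
  # a vanishing dilute-plateau start makes the gradient singular; floor it
  rb0 <- max(mean(rho[za >= stats::quantile(za, 0.9)]), 1e-4 * ra0)
  mid <- (ra0 + rb0) / 2
  zds0 <- za[which.min(abs(rho - mid))]
  df <- data.frame(za = za, rho = rho)
  fit <- try(minpack.lm::nlsLM(
    rho ~ (ra + rb) / 2 + (rb - ra) / 2 * tanh((za - zds) / t),
    data = df, start = list(ra = ra0, rb = rb0, zds = zds0, t = 1),
    lower = c(0, 0, 0, 1e-3), upper = c(Inf, Inf, max(za), max(za)),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  list(coef = co, se = se)
}

#' Fit the tanh interface model to a density profile
#'
#' Nonlinear least-squares fit of
#' \deqn{\rho(z) = \frac{\rho_a + \rho_b}{2} +
#'   \frac{\rho_b - \rho_a}{2}\tanh\left(\frac{|z| - z_{DS}}{t}\right)}
#' to the two semi-profiles (z > 0 and z < 0) of a centered profile;
#' \eqn{\rho_a} and \eqn{\rho_b} are the dense- and dilute-phase plateau
#' densities, \eqn{z_{DS}} the dividing surface and \eqn{t} the interface
#' width. Reported parameters are the averages over the two sides. If the
#' fit does not converge, or the fitted plateaus are too similar
#' (dense/dilute ratio below `min_contrast`), the profile is flagged as not
#' phase separated rather than raising an error.
#'
#' @param profile A `density_profile`.
#' @param min_contrast Minimum dense/dilute density ratio for a profile to
#'   count as phase separated.
#' @return Object of class `tanh_fit` with `rho_dense`, `rho_dilute`,
#'   `z_interface`, `width` (+ `per_side` coefficient/uncertainty tables)
#'   and logical `phase_separated`.
#' @export
fit_tanh_profile <- function(profile, min_contrast = 5) {
  z <- profile$z_centers
  rho <- profile$density
  sides <- list(pos = z > 0, neg = z < 0)
  if (sum(sides$pos) < 20 || sum(sides$neg) < 20) {
    stop("profile needs at least 20 bins per side", call. = FALSE)
  }
  fits <- list(
    pos = .fit_semiprofile(z[sides$pos], rho[sides$pos]),
    neg = .fit_semiprofile(-z[sides$neg], rho[sides$neg]))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    return(structure(list(phase_separated = FALSE, per_side = fits),
                     class = "tanh_fit"))
  }
  co <- rowMeans(vapply(fits[ok], function(f) f$coef, numeric(4)))
  separated <- is.finite(co["ra"]) && is.finite(co["rb"]) &&
    co["ra"] > min_contrast * max(co["rb"], 1e-12) &&
    co["ra"] > co["rb"]
  structure(list(rho_dense = unname(co["ra"]), rho_dilute = unname(co["rb"]),
                 z_interface = unname(co["zds"]), width = unname(co["t"]),
                 per_side = fits, phase_separated = separated),
            class = "tanh_fit")
}

#' @export
print.tanh_fit <- function(x, ...) {
  if (!isTRUE(x$phase_separated)) {
    cat("<tanh_fit> no phase separation detected\n")
  } else {
    cat("<tanh_fit> rho_dense:", signif(x$rho_dense, 4), "mg/mL;",
        "rho_dilute:", signif(x$rho_dilute, 4), "mg/mL;",
        "z_DS:", signif(x$z_interface, 4), "nm; t:",
        signif(x$width, 4), "nm\n")
  }
  invisible(x)
}

#' Coexisting phase concentrations
#'
#' Averages the density profile over the bulk regions on either side of the
#' fitted interface: the central region \eqn{|z| < z_{DS} - t/2} is the
#' condensed phase (the slab sits at the box centre) and the far region
#' \eqn{|z| > z_{DS} + 6t} is the dilute phase. Mass densities are
#' converted to molar protein concentrations with the chain molecular
#' weight. Uncertainties are blocking standard errors over per-frame
#' region averages when the profile carries per-frame data.
#'
#' @param profile A `density_profile`.
#' @param fit A `tanh_fit` with `phase_separated = TRUE`.
#' @param chain_mass_Da Chain molecular weight, Da.
#' @return Object of class `phase_densities`: `c_con_mM`, `c_sat_mM` (and
#'   `_mg_ml` variants), `c_con_se_mM`, `c_sat_se_mM`, and
#'   `dilute_empty` flag (`c_sat = 0` when no mass lies beyond the
#'   interface region).
#' @export
phase_concentrations <- function(profile, fit, chain_mass_Da) {
  if (!isTRUE(fit$phase_separated)) {
    stop("no phase separation detected; phase concentrations undefined",
         call. = FALSE)
  }
  az <- abs(profile$z_centers)
  dense <- az < fit$z_interface - fit$width / 2
  dilute <- az > fit$z_interface + 6 * fit$width
  if (!any(dense)) stop("empty condensed region", call. = FALSE)
  to_mM <- function(mg_ml) mg_ml / chain_mass_Da * 1e3
  rho_con <- mean(profile$density[dense])
  dilute_empty <- !any(dilute) || all(profile$density[dilute] == 0)
  rho_sat <- if (dilute_empty && !any(dilute)) 0 else mean(profile$density[dilute])
  se <- c(NA_real_, NA_real_)
  if (!is.null(profile$per_frame) && ncol(profile$per_frame) >= 8) {
    con_f <- colMeans(profile$per_frame[dense, , drop = FALSE])
    se[1] <- blocking_error(con_f)
    if (any(dilute)) {
      sat_f <- colMeans(profile$per_frame[dilute, , drop = FALSE])
      se[2] <- if (stats::var(sat_f) == 0) 0 else blocking_error(sat_f)
    }
  }
  structure(list(c_con_mg_ml = rho_con, c_sat_mg_ml = rho_sat,
                 c_con_mM = to_mM(rho_con), c_sat_mM = to_mM(rho_sat),
                 c_con_se_mM = to_mM(se[1]), c_sat_se_mM = to_mM(se[2]),
                 dilute_empty = dilute_empty),
            class = "phase_densities")
}

#' @export
print.phase_densities <- function(x, ...) {
  cat("<phase_densities> c_con:", signif(x$c_con_mM, 4), "mM;",
      "c_sat:", signif(x$c_sat_mM * 1e3, 4), "uM",
      if (isTRUE(x$dilute_empty)) "(dilute region empty)" else "", "\n")
  invisible(x)
}

#' Nonionic energy change between two cutoffs
#'
#' Mean over frames of \eqn{[U_{nonionic}(r_c^{small}) -
#' U_{nonionic}(r_c^{large})] / n_{chains}} using bare (unshifted) pair
#' energies, i.e. the interaction energy per protein that a shorter cutoff
#' ignores. The standard deviation across frames is reported alongside.
#'
#' @param traj A `cg_trajectory` with topology.
#' @param params A `parameter_set`.
#' @param rc_small,rc_large The two nonionic cutoffs, nm.
#' @param frames Frame indices to include.
#' @return List with `mean_kJmol`, `sd_kJmol`, `per_frame`.
#' @export
cutoff_energy_difference <- function(traj, params, rc_small = 2,
                                     rc_large = 4,
                                     frames = seq_len(n_frames(traj))) {
  topo <- traj$topology
  if (is.null(topo)) stop("trajectory carries no topology", call. = FALSE)
  nch <- length(topo$chains)
  du <- vapply(frames, function(f) {
    pos <- get_frame(traj, f)
    e <- function(rc) {
      cpp_system_energy(pos, traj$box, topo$bonds - 1L,
                        topo$beads$sigma_nm, topo$beads$lambda,
                        topo$beads$charge, topo$beads$chain,
                        params$epsilon, params$bond_k, params$bond_r0,
                        rc, params$rc_ionic, 1.0, 0.0,
                        FALSE)$nonionic
    }
    (e(rc_small) - e(rc_large)) / nch
  }, numeric(1))
  list(mean_kJmol = mean(du), sd_kJmol = stats::sd(du), per_frame = du)
}
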