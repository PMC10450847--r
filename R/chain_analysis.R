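#' Unwrap a chain across periodic boundaries
#'
#' Rebuilds contiguous coordinates by accumulating minimum-image
#' displacements between consecutive beads, so that bonded neighbours are
#' never separated by a box jump.
#'
#' @param positions N x 3 matrix of (possibly wrapped) coordinates, nm.
#' @param box Box edge lengths, nm.
#' @return N x 3 matrix of unwrapped coordinates.
#' @export
unwrap_chain <- function(positions, box) {
  d <- diff(positions)
  for (k in 1:3) d[, k] <- .min_image(d[, k], box[k])
  rbind(positions[1, , drop = FALSE],
        sweep(apply(d, 2, cumsum), 2, positions[1, ], "+"))
}

#' Radius of gyration of one conformation
#'
#' Mass-weighted root-mean-square distance of the beads from their centre
#' of mass. If `box` is supplied the chain is unwrapped across periodic
#' boundaries first. With `masses = NULL` all beads are weighted equally.
#'
#' @param positions N x 3 matrix, nm.
#' @param masses Per-bead masses, Da, or `NULL` for uniform weighting.
#' @param box Optional box for unwrapping.
#' @return Radius of gyration, nm.
#' @export
radius_of_gyration <- function(positions, masses = NULL, box = NULL) {
  positions <- as.matrix(positions)
  if (!is.null(box)) positions <- unwrap_chain(positions, box)
  n <- nrow(positions)
  if (is.null(masses)) masses <- rep(1, n)
  w <- masses / sum(masses)
  com <- colSums(positions * w)
  d2 <- rowSums(sweep(positions, 2, com)^2)
  sqrt(sum(w * d2))
}

#' Per-frame radius of gyration of a trajectory
#'
#' @param traj A `cg_trajectory` of a single chain.
#' @param masses Per-bead masses; defaults to the topology's mass table.
#' @return Numeric vector, one Rg (nm) per frame.
#' @export
trajectory_rg <- function(traj, masses = NULL) {
  if (is.null(masses) && !is.null(traj$topology)) {
    masses <- traj$topology$beads$mass_Da
  }
  vapply(seq_len(n_frames(traj)), function(i) {
    radius_of_gyration(get_frame(traj, i), masses, traj$box)
  }, numeric(1))
}

#' Ensemble radius-of-gyration statistics
#'
#' Returns both the plain average \eqn{\langle R_g\rangle} and the
#' root-mean-square \eqn{\sqrt{\langle R_g^2\rangle}}. By Jensen's
#' inequality the rms is always at least the mean; the two are distinct
#' summary statistics of the same ensemble and fitting experimental data
#' with one or the other is not equivalent.
#'
#' @param values Per-frame Rg series, nm.
#' @return Named vector `c(mean =, rms =)`.
#' @export
ensemble_rg <- function(values) {
  if (!length(values)) stop("empty Rg series", call. = FALSE)
  c(mean = mean(values), rms = sqrt(mean(values^2)))
}

#' Radius-of-gyration discrepancy
#'
#' Squared standardized residual against an experimental value:
#' \eqn{\chi^2_{Rg} = [(R_g^{exp} - R_g^{calc}) / \sigma^{exp}]^2}.
#'
#' @param calc Calculated ensemble mean Rg, nm.
#' @param exp_value Experimental Rg, nm.
#' @param sigma_exp Experimental uncertainty, nm (> 0).
#' @return Dimensionless chi-squared.
#' @export
chi2_rg <- function(calc, exp_value, sigma_exp) {
  if (any(sigma_exp <= 0)) stop("sigma_exp must be positive", call. = FALSE)
  ((exp_value - calc) / sigma_exp)^2
}

#' PRE discrepancy
#'
#' Mean squared standardized residual over a label x residue matrix of
#' paramagnetic relaxation enhancement observables (rates or intensity
#' ratios):
#' \eqn{\chi^2_{PRE} = \frac{1}{N_{labels} N_{res}} \sum_j \sum_i
#'   [(Y_{ij}^{exp} - Y_{ij}^{calc}) / \sigma_{ij}^{exp}]^2.}
#' Entries that are `NA` in the experimental matrix are masked: they are
#' excluded from the sum and the normalization uses the count of observed
#' entries.
#'
#' @param Y_calc Calculated observable matrix (labels x residues).
#' @param Y_exp Experimental matrix, same shape; `NA` marks gaps.
#' @param sigma Uncertainty matrix, same shape, positive where observed.
#' @return Dimensionless chi-squared.
#' @export
chi2_pre <- function(Y_calc, Y_exp, sigma) {
  Y_calc <- as.matrix(Y_calc); Y_exp <- as.matrix(Y_exp)
  sigma <- as.matrix(sigma)
  if (!all(dim(Y_calc) == dim(Y_exp)) || !all(dim(Y_exp) == dim(sigma))) {
    stop("Y_calc, Y_exp and sigma must have identical dimensions", call. = FALSE)
  }
  obs <- !is.na(Y_exp)
  if (!any(obs)) stop("no observed entries", call. = FALSE)
  if (any(sigma[obs] <= 0)) stop("sigma must be positive where observed",
                                 call. = FALSE)
  mean(((Y_exp[obs] - Y_calc[obs]) / sigma[obs])^2)
}

#' Autocorrelation at a given lag
#'
#' Normalized autocorrelation function of a scalar series; a constant
#' series has no defined correlation and is refused.
#'
#' @param x Numeric series.
#' @param lag Lag in frames (`0 <= lag < length(x)`).
#' @return Correlation in \[-1, 1\].
#' @export
acf_lag <- function(x, lag) {
  stopifnot(lag >= 0, lag < length(x))
  if (stats::var(x) == 0) {
    stop("autocorrelation undefined for a constant series", call. = FALSE)
  }
  as.numeric(stats::acf(x, lag.max = lag, plot = FALSE,
                        demean = TRUE)$acf[lag + 1])
}

#' Blocking estimate of the standard error of the mean
#'
#' Flyvbjerg-Petersen block transform: the series is repeatedly coarsened
#' by averaging pairs of neighbours; at each level the naive standard error
#' of the mean of the blocked series is computed. For a correlated series
#' these estimates grow with block size and plateau once blocks are longer
#' than the correlation time. The plateau is detected as the first level
#' whose estimate is statistically consistent with the next two levels
#' (within their own sampling uncertainty); if no plateau is found the
#' maximum over levels is returned (conservative).
#'
#' @param x Numeric series (length >= 8).
#' @param details If `TRUE`, return the per-level estimates as well.
#' @return Standard error of the mean (or a list when `details = TRUE`).
#' @export
blocking_error <- function(x, details = FALSE) {
  n <- length(x)
  if (n < 8) stop("series too short for blocking (need >= 8)", call. = FALSE)
  if (stats::var(x) == 0) return(if (details) list(se = 0) else 0)
  est <- c(); unc <- c()
  y <- x
  while (length(y) >= 4) {
    m <- length(y)
    se <- sqrt(stats::var(y) / m)
    est <- c(est, se)
    unc <- c(unc, se / sqrt(2 * (m - 1)))
    if (m %% 2 == 1) y <- y[-m]
    y <- (y[seq(1, length(y), 2)] + y[seq(2, length(y), 2)]) / 2
  }
  k <- length(est)
  pick <- NA_integer_
  for (l in seq_len(max(0, k - 2))) {
    ok <- TRUE
    for (m in (l + 1):(l + 2)) {
      tol <- 2 * sqrt(unc[l]^2 + unc[m]^2)
      if (abs(est[l] - est[m]) > tol) { ok <- FALSE; break }
    }
    if (ok) { pick <- l; break }
  }
  se <- if (is.na(pick)) max(est) else est[pick]
  if (details) list(se = se, levels = est, uncertainty = unc, plateau = pick)
  else se
}
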