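#' @useDynLib cgidp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.CANONICAL_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Path to a packaged data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or vector of file names).
#' @export
cgidp_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "cgidp")))
  }
  path <- system.file("extdata", file, package = "cgidp")
  if (!nzchar(path)) stop("no packaged file '", file, "'", call. = FALSE)
  path
}

#' Construct a residue parameter set
#'
#' A parameter set bundles the per-residue bead parameters (stickiness
#' \eqn{\lambda}, diameter \eqn{\sigma}, formal charge, mass, optional pKa)
#' with the model-level constants: the Ashbaugh-Hatch energy scale
#' \eqn{\epsilon}, the harmonic bond parameters, and the cutoff distances of
#' the nonionic and ionic pair potentials.
#'
#' @param residues Data frame with columns `one_letter`, `lambda`,
#'   `sigma_nm`, `charge`, `mass_Da`, `pKa`; one row per canonical residue.
#' @param name Model identifier, e.g. `"CALVADOS2"` or `"custom"`.
#' @param epsilon Ashbaugh-Hatch energy scale, kJ/mol.
#' @param bond_k Harmonic bond force constant, kJ mol^-1 nm^-2.
#' @param bond_r0 Equilibrium bond length, nm.
#' @param rc_nonionic Cutoff of the nonionic potential, nm.
#' @param rc_ionic Cutoff of the Debye-Hueckel potential, nm.
#' @param termini_charges If `TRUE` (default) the first bead of every chain
#'   receives an extra +1 and the last an extra -1, modelling the ionized
#'   amine/carboxyl termini at neutral pH. Set `FALSE` for the strict
#'   internal-residue-only charge assignment.
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(residues, name = "custom", epsilon = 0.8368,
                          bond_k = 8033, bond_r0 = 0.38,
                          rc_nonionic = 2.0, rc_ionic = 4.0,
                          termini_charges = TRUE) {
  req <- c("one_letter", "lambda", "sigma_nm", "charge", "mass_Da", "pKa")
  missing_cols <- setdiff(req, names(residues))
  if (length(missing_cols)) {
    stop("residue table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  residues <- as.data.frame(residues)[, req]
  missing_aa <- setdiff(.CANONICAL_AA, residues$one_letter)
  if (length(missing_aa)) {
    stop("incomplete residue table; missing: ", paste(missing_aa, collapse = ", "),
         call. = FALSE)
  }
  dup <- residues$one_letter[duplicated(residues$one_letter)]
  if (length(dup)) stop("duplicated residue rows: ", paste(dup, collapse = ", "),
                        call. = FALSE)
  rownames(residues) <- residues$one_letter
  residues <- residues[.CANONICAL_AA, ]
  if (!all(is.finite(residues$lambda)) ||
      any(residues$lambda < -0.2 | residues$lambda > 1.2)) {
    stop("lambda values must be finite and within [-0.2, 1.2]", call. = FALSE)
  }
  if (any(residues$sigma_nm <= 0.2 | residues$sigma_nm >= 1.0)) {
    stop("sigma values must lie in (0.2, 1.0) nm", call. = FALSE)
  }
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  if (rc_ionic <= 0) stop("rc_ionic must be positive", call. = FALSE)
  if (rc_nonionic < 2^(1 / 6) * max(residues$sigma_nm)) {
    stop("rc_nonionic must exceed the largest pair minimum 2^(1/6)*sigma",
         call. = FALSE)
  }
  structure(list(name = name, residues = residues, epsilon = epsilon,
                 bond_k = bond_k, bond_r0 = bond_r0,
                 rc_nonionic = rc_nonionic, rc_ionic = rc_ionic,
                 termini_charges = termini_charges),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>", x$name, "\n")
  cat("  epsilon:", x$epsilon, "kJ/mol; bond k:", x$bond_k,
      "kJ/mol/nm^2; r0:", x$bond_r0, "nm\n")
  cat("  cutoffs: nonionic", x$rc_nonionic, "nm, ionic", x$rc_ionic, "nm;",
      "termini charges:", x$termini_charges, "\n")
  cat("  lambda range: [", round(min(x$residues$lambda), 3), ",",
      round(max(x$residues$lambda), 3), "]\n")
  invisible(x)
}

#' Load a parameter set from a CSV table
#'
#' The file must contain the columns `one_letter`, `lambda`, `sigma_nm`,
#' `charge`, `mass_Da`, `pKa` and all 20 canonical residues; incomplete
#' tables are refused rather than imputed.
#'
#' @param path CSV file path.
#' @param ... Passed to [parameter_set()] (model constants, cutoffs).
#' @return A `parameter_set`.
#' @export
load_parameter_set <- function(path, ...) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  parameter_set(tab, ...)
}

#' @rdname load_parameter_set
#' @param params A `parameter_set` to serialize.
#' @export
write_parameter_set <- function(params, path) {
  stopifnot(inherits(params, "parameter_set"))
  utils::write.csv(params$residues, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged model variants
#'
#' Returns one of the vendored parameter sets. `CALVADOS1` pairs the original
#' stickiness optimization with a 4 nm nonionic cutoff; `CALVADOS2` is the
#' re-optimized scale intended for use with a 2 nm nonionic cutoff. Both use
#' van der Waals bead diameters and a 4 nm electrostatic cutoff.
#'
#' @param name `"CALVADOS1"` or `"CALVADOS2"`.
#' @param ... Overrides passed to [parameter_set()].
#' @return A `parameter_set`.
#' @export
default_parameter_set <- function(name = c("CALVADOS2", "CALVADOS1"), ...) {
  name <- match.arg(name)
  file <- if (name == "CALVADOS1") "calvados1.csv" else "calvados2.csv"
  rc <- if (name == "CALVADOS1") 4.0 else 2.0
  args <- list(...)
  if (is.null(args$rc_nonionic)) args$rc_nonionic <- rc
  do.call(load_parameter_set,
          c(list(path = cgidp_extdata(file), name = name), args))
}

#' Solution conditions
#'
#' @param temperature_K Absolute temperature, K (250-400).
#' @param ionic_strength_M Ionic strength, mol/L (monovalent salt assumed).
#' @param pH Solution pH.
#' @return An object of class `solution_conditions`.
#' @export
solution_conditions <- function(temperature_K, ionic_strength_M, pH = 7.0) {
  if (temperature_K <= 250 || temperature_K >= 400) {
    stop("temperature must lie in (250, 400) K", call. = FALSE)
  }
  if (ionic_strength_M < 0) stop("ionic strength must be >= 0", call. = FALSE)
  if (pH <= 0 || pH >= 14) stop("pH must lie in (0, 14)", call. = FALSE)
  structure(list(temperature_K = temperature_K,
                 ionic_strength_M = ionic_strength_M, pH = pH),
            class = "solution_conditions")
}

#' Protein specification
#'
#' @param name Identifier.
#' @param sequence One-letter amino acid string (canonical alphabet only).
#' @param conditions A [solution_conditions()] object (optional).
#' @return An object of class `protein_spec`.
#' @export
protein_spec <- function(name, sequence, conditions = NULL) {
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(res), .CANONICAL_AA)
  if (length(bad)) {
    stop("non-canonical residue code(s) in '", name, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(conditions)) stopifnot(inherits(conditions, "solution_conditions"))
  structure(list(name = name, sequence = sequence, conditions = conditions),
            class = "protein_spec")
}

#' Read protein specifications from a FASTA file
#'
#' @param path FASTA file.
#' @param conditions Optional [solution_conditions()] applied to every record.
#' @return List of `protein_spec`, in file order.
#' @export
load_sequences <- function(path, conditions = NULL) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  lapply(seq_along(recs), function(i) {
    protein_spec(attr(recs[[i]], "name"), as.character(recs[[i]]), conditions)
  })
}

.check_codes <- function(code, params) {
  bad <- setdiff(unique(code), rownames(params$residues))
  if (length(bad)) {
    stop("unknown residue code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
}

#' Average residue charge at a given pH
#'
#' Aspartate and glutamate carry -1, lysine and arginine +1. Histidine is
#' titratable: its average charge is given by the Henderson-Hasselbalch
#' equation, \eqn{q_H = 1 / (1 + 10^{pH - pKa})}, with pKa = 6. All other
#' residues are neutral.
#'
#' @param code One-letter residue code(s).
#' @param pH Solution pH.
#' @param params A `parameter_set`.
#' @return Charge(s) in elementary-charge units.
#' @export
residue_charge <- function(code, pH, params = default_parameter_set()) {
  stopifnot(pH > 0, pH < 14)
  .check_codes(code, params)
  tab <- params$residues[code, ]
  q <- tab$charge
  tit <- !is.na(tab$pKa)
  q[tit] <- 1 / (1 + 10^(pH - tab$pKa[tit]))
  q
}

#' Mean stickiness of a sequence
#'
#' Arithmetic mean of the per-residue stickiness parameters
#' \eqn{\langle\lambda\rangle} over the chain, a coarse one-number summary
#' of chain hydropathy.
#'
#' @param sequence One-letter string or a `protein_spec`.
#' @param params A `parameter_set`.
#' @return Dimensionless mean \eqn{\langle\lambda\rangle}.
#' @export
mean_hydropathy <- function(sequence, params = default_parameter_set()) {
  if (inherits(sequence, "protein_spec")) sequence <- sequence$sequence
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  res <- strsplit(sequence, "")[[1]]
  .check_codes(res, params)
  mean(params$residues[res, "lambda"])
}

#' Combining rule for pair interaction parameters
#'
#' Bead diameters and stickiness of a residue pair are the arithmetic
#' averages of the single-residue values.
#'
#' @param code_i,code_j One-letter residue codes.
#' @param params A `parameter_set`.
#' @return Named vector `c(sigma_nm =, lambda =)`.
#' @export
pair_params <- function(code_i, code_j, params = default_parameter_set()) {
  .check_codes(c(code_i, code_j), params)
  c(sigma_nm = (params$residues[code_i, "sigma_nm"] +
                  params$residues[code_j, "sigma_nm"]) / 2,
    lambda = (params$residues[code_i, "lambda"] +
                params$residues[code_j, "lambda"]) / 2)
}

#' Chain molecular weight
#'
#' @param sequence One-letter string or `protein_spec`.
#' @param params A `parameter_set`.
#' @return Sum of residue masses, Da.
#' @export
chain_mass <- function(sequence, params = default_parameter_set()) {
  if (inherits(sequence, "protein_spec")) sequence <- sequence$sequence
  res <- strsplit(sequence, "")[[1]]
  .check_codes(res, params)
  sum(params$residues[res, "mass_Da"])
}
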