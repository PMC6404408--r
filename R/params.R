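#' Model parameters for the C-alpha Go-like force field
#'
#' Bundles the force-field constants: harmonic pseudo-bond, bond-angle and
#' dihedral stiffnesses, the uniform native-contact depth \eqn{\epsilon},
#' the non-native repulsion strength and length scale, the heavy-atom
#' van der Waals enlargement factor used by the overlap criterion, and the
#' per-class van der Waals radius table.
#'
#' Internal units are Angstrom for length, kcal/mol for energy, tau for time
#' and \eqn{\epsilon/k_B} for temperature.
#'
#' @param K_r bond stiffness, kcal/mol/A^2.
#' @param K_theta angle stiffness, kcal/mol/rad^2.
#' @param K_phi dihedral stiffness, kcal/mol/rad^2.
#' @param epsilon native-contact Lennard-Jones depth, kcal/mol.
#' @param epsilon_rep non-native repulsion strength, kcal/mol; defaults to
#'   \code{epsilon}.
#' @param r_cut non-native repulsion range, A. The repulsive branch is shifted
#'   so that it vanishes, with zero slope, exactly at \code{r_cut}.
#' @param enlargement multiplicative enlargement of the van der Waals radii in
#'   the overlap criterion (dimensionless).
#' @param radius_table named numeric vector of van der Waals radii (A) keyed by
#'   atom class (see \code{\link{atom_radius}}); must contain a
#'   \code{"default"} entry used as fallback for unlisted heavy atoms.
#' @param temperature_room reduced room temperature, \eqn{\epsilon/k_B}.
#'
#' @return An object of class \code{"model_params"} (a named list).
#' @examples
#' p <- model_params()
#' p$epsilon
#' @export
model_params <- function(K_r = 100, K_theta = 45, K_phi = 5,
                         epsilon = 1.5, epsilon_rep = epsilon,
                         r_cut = 4, enlargement = 1.24,
                         radius_table = tsai_radius_table(),
                         temperature_room = 0.35) {
  vals <- c(K_r = K_r, K_theta = K_theta, K_phi = K_phi, epsilon = epsilon,
            epsilon_rep = epsilon_rep, r_cut = r_cut, enlargement = enlargement)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all model constants must be positive and finite")
  if (!("default" %in% names(radius_table)))
    stop("radius_table must contain a 'default' fallback entry")
  structure(list(K_r = K_r, K_theta = K_theta, K_phi = K_phi,
                 epsilon = epsilon, epsilon_rep = epsilon_rep,
                 r_cut = r_cut, enlargement = enlargement,
                 radius_table = radius_table,
                 temperature_room = temperature_room),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("C-alpha Go-model parameters\n")
  cat(sprintf("  K_r = %g kcal/mol/A^2, K_theta = %g kcal/mol/rad^2, K_phi = %g kcal/mol/rad^2\n",
              x$K_r, x$K_theta, x$K_phi))
  cat(sprintf("  epsilon = %g kcal/mol (epsilon_rep = %g), r_cut = %g A\n",
              x$epsilon, x$epsilon_rep, x$r_cut))
  cat(sprintf("  overlap enlargement = %g, room temperature = %g eps/kB\n",
              x$enlargement, x$temperature_room))
  invisible(x)
}

#' Heavy-atom van der Waals radius table
#'
#' Radii (A) per atom class in the style of the Tsai packing radii commonly
#' used with the overlap criterion: sp3 carbon 1.88, sp2/carbonyl carbon 1.76,
#' aromatic carbon 1.61, nitrogen 1.64, oxygen 1.42, sulfur 1.77, with a
#' documented 1.80 A fallback for anything unclassified.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
tsai_radius_table <- function() {
  c(C_sp3 = 1.88, C_sp2 = 1.76, C_aro = 1.61,
    N = 1.64, O = 1.42, S = 1.77, default = 1.80)
}

# aromatic ring carbons per residue type
.aromatic_atoms <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

# side-chain sp2 carbons (carboxyl / amide / guanidinium)
.sp2_side <- list(
  ASP = "CG", ASN = "CG", GLU = "CD", GLN = "CD", ARG = "CZ")

#' Classify a heavy atom and look up its van der Waals radius
#'
#' @param atom_name PDB atom name (e.g. "CA", "CB", "OD1").
#' @param element chemical element symbol ("C", "N", "O", "S", ...).
#' @param resid three-letter residue name, used to split carbon classes.
#' @param radius_table named radius vector as in \code{\link{tsai_radius_table}}.
#' @param warn_unknown emit a warning when falling back to the default radius.
#' @return Radius in Angstrom.
#' @export
atom_radius <- function(atom_name, element, resid = "",
                        radius_table = tsai_radius_table(),
                        warn_unknown = FALSE) {
  cls <- atom_class(atom_name, element, resid)
  r <- radius_table[cls]
  miss <- is.na(r)
  if (any(miss)) {
    if (warn_unknown)
      warning("no radius for atom class(es) ", paste(unique(cls[miss]), collapse = ", "),
              "; using default ", radius_table["default"], " A")
    r[miss] <- radius_table["default"]
  }
  unname(r)
}

# vectorised atom-class assignment
atom_class <- function(atom_name, element, resid = "") {
  element <- toupper(element)
  atom_name <- toupper(atom_name)
  resid <- toupper(resid)
  cls <- rep("unknown", length(atom_name))
  cls[element == "N"] <- "N"
  cls[element == "O"] <- "O"
  cls[element == "S"] <- "S"
  isC <- element == "C"
  cls[isC] <- "C_sp3"
  cls[isC & atom_name == "C"] <- "C_sp2"   # backbone carbonyl
  for (rs in names(.aromatic_atoms)) {
    hit <- isC & resid == rs & atom_name %in% .aromatic_atoms[[rs]]
    cls[hit] <- "C_aro"
  }
  for (rs in names(.sp2_side)) {
    hit <- isC & resid == rs & atom_name %in% .sp2_side[[rs]]
    cls[hit] <- "C_sp2"
  }
  cls
}

#' Unit conversions between internal and SI-derived mechanical units
#'
#' Internal stress/modulus unit is kcal/(mol A^3); 1 kcal/(mol A^3) =
#' 6.9477 GPa. Reduced temperatures (\eqn{\epsilon/k_B}) convert to Kelvin via
#' \eqn{\epsilon} = 1.5 kcal/mol and \eqn{k_B} = 0.0019872 kcal/mol/K
#' (approximately 754.8 K per reduced unit); the Kelvin mapping is a reporting
#' convenience, not a calibrated thermometer.
#'
#' @param x numeric values to convert.
#' @return Converted numeric vector.
#' @name units
NULL

#' @rdname units
#' @export
kcal_mol_A3_to_gpa <- function(x) x * 6.9477

#' @rdname units
#' @export
gpa_to_kcal_mol_A3 <- function(x) x / 6.9477

#' @rdname units
#' @param epsilon contact energy in kcal/mol.
#' @export
reduced_temperature_to_kelvin <- function(x, epsilon = 1.5) {
  x * epsilon / 0.0019872
}
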