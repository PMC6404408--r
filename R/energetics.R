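#' Potential energy breakdown of a configuration
#'
#' Evaluates the Go-model potential: harmonic pseudo-bond, angle and dihedral
#' terms (the dihedral difference wrapped to (-pi, pi]), the native-contact
#' 12-6 Lennard-Jones term, and the purely repulsive non-native term (the
#' repulsive branch of a Lennard-Jones whose shifted minimum sits exactly at
#' \code{r_cut}, so it is zero with zero slope at and beyond \code{r_cut}).
#' Non-native pairs exclude 1-2, 1-3 and 1-4 bonded neighbours and all native
#' pairs; a pair sharing a native contact is governed solely by its own
#' Lennard-Jones wall.
#'
#' @param positions n x 3 coordinate matrix, A.
#' @param topology a \code{fibril_topology}.
#' @param params a \code{model_params}; defaults to the topology's.
#' @return Named numeric vector of class \code{"energy_breakdown"}: bond,
#'   angle, dihedral, native_lj, nonnative_rep, total (kcal/mol).
#' @export
compute_energy <- function(positions, topology, params = topology$params) {
  positions <- .as_positions(positions, topology$n_beads)
  e <- cg_energy_cpp(positions, .topo_for_cpp(topology), .params_for_cpp(params))
  class(e) <- "energy_breakdown"
  e
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("energy breakdown (kcal/mol):\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Analytic forces of the Go-model potential
#'
#' @inheritParams compute_energy
#' @return n x 3 matrix of forces, kcal/mol/A; \code{-grad E}.
#' @export
compute_forces <- function(positions, topology, params = topology$params) {
  positions <- .as_positions(positions, topology$n_beads)
  cg_forces_cpp(positions, .topo_for_cpp(topology), .params_for_cpp(params))
}

.as_positions <- function(positions, n_beads) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3 || nrow(positions) != n_beads)
    stop("positions must be a ", n_beads, " x 3 matrix")
  if (any(!is.finite(positions))) stop("non-finite positions")
  storage.mode(positions) <- "double"
  positions
}

#' Write per-frame energy breakdowns to CSV
#'
#' Columns: time, bond, angle, dihedral, native_lj, nonnative_rep, total.
#'
#' @param frames list of coordinate matrices.
#' @param times numeric vector of frame times (tau).
#' @param topology a \code{fibril_topology}.
#' @param file output path.
#' @return Invisibly, the path.
#' @export
write_energy_csv <- function(frames, times, topology, file) {
  rows <- t(vapply(frames, function(fr)
    unclass(compute_energy(fr, topology)), numeric(6)))
  df <- data.frame(time = times, rows)
  names(df) <- c("time", "bond", "angle", "dihedral", "native_lj",
                 "nonnative_rep", "total")
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
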