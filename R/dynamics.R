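#' Overdamped Langevin dynamics
#'
#' Integrates the inertialess Langevin equation with the Euler-Maruyama
#' scheme: \eqn{x \leftarrow x + (F/\gamma)\,dt + \sqrt{2 k_B T\, dt/\gamma}\,\xi}
#' with standard-normal \eqn{\xi} per coordinate. Temperature is in reduced
#' units (\eqn{\epsilon/k_B}); \eqn{k_B T = T \epsilon}. Randomness comes from
#' R's RNG, so runs are reproducible under \code{set.seed}. The integrator
#' aborts with an instability error if any bead moves more than 0.5 A in one
#' step.
#'
#' Optional external terms: fixed anchor springs, tether springs whose target
#' points translate at constant velocity, a spherical indenter with a
#' divergent inverse-10th-power tip-bead repulsion, and a repulsive
#' \eqn{z_0^{-10}} base plane acting on all beads.
#'
#' @param positions starting n x 3 coordinates, A.
#' @param topology a \code{fibril_topology}.
#' @param n_steps number of integration steps.
#' @param dt time step, tau (default 0.002; the harmonic pseudo-bonds set the stability limit of the explicit overdamped update near 0.006, so the default keeps a 3x margin).
#' @param temperature reduced temperature, \eqn{\epsilon/k_B}.
#' @param gamma friction per bead, mass/tau (default 2).
#' @param record_every record a frame every this many steps.
#' @param restraints restraint list from \code{\link{restraint_set}}; NULL for
#'   a free run.
#' @param params \code{model_params}; defaults to the topology's.
#' @param t_start time stamp of the first frame, tau.
#' @param rupture_factor abort recording when any pseudo-bond exceeds this
#'   multiple of its native length.
#' @return Object of class \code{"cg_trajectory"}: list with \code{frames}
#'   (list of n x 3 matrices), \code{times}, \code{f_pull} (per-interval mean
#'   tether-spring force vectors), \code{f_tip} (mean tip reaction force along
#'   the approach axis), final \code{positions}, \code{ruptured} flag.
#' @export
run_dynamics <- function(positions, topology, n_steps, dt = 0.002,
                         temperature = 0.35, gamma = 2,
                         record_every = max(1L, n_steps %/% 200L),
                         restraints = NULL, params = topology$params,
                         t_start = 0, rupture_factor = 3) {
  positions <- .as_positions(positions, topology$n_beads)
  if (n_steps < 0) stop("n_steps must be >= 0")
  if (is.null(restraints)) restraints <- list()
  out <- cg_run_cpp(positions, .topo_for_cpp(topology), .params_for_cpp(params),
                    as.integer(n_steps), dt, temperature, gamma,
                    as.integer(max(1L, record_every)), restraints, t_start,
                    0.5, rupture_factor)
  structure(list(frames = out$frames, times = as.numeric(out$times),
                 f_pull = out$f_pull, f_tip = as.numeric(out$f_tip),
                 positions = out$positions, ruptured = out$ruptured,
                 dt = dt, temperature = temperature, gamma = gamma,
                 record_every = record_every),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: %d frames over %.3g tau (T = %g eps/kB%s)\n",
              length(x$frames), max(x$times) - min(x$times), x$temperature,
              if (isTRUE(x$ruptured)) ", RUPTURED" else ""))
  invisible(x)
}

#' Assemble external restraints for the integrator
#'
#' @param anchor_idx bead indices held by stiff springs to fixed points.
#' @param anchor_k anchor stiffness, kcal/mol/A^2.
#' @param anchor_pos matrix of anchor target points; defaults to the beads'
#'   positions in \code{ref_positions}.
#' @param pull_idx bead indices tethered to moving target points.
#' @param pull_k tether stiffness, kcal/mol/A^2.
#' @param pull_vel 3-vector target velocity, A/tau.
#' @param pull_pos0 matrix of tether starting points; defaults to positions in
#'   \code{ref_positions}.
#' @param indenter list(center, vel, R, A): spherical tip with centre starting
#'   at \code{center}, moving at \code{vel} (A/tau), radius \code{R} (A) and
#'   inverse-10 amplitude \code{A} (kcal A^10/mol).
#' @param plane list(z, A): base plane at height z with inverse-10 amplitude A.
#' @param ref_positions reference coordinates supplying default anchor/tether
#'   points.
#' @return Restraint list consumable by \code{\link{run_dynamics}}.
#' @export
restraint_set <- function(anchor_idx = NULL, anchor_k = 100, anchor_pos = NULL,
                          pull_idx = NULL, pull_k = 0.1, pull_vel = c(0, 0, 0),
                          pull_pos0 = NULL, indenter = NULL, plane = NULL,
                          ref_positions = NULL) {
  r <- list()
  if (!is.null(anchor_idx) && length(anchor_idx) > 0) {
    if (is.null(anchor_pos)) {
      stopifnot(!is.null(ref_positions))
      anchor_pos <- ref_positions[anchor_idx, , drop = FALSE]
    }
    if (anchor_k < 0) stop("anchor stiffness must be >= 0")
    r$anchor_idx <- as.integer(anchor_idx)
    r$anchor_k <- anchor_k
    r$anchor_pos <- as.matrix(anchor_pos)
  }
  if (!is.null(pull_idx) && length(pull_idx) > 0) {
    if (is.null(pull_pos0)) {
      stopifnot(!is.null(ref_positions))
      pull_pos0 <- ref_positions[pull_idx, , drop = FALSE]
    }
    if (pull_k < 0) stop("tether stiffness must be >= 0")
    r$pull_idx <- as.integer(pull_idx)
    r$pull_k <- pull_k
    r$pull_pos0 <- as.matrix(pull_pos0)
    r$pull_vel <- as.numeric(pull_vel)
  }
  if (!is.null(indenter)) {
    r$ind_center0 <- as.numeric(indenter$center)
    r$ind_vel <- as.numeric(indenter$vel)
    r$ind_R <- indenter$R
    r$ind_A <- indenter$A
  }
  if (!is.null(plane)) {
    r$plane_z <- plane$z
    r$plane_A <- plane$A
  }
  r
}

#' Default amplitude of the inverse-10 tip/plane repulsion
#'
#' Chosen so the potential equals the room-temperature thermal energy
#' \eqn{k_B T_{room}} at a 1 A gap.
#'
#' @param params a \code{model_params}.
#' @return Amplitude in kcal A^10 / mol.
#' @export
inverse10_amplitude <- function(params = model_params()) {
  params$temperature_room * params$epsilon
}
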