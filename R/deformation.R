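#' Bundle a structure with its Go-model topology
#'
#' @param structure a \code{fibril_structure}.
#' @param params a \code{model_params}.
#' @param frame optional precomputed \code{fibril_frame}.
#' @return Object of class \code{"cg_system"}: list(structure, topology,
#'   frame, params, positions) where positions are the native C-alpha
#'   coordinates.
#' @export
cg_system <- function(structure, params = model_params(), frame = NULL) {
  if (is.null(frame)) frame <- fibril_frame(structure)
  topology <- build_topology(structure, params, frame)
  structure(list(structure = structure, topology = topology, frame = frame,
                 params = params, positions = calpha_coords(structure)),
            class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  print(x$structure)
  print(x$topology)
  invisible(x)
}

# orthonormal frame (axis, t2, t3) with t3 the least-variance direction
# perpendicular to the axis
.lab_frame <- function(positions, axis) {
  axis <- axis / sqrt(sum(axis^2))
  c0 <- sweep(positions, 2, colMeans(positions))
  perp <- c0 - outer(as.numeric(c0 %*% axis), axis)
  ev <- eigen(crossprod(perp) / nrow(perp), symmetric = TRUE)
  t2 <- ev$vectors[, 1]            # widest perpendicular direction
  t2 <- t2 - sum(t2 * axis) * axis
  t2 <- t2 / sqrt(sum(t2^2))
  t3 <- c(axis[2] * t2[3] - axis[3] * t2[2],
          axis[3] * t2[1] - axis[1] * t2[3],
          axis[1] * t2[2] - axis[2] * t2[1])
  list(axis = axis, t2 = t2, t3 = t3)
}

#' Select anchored bead sets for a deformation protocol
#'
#' Tensile: beads within an axial slab of thickness \code{d_anchor} at each
#' fibril end. Shear: the bottom set is a slab of thickness \code{d_anchor} at
#' the low end of the transverse (least-variance perpendicular) direction, and
#' the top set is a configured residue-index segment replicated over every
#' chain not in the bottom set. Indentation: both sets empty (the base plane
#' supports the fibril).
#'
#' @param system a \code{cg_system}.
#' @param mode "tensile", "shear" or "indentation".
#' @param d_anchor slab thickness, A (default 5).
#' @param shear_segment integer vector of residue indices (sequential within
#'   chain) defining the shear plane; required for shear.
#' @return List with integer vectors \code{bottom} and \code{top} (bead
#'   indices), plus the \code{axis} and transverse directions used.
#' @export
select_anchor_sets <- function(system, mode = c("tensile", "shear", "indentation"),
                               d_anchor = 5, shear_segment = NULL) {
  mode <- match.arg(mode)
  pos <- system$positions
  axis <- system$frame$axis
  lf <- .lab_frame(pos, axis)
  res <- system$structure$residues
  if (mode == "tensile") {
    s <- as.numeric(pos %*% lf$axis)
    lo <- min(s); hi <- max(s)
    if (d_anchor >= (hi - lo) / 2)
      stop("anchor slab thickness ", d_anchor,
           " A too large for fibril extent ", round(hi - lo, 2), " A")
    bottom <- which(s <= lo + d_anchor)
    top <- which(s >= hi - d_anchor)
  } else if (mode == "shear") {
    if (is.null(shear_segment)) stop("shear mode requires shear_segment")
    tproj <- as.numeric(pos %*% lf$t3)
    lo <- min(tproj); hi <- max(tproj)
    if (d_anchor >= (hi - lo))
      stop("anchor slab thickness too large for fibril height")
    bottom <- which(tproj <= lo + d_anchor)
    top <- setdiff(which(res$ridx %in% shear_segment), bottom)
  } else {
    bottom <- integer(0); top <- integer(0)
  }
  if (mode != "indentation" && (length(bottom) == 0 || length(top) == 0))
    stop("empty anchor set for mode ", mode)
  list(bottom = bottom, top = top,
       axis = lf$axis, t2 = lf$t2, t3 = lf$t3)
}

# assemble the deformation_record object
.make_record <- function(protocol, series, metadata) {
  stopifnot(all(diff(series$time) > 0))
  structure(list(protocol = protocol, series = series, metadata = metadata),
            class = "deformation_record")
}

#' @export
print.deformation_record <- function(x, ...) {
  s <- x$series
  cat(sprintf("deformation_record [%s]: %d frames, control 0..%.3g A%s\n",
              x$protocol, nrow(s), max(s$control),
              if (isTRUE(x$metadata$ruptured)) ", RUPTURED" else ""))
  invisible(x)
}

#' @export
plot.deformation_record <- function(x, ...) {
  s <- x$series
  if (x$protocol == "indentation") {
    ok <- !is.na(s$h)
    graphics::plot(s$h[ok], s$force[ok], xlab = "indentation depth h (A)",
                   ylab = "force (kcal/mol/A)", type = "l", ...)
  } else {
    graphics::plot(s$strain, s$force, xlab = "strain",
                   ylab = "spring force (kcal/mol/A)", type = "l", ...)
  }
  invisible(x)
}

# run production in chunks, stopping on a predicate of the latest series rows
.chunked_pull <- function(positions, topology, restr, v_vec, dt, temperature,
                          gamma, record_every, chunk_steps, max_steps,
                          stop_fun, t0 = 0) {
  frames <- list(); times <- numeric(0); fpull <- NULL
  done <- 0
  pos <- positions
  ruptured <- FALSE
  while (done < max_steps) {
    nst <- min(chunk_steps, max_steps - done)
    tr <- run_dynamics(pos, topology, nst, dt = dt, temperature = temperature,
                       gamma = gamma, record_every = record_every,
                       restraints = restr, t_start = t0 + done * dt)
    sel <- if (length(frames) > 0) -1L else TRUE  # drop repeated first frame
    frames <- c(frames, tr$frames[sel])
    times <- c(times, tr$times[sel])
    fpull <- rbind(fpull, tr$f_pull[sel, , drop = FALSE])
    pos <- tr$positions
    done <- done + nst
    if (!is.null(restr$pull_idx))
      restr$pull_pos0 <- restr$pull_pos0 +
        matrix(v_vec * (nst * dt), nrow(restr$pull_pos0), 3, byrow = TRUE)
    if (isTRUE(tr$ruptured)) { ruptured <- TRUE; break }
    if (stop_fun(frames, times)) break
  }
  list(frames = frames, times = times, f_pull = fpull, positions = pos,
       ruptured = ruptured)
}

#' Constant-speed tensile deformation
#'
#' The bottom anchor beads are held by stiff springs at their equilibrated
#' positions; each top bead is tethered to a target point that translates
#' along the fibril axis at \code{v_pull}. The record stores the
#' interval-averaged total tether force projected on the axis, the strain
#' \eqn{(L - L_0)/L_0} measured from the axial distance between the top and
#' bottom anchor-set centroids (with \eqn{L_0} taken after equilibration),
#' and the convex-hull cross-section area per frame.
#'
#' @param system a \code{cg_system}.
#' @param v_pull pulling speed, A/tau.
#' @param k_bottom,k_top anchor and tether stiffness, kcal/mol/A^2.
#' @param max_strain stop once this strain is reached (in (0, 0.2]).
#' @param temperature reduced temperature (default: room, 0.35).
#' @param dt,gamma integrator settings.
#' @param d_anchor anchor slab thickness, A.
#' @param t_equil equilibration time before the pull, tau.
#' @param record_every recording stride in steps.
#' @param max_time hard cap on production time, tau.
#' @param seed RNG seed.
#' @return A \code{deformation_record} with protocol "tensile".
#' @export
run_tensile <- function(system, v_pull = 0.0005, k_bottom = 100, k_top = 0.1,
                        max_strain = 0.05, temperature = system$params$temperature_room,
                        dt = 0.002, gamma = 2, d_anchor = 5, t_equil = 100,
                        record_every = 400, max_time = Inf, seed = NULL) {
  if (max_strain <= 0 || max_strain > 0.2) stop("max_strain must be in (0, 0.2]")
  if (!is.null(seed)) set.seed(seed)
  sets <- select_anchor_sets(system, "tensile", d_anchor)
  axis <- sets$axis
  topo <- system$topology
  pos0 <- system$positions

  # equilibrate with the protocol springs at zero speed
  restr0 <- restraint_set(anchor_idx = sets$bottom, anchor_k = k_bottom,
                          pull_idx = sets$top, pull_k = k_top,
                          pull_vel = c(0, 0, 0), ref_positions = pos0)
  eq <- run_dynamics(pos0, topo, round(t_equil / dt), dt = dt,
                     temperature = temperature, gamma = gamma,
                     record_every = max(1L, round(t_equil / dt / 20)),
                     restraints = restr0)
  pos_eq <- eq$positions
  axlen <- function(p) mean(p[sets$top, , drop = FALSE] %*% axis) -
    mean(p[sets$bottom, , drop = FALSE] %*% axis)
  nf <- length(eq$frames)
  L0 <- mean(vapply(eq$frames[seq(ceiling(nf / 2), nf)], axlen, numeric(1)))

  v_vec <- v_pull * axis
  restr <- restraint_set(anchor_idx = sets$bottom, anchor_k = k_bottom,
                         anchor_pos = restr0$anchor_pos,
                         pull_idx = sets$top, pull_k = k_top,
                         pull_vel = v_vec, pull_pos0 = restr0$pull_pos0)
  stop_fun <- function(frames, times) {
    (axlen(frames[[length(frames)]]) - L0) / L0 >= max_strain
  }
  # generous cap: tether travel for a rigid rod plus soft-spring stretch
  max_steps <- if (is.finite(max_time)) round(max_time / dt) else
    round((max_strain * L0 * 50 + 100) / v_pull / dt)
  out <- .chunked_pull(pos_eq, topo, restr, v_vec, dt, temperature, gamma,
                       record_every, chunk_steps = 20 * record_every,
                       max_steps = max_steps, stop_fun = stop_fun)

  strain <- vapply(out$frames, function(f) (axlen(f) - L0) / L0, numeric(1))
  area <- vapply(out$frames, function(f)
    tryCatch(cross_section_area(f, axis), error = function(e) NA_real_),
    numeric(1))
  force <- as.numeric(out$f_pull %*% axis)
  series <- data.frame(time = out$times, control = v_pull * out$times,
                       force = force, strain = strain, area = area)
  .make_record("tensile", series,
               list(v_pull = v_pull, k_top = k_top, k_bottom = k_bottom,
                    L0 = L0, axis = axis, temperature = temperature,
                    dt = dt, gamma = gamma,
                    bottom = sets$bottom, top = sets$top,
                    n_top = length(sets$top), ruptured = out$ruptured,
                    frames = out$frames))
}

#' Constant-speed shear deformation
#'
#' Bottom-plane beads (a transverse slab) are held by stiff springs; the
#' configured residue segment on every chain is tethered by soft springs whose
#' targets translate along the fibril axis, shearing the fibril. Strain is
#' \eqn{x/y}: the measured axial displacement of the top-plane centroid over
#' the transverse distance between the plane centroids. Stress uses the
#' convex-hull area of the top-plane beads projected on the plane spanned by
#' the axis and the widest perpendicular direction.
#'
#' @inheritParams run_tensile
#' @param shear_segment residue indices (within-chain, sequential) defining
#'   the sheared top plane.
#' @return A \code{deformation_record} with protocol "shear".
#' @export
run_shear <- function(system, shear_segment, v_pull = 0.0005, k_bottom = 100,
                      k_top = 0.1, max_strain = 0.05,
                      temperature = system$params$temperature_room,
                      dt = 0.002, gamma = 2, d_anchor = 5, t_equil = 100,
                      record_every = 400, max_time = Inf, seed = NULL) {
  if (max_strain <= 0 || max_strain > 0.2) stop("max_strain must be in (0, 0.2]")
  if (!is.null(seed)) set.seed(seed)
  sets <- select_anchor_sets(system, "shear", d_anchor, shear_segment)
  axis <- sets$axis; tdir <- sets$t3
  topo <- system$topology
  pos0 <- system$positions

  restr0 <- restraint_set(anchor_idx = sets$bottom, anchor_k = k_bottom,
                          pull_idx = sets$top, pull_k = k_top,
                          pull_vel = c(0, 0, 0), ref_positions = pos0)
  eq <- run_dynamics(pos0, topo, round(t_equil / dt), dt = dt,
                     temperature = temperature, gamma = gamma,
                     record_every = max(1L, round(t_equil / dt / 20)),
                     restraints = restr0)
  pos_eq <- eq$positions
  topc <- function(p) mean(p[sets$top, , drop = FALSE] %*% axis)
  x0 <- topc(pos_eq)
  height <- abs(mean(pos_eq[sets$top, , drop = FALSE] %*% tdir) -
                mean(pos_eq[sets$bottom, , drop = FALSE] %*% tdir))

  v_vec <- v_pull * axis
  restr <- restraint_set(anchor_idx = sets$bottom, anchor_k = k_bottom,
                         anchor_pos = restr0$anchor_pos,
                         pull_idx = sets$top, pull_k = k_top,
                         pull_vel = v_vec, pull_pos0 = restr0$pull_pos0)
  stop_fun <- function(frames, times)
    (topc(frames[[length(frames)]]) - x0) / height >= max_strain
  max_steps <- if (is.finite(max_time)) round(max_time / dt) else
    round((max_strain * height * 50 + 100) / v_pull / dt)
  out <- .chunked_pull(pos_eq, topo, restr, v_vec, dt, temperature, gamma,
                       record_every, chunk_steps = 20 * record_every,
                       max_steps = max_steps, stop_fun = stop_fun)

  # top-plane area projected on the (axis, widest-perpendicular) plane
  plane_area <- function(f) {
    pts <- f[sets$top, , drop = FALSE]
    .hull_area(cbind(pts %*% axis, pts %*% sets$t2))
  }
  strain <- vapply(out$frames, function(f) (topc(f) - x0) / height, numeric(1))
  area <- vapply(out$frames, plane_area, numeric(1))
  force <- as.numeric(out$f_pull %*% axis)
  series <- data.frame(time = out$times, control = v_pull * out$times,
                       force = force, strain = strain, area = area)
  .make_record("shear", series,
               list(v_pull = v_pull, k_top = k_top, k_bottom = k_bottom,
                    height = height, axis = axis, tdir = tdir,
                    temperature = temperature, dt = dt, gamma = gamma,
                    bottom = sets$bottom, top = sets$top,
                    shear_segment = shear_segment, ruptured = out$ruptured,
                    frames = out$frames))
}

#' Constant-speed spherical nanoindentation
#'
#' The fibril is rotated so its axis lies along lab x and its least-variance
#' perpendicular direction along lab z, then rested on a repulsive
#' \eqn{z_0^{-10}} base plane. A rigid sphere of radius \code{R_ind} descends
#' along -z above the axial position \code{position_fraction * L0} with speed
#' \code{v_ind}; a divergent inverse-10th-power tip-bead interaction prevents
#' adhesion. The indentation depth \eqn{h} is measured from the first
#' tip-particle interaction (interval-mean tip force above
#' \code{contact_threshold}).
#'
#' @param system a \code{cg_system}.
#' @param R_ind tip radius, A (default 100 A = 10 nm).
#' @param v_ind descent speed, A/tau.
#' @param position_fraction axial position of the tip as a fraction of the
#'   fibril length.
#' @param max_depth stop after this indentation depth, A.
#' @param temperature,dt,gamma integrator settings.
#' @param t_equil resting time on the base plane before descent, tau.
#' @param record_every recording stride in steps.
#' @param start_gap initial clearance between tip surface and the highest
#'   bead, A.
#' @param contact_threshold tip force (kcal/mol/A) defining first contact.
#' @param seed RNG seed.
#' @return A \code{deformation_record} with protocol "indentation"; the series
#'   has columns time, control (descent), force and h (NA before contact).
#' @export
run_indentation <- function(system, R_ind = 100, v_ind = 0.005,
                            position_fraction = 0.5, max_depth = 3,
                            temperature = system$params$temperature_room,
                            dt = 0.002, gamma = 2, t_equil = 50,
                            record_every = 200, start_gap = 2,
                            contact_threshold = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  topo <- system$topology
  pos <- system$positions
  lf <- .lab_frame(pos, system$frame$axis)
  Q <- rbind(lf$axis, lf$t2, lf$t3)          # rows: new basis in old coords
  posr <- sweep(pos, 2, colMeans(pos)) %*% t(Q)

  A_amp <- inverse10_amplitude(system$params)
  z_plane <- min(posr[, 3]) - 1.0
  restr_eq <- restraint_set(plane = list(z = z_plane, A = A_amp))
  eq <- run_dynamics(posr, topo, round(t_equil / dt), dt = dt,
                     temperature = temperature, gamma = gamma,
                     record_every = max(1L, round(t_equil / dt / 10)),
                     restraints = restr_eq)
  posr <- eq$positions

  xs <- posr[, 1]
  L0 <- max(xs) - min(xs)
  tip_x <- min(xs) + position_fraction * L0
  tip_y <- mean(posr[, 2])
  near <- abs(posr[, 1] - tip_x) < max(6, 0.15 * L0)
  z_top <- max(posr[near, 3])
  tip_z0 <- z_top + R_ind + start_gap
  if (any(sqrt((posr[, 1] - tip_x)^2 + (posr[, 2] - tip_y)^2 +
               (posr[, 3] - tip_z0)^2) < R_ind))
    stop("indenter initially overlaps the fibril")

  restr <- restraint_set(plane = list(z = z_plane, A = A_amp),
                         indenter = list(center = c(tip_x, tip_y, tip_z0),
                                         vel = c(0, 0, -v_ind),
                                         R = R_ind, A = A_amp))
  frames <- list(); times <- numeric(0); ftip <- numeric(0)
  done <- 0
  chunk <- 20 * record_every
  travel_max <- start_gap + max_depth + 4   # descent budget, A
  max_steps <- round(travel_max / v_ind / dt)
  p <- posr
  ruptured <- FALSE
  contact_z <- NA_real_
  while (done < max_steps) {
    nst <- min(chunk, max_steps - done)
    tr <- run_dynamics(p, topo, nst, dt = dt, temperature = temperature,
                       gamma = gamma, record_every = record_every,
                       restraints = restr, t_start = done * dt)
    sel <- if (length(frames) > 0) -1L else TRUE
    frames <- c(frames, tr$frames[sel])
    times <- c(times, tr$times[sel])
    ftip <- c(ftip, tr$f_tip[sel])
    p <- tr$positions
    done <- done + nst
    restr$ind_center0 <- restr$ind_center0 + c(0, 0, -v_ind) * nst * dt
    if (isTRUE(tr$ruptured)) { ruptured <- TRUE; break }
    tip_z <- tip_z0 - v_ind * times[length(times)]
    if (is.na(contact_z)) {
      ic <- which(ftip > contact_threshold)[1]
      if (!is.na(ic)) contact_z <- tip_z0 - v_ind * times[ic]
    }
    if (!is.na(contact_z) && (contact_z - tip_z) >= max_depth) break
  }
  if (is.na(contact_z)) {
    ic <- which(ftip > contact_threshold)[1]
    if (!is.na(ic)) contact_z <- tip_z0 - v_ind * times[ic]
  }
  control <- v_ind * times
  ic <- which(ftip > contact_threshold)[1]
  if (is.na(ic)) {
    h <- rep(NA_real_, length(times))
  } else {
    h <- control - control[ic]
    if (ic > 1) h[seq_len(ic - 1)] <- NA_real_
  }
  series <- data.frame(time = times, control = control, force = ftip, h = h)
  .make_record("indentation", series,
               list(v_ind = v_ind, R_ind = R_ind,
                    position_fraction = position_fraction,
                    L0 = L0, z_plane = z_plane, tip_x = tip_x, tip_y = tip_y,
                    tip_z0 = tip_z0, contact_z = contact_z, A = A_amp,
                    temperature = temperature, dt = dt, gamma = gamma,
                    ruptured = ruptured, frames = frames))
}
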