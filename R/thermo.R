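#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation of \code{moving} onto \code{reference}
#' via the SVD construction; returns the transformed coordinates. The global
#' minimum of the squared deviation over rigid motions is attained.
#'
#' @param moving,reference n x 3 coordinate matrices.
#' @return Superposed copy of \code{moving}.
#' @export
superpose <- function(moving, reference) {
  moving <- as.matrix(moving); reference <- as.matrix(reference)
  if (!all(dim(moving) == dim(reference))) stop("mismatched bead counts")
  cm <- colMeans(moving); cr <- colMeans(reference)
  P <- sweep(moving, 2, cm); Q <- sweep(reference, 2, cr)
  s <- svd(crossprod(P, Q))        # 3x3, H = P^T Q
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(P %*% t(R), 2, cr, "+")
}

#' Root-mean-square deviation after optimal superposition
#'
#' \deqn{RMSD = \sqrt{\frac{1}{N}\sum_i |r_i - r_i^{nat}|^2}} computed after
#' superimposing the structure on the reference by the optimal rigid motion.
#'
#' @param positions,reference n x 3 coordinate matrices (n >= 3).
#' @param fit superpose first (default TRUE).
#' @return RMSD in A.
#' @export
rmsd <- function(positions, reference, fit = TRUE) {
  positions <- as.matrix(positions); reference <- as.matrix(reference)
  if (!all(dim(positions) == dim(reference))) stop("mismatched bead counts")
  if (nrow(positions) < 3) stop("need at least 3 beads")
  if (fit) positions <- superpose(positions, reference)
  sqrt(mean(rowSums((positions - reference)^2)))
}

#' Per-residue root-mean-square fluctuation
#'
#' Each frame is superposed on the reference; the RMSF of residue i is
#' \eqn{\sqrt{\langle |r_i - \langle r_i\rangle|^2 \rangle}} over frames.
#'
#' @param frames list of n x 3 coordinate matrices (>= 2).
#' @param reference native coordinates used for superposition.
#' @return Numeric vector of per-residue RMSF, A.
#' @export
rmsf <- function(frames, reference) {
  if (length(frames) < 2) stop("need at least 2 frames for RMSF")
  sup <- lapply(frames, superpose, reference = reference)
  n <- nrow(reference)
  arr <- array(unlist(sup), dim = c(n, 3, length(sup)))
  mu <- apply(arr, c(1, 2), mean)
  sqrt(rowMeans(apply(arr, 3, function(f) rowSums((f - mu)^2))))
}

#' Probability of residing in the native state
#'
#' Under the default contact criterion a frame is native iff every native
#' contact is formed, i.e. its instantaneous length is below
#' \code{formed_factor} times its native length. The alternative RMSD
#' criterion calls a frame native when its superposed RMSD from the
#' reference stays below \code{rmsd_max}. P0 is the fraction of native
#' frames; outputs of the scan pipeline are labelled with the criterion
#' used.
#'
#' @param frames list of coordinate matrices (production frames only).
#' @param contacts contact data.frame (columns i, j, r0) or a
#'   \code{fibril_topology}.
#' @param formed_factor formed-contact threshold factor (default 1.5).
#' @param criterion "contacts" (default) or "rmsd".
#' @param reference native coordinates (required for the RMSD criterion).
#' @param rmsd_max RMSD threshold, A (RMSD criterion only).
#' @return P0 in [0, 1].
#' @export
native_state_probability <- function(frames, contacts, formed_factor = 1.5,
                                     criterion = c("contacts", "rmsd"),
                                     reference = NULL, rmsd_max = 3) {
  criterion <- match.arg(criterion)
  if (length(frames) == 0) stop("no frames")
  if (criterion == "rmsd") {
    if (is.null(reference)) stop("RMSD criterion requires a reference")
    return(mean(vapply(frames, function(f)
      rmsd(f, reference) < rmsd_max, logical(1))))
  }
  if (inherits(contacts, "fibril_topology")) contacts <- contacts$contacts
  if (nrow(contacts) == 0) return(1)
  thr <- formed_factor * contacts$r0
  native <- vapply(frames, function(f) {
    d <- sqrt(rowSums((f[contacts$i, , drop = FALSE] -
                       f[contacts$j, , drop = FALSE])^2))
    all(d < thr)
  }, logical(1))
  mean(native)
}

#' Temperature scan of native-state stability
#'
#' For each temperature, runs equilibration then production overdamped
#' Langevin dynamics and computes P0, mean RMSD from the native structure and
#' the per-residue RMSF. Defaults mirror the full protocol (35 temperatures
#' uniform in 0.1-0.7 eps/kB, 1e3 tau equilibration, 1e4 tau production); all
#' are scalable for desk runs.
#'
#' @param system a \code{cg_system}.
#' @param T_grid increasing reduced temperatures.
#' @param t_equil,t_prod equilibration / production time, tau.
#' @param dt,gamma integrator settings.
#' @param record_every recording stride (steps).
#' @param replicas independent replicas per temperature (averaged).
#' @param seed base RNG seed; replica r at temperature index k uses
#'   \code{seed + 1000*k + r}.
#' @param formed_factor native-contact threshold factor for P0.
#' @return Object of class \code{"thermo_scan"}: list with \code{table}
#'   (data.frame: temperature, P0, mean_rmsd), \code{rmsf} (T x residue
#'   matrix), and settings.
#' @export
temperature_scan <- function(system, T_grid = seq(0.1, 0.7, length.out = 35),
                             t_equil = 1000, t_prod = 10000,
                             dt = 0.002, gamma = 2, record_every = 200,
                             replicas = 1, seed = 1, formed_factor = 1.5) {
  if (is.unsorted(T_grid, strictly = TRUE)) stop("T_grid must be strictly increasing")
  topo <- system$topology
  ref <- system$positions
  nT <- length(T_grid)
  P0 <- rmsd_mean <- numeric(nT)
  rmsf_mat <- matrix(NA_real_, nT, nrow(ref))
  for (k in seq_len(nT)) {
    Tk <- T_grid[k]
    # typical repulsive-wall forces grow with k_B T (beads penetrate until the
    # wall energy reaches ~k_B T), so the step shrinks above T = 0.5 to keep
    # the per-step displacement distribution comparable across the scan
    dt_k <- dt * min(1, 0.5 / Tk)
    p0s <- rms <- numeric(replicas)
    rfs <- matrix(0, replicas, nrow(ref))
    for (r in seq_len(replicas)) {
      # rare wall-escape events can trip the 0.5 A per-step guard; the error
      # advises a smaller step, so the replica is retried at dt/2 (twice)
      # before the failure propagates, tagged with its temperature
      frames <- NULL
      dt_try <- dt_k
      for (attempt in 1:3) {
        set.seed(seed + 1000L * k + r)
        frames <- tryCatch({
          eq <- run_dynamics(ref, topo, round(t_equil / dt_try), dt = dt_try,
                             temperature = Tk, gamma = gamma,
                             record_every = max(1L, round(t_equil / dt_try)))
          pr <- run_dynamics(eq$positions, topo, round(t_prod / dt_try),
                             dt = dt_try, temperature = Tk, gamma = gamma,
                             record_every = max(1L, round(record_every * dt_k / dt_try)),
                             t_start = t_equil)
          pr$frames[-1]          # production frames only
        }, error = function(e) {
          if (attempt < 3 && grepl("unstable", conditionMessage(e))) NULL
          else stop("at T = ", Tk, ": ", conditionMessage(e))
        })
        if (!is.null(frames)) break
        dt_try <- dt_try / 2
      }
      p0s[r] <- native_state_probability(frames, topo, formed_factor)
      rms[r] <- mean(vapply(frames, rmsd, numeric(1), reference = ref))
      rfs[r, ] <- rmsf(frames, ref)
    }
    P0[k] <- mean(p0s)
    rmsd_mean[k] <- mean(rms)
    rmsf_mat[k, ] <- colMeans(rfs)
  }
  structure(list(table = data.frame(temperature = T_grid, P0 = P0,
                                    mean_rmsd = rmsd_mean),
                 rmsf = rmsf_mat,
                 settings = list(t_equil = t_equil, t_prod = t_prod, dt = dt,
                                 gamma = gamma, replicas = replicas,
                                 seed = seed, formed_factor = formed_factor)),
            class = "thermo_scan")
}

#' @export
print.thermo_scan <- function(x, ...) {
  cat(sprintf("thermo_scan: %d temperatures in [%.3g, %.3g] eps/kB\n",
              nrow(x$table), min(x$table$temperature), max(x$table$temperature)))
  print(utils::head(x$table, 10))
  invisible(x)
}

#' @export
plot.thermo_scan <- function(x, ...) {
  graphics::plot(x$table$temperature, x$table$P0, type = "b",
                 xlab = "T (eps/kB)", ylab = "P0", ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}

#' Folding temperature from a P0(T) curve
#'
#' The temperature at which P0 crosses 1/2, by linear interpolation between
#' the bracketing grid points. With several crossings the lowest-temperature
#' one is returned with a warning.
#'
#' @param scan a \code{thermo_scan}, or a data.frame with columns
#'   \code{temperature} and \code{P0}.
#' @return Tf in eps/kB.
#' @export
folding_temperature <- function(scan) {
  tab <- if (inherits(scan, "thermo_scan")) scan$table else scan
  Tg <- tab$temperature; P <- tab$P0
  s <- P - 0.5
  hit <- which(s == 0)
  cross <- which(s[-length(s)] * s[-1] < 0)
  cand <- sort(c(Tg[hit],
                 vapply(cross, function(i)
                   Tg[i] + (0.5 - P[i]) * (Tg[i + 1] - Tg[i]) / (P[i + 1] - P[i]),
                   numeric(1))))
  if (length(cand) == 0)
    stop("P0 does not cross 1/2 on the grid; widen the temperature range")
  if (length(cand) > 1)
    warning("multiple P0 = 1/2 crossings; reporting the lowest temperature")
  cand[1]
}
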