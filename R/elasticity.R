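# 2-D convex hull area (shoelace over grDevices::chull vertices)
.hull_area <- function(pts) {
  pts <- unique(pts[stats::complete.cases(pts), , drop = FALSE])
  if (nrow(pts) < 3) stop("need at least 3 distinct points for a hull area")
  hid <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(hid) < 3) stop("degenerate (collinear) point set")
  xs <- pts[hid, 1]; ys <- pts[hid, 2]
  a <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  if (a < 1e-9) stop("degenerate (collinear) point set")
  a
}

#' Convex-hull cross-section area perpendicular to the fibril axis
#'
#' Projects the bead positions on the plane perpendicular to the axis and
#' returns the area of the smallest convex polygon containing the projected
#' points.
#'
#' @param positions n x 3 coordinate matrix, A.
#' @param axis fibril axis (3-vector, need not be unit).
#' @return Area in A^2.
#' @export
cross_section_area <- function(positions, axis) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 3) stop("need at least 3 points")
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal in-plane basis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  .hull_area(cbind(positions %*% u, positions %*% v))
}

#' Stress-strain curve from a deformation record
#'
#' Stress is the total tether-spring force divided by the cross-section area:
#' either the record-mean area (default, matching the use of the average
#' monitored area) or the per-frame area.
#'
#' @param record a tensile or shear \code{deformation_record}.
#' @param area_mode "mean" or "frame".
#' @param area optional externally supplied area (A^2) overriding the
#'   monitored one.
#' @return data.frame with columns strain, stress (kcal/mol/A^3), time.
#' @export
stress_strain <- function(record, area_mode = c("mean", "frame"), area = NULL) {
  area_mode <- match.arg(area_mode)
  if (!record$protocol %in% c("tensile", "shear"))
    stop("record must be tensile or shear")
  s <- record$series
  A <- if (!is.null(area)) rep(area, nrow(s))
       else if (area_mode == "mean") rep(mean(s$area, na.rm = TRUE), nrow(s))
       else s$area
  if (any(!is.finite(A)) || any(A <= 0))
    stop("cross-section area unavailable or non-positive; supply `area`")
  data.frame(strain = s$strain, stress = s$force / A, time = s$time)
}

# average a noisy (x, y) scatter into equal-count bins ordered by x; thermal
# fluctuations in the measured strain average out before any slope is taken
.bin_curve <- function(x, y, n_bins = 25) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  n <- length(x)
  if (n <= 2 * n_bins) return(data.frame(x = x, y = y))
  grp <- ceiling(seq_len(n) / (n / n_bins))
  data.frame(x = tapply(x, grp, mean), y = tapply(y, grp, mean))
}

# largest initial window (ordered by abscissa) with linear-fit R^2 >= r2_min;
# returns the x upper bound of the window
.auto_window <- function(x, y, min_pts = 5, r2_min = 0.99) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  n <- length(x)
  if (n < min_pts) stop("fewer than ", min_pts, " points for fitting")
  best <- NA_integer_
  for (m in seq(min_pts, n)) {
    fit <- stats::lm(y[1:m] ~ x[1:m])
    r2 <- summary(fit)$r.squared
    if (!is.finite(r2) || r2 >= r2_min) best <- m
  }
  # nothing met the threshold (noise-dominated start): keep the full range --
  # the deformation protocols already stop within the linear regime, and the
  # R^2 of the final fit still flags a genuinely poor window
  if (is.na(best)) best <- n
  x[best]
}

#' Fit an elastic modulus from the linear regime of a stress-strain curve
#'
#' Least-squares slope over the chosen strain window, converted to GPa via
#' 1 kcal/(mol A^3) = 6.9477 GPa. When no window is given, the largest
#' initial window (anchored at the smallest strains) with R^2 >= 0.99 is
#' used. A window R^2 below 0.9 attaches a poor-fit warning.
#'
#' @param curve data.frame with columns strain and stress (internal units), as
#'   from \code{\link{stress_strain}}.
#' @param kind label: "Y_L" (tensile) or "S" (shear).
#' @param window optional numeric length-2 strain interval.
#' @param replicas optional list of curves from independent replicas; when
#'   given, the fit uses the replica-mean curve and the standard error comes
#'   from bootstrap over replicas.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed seed for the bootstrap.
#' @return Object of class \code{"modulus_estimate"}.
#' @export
fit_linear_modulus <- function(curve, kind = "Y_L", window = NULL,
                               replicas = NULL, n_boot = 1000, seed = 1) {
  if (!is.null(replicas) && length(replicas) > 1) {
    curve <- do.call(rbind, lapply(replicas, function(r)
      data.frame(strain = r$strain, stress = r$stress)))
  }
  fitted <- .fit_window_slope(curve$strain, curve$stress, window)
  poor <- FALSE
  if (!is.finite(fitted$r2) || fitted$r2 < 0.9) {
    warning("poor linear fit (R^2 = ", round(fitted$r2, 3), ") in chosen window")
    poor <- TRUE
  }
  nrep <- if (is.null(replicas)) 1L else length(replicas)
  se <- fitted$se
  if (!is.null(replicas) && length(replicas) > 1) {
    se <- .boot_slope_se(replicas, fitted$window, n_boot, seed)
  }
  structure(list(kind = kind, value = kcal_mol_A3_to_gpa(fitted$slope),
                 stderr = kcal_mol_A3_to_gpa(se),
                 slope_internal = fitted$slope,
                 fit_window = fitted$window, n_points = fitted$n,
                 r_squared = fitted$r2, poor_fit = poor, replicas_used = nrep,
                 exponent_n = NA_real_),
            class = "modulus_estimate")
}

# bin, pick the window (given or auto), fit the slope on the binned curve
.fit_window_slope <- function(x, y, window = NULL) {
  b <- .bin_curve(x, y)
  if (is.null(window)) window <- c(min(b$x), .auto_window(b$x, b$y))
  sel <- b$x >= window[1] & b$x <= window[2]
  if (sum(sel) < 5) stop("fewer than 5 points in fit window")
  fit <- stats::lm(y ~ x, b[sel, ])
  list(slope = unname(stats::coef(fit)[2]),
       se = unname(summary(fit)$coefficients[2, 2]),
       r2 = summary(fit)$r.squared, window = range(b$x[sel]), n = sum(sel))
}

.boot_slope_se <- function(replicas, window, n_boot, seed) {
  slopes <- .with_preserved_rng(seed, {
    vapply(seq_len(n_boot), function(b) {
      pick <- sample(length(replicas), replace = TRUE)
      pooled <- do.call(rbind, lapply(replicas[pick], function(r)
        data.frame(strain = r$strain, stress = r$stress)))
      out <- tryCatch(.fit_window_slope(pooled$strain, pooled$stress, window),
                      error = function(e) NULL)
      if (is.null(out)) NA_real_ else out$slope
    }, numeric(1))
  })
  stats::sd(slopes, na.rm = TRUE)
}

#' @export
print.modulus_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4g GPa (stderr %.3g, window [%.4g, %.4g], R^2 = %.4f)\n",
              x$kind, x$value, x$stderr, x$fit_window[1], x$fit_window[2],
              x$r_squared))
  if (is.finite(x$exponent_n))
    cat(sprintf("  free depth exponent n = %.3f\n", x$exponent_n))
  invisible(x)
}

#' @export
coef.modulus_estimate <- function(object, ...) {
  c(value_gpa = object$value, stderr_gpa = object$stderr,
    exponent_n = object$exponent_n)
}

#' Hertzian fit of an indentation force-depth curve
#'
#' Fits the non-adhesive sphere-on-half-space relation
#' \deqn{F = \frac{4}{3}\,\frac{Y_T}{1-\nu^2}\,\sqrt{R_{ind}}\; h^{3/2}}
#' over the Hertzian (small-depth) window to estimate the transverse Young's
#' modulus, and independently fits the free exponent \eqn{n} in
#' \eqn{F \propto h^n} over the same window.
#'
#' @param record an indentation \code{deformation_record}, or a data.frame
#'   with columns h and force.
#' @param R_ind tip radius, A; defaults to the record's metadata.
#' @param nu Poisson coefficient (default 0.5, incompressible in-plane
#'   deformation).
#' @param window optional depth interval c(h_min, h_max), A; defaults to the
#'   largest initial window with R^2 >= 0.99 for F against h^(3/2).
#' @return A \code{modulus_estimate} with kind "Y_T" and the fitted
#'   \code{exponent_n}.
#' @export
fit_hertz <- function(record, R_ind = NULL, nu = 0.5, window = NULL) {
  if (inherits(record, "deformation_record")) {
    if (record$protocol != "indentation") stop("record must be indentation")
    if (is.null(R_ind)) R_ind <- record$metadata$R_ind
    s <- record$series
  } else s <- record
  if (is.null(R_ind)) stop("R_ind required")
  ok <- !is.na(s$h) & s$h > 0 & is.finite(s$force)
  h <- s$h[ok]; f <- s$force[ok]
  if (length(h) < 5 || all(f == 0)) stop("no usable force-depth data to fit")
  # bin the noisy measurements along h before any windowing or fitting
  b <- .bin_curve(h, f)
  if (!is.null(window)) {
    idx <- which(b$x >= window[1] & b$x <= window[2])
  } else {
    # largest initial window by R^2 of the through-origin Hertz form; when
    # noise keeps every window below threshold, use the full recorded depth
    hh <- b$x; ff <- b$y
    best <- NA_integer_
    for (m in seq(5, length(hh))) {
      x32 <- hh[1:m]^1.5
      fit <- stats::lm(ff[1:m] ~ x32 + 0)
      ssr <- sum(stats::resid(fit)^2)
      sst <- sum((ff[1:m] - mean(ff[1:m]))^2)
      r2 <- if (sst > 0) 1 - ssr / sst else 1
      if (r2 >= 0.99) best <- m
    }
    if (is.na(best)) best <- length(hh)
    idx <- seq_len(best)
  }
  if (length(idx) < 5) stop("fewer than 5 points in Hertz window")
  hw <- b$x[idx]; fw <- b$y[idx]
  x32 <- hw^1.5
  fit <- stats::lm(fw ~ x32 + 0)
  slope <- unname(stats::coef(fit)[1])           # kcal/mol/A / A^(3/2)
  se_sl <- unname(summary(fit)$coefficients[1, 2])
  YT_int <- 0.75 * (1 - nu^2) * slope / sqrt(R_ind)
  if (YT_int <= 0) stop("negative fitted transverse modulus; window mischosen")
  # free exponent on the same window
  pos <- fw > 0
  if (sum(pos) < 5) stop("too few positive forces for exponent fit")
  efit <- stats::lm(log(fw[pos]) ~ log(hw[pos]))
  n_exp <- unname(stats::coef(efit)[2])
  ssr <- sum(stats::resid(fit)^2); sst <- sum((fw - mean(fw))^2)
  structure(list(kind = "Y_T", value = kcal_mol_A3_to_gpa(YT_int),
                 stderr = kcal_mol_A3_to_gpa(0.75 * (1 - nu^2) * se_sl / sqrt(R_ind)),
                 slope_internal = slope,
                 fit_window = range(hw), n_points = length(idx),
                 r_squared = if (sst > 0) 1 - ssr / sst else 1,
                 poor_fit = FALSE, replicas_used = 1L,
                 exponent_n = n_exp, nu = nu, R_ind = R_ind),
            class = "modulus_estimate")
}

#' Contact-length distributions by contact class
#'
#' Instantaneous native-contact lengths, split into intrachain, interchain
#' and intersheet classes, as normalised histograms. A class with no contacts
#' yields an empty histogram, not an error.
#'
#' @param positions a coordinate matrix (single frame), or a list of frames
#'   whose lengths are pooled.
#' @param topology a \code{fibril_topology}.
#' @param bin_width histogram bin width, A (default 0.05).
#' @return Named list per class: list(breaks, mids, density, lengths,
#'   mean_length, n).
#' @export
contact_length_distributions <- function(positions, topology, bin_width = 0.05) {
  frames <- if (is.matrix(positions)) list(positions) else positions
  cs <- topology$contacts
  classes <- c("intrachain", "interchain", "intersheet")
  out <- list()
  for (cl in classes) {
    sel <- cs$class == cl
    if (!any(sel)) {
      out[[cl]] <- list(breaks = numeric(0), mids = numeric(0),
                        density = numeric(0), lengths = numeric(0),
                        mean_length = NA_real_, n = 0L)
      next
    }
    lens <- unlist(lapply(frames, function(f)
      sqrt(rowSums((f[cs$i[sel], , drop = FALSE] -
                    f[cs$j[sel], , drop = FALSE])^2))))
    lo <- floor(min(lens) / bin_width) * bin_width
    hi <- ceiling(max(lens) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    hh <- graphics::hist(lens, breaks = seq(lo, hi, by = bin_width),
                         plot = FALSE)
    out[[cl]] <- list(breaks = hh$breaks, mids = hh$mids,
                      density = hh$density, lengths = lens,
                      mean_length = mean(lens), n = length(lens))
  }
  out
}

#' Select the recorded frame nearest a requested control value
#'
#' @param record a \code{deformation_record} whose metadata retains frames.
#' @param at requested strain (tensile/shear) or depth h (indentation).
#' @return The coordinate matrix of the nearest frame.
#' @export
frame_at <- function(record, at) {
  s <- record$series
  key <- if (record$protocol == "indentation") s$h else s$strain
  if (all(is.na(key))) stop("record has no usable control values")
  if (at < min(key, na.rm = TRUE) - 1e-9 || at > max(key, na.rm = TRUE) + 1e-9)
    stop("requested control value outside the recorded range")
  i <- which.min(abs(key - at))
  record$metadata$frames[[i]]
}
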