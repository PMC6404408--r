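#' Default run configuration
#'
#' All force-field constants and protocol settings in one serializable list;
#' the YAML form of this object fully determines a run given a seed.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    structure = list(path = NULL,
                     synthetic = list(n_layers = 6, n_protofilaments = 2,
                                      residues_per_chain = 12, rise = 4.8,
                                      lateral_spacing = 9.0, seed = 1,
                                      fold = "hairpin", n_tail = 0)),
    params = list(K_r = 100, K_theta = 45, K_phi = 5, epsilon = 1.5,
                  r_cut = 4, enlargement = 1.24, temperature_room = 0.35),
    protocol = list(v_pull = 5e-4, v_ind = 5e-3, k_bottom = 100, k_top = 0.1,
                    R_ind = 100, max_strain = 0.03, max_depth = 3,
                    d_anchor = 5, position_fraction = 0.5,
                    shear_segment = NULL),
    schedule = list(dt = 0.002, gamma = 2, temperature = 0.35,
                    replicas = 3, seed = 1, record_every = 400,
                    t_equil = 100),
    thermo = list(T_grid = seq(0.1, 0.7, length.out = 35),
                  t_equil = 1000, t_prod = 10000, scale = 1,
                  formed_factor = 1.5))
}

#' Read a run configuration from YAML
#'
#' Unspecified keys fall back to \code{\link{default_config}}.
#'
#' @param path YAML file path; NULL returns the defaults.
#' @return Configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  utils::modifyList(cfg, user)
}

.config_structure <- function(config) {
  st <- config$structure
  if (!is.null(st$path)) return(read_structure(st$path))
  sy <- st$synthetic
  generate_synthetic_fibril(sy$n_layers, sy$n_protofilaments,
                            sy$residues_per_chain, sy$rise,
                            sy$lateral_spacing, sy$seed,
                            fold = sy$fold, n_tail = sy$n_tail)
}

.config_params <- function(config) {
  p <- config$params
  model_params(K_r = p$K_r, K_theta = p$K_theta, K_phi = p$K_phi,
               epsilon = p$epsilon, r_cut = p$r_cut,
               enlargement = p$enlargement,
               temperature_room = p$temperature_room)
}

.write_manifest <- function(config, out_prefix, extra = list()) {
  cfg_str <- yaml::as.yaml(config)
  manifest <- c(list(config_sha = substr(.simple_hash(cfg_str), 1, 16),
                     config = config,
                     r_version = as.character(getRversion()),
                     package_version = as.character(
                       utils::packageVersion("fibrilmech")),
                     timestamp = format(Sys.time(), tz = "UTC")),
                extra)
  jsonlite::write_json(manifest, paste0(out_prefix, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# small deterministic content hash (djb2 over utf-8 bytes, hex)
.simple_hash <- function(s) {
  b <- utf8ToInt(s)
  h <- 5381
  for (x in b) h <- (h * 33 + x) %% 2^31
  sprintf("%08x%08x", h, length(b))
}

#' Pipeline: build and export a topology
#'
#' Runs read/generate -> fibril frame -> contact map and writes the topology
#' JSON and plain-text contact table.
#'
#' @param config configuration list (see \code{\link{read_run_config}}).
#' @param out_prefix output path prefix.
#' @return The \code{fibril_topology}, invisibly.
#' @export
cmd_topology <- function(config = default_config(), out_prefix = "topology") {
  st <- .config_structure(config)
  pars <- .config_params(config)
  topo <- build_topology(st, pars)
  write_topology_json(topo, paste0(out_prefix, ".json"))
  write_contact_table(topo, paste0(out_prefix, "_contacts.txt"))
  .write_manifest(config, out_prefix,
                  list(n_beads = topo$n_beads, n_contacts = nrow(topo$contacts)))
  message(sprintf("topology: %d beads, %d contacts -> %s.json",
                  topo$n_beads, nrow(topo$contacts), out_prefix))
  invisible(topo)
}

#' Pipeline: run a mechanical deformation protocol and fit the modulus
#'
#' Runs the requested protocol over replicas, aggregates the replica curves,
#' fits the modulus (stress-strain slope for pull/shear, Hertz fit for
#' indent) and writes the record CSV plus a modulus JSON.
#'
#' @param config configuration list.
#' @param protocol "pull", "shear" or "indent".
#' @param out_prefix output path prefix.
#' @return List(records, estimate), invisibly.
#' @export
cmd_mech <- function(config = default_config(), protocol = c("pull", "shear", "indent"),
                     out_prefix = protocol) {
  protocol <- match.arg(protocol)
  st <- .config_structure(config)
  pars <- .config_params(config)
  sys <- cg_system(st, pars)
  pc <- config$protocol; sc <- config$schedule
  n_rep <- sc$replicas
  records <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    seed_r <- sc$seed + r
    records[[r]] <- switch(protocol,
      pull = run_tensile(sys, v_pull = pc$v_pull, k_bottom = pc$k_bottom,
                         k_top = pc$k_top, max_strain = pc$max_strain,
                         temperature = sc$temperature, dt = sc$dt,
                         gamma = sc$gamma, d_anchor = pc$d_anchor,
                         t_equil = sc$t_equil, record_every = sc$record_every,
                         seed = seed_r),
      shear = run_shear(sys, shear_segment = pc$shear_segment,
                        v_pull = pc$v_pull, k_bottom = pc$k_bottom,
                        k_top = pc$k_top, max_strain = pc$max_strain,
                        temperature = sc$temperature, dt = sc$dt,
                        gamma = sc$gamma, d_anchor = pc$d_anchor,
                        t_equil = sc$t_equil, record_every = sc$record_every,
                        seed = seed_r),
      indent = run_indentation(sys, R_ind = pc$R_ind, v_ind = pc$v_ind,
                               position_fraction = pc$position_fraction,
                               max_depth = pc$max_depth,
                               temperature = sc$temperature, dt = sc$dt,
                               gamma = sc$gamma,
                               record_every = sc$record_every, seed = seed_r))
  }
  n_rupt <- sum(vapply(records, function(r) isTRUE(r$metadata$ruptured), logical(1)))
  if (n_rupt > n_rep / 2)
    stop(sprintf("rupture in %d of %d replicas; no modulus fitted", n_rupt, n_rep))
  if (protocol == "indent") {
    pooled <- do.call(rbind, lapply(records, function(r)
      r$series[!is.na(r$series$h), c("h", "force")]))
    est <- fit_hertz(pooled, R_ind = pc$R_ind)
  } else {
    curves <- lapply(records, stress_strain)
    est <- fit_linear_modulus(curves[[1]],
                              kind = if (protocol == "pull") "Y_L" else "S",
                              replicas = if (n_rep > 1) curves else NULL,
                              seed = sc$seed)
  }
  # series CSV (first replica) + fit JSON
  utils::write.csv(records[[1]]$series, paste0(out_prefix, "_record.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(kind = est$kind, value_gpa = est$value, stderr_gpa = est$stderr,
         exponent_n = est$exponent_n, fit_window = est$fit_window,
         r_squared = est$r_squared, replicas = n_rep, ruptured = n_rupt,
         unit_conversion = "1 kcal/(mol A^3) = 6.9477 GPa"),
    paste0(out_prefix, "_modulus.json"), auto_unbox = TRUE, digits = NA)
  .write_manifest(config, out_prefix, list(protocol = protocol))
  message(sprintf("%s: %s = %.3g GPa (window [%.3g, %.3g])", protocol,
                  est$kind, est$value, est$fit_window[1], est$fit_window[2]))
  invisible(list(records = records, estimate = est))
}

#' Pipeline: temperature scan
#'
#' Runs \code{\link{temperature_scan}} (optionally scaled down by
#' \code{thermo$scale} in grid size and run length, recorded in the manifest)
#' and writes the per-temperature table and the RMSF matrix as CSV.
#'
#' @param config configuration list.
#' @param out_prefix output path prefix.
#' @return The \code{thermo_scan}, invisibly.
#' @export
cmd_thermo <- function(config = default_config(), out_prefix = "thermo") {
  st <- .config_structure(config)
  pars <- .config_params(config)
  sys <- cg_system(st, pars)
  tc <- config$thermo; sc <- config$schedule
  scale <- if (is.null(tc$scale)) 1 else tc$scale
  Tg <- tc$T_grid
  if (scale < 1) {
    nT <- max(5L, round(length(Tg) * scale))
    Tg <- seq(min(Tg), max(Tg), length.out = nT)
  }
  scan <- temperature_scan(sys, T_grid = Tg,
                           t_equil = tc$t_equil * scale,
                           t_prod = tc$t_prod * scale,
                           dt = sc$dt, gamma = sc$gamma,
                           replicas = sc$replicas, seed = sc$seed,
                           formed_factor = tc$formed_factor)
  utils::write.csv(scan$table, paste0(out_prefix, "_scan.csv"), row.names = FALSE)
  rm_df <- as.data.frame(scan$rmsf)
  names(rm_df) <- paste0("res", seq_len(ncol(rm_df)))
  utils::write.csv(cbind(temperature = scan$table$temperature, rm_df),
                   paste0(out_prefix, "_rmsf.csv"), row.names = FALSE)
  tf <- tryCatch(folding_temperature(scan), error = function(e) NA_real_)
  .write_manifest(config, out_prefix, list(scale = scale, Tf = tf))
  message(sprintf("thermo: %d temperatures, Tf = %s", nrow(scan$table),
                  if (is.na(tf)) "not bracketed" else sprintf("%.3f eps/kB", tf)))
  invisible(scan)
}
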