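# Configuration loading and output serialization.
#
# Config files are YAML with SI units and explicit unit suffixes in key
# names (Ta_K, Vdg_m_s, ...) so that the cm/s vs m/s ambiguity common in
# spray work cannot creep in silently. Unknown keys are rejected by name.

.CONFIG_SCHEMA <- list(
  material = c("rho_kg_m3", "cp_liquid_J_kgK", "cp_solid_J_kgK",
               "latent_heat_J_kg", "T_freeze_K", "T_solidus_K",
               "k_thermal_W_mK"),
  droplet = c("d_m", "T_init_K"),
  ambient = c("Ta_K", "p_Pa", "Vdg_m_s"),
  coupling = c("enabled", "V_cell_m3", "d_hole_m", "v_in_m_s", "T_in_K"),
  solver = c("rtol", "atol", "epsilon_end_K", "t_max_s", "sample_dt_s"),
  output = c("csv", "json")
)

.check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown)) {
    stop(sprintf("load_config: unknown key(s) in '%s': %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
}

.require_number <- function(block, key, where, positive = TRUE) {
  v <- block[[key]]
  if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
    stop(sprintf("load_config: '%s.%s' must be a finite number", where, key),
         call. = FALSE)
  }
  if (positive && v <= 0) {
    stop(sprintf("load_config: '%s.%s' must be strictly positive", where,
                 key), call. = FALSE)
  }
  v
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing the material, droplet, ambient
#' conditions, optional gas-cell coupling and solver options. Every field
#' is validated on load; unknown keys raise an error naming them. The
#' `material`, `solver`, `coupling` and `output` blocks may be omitted
#' (defaults: cocoa butter, [solidify_control()] defaults, coupling
#' disabled, no output files).
#'
#' @param path Path to the YAML file.
#' @return Object of class `run_config`: list with `material`
#'   ([material_properties()]), `d`, `T_init`, `Ta`, `p`, `Vdg`,
#'   `coupling` (NULL or a [gas_cell()]), `control`
#'   ([solidify_control()]) and `output` (list with `csv`, `json`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("load_config: no such file: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  .check_keys(cfg, names(.CONFIG_SCHEMA), "top level")
  for (blk in intersect(names(cfg), names(.CONFIG_SCHEMA))) {
    .check_keys(cfg[[blk]], .CONFIG_SCHEMA[[blk]], blk)
  }
  if (is.null(cfg$droplet) || is.null(cfg$ambient)) {
    stop("load_config: 'droplet' and 'ambient' blocks are required",
         call. = FALSE)
  }

  material <- if (is.null(cfg$material)) {
    cocoa_butter()
  } else {
    mb <- cfg$material
    for (key in .CONFIG_SCHEMA$material) {
      .require_number(mb, key, "material",
                      positive = key != "latent_heat_J_kg")
    }
    material_properties(rho = mb$rho_kg_m3, cp_liquid = mb$cp_liquid_J_kgK,
                        cp_solid = mb$cp_solid_J_kgK,
                        latent_heat = mb$latent_heat_J_kg,
                        T_freeze = mb$T_freeze_K,
                        T_solidus = mb$T_solidus_K,
                        k_thermal = mb$k_thermal_W_mK)
  }

  d <- .require_number(cfg$droplet, "d_m", "droplet")
  T_init <- .require_number(cfg$droplet, "T_init_K", "droplet")
  Ta <- .require_number(cfg$ambient, "Ta_K", "ambient")
  p <- .require_number(cfg$ambient, "p_Pa", "ambient")
  Vdg <- cfg$ambient$Vdg_m_s
  if (is.null(Vdg) || !is.numeric(Vdg) || Vdg < 0) {
    stop("load_config: 'ambient.Vdg_m_s' must be a non-negative number",
         call. = FALSE)
  }

  sv <- if (is.null(cfg$solver)) list() else cfg$solver
  defaults <- solidify_control()
  control <- solidify_control(
    rtol = if (is.null(sv$rtol)) defaults$rtol else sv$rtol,
    atol = if (is.null(sv$atol)) defaults$atol else sv$atol,
    epsilon_end_K = if (is.null(sv$epsilon_end_K)) defaults$epsilon_end_K
      else sv$epsilon_end_K,
    t_max_s = if (is.null(sv$t_max_s)) defaults$t_max_s else sv$t_max_s,
    sample_dt_s = if (is.null(sv$sample_dt_s)) defaults$sample_dt_s
      else sv$sample_dt_s)

  coupling <- NULL
  cb <- cfg$coupling
  if (!is.null(cb) && isTRUE(cb$enabled)) {
    coupling <- gas_cell(
      V_cell = .require_number(cb, "V_cell_m3", "coupling"),
      T_in = if (is.null(cb$T_in_K)) Ta else cb$T_in_K,
      v_in = if (is.null(cb$v_in_m_s)) Vdg else cb$v_in_m_s,
      d_hole = if (is.null(cb$d_hole_m)) 0.0032 else cb$d_hole_m)
  }

  out <- cfg$output
  structure(list(material = material, d = d, T_init = T_init, Ta = Ta,
                 p = p, Vdg = Vdg, coupling = coupling, control = control,
                 output = list(csv = out$csv, json = out$json)),
            class = "run_config")
}

#' Run a loaded configuration
#'
#' Executes the uncoupled staged simulation, or the gas-cell-coupled one
#' when the configuration enables coupling, and writes the CSV/JSON
#' outputs when paths are configured.
#'
#' @param cfg A `run_config` from [load_config()].
#' @return The `droplet_trajectory`, invisibly when outputs were written.
#' @export
run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  traj <- if (is.null(cfg$coupling)) {
    simulate_droplet(d = cfg$d, T_init = cfg$T_init, mat = cfg$material,
                     Ta = cfg$Ta, Vdg = cfg$Vdg, p = cfg$p,
                     control = cfg$control)
  } else {
    simulate_coupled(d = cfg$d, T_init = cfg$T_init, mat = cfg$material,
                     cell = cfg$coupling, Vdg = cfg$Vdg, p = cfg$p,
                     control = cfg$control)
  }
  if (!is.null(cfg$output$csv) || !is.null(cfg$output$json)) {
    write_outputs(traj, csv = cfg$output$csv, json = cfg$output$json)
    return(invisible(traj))
  }
  traj
}

#' Write trajectory outputs
#'
#' Serializes the sampled time series as CSV (columns
#' `t_s, T_K, f_solid, stage, Nu, h_W_m2K`, plus `T_local_K` for coupled
#' runs) and the summary as JSON (`t_precool_s, t_solidify_s,
#' rate_initial_K_s, rate_solid_onset_K_s, Nu_mean, h_mean, Bi,
#' energy_residual_J`). Rewriting the same trajectory is idempotent.
#'
#' @param traj A `droplet_trajectory`.
#' @param csv,json Output paths; `NULL` skips that artifact.
#' @return Invisibly, the list of paths written.
#' @export
write_outputs <- function(traj, csv = NULL, json = NULL) {
  stopifnot(inherits(traj, "droplet_trajectory"))
  if (nrow(traj$samples) == 0L) {
    stop("write_outputs: empty trajectory", call. = FALSE)
  }
  written <- list()
  if (!is.null(csv)) {
    utils::write.csv(traj$samples, csv, row.names = FALSE)
    written$csv <- csv
  }
  if (!is.null(json)) {
    audit <- energy_audit(traj)
    summary <- list(t_precool_s = traj$t_precool_s,
                    t_solidify_s = traj$t_solidify_s,
                    rate_initial_K_s = traj$rate_initial_K_s,
                    rate_solid_onset_K_s = traj$rate_solid_onset_K_s,
                    Nu_mean = traj$Nu_mean, h_mean = traj$h_mean,
                    Bi = traj$Bi,
                    energy_residual_J = audit$residual_J,
                    q_rejected_J = traj$q_rejected_J,
                    q_latent_J = traj$q_latent_J,
                    t_end_s = traj$t_end_s, T_end_K = traj$T_end,
                    truncated = traj$truncated)
    jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    written$json <- json
  }
  invisible(written)
}
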