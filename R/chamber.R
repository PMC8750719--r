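# Well-mixed local gas cell: a lumped surrogate for droplet-gas thermal
# coupling. The droplet rejects heat into a single control volume that is
# continuously flushed by cold inflow air, so the ambient temperature the
# droplet sees rises above the inflow temperature while it cools.

#' Construct a well-mixed gas cell
#'
#' @param V_cell Control-volume size, m^3.
#' @param T_in Inflow air temperature, K.
#' @param v_in Inflow speed through the supply hole, m/s.
#' @param d_hole Supply-hole diameter, m (default 3.2 mm).
#' @param T_local Initial local gas temperature, K (defaults to `T_in`).
#' @return Object of class `gas_cell`.
#' @export
gas_cell <- function(V_cell, T_in, v_in, d_hole = 0.0032, T_local = T_in) {
  if (V_cell <= 0) stop("gas_cell: V_cell must be positive", call. = FALSE)
  if (T_in <= 0 || T_local <= 0) {
    stop("gas_cell: temperatures must be positive", call. = FALSE)
  }
  if (v_in <= 0 || d_hole <= 0) {
    stop("gas_cell: inflow speed and hole diameter must be positive",
         call. = FALSE)
  }
  structure(list(V_cell = V_cell, T_in = T_in, v_in = v_in,
                 d_hole = d_hole, T_local = T_local),
            class = "gas_cell")
}

# Inflow mass rate, kg/s, with the density taken at the inflow state.
.cell_mdot <- function(cell, p) {
  air_density(cell$T_in, p) * cell$v_in * pi * cell$d_hole^2 / 4
}

#' Rate of change of the local gas temperature
#'
#' Energy balance of the well-mixed cell: inflow enthalpy exchange plus the
#' heat input from the droplet, over the (constant) thermal mass of the
#' cell evaluated at the inflow state.
#'
#' @param cell A [gas_cell()].
#' @param q_drop Heat input from the droplet, W.
#' @param air An [air_state()] at the inflow state, supplying the density
#'   and specific heat of the cell gas.
#' @return dT_local/dt, K/s.
#' @export
gas_cell_rhs <- function(cell, q_drop, air) {
  stopifnot(inherits(cell, "gas_cell"))
  mdot <- air$rho_a * cell$v_in * pi * cell$d_hole^2 / 4
  (mdot * air$cp_a * (cell$T_in - cell$T_local) + q_drop) /
    (air$rho_a * cell$V_cell * air$cp_a)
}

#' Simulate a droplet coupled to a well-mixed gas cell
#'
#' Co-integrates the three-stage droplet model with the cell energy
#' balance: the ambient temperature the droplet experiences is the local
#' cell temperature, which in turn is heated by the droplet and flushed by
#' the inflow. As `V_cell` grows (or the inflow rate grows) the result
#' converges to the uncoupled [simulate_droplet()] run at `Ta = T_in`.
#'
#' The run terminates when the droplet is within `epsilon_end_K` of the
#' local gas temperature.
#'
#' @inheritParams simulate_droplet
#' @param cell A [gas_cell()].
#' @return A `droplet_trajectory` whose samples carry an extra
#'   `T_local_K` column, plus fields `q_outflow_J` (enthalpy carried out by
#'   the flushed air in excess of the inflow state) and
#'   `cell_residual_rel` (energy-conservation residual of
#'   droplet + cell + outflow, relative to the heat exchanged).
#' @export
simulate_coupled <- function(d, T_init, mat = cocoa_butter(), cell, Vdg,
                             p = 1e5, control = solidify_control()) {
  stopifnot(inherits(cell, "gas_cell"), inherits(mat, "material_properties"))
  if (T_init < cell$T_in) {
    stop("simulate_coupled: T_init below T_in - this is a cooling model",
         call. = FALSE)
  }
  air_in <- air_state(cell$T_in, p)
  Bi0 <- transfer_state(d, T_init, cell$T_in, Vdg, p,
                        k_material = mat$k_thermal)$Bi
  if (is.finite(Bi0) && Bi0 > 0.1) {
    warning(warningCondition(
      sprintf(paste0("initial Biot number %.3f exceeds 0.1; the uniform-",
                     "temperature assumption is strained"), Bi0),
      class = "dropsolid_biot_warning"))
  }
  mdot <- .cell_mdot(cell, p)
  C_cell <- air_in$rho_a * cell$V_cell * air_in$cp_a

  stage0 <- .stage_of(T_init, mat)
  stages_to_run <- .STAGES[match(stage0, .STAGES):3]
  eps <- control$epsilon_end_K

  rhs_for <- function(stage) {
    function(t, y, parms) {
      Td <- y[[1]]; Tl <- y[[3]]
      r <- droplet_rate(Td, stage, d, mat, Tl, Vdg, p,
                        h_fixed = control$h_fixed)
      dTl <- (mdot * air_in$cp_a * (cell$T_in - Tl) + r$dq_dt) / C_cell
      dqo <- mdot * air_in$cp_a * (Tl - cell$T_in)
      list(c(r$dT_dt, r$dq_dt, dTl, dqo))
    }
  }

  t0 <- 0
  y <- c(T = T_init, q = 0, Tl = cell$T_local, qo = 0)
  pieces <- list()
  t_enter <- c(precooling = NA_real_, solidifying = NA_real_,
               tempering = NA_real_)
  rate2 <- NA_real_
  truncated <- FALSE

  for (stage in stages_to_run) {
    t_enter[[stage]] <- t0
    if (stage == "solidifying") {
      rate2 <- -droplet_rate(y[["T"]], "solidifying", d, mat, y[["Tl"]],
                             Vdg, p, h_fixed = control$h_fixed)$dT_dt
    }
    thr <- switch(stage, precooling = mat$T_freeze,
                  solidifying = mat$T_solidus, tempering = NA_real_)
    rootfun <- function(t, y, parms) {
      stop_root <- (y[[1]] - y[[3]]) - eps
      if (is.na(thr)) stop_root else c(y[[1]] - thr, stop_root)
    }
    times <- seq(t0, control$t_max_s, by = control$sample_dt_s)
    if (length(times) < 2L) times <- c(t0, control$t_max_s)
    out <- deSolve::lsodar(y, times, rhs_for(stage), parms = NULL,
                           rootfunc = rootfun,
                           rtol = control$rtol, atol = control$atol)
    iroot <- attr(out, "iroot")
    ended_by <- if (is.null(iroot) || all(iroot == 0)) "t_max"
      else if (!is.na(thr) && iroot[1] != 0) "threshold" else "ambient"
    df <- data.frame(t_s = out[, "time"], T_K = out[, "T"],
                     q_J = out[, "q"], T_local_K = out[, "Tl"],
                     qo_J = out[, "qo"], stage = stage,
                     stringsAsFactors = FALSE)
    pieces[[stage]] <- df
    n <- nrow(out)
    t0 <- out[n, "time"]
    y <- c(T = unname(out[n, "T"]), q = unname(out[n, "q"]),
           Tl = unname(out[n, "Tl"]), qo = unname(out[n, "qo"]))
    if (ended_by == "ambient") break
    if (ended_by == "t_max") { truncated <- TRUE; break }
  }

  samples <- do.call(rbind, pieces)
  keep <- c(diff(samples$t_s) > 0, TRUE)
  samples <- samples[keep, , drop = FALSE]
  rownames(samples) <- NULL

  ts_rows <- transfer_state(d, samples$T_K, samples$T_local_K, Vdg, p)
  samples_full <- data.frame(
    t_s = samples$t_s, T_K = samples$T_K,
    f_solid = ifelse(samples$stage == "precooling", 0,
                     ifelse(samples$stage == "tempering", 1,
                            solid_fraction(samples$T_K, mat))),
    stage = samples$stage, Nu = ts_rows$Nu, h_W_m2K = ts_rows$h,
    q_J = samples$q_J, stringsAsFactors = FALSE)

  t1 <- if (!is.na(t_enter[["precooling"]]) &&
            !is.na(t_enter[["solidifying"]])) {
    t_enter[["solidifying"]] - t_enter[["precooling"]]
  } else NA_real_
  t2 <- if (!is.na(t_enter[["solidifying"]]) &&
            !is.na(t_enter[["tempering"]])) {
    t_enter[["tempering"]] - t_enter[["solidifying"]]
  } else NA_real_

  ts0 <- transfer_state(d, T_init, cell$T_in, Vdg, p,
                        k_material = mat$k_thermal)
  rate0 <- droplet_rate(T_init, stage0, d, mat, cell$T_local, Vdg, p,
                        h_fixed = control$h_fixed)

  traj <- .new_trajectory(samples_full, d, T_init, mat, cell$T_in, Vdg, p,
                          control, rate0 = -rate0$dT_dt, rate2 = rate2,
                          t1 = t1, t2 = t2,
                          q_end = samples$q_J[nrow(samples)], Bi = ts0$Bi,
                          truncated = truncated)
  traj$samples$T_local_K <- samples$T_local_K
  n <- nrow(samples)
  cell_stored <- C_cell * (samples$T_local_K[n] - cell$T_local)
  exchanged <- samples$q_J[n]
  traj$q_outflow_J <- samples$qo_J[n]
  traj$cell_residual_rel <- if (exchanged > 0) {
    abs(exchanged - (cell_stored + samples$qo_J[n])) / exchanged
  } else 0
  traj$cell <- cell
  traj
}
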