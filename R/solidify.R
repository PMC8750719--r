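# The three-stage lumped solidification model.
#
# Stage 1 (pre-cooling):   rho V Cpd  dT/dt = A h (Ta - T)
# Stage 2 (solidifying):   rho V Cpsd dT/dt = A h (Ta - T) + rho Vf' L
# Stage 3 (tempering):     rho V Cps  dT/dt = A h (Ta - T)
#
# Stage 2 is closed by taking the solid volume fraction linear in
# temperature between the onset T_freeze and the solidus T_solidus, which
# turns the latent-heat source into an effective heat capacity
# Ceff = Cpsd(f) + L/(Tf - Ts) and couples latent-heat release exactly to
# the solidified fraction.

.STAGES <- c("precooling", "solidifying", "tempering")

#' Solid volume fraction at a droplet temperature
#'
#' Linear-in-temperature closure for the phase-change progress: f = 0 at the
#' onset temperature, f = 1 at the solidus, clipped outside the interval.
#'
#' @param T Droplet temperature, K.
#' @param mat A [material_properties()] object.
#' @return Solid volume fraction in `[0, 1]` (vectorized over `T`).
#' @export
solid_fraction <- function(T, mat) {
  pmin(pmax((mat$T_freeze - T) / (mat$T_freeze - mat$T_solidus), 0), 1)
}

#' Heat capacity of a semisolid droplet
#'
#' The droplet solidifies from the outer surface inward, leaving a liquid
#' core of radius ratio a = (1 - f)^(1/3). The semisolid heat capacity
#' interpolates between the solid and liquid values with that radius ratio:
#' Cpsd = (1 - a) Cps + a Cpd.
#'
#' @param f_solid Solid volume fraction in `[0, 1]`.
#' @param mat A [material_properties()] object.
#' @return Heat capacity, J/(kg K).
#' @export
cp_semisolid <- function(f_solid, mat) {
  if (any(f_solid < 0 | f_solid > 1)) {
    stop("cp_semisolid: f_solid must lie in [0, 1]", call. = FALSE)
  }
  a <- (1 - f_solid)^(1 / 3)
  (1 - a) * mat$cp_solid + a * mat$cp_liquid
}

# Effective heat capacity seen by the energy balance in each stage.
.cp_effective <- function(T, stage, mat) {
  switch(stage,
    precooling = mat$cp_liquid,
    solidifying = cp_semisolid(solid_fraction(T, mat), mat) +
      mat$latent_heat / (mat$T_freeze - mat$T_solidus),
    tempering = mat$cp_solid,
    stop("unknown stage: ", stage, call. = FALSE)
  )
}

# Stage implied by a temperature alone (used for initial placement and for
# labelling apparent-Cp trajectories).
.stage_of <- function(T, mat) {
  ifelse(T > mat$T_freeze, "precooling",
         ifelse(T > mat$T_solidus, "solidifying", "tempering"))
}

#' Instantaneous rates of the staged energy balance
#'
#' Evaluates dT/dt and the surface heat-rejection rate for a droplet in a
#' given stage, with the heat-transfer coefficient from [transfer_state()]
#' (film-temperature gas properties) unless `h_fixed` is supplied.
#'
#' @param T Droplet temperature, K.
#' @param stage One of `"precooling"`, `"solidifying"`, `"tempering"`.
#' @param d Droplet diameter, m.
#' @param mat A [material_properties()] object.
#' @param Ta Ambient temperature, K.
#' @param Vdg Relative drop-gas speed, m/s.
#' @param p Pressure, Pa.
#' @param h_fixed Optional fixed heat-transfer coefficient, W/(m^2 K).
#' @return List with `dT_dt` (K/s), `dq_dt` (W, heat flowing droplet to
#'   gas), and the `h` used.
#' @export
droplet_rate <- function(T, stage, d, mat, Ta, Vdg, p, h_fixed = NULL) {
  stage <- match.arg(stage, .STAGES)
  h <- if (is.null(h_fixed)) transfer_state(d, T, Ta, Vdg, p)$h else h_fixed
  cp <- .cp_effective(T, stage, mat)
  list(dT_dt = 6 * h * (Ta - T) / (mat$rho * cp * d),
       dq_dt = pi * d^2 * h * (T - Ta),
       h = h)
}

#' Solver options for the droplet simulations
#'
#' @param rtol,atol Relative and absolute tolerances of the adaptive
#'   integrator.
#' @param epsilon_end_K Termination band, K: the run ends when the droplet
#'   is within this distance of the ambient temperature (the ambient is an
#'   asymptote and is never reached exactly).
#' @param t_max_s Hard time limit, s; reaching it sets the `truncated` flag
#'   on the trajectory rather than raising an error.
#' @param sample_dt_s Output sampling interval, s.
#' @param h_fixed Optional frozen heat-transfer coefficient, W/(m^2 K);
#'   `NULL` (the default) recomputes h from the film-temperature gas
#'   properties at every step.
#' @return A list of class `solidify_control`.
#' @export
solidify_control <- function(rtol = 1e-8, atol = 1e-8, epsilon_end_K = 0.5,
                             t_max_s = 600, sample_dt_s = 0.05,
                             h_fixed = NULL) {
  if (rtol <= 0 || atol <= 0 || epsilon_end_K <= 0 || t_max_s <= 0 ||
      sample_dt_s <= 0) {
    stop("solidify_control: tolerances, epsilon_end_K, t_max_s and ",
         "sample_dt_s must be positive", call. = FALSE)
  }
  structure(list(rtol = rtol, atol = atol, epsilon_end_K = epsilon_end_K,
                 t_max_s = t_max_s, sample_dt_s = sample_dt_s,
                 h_fixed = h_fixed),
            class = "solidify_control")
}

# Integrate one stage with event location. Roots: the stage-exit threshold
# (T reaching T_freeze or T_solidus) and the termination band |T-Ta|<eps.
# Returns the deSolve matrix plus which root (if any) ended the stage.
.integrate_stage <- function(stage, t0, T0, q0, d, mat, Ta, Vdg, p, control) {
  thr <- switch(stage, precooling = mat$T_freeze,
                solidifying = mat$T_solidus, tempering = NA_real_)
  rhs <- function(t, y, parms) {
    r <- droplet_rate(y[[1]], stage, d, mat, Ta, Vdg, p,
                      h_fixed = control$h_fixed)
    list(c(r$dT_dt, r$dq_dt))
  }
  rootfun <- function(t, y, parms) {
    stop_root <- (y[[1]] - Ta) - control$epsilon_end_K
    if (is.na(thr)) stop_root else c(y[[1]] - thr, stop_root)
  }
  times <- seq(t0, control$t_max_s, by = control$sample_dt_s)
  if (length(times) < 2L) times <- c(t0, control$t_max_s)
  out <- deSolve::lsodar(c(T = unname(T0), q = unname(q0)), times, rhs,
                         parms = NULL,
                         rootfunc = rootfun,
                         rtol = control$rtol, atol = control$atol)
  iroot <- attr(out, "iroot")
  ended_by <- if (is.null(iroot) || all(iroot == 0)) {
    "t_max"
  } else if (!is.na(thr) && iroot[1] != 0) {
    "threshold"
  } else {
    "ambient"
  }
  list(out = out, ended_by = ended_by)
}

#' Simulate the three-stage solidification of a droplet
#'
#' Integrates the staged lumped energy balance from `T_init` down towards
#' the ambient temperature, with root-located transitions at the
#' phase-change onset (`T_freeze`) and the solidus (`T_solidus`), so the
#' stage switches land exactly on the thresholds. The run terminates when
#' the droplet temperature is within `epsilon_end_K` of ambient or at
#' `t_max_s` (then flagged truncated, not an error).
#'
#' A warning of class `dropsolid_biot_warning` is raised when the initial
#' Biot number exceeds 0.1, the usual validity limit of the lumped
#' (uniform-temperature) approximation.
#'
#' @param d Droplet diameter, m (constant for the whole run).
#' @param T_init Initial droplet temperature, K; must not be below `Ta`
#'   (this is a cooling model). `T_init == Ta` yields a degenerate
#'   constant-temperature trajectory.
#' @param mat A [material_properties()] object; default [cocoa_butter()].
#' @param Ta Ambient air temperature, K.
#' @param Vdg Relative drop-gas speed, m/s.
#' @param p Ambient pressure, Pa.
#' @param control A [solidify_control()] list.
#' @return An object of class `droplet_trajectory`: list with
#'   * `samples`: data.frame `(t_s, T_K, f_solid, stage, Nu, h_W_m2K)`;
#'   * `t_precool_s`, `t_solidify_s`: stage durations (NA when the stage
#'     was not entered or not completed);
#'   * `rate_initial_K_s`: cooling rate at t = 0 (positive, K/s);
#'   * `rate_solid_onset_K_s`: cooling rate just after entering stage 2;
#'   * `Nu_mean`, `h_mean`: time averages over the whole run;
#'   * `Bi`: Biot number at the initial state;
#'   * `q_rejected_J`, `q_latent_J`: cumulative heat to the gas and latent
#'     heat released at the end of the run;
#'   * `truncated`: TRUE when `t_max_s` was hit before the termination band.
#' @examples
#' \donttest{
#' traj <- suppressWarnings(
#'   simulate_droplet(d = 2e-3, T_init = 318, Ta = 277, Vdg = 0.83, p = 1e5))
#' traj$t_precool_s  # about 7 s to reach the 291 K onset
#' }
#' @export
simulate_droplet <- function(d, T_init, mat = cocoa_butter(), Ta, Vdg,
                             p = 1e5, control = solidify_control()) {
  if (!inherits(mat, "material_properties")) {
    stop("simulate_droplet: 'mat' must be a material_properties object",
         call. = FALSE)
  }
  if (d <= 0) stop("simulate_droplet: d must be positive", call. = FALSE)
  if (T_init <= 0 || Ta <= 0 || p <= 0) {
    stop("simulate_droplet: temperatures and pressure must be positive",
         call. = FALSE)
  }
  if (Vdg < 0) stop("simulate_droplet: Vdg must be non-negative",
                    call. = FALSE)
  if (T_init < Ta) {
    stop("simulate_droplet: T_init below Ta - this is a cooling model",
         call. = FALSE)
  }

  mass <- mat$rho * pi * d^3 / 6
  ts0 <- transfer_state(d, T_init, Ta, Vdg, p, k_material = mat$k_thermal)
  Bi0 <- if (is.null(control$h_fixed)) ts0$Bi else
    biot(control$h_fixed, d, mat$k_thermal)
  if (is.finite(Bi0) && Bi0 > 0.1) {
    warning(warningCondition(
      sprintf(paste0("initial Biot number %.3f exceeds 0.1; the uniform-",
                     "temperature assumption is strained"), Bi0),
      class = "dropsolid_biot_warning"))
  }

  stage0 <- .stage_of(T_init, mat)
  rate0 <- droplet_rate(T_init, stage0, d, mat, Ta, Vdg, p,
                        h_fixed = control$h_fixed)

  # Degenerate run: already inside the termination band.
  if (T_init - Ta <= control$epsilon_end_K) {
    samples <- data.frame(t_s = 0, T_K = T_init,
                          f_solid = solid_fraction(T_init, mat),
                          stage = stage0, Nu = ts0$Nu, h_W_m2K = ts0$h,
                          stringsAsFactors = FALSE)
    return(.new_trajectory(samples, d, T_init, mat, Ta, Vdg, p, control,
                           rate0 = 0, rate2 = NA_real_, t1 = NA_real_,
                           t2 = NA_real_, q_end = 0, Bi = Bi0,
                           truncated = FALSE))
  }

  stages_to_run <- .STAGES[match(stage0, .STAGES):3]
  t0 <- 0; T0 <- T_init; q0 <- 0
  pieces <- list()
  t_enter <- c(precooling = NA_real_, solidifying = NA_real_,
               tempering = NA_real_)
  t_exit <- t_enter
  rate2 <- NA_real_
  truncated <- FALSE

  for (stage in stages_to_run) {
    t_enter[[stage]] <- t0
    if (stage == "solidifying") {
      rate2 <- -droplet_rate(T0, "solidifying", d, mat, Ta, Vdg, p,
                             h_fixed = control$h_fixed)$dT_dt
    }
    res <- .integrate_stage(stage, t0, T0, q0, d, mat, Ta, Vdg, p, control)
    out <- res$out
    n <- nrow(out)
    df <- data.frame(t_s = out[, "time"], T_K = out[, "T"], q_J = out[, "q"],
                     stage = stage, stringsAsFactors = FALSE)
    pieces[[stage]] <- df
    t0 <- out[n, "time"]; T0 <- out[n, "T"]; q0 <- out[n, "q"]
    t_exit[[stage]] <- t0
    if (res$ended_by == "ambient") break
    if (res$ended_by == "t_max") { truncated <- TRUE; break }
  }

  samples <- do.call(rbind, pieces)
  # Drop duplicated boundary times (each stage restarts at the previous
  # root time); keep the row carrying the new stage label.
  keep <- c(diff(samples$t_s) > 0, TRUE)
  samples <- samples[keep, , drop = FALSE]
  rownames(samples) <- NULL

  ts_rows <- transfer_state(d, samples$T_K, Ta, Vdg, p)
  h_col <- if (is.null(control$h_fixed)) ts_rows$h else
    rep(control$h_fixed, nrow(samples))
  Nu_col <- if (is.null(control$h_fixed)) ts_rows$Nu else
    h_col * d / ts_rows$ka
  samples <- data.frame(t_s = samples$t_s, T_K = samples$T_K,
                        f_solid = ifelse(samples$stage == "precooling", 0,
                          ifelse(samples$stage == "tempering", 1,
                                 solid_fraction(samples$T_K, mat))),
                        stage = samples$stage, Nu = Nu_col, h_W_m2K = h_col,
                        q_J = samples$q_J, stringsAsFactors = FALSE)

  t1 <- if (stage0 == "precooling" && !is.na(t_exit[["precooling"]]) &&
            (!is.na(t_enter[["solidifying"]]) ||
             samples$T_K[nrow(samples)] <= mat$T_freeze)) {
    t_exit[["precooling"]] - t_enter[["precooling"]]
  } else NA_real_
  # Pre-cooling that ended in the termination band without reaching the
  # onset is not a completed stage 1.
  if (!is.na(t1) && is.na(t_enter[["solidifying"]]) &&
      stage0 == "precooling") {
    t1 <- NA_real_
  }
  t2 <- if (!is.na(t_enter[["solidifying"]]) &&
            !is.na(t_enter[["tempering"]])) {
    t_enter[["tempering"]] - t_enter[["solidifying"]]
  } else NA_real_

  .new_trajectory(samples, d, T_init, mat, Ta, Vdg, p, control,
                  rate0 = -rate0$dT_dt, rate2 = rate2, t1 = t1, t2 = t2,
                  q_end = samples$q_J[nrow(samples)], Bi = Bi0,
                  truncated = truncated)
}

# Trapezoidal time average of a sampled signal.
.time_mean <- function(t, v) {
  if (length(t) < 2L) return(v[1])
  sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2) /
    (t[length(t)] - t[1])
}

.new_trajectory <- function(samples, d, T_init, mat, Ta, Vdg, p, control,
                            rate0, rate2, t1, t2, q_end, Bi, truncated) {
  mass <- mat$rho * pi * d^3 / 6
  f_end <- samples$f_solid[nrow(samples)]
  f_start <- samples$f_solid[1]
  structure(list(
    samples = samples[, c("t_s", "T_K", "f_solid", "stage", "Nu", "h_W_m2K")],
    d = d, T_init = T_init, Ta = Ta, Vdg = Vdg, p = p, mat = mat,
    control = control,
    t_precool_s = t1, t_solidify_s = t2,
    rate_initial_K_s = rate0, rate_solid_onset_K_s = rate2,
    Nu_mean = .time_mean(samples$t_s, samples$Nu),
    h_mean = .time_mean(samples$t_s, samples$h_W_m2K),
    Bi = Bi,
    T_end = samples$T_K[nrow(samples)],
    t_end_s = samples$t_s[nrow(samples)],
    q_rejected_J = q_end,
    q_latent_J = mass * mat$latent_heat * (f_end - f_start),
    mass_kg = mass,
    truncated = truncated
  ), class = "droplet_trajectory")
}

#' @export
print.droplet_trajectory <- function(x, ...) {
  cat(sprintf("Droplet trajectory: d = %g um, T %g -> %.2f K, Ta = %g K\n",
              x$d * 1e6, x$T_init, x$T_end, x$Ta))
  cat(sprintf("  stages sampled: %s%s\n",
              paste(unique(x$samples$stage), collapse = " -> "),
              if (x$truncated) "  [truncated at t_max]" else ""))
  cat(sprintf("  t_precool = %s s, t_solidify = %s s, t_end = %.2f s\n",
              format(x$t_precool_s, digits = 4),
              format(x$t_solidify_s, digits = 4), x$t_end_s))
  cat(sprintf("  rate(t=0) = %.3f K/s, rate(onset) = %s K/s\n",
              x$rate_initial_K_s, format(x$rate_solid_onset_K_s, digits = 3)))
  cat(sprintf("  Nu_mean = %.3f, h_mean = %.2f W/(m^2 K), Bi = %.3f\n",
              x$Nu_mean, x$h_mean, x$Bi))
  cat(sprintf("  q_rejected = %.4g J, q_latent = %.4g J\n",
              x$q_rejected_J, x$q_latent_J))
  invisible(x)
}

#' Plot a droplet temperature profile
#'
#' @param x A `droplet_trajectory`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.droplet_trajectory <- function(x, ...) {
  graphics::plot(x$samples$t_s, x$samples$T_K, type = "l",
                 xlab = "time (s)", ylab = "droplet temperature (K)", ...)
  graphics::abline(h = c(x$mat$T_freeze, x$mat$T_solidus), lty = 3)
  invisible(x)
}

#' Energy audit of a completed trajectory
#'
#' Checks global energy conservation: the heat rejected through the surface
#' must equal the sensible enthalpy change along the staged path plus the
#' latent heat released. The sensible part is evaluated in closed form from
#' the staged heat capacities (the semisolid integral over the shrinking
#' liquid core is analytic).
#'
#' @param traj A `droplet_trajectory`.
#' @return Object of class `energy_audit`: list with `residual_J`,
#'   `relative` (residual over heat rejected), `q_rejected_J`,
#'   `sensible_J`, `q_latent_J`.
#' @export
energy_audit <- function(traj) {
  stopifnot(inherits(traj, "droplet_trajectory"))
  mat <- traj$mat
  m <- traj$mass_kg
  T0 <- traj$T_init
  T1 <- traj$T_end
  Tf <- mat$T_freeze; Ts <- mat$T_solidus

  seg <- function(a, b) {  # sensible heat released cooling from a to b (a>=b)
    total <- 0
    # liquid part
    hi <- a; lo <- max(b, Tf)
    if (hi > lo) total <- total + m * mat$cp_liquid * (hi - lo)
    # semisolid part: integral of Cpsd dT with f linear in T
    hi <- min(a, Tf); lo <- max(b, Ts)
    if (hi > lo) {
      f1 <- solid_fraction(hi, mat); f2 <- solid_fraction(lo, mat)
      int_f <- mat$cp_solid * (f2 - f1) +
        (mat$cp_liquid - mat$cp_solid) * (3 / 4) *
        ((1 - f1)^(4 / 3) - (1 - f2)^(4 / 3))
      total <- total + m * (Tf - Ts) * int_f
    }
    # solid part
    hi <- min(a, Ts); lo <- b
    if (hi > lo) total <- total + m * mat$cp_solid * (hi - lo)
    total
  }

  sensible <- seg(T0, T1)
  resid <- abs(traj$q_rejected_J - (sensible + traj$q_latent_J))
  structure(list(residual_J = resid,
                 relative = if (traj$q_rejected_J > 0)
                   resid / traj$q_rejected_J else 0,
                 q_rejected_J = traj$q_rejected_J,
                 sensible_J = sensible,
                 q_latent_J = traj$q_latent_J),
            class = "energy_audit")
}

#' @export
print.energy_audit <- function(x, ...) {
  cat(sprintf(paste0("Energy audit: rejected %.5g J = sensible %.5g J + ",
                     "latent %.5g J (residual %.3g J, %.3g%%)\n"),
              x$q_rejected_J, x$sensible_J, x$q_latent_J,
              x$residual_J, 100 * x$relative))
  invisible(x)
}
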