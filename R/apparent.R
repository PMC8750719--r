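# Apparent-specific-heat comparator.
#
# The alternative to staged latent-heat bookkeeping is a single energy
# balance in which latent heat is folded into a temperature-dependent
# "apparent" heat capacity with a spike over the phase-change range. That
# formulation is equivalent to the staged model in exact arithmetic, but a
# fixed-step integrator that samples the capacity at the step-start
# temperature can step across the spike and silently under-release latent
# heat. The comparator here makes that failure mode measurable.

#' Apparent specific heat
#'
#' Single-curve heat capacity with the latent heat folded in: equal to the
#' liquid capacity above the phase-change onset, to the solid capacity
#' below the solidus, and to the semisolid capacity plus the latent spike
#' L/(T_freeze - T_solidus) in between.
#'
#' @param T Droplet temperature, K (vectorized).
#' @param mat A [material_properties()] object.
#' @return Apparent heat capacity, J/(kg K).
#' @export
apparent_cp <- function(T, mat) {
  if (any(T <= 0)) stop("apparent_cp: T must be positive", call. = FALSE)
  spike <- mat$latent_heat / (mat$T_freeze - mat$T_solidus)
  ifelse(T > mat$T_freeze, mat$cp_liquid,
         ifelse(T < mat$T_solidus, mat$cp_solid,
                cp_semisolid(solid_fraction(T, mat), mat) + spike))
}

# Non-latent part of the capacity curve, for separating the implicitly
# released latent heat.
.baseline_cp <- function(T, mat) {
  ifelse(T > mat$T_freeze, mat$cp_liquid,
         ifelse(T < mat$T_solidus, mat$cp_solid,
                cp_semisolid(solid_fraction(T, mat), mat)))
}

#' Simulate with the apparent-specific-heat formulation
#'
#' Integrates the single-equation model
#' rho V Cp_app(T) dT/dt = A h (Ta - T) with a fixed-step explicit Euler
#' scheme that evaluates Cp_app at the step-start temperature -- the
#' classical discretization whose coarse-step behaviour under-releases
#' latent heat. In the fine-step limit it converges to the staged model of
#' [simulate_droplet()].
#'
#' @inheritParams simulate_droplet
#' @param dt Fixed step size, s.
#' @return A list of class `apparent_trajectory`: `samples` data.frame
#'   `(t_s, T_K, f_solid, stage)`, the inputs, plus
#'   `latent_implicit_J` (latent heat actually released through the
#'   capacity spike along the realized path), `latent_true_J` (the latent
#'   heat the staged model would have released reaching the same final
#'   temperature, m L f(T_end)), and `latent_deficit_J` (their difference,
#'   strictly positive when the scheme steps over the spike).
#' @export
simulate_apparent <- function(d, T_init, mat = cocoa_butter(), Ta, Vdg,
                              p = 1e5, dt = 1e-3,
                              control = solidify_control()) {
  if (dt <= 0) stop("simulate_apparent: dt must be positive", call. = FALSE)
  if (d <= 0) stop("simulate_apparent: d must be positive", call. = FALSE)
  if (T_init < Ta) {
    stop("simulate_apparent: T_init below Ta - this is a cooling model",
         call. = FALSE)
  }
  mass <- mat$rho * pi * d^3 / 6
  area <- pi * d^2
  eps <- control$epsilon_end_K
  n_max <- ceiling(control$t_max_s / dt)

  # Record roughly every sample_dt_s seconds, but at least every step for
  # very coarse dt.
  rec_every <- max(1L, floor(control$sample_dt_s / dt))

  T_cur <- T_init
  q <- 0
  latent_implicit <- 0
  t_rec <- numeric(0); T_rec <- numeric(0)
  i <- 0L
  truncated <- TRUE
  repeat {
    if (i %% rec_every == 0L) {
      t_rec <- c(t_rec, i * dt); T_rec <- c(T_rec, T_cur)
    }
    if (T_cur - Ta <= eps) { truncated <- FALSE; break }
    if (i >= n_max) break
    h <- if (is.null(control$h_fixed)) {
      transfer_state(d, T_cur, Ta, Vdg, p)$h
    } else control$h_fixed
    cp <- apparent_cp(T_cur, mat)
    dT <- dt * 6 * h * (Ta - T_cur) / (mat$rho * cp * d)
    q <- q + dt * area * h * (T_cur - Ta)
    latent_implicit <- latent_implicit +
      mass * (cp - .baseline_cp(T_cur, mat)) * (-dT)
    T_cur <- T_cur + dT
    i <- i + 1L
  }
  if (t_rec[length(t_rec)] < i * dt) {
    t_rec <- c(t_rec, i * dt); T_rec <- c(T_rec, T_cur)
  }

  latent_true <- mass * mat$latent_heat * solid_fraction(T_cur, mat)
  samples <- data.frame(t_s = t_rec, T_K = T_rec,
                        f_solid = solid_fraction(T_rec, mat),
                        stage = .stage_of(T_rec, mat),
                        stringsAsFactors = FALSE)
  structure(list(samples = samples, d = d, T_init = T_init, Ta = Ta,
                 Vdg = Vdg, p = p, mat = mat, dt = dt,
                 T_end = T_cur, t_end_s = i * dt,
                 q_rejected_J = q,
                 latent_implicit_J = latent_implicit,
                 latent_true_J = latent_true,
                 latent_deficit_J = latent_true - latent_implicit,
                 truncated = truncated),
            class = "apparent_trajectory")
}

#' @export
print.apparent_trajectory <- function(x, ...) {
  cat(sprintf(paste0("Apparent-Cp trajectory: dt = %g s, T %g -> %.2f K\n",
                     "  latent released %.4g J of %.4g J (deficit %.4g J)\n"),
              x$dt, x$T_init, x$T_end, x$latent_implicit_J,
              x$latent_true_J, x$latent_deficit_J))
  invisible(x)
}
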