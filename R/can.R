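## Capillary-astrocyte-neuron (CAN) model: Izhikevich spiking units whose
## excitability is modulated by metabolic state.
##
## Spiking subsystem (per unit, explicit Euler, dimensionless Izhikevich
## 2003 regular-spiking constants by default):
##   dv/dt = 0.04 v^2 + 5 v + 140 - u + I(t)
##   du/dt = a (b+ v - u),   b+ = omega * b + beta * m(t)
##   if v >= v_peak: spike, v <- c_reset, u <- u + d
## Metabolic subsystem (astrocyte glycogen g, mitochondrial ATP m):
##   dg/dt = -Psi1(g, m) + kappa * drive(t)
##   dm/dt = -Psi2(g, m) + Psi1(g, m)
## with Psi1 = k_g * g * (1 - m/m_max) (glycogen -> ATP conversion, slowing
## at ATP saturation) and Psi2 = k_m * m (linear consumption). drive(t) is
## a sliding-window functional of recent membrane activity (default: the
## rectified excursion above the spike-threshold potential, integrating
## the cumulative effect of spiking over the window tau).

#' Izhikevich unit parameters with metabolic feedback gains
#'
#' @param a recovery time scale (default 0.02).
#' @param b nominal recovery sensitivity; b = 0.2 gives regular spiking.
#' @param c_reset post-spike membrane reset (default -65).
#' @param d post-spike recovery increment (default 8).
#' @param v_peak spike cutoff (default 30).
#' @param omega excitability scaling, in \code{[0.75, 1.25]}.
#' @param beta metabolic feedback gain, in \code{[0, 0.5]}; at beta = 0 the
#'   metabolic state has no effect on spiking.
#' @return Object of class \code{"izhikevich_params"}.
#' @export
izhikevich_params <- function(a = 0.02, b = 0.2, c_reset = -65, d = 8,
                              v_peak = 30, omega = 1, beta = 0) {
  check_scalar_number(b, "b")
  if (b <= 0) stop_config("b must be > 0")
  check_scalar_number(omega, "omega", lo = 0.75, hi = 1.25)
  check_scalar_number(beta, "beta", lo = 0, hi = 0.5)
  structure(list(a = a, b = b, c_reset = c_reset, d = d, v_peak = v_peak,
                 omega = omega, beta = beta),
            class = "izhikevich_params")
}

#' Metabolic subsystem parameters
#'
#' All quantities are dimensionless model units; time is in the same unit
#' as the integrator step (nominally ms).
#'
#' @param kappa spiking-to-glycogen drive gain.
#' @param tau sliding-window length for the activity drive.
#' @param k_g glycogen-to-ATP conversion rate (inside Psi1).
#' @param k_m ATP consumption rate (inside Psi2).
#' @param g_max,m_max pool capacities (states are clamped to
#'   \code{[0, capacity]}).
#' @param drive_mode one of \code{"rectified"} (integral of
#'   \code{max(v - v_rest, 0)}), \code{"raw"} (integral of v), or
#'   \code{"spike_count"} (spikes in the window).
#' @return Object of class \code{"metabolic_params"}.
#' @export
metabolic_params <- function(kappa = 5e-4, tau = 20, k_g = 0.05, k_m = 0.01,
                             g_max = 5, m_max = 1,
                             drive_mode = c("rectified", "raw", "spike_count")) {
  drive_mode <- match.arg(drive_mode)
  for (nm in c("kappa", "k_g", "k_m"))
    check_scalar_number(get(nm), nm, lo = 0)
  check_scalar_number(tau, "tau"); if (tau <= 0) stop_config("tau must be > 0")
  if (g_max <= 0 || m_max <= 0) stop_config("capacities must be > 0")
  structure(list(kappa = kappa, tau = tau, k_g = k_g, k_m = k_m,
                 g_max = g_max, m_max = m_max, drive_mode = drive_mode),
            class = "metabolic_params")
}

#' Effective recovery sensitivity b+ under metabolic modulation
#'
#' \code{b+ = omega * b + beta * m}: the feedback path from available ATP
#' to neuronal excitability.
#'
#' @param params an \code{\link{izhikevich_params}}.
#' @param m ATP level(s), >= 0.
#' @return Effective sensitivity, same length as \code{m}.
#' @export
sensitivity_modulation <- function(params, m) {
  if (any(m < 0)) stop_config("m must be >= 0")
  params$omega * params$b + params$beta * m
}

#' Resting membrane potential of the Izhikevich unit
#'
#' The stable equilibrium of the (v, u) subsystem at constant input I and
#' fixed sensitivity \code{b_eff} (more negative root of the quadratic
#' nullcline intersection), or NA when no equilibrium exists (tonic
#' firing).
#'
#' @param params an \code{\link{izhikevich_params}}.
#' @param I constant input current.
#' @param b_eff effective sensitivity; default \code{omega * b}.
#' @return Resting potential or NA.
#' @export
izhikevich_rest <- function(params, I = 0, b_eff = NULL) {
  b_eff <- b_eff %||% (params$omega * params$b)
  disc <- (5 - b_eff)^2 - 4 * 0.04 * (140 + I)
  if (disc < 0) return(NA_real_)
  (-(5 - b_eff) - sqrt(disc)) / (2 * 0.04)
}

#' Spike-threshold potential of the Izhikevich unit
#'
#' The unstable equilibrium separating rest from the spike upstroke at
#' constant input I (the larger root of the nullcline quadratic); NA when
#' no equilibrium exists. Used by the simulators as the rectification
#' reference for the metabolic drive, so purely subthreshold fluctuation
#' releases no drive.
#'
#' @inheritParams izhikevich_rest
#' @return Threshold potential or NA.
#' @export
izhikevich_threshold <- function(params, I = 0, b_eff = NULL) {
  b_eff <- b_eff %||% (params$omega * params$b)
  disc <- (5 - b_eff)^2 - 4 * 0.04 * (140 + I)
  if (disc < 0) return(NA_real_)
  (-(5 - b_eff) + sqrt(disc)) / (2 * 0.04)
}

#' One explicit-Euler step of the Izhikevich unit
#'
#' Vectorized over units. The recovery update uses the pre-update membrane
#' potential; the reset is applied after the update when v crosses
#' \code{v_peak}.
#'
#' @param v,u current membrane and recovery values (vectors).
#' @param I input current (scalar or vector).
#' @param b_plus effective sensitivity (scalar or vector), see
#'   \code{\link{sensitivity_modulation}}.
#' @param dt time step (> 0).
#' @param params an \code{\link{izhikevich_params}}.
#' @return \code{list(v, u, spiked)} with \code{spiked} logical.
#' @export
izhikevich_step <- function(v, u, I, b_plus, dt, params) {
  if (dt <= 0) stop_config("dt must be > 0")
  v1 <- v + dt * (0.04 * v * v + 5 * v + 140 - u + I)
  u1 <- u + dt * (params$a * (b_plus * v - u))
  if (any(!is.finite(v1)) || any(!is.finite(u1)))
    stop(sprintf("non-finite state in izhikevich_step (v range [%g, %g])",
                 min(v), max(v)), call. = FALSE)
  spiked <- v1 >= params$v_peak
  v1[spiked] <- params$c_reset
  u1[spiked] <- u1[spiked] + params$d
  list(v = v1, u = u1, spiked = spiked)
}

#' Sliding-window activity drive
#'
#' The cumulative effect of recent membrane activity over the last
#' \code{tau} time units. History shorter than the window contributes only
#' its available samples (missing early samples contribute zero drive,
#' matching the simulators' start-up behavior).
#'
#' @param v_history numeric vector of per-step membrane values (most recent
#'   last); for mode \code{"spike_count"}, a 0/1 per-step spike indicator.
#' @param tau window length.
#' @param dt step size.
#' @param mode \code{"raw"}, \code{"rectified"} or \code{"spike_count"}.
#' @param v_rest rectification reference (the simulators pass the
#'   spike-threshold potential; the default is the nominal resting
#'   potential -70).
#' @return Scalar drive value.
#' @export
sliding_window_drive <- function(v_history, tau, dt,
                                 mode = c("rectified", "raw", "spike_count"),
                                 v_rest = -70) {
  mode <- match.arg(mode)
  L <- max(1L, round(tau / dt))
  h <- if (length(v_history) >= L)
    v_history[(length(v_history) - L + 1L):length(v_history)]
  else v_history
  switch(mode,
         raw = sum(h) * dt,
         rectified = sum(pmax(h - v_rest, 0)) * dt,
         spike_count = sum(h))
}

#' One explicit-Euler step of the metabolic pools
#'
#' @param g,m glycogen and ATP levels (vectors allowed).
#' @param drive activity drive feeding the glycogen pool.
#' @param dt time step.
#' @param met a \code{\link{metabolic_params}}.
#' @return \code{list(g, m)}, clamped to the pool capacities.
#' @export
metabolic_step <- function(g, m, drive, dt, met) {
  psi1 <- met$k_g * g * (1 - m / met$m_max)
  psi2 <- met$k_m * m
  g1 <- clamp(g + dt * (-psi1 + met$kappa * drive), 0, met$g_max)
  m1 <- clamp(m + dt * (-psi2 + psi1), 0, met$m_max)
  list(g = g1, m = m1)
}

#' Population wiring and input configuration
#'
#' @param n neuron count.
#' @param coupling \code{"all_to_all"} or \code{"erdos_renyi"}.
#' @param p_connect connection probability for \code{"erdos_renyi"}.
#' @param w synaptic weight; each neuron receives \code{w/n} times the sum
#'   of presynaptic exponential spike traces (self-connections excluded).
#' @param syn_tau synaptic trace decay time.
#' @param I_dc baseline current.
#' @param sigma_noise white-noise current amplitude (the membrane receives
#'   \code{sigma_noise * sqrt(dt) * xi} per step).
#' @param shared_glycogen one glycogen pool for the population (TRUE,
#'   default: astrocytes service many synapses) or one per neuron.
#' @return Object of class \code{"population_config"}.
#' @export
population_config <- function(n = 50L, coupling = c("all_to_all", "erdos_renyi"),
                              p_connect = 0.2, w = 5, syn_tau = 5, I_dc = 0,
                              sigma_noise = 0.2, shared_glycogen = TRUE) {
  coupling <- match.arg(coupling)
  if (n < 1) stop_config("n must be >= 1")
  check_scalar_number(w, "w")
  check_scalar_number(sigma_noise, "sigma_noise", lo = 0)
  structure(list(n = as.integer(n), coupling = coupling,
                 p_connect = p_connect, w = w, syn_tau = syn_tau,
                 I_dc = I_dc, sigma_noise = sigma_noise,
                 shared_glycogen = isTRUE(shared_glycogen)),
            class = "population_config")
}

## core integrator shared by simulate_unit and simulate_population.
## Per-step order: drive (from history up to t) -> metabolic step -> b+
## from the new m -> Izhikevich step; post-step membrane values (pre-reset,
## so the spike upstroke is seen by the drive) enter the history buffer.
can_engine <- function(n, params, met, T, dt, I_fn, config, init, seed) {
  if (T <= 0) stop_config("T must be > 0")
  if (dt <= 0) stop_config("dt must be > 0")
  set.seed(seed)
  steps <- as.integer(round(T / dt))
  v_rest <- izhikevich_rest(params)
  if (is.na(v_rest)) v_rest <- -70
  v_ref <- izhikevich_threshold(params)       # drive rectification reference
  if (is.na(v_ref)) v_ref <- -50

  ## wiring
  W <- NULL
  if (n > 1L && config$w != 0) {
    if (config$coupling == "all_to_all") {
      W <- matrix(config$w / n, n, n); diag(W) <- 0
    } else {
      A <- matrix(stats::runif(n * n) < config$p_connect, n, n)
      diag(A) <- FALSE
      W <- (config$w / n) * A
    }
  } else if (n > 1L) {
    if (config$coupling == "erdos_renyi") invisible(stats::runif(n * n))
  }

  ## initial state
  v <- init$v %||% {
    if (n > 1L) v_rest + stats::runif(n, -2, 2) else rep(v_rest, n)
  }
  b_eff0 <- sensitivity_modulation(params, pmax(init$m %||% rep(0, n), 0))
  u <- init$u %||% (b_eff0 * v)
  g <- init$g %||% (if (config$shared_glycogen) 0 else rep(0, n))
  m <- init$m %||% rep(0, n)
  if (config$shared_glycogen && length(g) != 1L) g <- mean(g)

  ## rolling drive buffer
  L <- max(1L, as.integer(round(met$tau / dt)))
  buf <- matrix(0, n, L)
  S <- rep(0, n)
  pos <- 1L
  drive_scale <- if (met$drive_mode == "spike_count") 1 else dt

  ## recording
  rec_every <- max(1L, as.integer(round(1 / dt)))   # ~1 time-unit resolution
  n_rec <- steps %/% rec_every
  rec <- list(t = numeric(n_rec), v = numeric(n_rec), u = numeric(n_rec),
              g = numeric(n_rec), m = numeric(n_rec))
  sp_id <- vector("list", steps); sp_t <- vector("list", steps)
  syn <- rep(0, n)
  decay <- 1 - dt / config$syn_tau
  if (decay < 0) stop_config("dt must not exceed syn_tau")
  ri <- 0L

  for (s in seq_len(steps)) {
    t_now <- (s - 1) * dt
    drive <- S * drive_scale

    ## metabolic update (shared glycogen pool: population-mean fluxes)
    psi1 <- met$k_g * g * (1 - m / met$m_max)     # length n (g scalar recycles)
    if (config$shared_glycogen) {
      g <- clamp(g + dt * (-mean(psi1) + met$kappa * mean(drive)), 0, met$g_max)
    } else {
      g <- clamp(g + dt * (-psi1 + met$kappa * drive), 0, met$g_max)
    }
    m <- clamp(m + dt * (-met$k_m * m + psi1), 0, met$m_max)

    b_plus <- sensitivity_modulation(params, m)

    I <- rep(I_fn(t_now) + config$I_dc, length.out = n)
    if (!is.null(W)) I <- I + as.numeric(W %*% syn)
    if (config$sigma_noise > 0)
      I <- I + config$sigma_noise * stats::rnorm(n) / sqrt(dt)

    st <- izhikevich_step(v, u, I, b_plus, dt, params)
    v_pre <- v + dt * (0.04 * v * v + 5 * v + 140 - u + I)  # pre-reset value
    v <- st$v; u <- st$u

    if (any(st$spiked)) {
      ids <- which(st$spiked)
      sp_id[[s]] <- ids; sp_t[[s]] <- rep(s * dt, length(ids))
      syn[ids] <- syn[ids] + 1
    }
    syn <- syn * decay

    ## push membrane history (capped at v_peak so one sample carries the
    ## spike upstroke without Euler overshoot)
    contrib <- switch(met$drive_mode,
                      rectified = pmax(pmin(v_pre, params$v_peak) - v_ref, 0),
                      raw = pmin(v_pre, params$v_peak),
                      spike_count = as.numeric(st$spiked))
    S <- S - buf[, pos] + contrib
    buf[, pos] <- contrib
    pos <- if (pos == L) 1L else pos + 1L

    if (s %% rec_every == 0L) {
      ri <- ri + 1L
      rec$t[ri] <- s * dt
      rec$v[ri] <- mean(v); rec$u[ri] <- mean(u)
      rec$g[ri] <- mean(g); rec$m[ri] <- mean(m)
    }
  }

  spikes <- data.frame(neuron_id = unlist(sp_id) %||% integer(0),
                       time = unlist(sp_t) %||% numeric(0))
  structure(list(n = n, T = T, dt = dt, t = rec$t,
                 v = rec$v, u = rec$u, g = rec$g, m = rec$m,
                 spikes = spikes,
                 final = list(v = v, u = u, g = g, m = m,
                              syn = syn, buf = buf, pos = pos, S = S),
                 params = params, met = met, config = config, seed = seed,
                 v_rest = v_rest),
            class = "can_sim")
}

#' Simulate a single CAN unit
#'
#' Full coupled integration of the spiking and metabolic subsystems. The
#' per-step order is: activity drive from the membrane history, metabolic
#' update, effective sensitivity from the new ATP level, Izhikevich update.
#'
#' @param params an \code{\link{izhikevich_params}}.
#' @param met a \code{\link{metabolic_params}}.
#' @param T total time.
#' @param dt step size (default 0.1).
#' @param I_fn input current: a constant or a function of time.
#' @param seed RNG seed.
#' @param init optional named list overriding initial \code{v, u, g, m}.
#' @return Object of class \code{"can_sim"}: recorded traces \code{t, v, u,
#'   g, m}, spike table \code{spikes}, and the final state.
#' @export
simulate_unit <- function(params = izhikevich_params(),
                          met = metabolic_params(), T = 1000, dt = 0.1,
                          I_fn = 0, seed = 0L, init = NULL) {
  if (!is.function(I_fn)) { I_const <- I_fn; I_fn <- function(t) I_const }
  cfg <- population_config(n = 1L, w = 0, sigma_noise = 0, I_dc = 0)
  can_engine(1L, params, met, T, dt, I_fn, cfg, init %||% list(), seed)
}

#' Simulate a coupled CAN population
#'
#' Neurons interact through current-based exponential synaptic traces
#' (weight \code{w/n}, self-connections excluded); the metabolic pools are
#' shared (one glycogen pool, per-neuron ATP) or per-neuron according to
#' the configuration. With \code{n = 1} this reduces exactly to
#' \code{\link{simulate_unit}}.
#'
#' @param config a \code{\link{population_config}}.
#' @param params an \code{\link{izhikevich_params}}.
#' @param met a \code{\link{metabolic_params}}.
#' @param T total time.
#' @param dt step size.
#' @param seed RNG seed (initial jitter, wiring, current noise).
#' @param init optional named list overriding initial \code{v, u, g, m}.
#' @param I_fn optional additional input current (constant or function of
#'   time), added to \code{config$I_dc}.
#' @return Object of class \code{"can_sim"}.
#' @export
simulate_population <- function(config = population_config(),
                                params = izhikevich_params(),
                                met = metabolic_params(), T = 1000, dt = 0.1,
                                seed = 0L, init = NULL, I_fn = 0) {
  if (!is.function(I_fn)) { I_const <- I_fn; I_fn <- function(t) I_const }
  can_engine(config$n, params, met, T, dt, I_fn, config, init %||% list(), seed)
}

#' @export
print.can_sim <- function(x, ...) {
  cat(sprintf("can_sim: n = %d, T = %g, dt = %g, %d spikes (%.2f Hz/unit)\n",
              x$n, x$T, x$dt, nrow(x$spikes),
              1000 * nrow(x$spikes) / (x$n * x$T)))
  cat(sprintf("  final mean m = %.3f, g = %.3f\n",
              mean(x$final$m), mean(x$final$g)))
  invisible(x)
}

#' Extract the spike raster from a simulation
#'
#' @param sim a \code{"can_sim"} object.
#' @return Object of class \code{"spike_raster"}: spike events sorted by
#'   time, with \code{n}, \code{duration}, \code{dt}.
#' @export
as_spike_raster <- function(sim) {
  sp <- sim$spikes[order(sim$spikes$time, sim$spikes$neuron_id), , drop = FALSE]
  rownames(sp) <- NULL
  structure(list(spikes = sp, n = sim$n, duration = sim$T, dt = sim$dt),
            class = "spike_raster")
}

#' Construct a spike raster from event vectors
#' @param neuron_id integer neuron indices (1-based).
#' @param time spike times in \code{[0, duration]}.
#' @param n neuron count.
#' @param duration total duration.
#' @param dt native step size of the generating simulation.
#' @export
spike_raster <- function(neuron_id, time, n, duration, dt = 0.1) {
  if (length(neuron_id) != length(time)) stop_config("length mismatch")
  if (length(time) && (min(time) < 0 || max(time) > duration))
    stop_config("spike times outside [0, duration]")
  o <- order(time, neuron_id)
  structure(list(spikes = data.frame(neuron_id = as.integer(neuron_id[o]),
                                     time = time[o]),
                 n = as.integer(n), duration = duration, dt = dt),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike_raster: %d neurons, %g time units, %d spikes\n",
              x$n, x$duration, nrow(x$spikes)))
  invisible(x)
}

#' Raster plot
#' @param x a \code{"spike_raster"}.
#' @param ... passed to \code{plot}.
#' @export
plot.spike_raster <- function(x, ...) {
  graphics::plot(x$spikes$time, x$spikes$neuron_id, pch = ".", cex = 2,
                 xlab = "time", ylab = "neuron", ...)
  invisible(x)
}

#' Export a raster as CSV (neuron_id, spike_time)
#' @param raster a \code{"spike_raster"}.
#' @param path output file.
#' @export
write_raster_csv <- function(raster, path) {
  df <- data.frame(neuron_id = raster$spikes$neuron_id,
                   spike_time_ms = raster$spikes$time)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export population traces as CSV (t, v, g, m)
#' @param sim a \code{"can_sim"}.
#' @param path output file.
#' @export
write_traces_csv <- function(sim, path) {
  df <- data.frame(t = sim$t, v_mean = sim$v, g_mean = sim$g, m_mean = sim$m)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
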