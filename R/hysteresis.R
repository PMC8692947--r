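## Hysteresis sweeps and cusp-bifurcation scans over the CAN population.
##
## A sweep walks a control parameter up and then back down over the same
## grid, carrying the dynamical state across steps; path-dependent branch
## separation (bistability) shows up as a nonzero loop area between the
## up and down branches.

## set `name` in whichever of config/params/met owns that field
set_swept_param <- function(name, value, config, params, met) {
  if (name %in% names(config)) config[[name]] <- value
  else if (name %in% names(params)) params[[name]] <- value
  else if (name %in% names(met)) met[[name]] <- value
  else stop_config(sprintf("unknown sweep parameter '%s'", name))
  list(config = config, params = params, met = met)
}

## mean and sd of the order parameter over the tail of a simulation
## segment; phases are extracted within the measurement window only, so
## neurons silent in the window carry no (spurious) phase
segment_R <- function(sim, measure_frac = 0.5, kernel_width = 5, bin = 1) {
  raster <- as_spike_raster(sim)
  tr <- smoothed_activity(raster, kernel_width = kernel_width, dt = bin)
  if (nrow(tr) < 2L) return(c(mean = 0, sd = 0))
  tt <- attr(tr, "t")
  keep <- tt >= (1 - measure_frac) * sim$T
  win <- tr[, keep, drop = FALSE]
  attr(win, "t") <- tt[keep]
  st <- order_parameter(win, dt = bin)
  c(mean = mean(st$R), sd = stats::sd(st$R))
}

## default simulator closure for hysteresis_sweep: one CAN population
## segment per parameter value, state carried over between segments
can_sweep_simulator <- function(param_name, config, params, met, dwell, dt,
                                measure_frac = 0.5) {
  function(value, state, seed) {
    obj <- set_swept_param(param_name, value, config, params, met)
    init <- if (is.null(state)) list()
            else list(v = state$v, u = state$u, g = state$g, m = state$m)
    sim <- simulate_population(obj$config, obj$params, obj$met,
                               T = dwell, dt = dt, seed = seed, init = init)
    r <- segment_R(sim, measure_frac)
    list(R = unname(r["mean"]), sd = unname(r["sd"]), state = sim$final)
  }
}

#' Hysteresis sweep of a control parameter (up then down)
#'
#' At each parameter value the system is simulated for one dwell segment
#' with the state carried over from the previous segment; the windowed
#' mean synchrony R is recorded. The sweep ascends \code{values} and then
#' descends the same grid. The bistable interval is where the up and down
#' branches separate by more than \code{delta_min}; the loop area is
#' \code{integral |R_up - R_down| d(param)}.
#'
#' @param param_name name of the swept field (looked up in the population
#'   config, the Izhikevich parameters, then the metabolic parameters);
#'   ignored when \code{simulate_fn} is supplied.
#' @param values ascending parameter grid.
#' @param config,params,met CAN population setup (defaults used when
#'   \code{simulate_fn} is NULL).
#' @param dwell simulated time per parameter step.
#' @param dt integrator step.
#' @param seed master seed; each segment uses a derived per-segment seed,
#'   so identical calls give identical curves.
#' @param delta_min branch-separation threshold defining bistability.
#' @param simulate_fn optional replacement system:
#'   \code{function(value, state, seed) -> list(R, state)} (e.g. a
#'   surrogate bistable map for validating the sweep machinery).
#' @return Object of class \code{"hysteresis_curve"}: \code{branches}
#'   data.frame (param_value, branch, mean_R, sd_R), \code{bistable_interval}
#'   (length-2 or NULL), \code{loop_area}.
#' @export
hysteresis_sweep <- function(param_name = "I_dc", values,
                             config = population_config(),
                             params = izhikevich_params(beta = 0.25),
                             met = metabolic_params(),
                             dwell = 600, dt = 0.2, seed = 0L,
                             delta_min = 0.2, simulate_fn = NULL) {
  if (is.unsorted(values)) stop_config("values must be ascending")
  if (is.null(simulate_fn))
    simulate_fn <- can_sweep_simulator(param_name, config, params, met,
                                       dwell, dt)
  nv <- length(values)
  path <- c(values, rev(values))
  branch <- rep(c("up", "down"), each = nv)
  R <- numeric(2L * nv); sdv <- rep(NA_real_, 2L * nv)
  state <- NULL
  for (i in seq_along(path)) {
    res <- simulate_fn(path[i], state, seed + i)
    R[i] <- res$R
    if (!is.null(res$sd)) sdv[i] <- res$sd
    state <- res$state
  }
  up <- R[seq_len(nv)]
  down <- rev(R[nv + seq_len(nv)])          # re-align on ascending grid
  sep <- abs(up - down)
  bist <- values[sep > delta_min]
  interval <- if (length(bist)) range(bist) else NULL
  area <- if (nv > 1L) trapz(values, sep) else 0

  structure(list(branches = data.frame(param_value = path, branch = branch,
                                       mean_R = R, sd_R = sdv),
                 values = values, up = up, down = down,
                 bistable_interval = interval, loop_area = area,
                 param_name = param_name, delta_min = delta_min, seed = seed),
            class = "hysteresis_curve")
}

#' @export
print.hysteresis_curve <- function(x, ...) {
  cat(sprintf("hysteresis_curve over '%s' (%d values)\n",
              x$param_name, length(x$values)))
  cat(sprintf("  loop area = %.4f; bistable interval: %s\n", x$loop_area,
              if (is.null(x$bistable_interval)) "none"
              else sprintf("[%g, %g]", x$bistable_interval[1],
                           x$bistable_interval[2])))
  invisible(x)
}

#' @export
plot.hysteresis_curve <- function(x, ...) {
  graphics::plot(x$values, x$up, type = "b", pch = 24, ylim = c(0, 1),
                 xlab = x$param_name, ylab = "mean R", ...)
  graphics::lines(x$values, x$down, type = "b", pch = 25)
  graphics::legend("topleft", legend = c("up", "down"), pch = c(24, 25),
                   bty = "n")
  invisible(x)
}

#' Export a hysteresis curve as CSV
#' @param curve a \code{\link{hysteresis_sweep}} result.
#' @param path output file.
#' @export
write_hysteresis_csv <- function(curve, path) {
  utils::write.csv(curve$branches, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Surrogate hysteretic system for validating the sweep machinery
#'
#' A deterministic two-state relay: the internal state switches on when
#' the parameter exceeds \code{theta_on} and off when it drops below
#' \code{theta_off}, so the true bistable interval is
#' \code{[theta_off, theta_on]}.
#'
#' @param theta_off,theta_on switching thresholds (off < on).
#' @param R_low,R_high reported synchrony in the two states.
#' @return A \code{simulate_fn} closure for \code{\link{hysteresis_sweep}}.
#' @export
make_bistable_surrogate <- function(theta_off = 0.3, theta_on = 0.7,
                                    R_low = 0.1, R_high = 0.9) {
  if (theta_off >= theta_on) stop_config("theta_off must be < theta_on")
  function(value, state, seed) {
    s <- state %||% 0
    if (value > theta_on) s <- 1
    else if (value < theta_off) s <- 0
    list(R = if (s == 1) R_high else R_low, sd = 0, state = s)
  }
}

#' Cusp scan: monostable vs. bistable over the (kappa, beta) gain plane
#'
#' For every cell of the forward-gain (kappa: spiking -> metabolism) by
#' feedback-gain (beta: metabolism -> spiking) grid, the population is run
#' once from a metabolically primed, high-synchrony initial condition and
#' once from a depleted, low-synchrony one; the cell is classified
#' bistable when the long-run mean R of the two runs differs by more than
#' \code{delta_min}.
#'
#' @param kappa_grid,beta_grid nonempty gain grids.
#' @param config,params,met CAN population setup (the \code{kappa} and
#'   \code{beta} fields are overridden per cell).
#' @param T simulated time per run.
#' @param dt integrator step.
#' @param seed RNG seed (same derived seed pair for every cell).
#' @param delta_min classification threshold on the R difference.
#' @param measure_frac trailing fraction of the run used for the long-run
#'   mean.
#' @return data.frame (kappa, beta, R_high_ic, R_low_ic, class).
#' @export
cusp_scan <- function(kappa_grid, beta_grid,
                      config = population_config(),
                      params = izhikevich_params(),
                      met = metabolic_params(),
                      T = 1200, dt = 0.2, seed = 0L,
                      delta_min = 0.2, measure_frac = 1/3) {
  if (!length(kappa_grid) || !length(beta_grid))
    stop_config("grids must be nonempty")
  cells <- expand.grid(kappa = kappa_grid, beta = beta_grid,
                       KEEP.OUT.ATTRS = FALSE)
  n <- config$n
  run_ic <- function(kappa, beta, init, s) {
    p <- params; p$beta <- beta
    mm <- met; mm$kappa <- kappa
    sim <- simulate_population(config, p, mm, T = T, dt = dt, seed = s,
                               init = init)
    segment_R(sim, measure_frac)["mean"]
  }
  ## prime the ATP pool only: with no forward gain (kappa = 0) nothing
  ## replenishes it, so the high state can persist only through the loop
  hi_init <- list(m = rep(0.9 * met$m_max, n), g = 0)
  lo_init <- list(m = rep(0, n), g = 0)
  R_hi <- R_lo <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    R_hi[i] <- run_ic(cells$kappa[i], cells$beta[i], hi_init, seed + 1L)
    R_lo[i] <- run_ic(cells$kappa[i], cells$beta[i], lo_init, seed + 2L)
  }
  data.frame(kappa = cells$kappa, beta = cells$beta,
             R_high_ic = R_hi, R_low_ic = R_lo,
             class = ifelse(abs(R_hi - R_lo) > delta_min,
                            "bistable", "monostable"))
}

#' Export a cusp scan as CSV
#' @param scan a \code{\link{cusp_scan}} result.
#' @param path output file.
#' @export
write_cusp_csv <- function(scan, path) {
  utils::write.csv(scan, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
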