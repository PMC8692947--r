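## Synchrony quantification: smoothed spike-train activity, analytic-signal
## phases, Kuramoto-style order parameter, hysteretic two-state labeling
## and dwell-time statistics.

#' Gaussian-smoothed per-neuron activity traces
#'
#' Each spike train is binned at \code{dt} and convolved with a unit-mass
#' Gaussian kernel (support +/- 4 SD), so an isolated spike integrates to
#' 1 over time.
#'
#' @param raster a \code{\link{spike_raster}}.
#' @param kernel_width Gaussian SD in time units (> 0).
#' @param dt output sampling interval.
#' @return Matrix (neurons x time bins) of smoothed rates; attribute
#'   \code{"t"} holds the bin centers.
#' @export
smoothed_activity <- function(raster, kernel_width = 5, dt = 1) {
  if (kernel_width <= 0) stop_config("kernel_width must be > 0")
  nb <- max(1L, as.integer(ceiling(raster$duration / dt)))
  tt <- (seq_len(nb) - 0.5) * dt
  half <- as.integer(ceiling(4 * kernel_width / dt))
  kern <- stats::dnorm(seq(-half, half) * dt, sd = kernel_width)
  kern <- kern / (sum(kern) * dt)           # unit mass after * dt
  out <- matrix(0, raster$n, nb)
  if (nrow(raster$spikes)) {
    bin <- pmin(nb, pmax(1L, as.integer(ceiling(raster$spikes$time / dt))))
    for (i in seq_len(raster$n)) {
      b <- bin[raster$spikes$neuron_id == i]
      if (!length(b)) next
      counts <- tabulate(b, nbins = nb)
      sm <- stats::convolve(counts, rev(kern), type = "open")
      out[i, ] <- sm[(half + 1L):(half + nb)]
    }
  }
  attr(out, "t") <- tt
  attr(out, "dt") <- dt
  out
}

## analytic signal via the FFT construction: zero the negative frequencies,
## double the positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Kuramoto-style synchrony order parameter from activity traces
#'
#' Each trace is mean-subtracted, its instantaneous phase extracted from
#' the analytic signal, and \code{R(t) = |mean_j exp(i phi_j(t))|}.
#' Zero-variance traces have no defined phase and are excluded; if fewer
#' than 2 informative traces remain, R is reported as 0 with the
#' \code{degenerate} flag set.
#'
#' @param traces matrix (neurons x time) of activity traces (>= 2 rows).
#' @param dt sampling interval of the traces.
#' @return Object of class \code{"synchrony_trace"}: \code{t}, \code{R} in
#'   \code{[0, 1]}, \code{method}, \code{degenerate}, \code{n_used}.
#' @export
order_parameter <- function(traces, dt = 1) {
  if (!is.matrix(traces) || nrow(traces) < 2L)
    stop_config("traces must be a matrix with >= 2 rows")
  tt <- attr(traces, "t") %||% ((seq_len(ncol(traces)) - 0.5) * dt)
  sds <- apply(traces, 1L, stats::sd)
  ok <- which(sds > 1e-12)
  if (length(ok) < 2L) {
    return(structure(list(t = tt, R = rep(0, ncol(traces)),
                          method = "analytic_phase", degenerate = TRUE,
                          n_used = length(ok)),
                     class = "synchrony_trace"))
  }
  z <- matrix(0i, length(ok), ncol(traces))
  for (r in seq_along(ok)) {
    a <- analytic_signal(traces[ok[r], ] - mean(traces[ok[r], ]))
    z[r, ] <- a / pmax(Mod(a), 1e-300)      # unit phasors
  }
  R <- Mod(colMeans(z))
  structure(list(t = tt, R = clamp(R, 0, 1), method = "analytic_phase",
                 degenerate = FALSE, n_used = length(ok)),
            class = "synchrony_trace")
}

#' @export
print.synchrony_trace <- function(x, ...) {
  cat(sprintf("synchrony_trace: %d samples, mean R = %.3f%s\n",
              length(x$R), mean(x$R),
              if (x$degenerate) " (degenerate: constant traces)" else ""))
  invisible(x)
}

#' Spike-coincidence synchrony (cross-check metric)
#'
#' Mean pairwise Pearson correlation of binned spike counts; an
#' alternative to the phase-based order parameter.
#'
#' @param raster a \code{\link{spike_raster}}.
#' @param bin bin width.
#' @return Scalar in \code{[-1, 1]} (0 when undefined).
#' @export
spike_coincidence <- function(raster, bin = 5) {
  nb <- max(2L, as.integer(ceiling(raster$duration / bin)))
  M <- matrix(0, raster$n, nb)
  if (nrow(raster$spikes)) {
    b <- pmin(nb, pmax(1L, as.integer(ceiling(raster$spikes$time / bin))))
    for (i in seq_len(raster$n))
      M[i, ] <- tabulate(b[raster$spikes$neuron_id == i], nbins = nb)
  }
  keep <- apply(M, 1L, stats::sd) > 0
  if (sum(keep) < 2L) return(0)
  cc <- stats::cor(t(M[keep, , drop = FALSE]))
  mean(cc[lower.tri(cc)])
}

#' Hysteretic (Schmitt-trigger) high/low state labeling
#'
#' The label switches to \code{high} only when R rises above
#' \code{theta_hi} and back to \code{low} only when it falls below
#' \code{theta_lo}, suppressing chatter inside the deadband. The initial
#' label compares the first sample to the threshold midpoint.
#'
#' @param R a \code{"synchrony_trace"} or numeric vector of order-parameter
#'   values.
#' @param theta_hi,theta_lo switching thresholds in \code{[0, 1]} with
#'   \code{theta_lo < theta_hi}.
#' @return Object of class \code{"state_labels"}: factor \code{labels}
#'   (levels low, high), thresholds, \code{dt} if known.
#' @export
classify_states <- function(R, theta_hi = 0.6, theta_lo = 0.3) {
  dt <- NA_real_
  if (inherits(R, "synchrony_trace")) {
    if (length(R$t) > 1L) dt <- diff(R$t[1:2])
    R <- R$R
  }
  if (theta_lo >= theta_hi) stop_config("theta_lo must be < theta_hi")
  if (theta_lo < 0 || theta_hi > 1) stop_config("thresholds must lie in [0, 1]")
  n <- length(R)
  lab <- character(n)
  cur <- if (R[1] >= (theta_hi + theta_lo) / 2) "high" else "low"
  for (i in seq_len(n)) {
    if (cur == "low" && R[i] > theta_hi) cur <- "high"
    else if (cur == "high" && R[i] < theta_lo) cur <- "low"
    lab[i] <- cur
  }
  structure(list(labels = factor(lab, levels = c("low", "high")),
                 theta_hi = theta_hi, theta_lo = theta_lo, dt = dt),
            class = "state_labels")
}

#' Dwell-time statistics of a two-state label sequence
#'
#' Contiguous-run statistics; the first and last runs are truncated by the
#' trace ends and flagged as censored (they are excluded from the mean and
#' median dwell estimates).
#'
#' @param labels a \code{\link{classify_states}} result or a factor/character
#'   vector of labels.
#' @param dt sample spacing (time units per label).
#' @return Object of class \code{"dwell_summary"}: per-state mean/median
#'   dwell, \code{n_transitions}, \code{runs} data.frame (state, length,
#'   censored).
#' @export
dwell_times <- function(labels, dt = 1) {
  if (inherits(labels, "state_labels")) {
    if (!is.na(labels$dt)) dt <- labels$dt
    labels <- labels$labels
  }
  labels <- as.character(labels)
  if (!length(labels)) stop_config("labels must be nonempty")
  r <- rle(labels)
  k <- length(r$lengths)
  censored <- seq_len(k) %in% c(1L, k)
  runs <- data.frame(state = r$values, length = r$lengths,
                     dwell = r$lengths * dt, censored = censored)
  states <- unique(r$values)
  stat <- function(st, f) {
    x <- runs$dwell[runs$state == st & !runs$censored]
    if (length(x)) f(x) else NA_real_
  }
  summ <- data.frame(state = states,
                     mean_dwell = vapply(states, stat, numeric(1), f = mean),
                     median_dwell = vapply(states, stat, numeric(1),
                                           f = stats::median),
                     n_complete = vapply(states, function(st)
                       sum(runs$state == st & !runs$censored), numeric(1)))
  structure(list(summary = summ, n_transitions = k - 1L, runs = runs,
                 dt = dt),
            class = "dwell_summary")
}

#' @export
print.dwell_summary <- function(x, ...) {
  cat(sprintf("dwell_summary: %d transitions\n", x$n_transitions))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
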