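## Annealed mean-field description of the activation process.
##
## Each vertex has 4 short neighbors plus a Poisson(lambda) number of long
## neighbors; in the mean-field approximation every neighbor is active
## independently with the current global density rho, giving the 1-D map
##   F(rho) = E_{J ~ Pois(lambda)} P(Binom(4 + J, rho) >= k).
## The critical initial density p_c is the interior unstable fixed point of
## F (the basin boundary between extinction and full activation).

#' Mean-field model for the threshold activation process
#'
#' @param lambda expected long-edge degree per vertex (>= 0).
#' @param k activation threshold (positive integer).
#' @param tail_mass Poisson truncation: the map is computed over degrees
#'   \code{0 .. j_max} where the truncated tail mass is below this value,
#'   and renormalized.
#' @return Object of class \code{"meanfield_model"} with fields
#'   \code{lambda}, \code{k}, \code{j_max}, \code{weights}.
#' @export
meanfield_model <- function(lambda, k, tail_mass = 1e-12) {
  check_scalar_number(lambda, "lambda", lo = 0)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop_config("k must be a positive integer")
  j_max <- 0L
  while (stats::ppois(j_max, lambda, lower.tail = FALSE) >= tail_mass)
    j_max <- j_max + 1L
  w <- stats::dpois(0:j_max, lambda)
  w <- w / sum(w)
  structure(list(lambda = lambda, k = as.integer(k), j_max = j_max,
                 weights = w),
            class = "meanfield_model")
}

#' The mean-field density map F(rho)
#'
#' @param rho density value(s) in \code{[0, 1]}; vectorized.
#' @param model a \code{\link{meanfield_model}}.
#' @return \code{F(rho)}, same length as \code{rho}.
#' @export
mean_field_map <- function(rho, model) {
  if (any(rho < 0 | rho > 1)) stop_config("rho must be in [0, 1]")
  js <- 0:model$j_max
  ## rows: j, cols: rho; P(Bin(4 + j, rho) >= k)
  tail <- vapply(rho, function(r)
    stats::pbinom(model$k - 1L, 4L + js, r, lower.tail = FALSE),
    numeric(length(js)))
  as.numeric(crossprod(model$weights, matrix(tail, nrow = length(js))))
}

#' Fixed points and stability of the mean-field map
#'
#' Roots of \code{F(rho) - rho} on \code{[0, 1]} are located by a
#' sign-change scan over a dense grid followed by bisection
#' (\code{uniroot}) to tolerance \code{tol}. Stability is a slope test:
#' a fixed point is stable when \code{|F'(rho*)| < 1} (finite differences,
#' one-sided at the boundary). \code{p_c} is the smallest interior unstable
#' fixed point; when no interior unstable point exists, the sentinel is 0
#' (F above the diagonal throughout: any positive density activates) or 1
#' (F below: activity always dies).
#'
#' @param model a \code{\link{meanfield_model}}.
#' @param tol root tolerance (default 1e-8).
#' @param grid_n scan resolution.
#' @return Object of class \code{"meanfield_solution"}: data.frame
#'   \code{fixed_points} (rho, stability), \code{p_c}, \code{flag}.
#' @export
fixed_points <- function(model, tol = 1e-8, grid_n = 4001L) {
  if (tol <= 0) stop_config("tol must be > 0")
  grid <- seq(0, 1, length.out = grid_n)
  g <- mean_field_map(grid, model) - grid
  roots <- grid[g == 0]
  sc <- which(g[-1] * g[-grid_n] < 0)
  for (s in sc) {
    r <- stats::uniroot(function(x) mean_field_map(x, model) - x,
                        c(grid[s], grid[s + 1L]), tol = tol)$root
    roots <- c(roots, r)
  }
  roots <- sort(unique(round(roots / tol) * tol))
  roots <- clamp(roots, 0, 1)
  ## merge near-duplicates
  if (length(roots) > 1L)
    roots <- roots[c(TRUE, diff(roots) > 10 * tol)]

  h <- 1e-6
  slope <- vapply(roots, function(r) {
    lo <- max(0, r - h); hi <- min(1, r + h)
    (mean_field_map(hi, model) - mean_field_map(lo, model)) / (hi - lo)
  }, numeric(1))
  stability <- ifelse(abs(slope) < 1, "stable", "unstable")

  interior <- roots > tol & roots < 1 - tol
  unstable_int <- roots[interior & stability == "unstable"]
  flag <- "ok"
  if (length(unstable_int) >= 1L) {
    p_c <- min(unstable_int)
    if (length(unstable_int) > 1L) flag <- "multiple_unstable"
  } else {
    ## no interior basin boundary: the map is one-sided of the diagonal
    mid <- mean_field_map(0.5, model) - 0.5
    above <- if (any(interior)) {
      ## interior stable point(s) but no unstable: classify by behavior near 0
      mean_field_map(tol, model) > tol
    } else mid > 0
    p_c <- if (above) 0 else 1
    flag <- "no_interior_unstable"
  }

  structure(list(fixed_points = data.frame(rho = roots, stability = stability,
                                           slope = slope),
                 p_c = p_c, flag = flag, model = model),
            class = "meanfield_solution")
}

#' @export
print.meanfield_solution <- function(x, ...) {
  cat(sprintf("meanfield_solution: lambda = %g, k = %d\n",
              x$model$lambda, x$model$k))
  print(x$fixed_points, row.names = FALSE)
  cat(sprintf("  p_c = %.6f (%s)\n", x$p_c, x$flag))
  invisible(x)
}

#' Critical initial activation density p_c(lambda, k)
#'
#' @inheritParams fixed_points
#' @return The critical density (0/1 sentinels when no interior unstable
#'   fixed point exists).
#' @export
critical_probability <- function(model, tol = 1e-8) {
  fixed_points(model, tol = tol)$p_c
}

#' Phase diagram p_c over a lambda grid for several thresholds k
#'
#' @param lambda_grid ascending lambda values.
#' @param k_values integer thresholds.
#' @param tol root tolerance.
#' @return data.frame with columns lambda, k, p_c, n_fixed_points, flag.
#' @export
phase_diagram <- function(lambda_grid, k_values, tol = 1e-8) {
  if (is.unsorted(lambda_grid)) stop_config("lambda_grid must be ascending")
  rows <- expand.grid(lambda = lambda_grid, k = k_values,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    sol <- fixed_points(meanfield_model(rows$lambda[i], rows$k[i]), tol = tol)
    data.frame(lambda = rows$lambda[i], k = rows$k[i], p_c = sol$p_c,
               n_fixed_points = nrow(sol$fixed_points), flag = sol$flag)
  })
  do.call(rbind, res)
}

#' Export a phase diagram as CSV
#' @param pd a \code{\link{phase_diagram}} result.
#' @param path output file.
#' @export
write_phase_diagram_csv <- function(pd, path) {
  utils::write.csv(pd, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Monte Carlo estimate of the critical initial density on a finite lattice
#'
#' Bisection on p0: at each probe, \code{reps} independent activation runs
#' are scored as successes when the final density reaches
#' \code{success_rho}; the estimate is the p0 at which the success fraction
#' crosses 1/2. The \code{reps} graphs are sampled once and reused across
#' probes (common random graphs across probes; fresh initial states per
#' probe). The confidence interval propagates the binomial probe
#' uncertainty through the local slope of the success curve (logit-free
#' linear fit over the recorded probes), floored at the final bisection
#' bracket.
#'
#' @param N lattice side length.
#' @param model a \code{\link{long_edge_model}}.
#' @param k activation threshold.
#' @param reps runs per probe (>= 10).
#' @param max_steps step cap per run.
#' @param tol bisection bracket width target.
#' @param seed master RNG seed.
#' @param success_rho final-density cutoff counted as full activation
#'   (0.99 tolerates small frozen voids on the finite lattice).
#' @param max_iter bisection budget; exceeding it flags non-convergence.
#' @return Object of class \code{"mc_critical"}: \code{estimate},
#'   \code{ci} (length 2), \code{converged}, \code{probes} data.frame.
#' @export
monte_carlo_critical <- function(N, model, k, reps = 20L, max_steps = 400L,
                                 tol = 0.01, seed = 0L, success_rho = 0.99,
                                 max_iter = 12L) {
  if (reps < 10) stop_config("reps must be >= 10")
  rule <- update_rule(k)
  set.seed(seed)
  gseeds <- sample.int(.Machine$integer.max, reps)
  rseeds <- sample.int(.Machine$integer.max, reps * max_iter)
  graphs <- lapply(gseeds, function(s) build_graph(N, model, seed = s))

  probe <- function(p0, it) {
    ok <- vapply(seq_len(reps), function(r) {
      tr <- run_dynamics(graphs[[r]], p0, rule, max_steps = max_steps,
                         seed = rseeds[(it - 1L) * reps + r])
      tr$rho[length(tr$rho)] >= success_rho
    }, logical(1))
    mean(ok)
  }

  lo <- 0; hi <- 1; it <- 0L
  probes <- data.frame(p0 = numeric(0), frac = numeric(0))
  while (hi - lo > tol && it < max_iter) {
    it <- it + 1L
    mid <- (lo + hi) / 2
    fr <- probe(mid, it)
    probes <- rbind(probes, data.frame(p0 = mid, frac = fr))
    if (fr >= 0.5) hi <- mid else lo <- mid
  }
  est <- (lo + hi) / 2
  converged <- (hi - lo) <= tol

  ## binomial error propagated through the success-curve slope
  half <- (hi - lo) / 2
  inf <- probes[probes$frac > 0 & probes$frac < 1, , drop = FALSE]
  se <- NA_real_
  if (nrow(inf) >= 2L && stats::var(inf$p0) > 0) {
    sl <- stats::coef(stats::lm(frac ~ p0, data = inf))[2L]
    if (is.finite(sl) && sl > 0)
      se <- stats::qnorm(0.975) * sqrt(0.25 / reps) / sl
  }
  width <- max(half, se, na.rm = TRUE)
  structure(list(estimate = est, ci = clamp(c(est - width, est + width), 0, 1),
                 converged = converged, probes = probes,
                 N = N, k = rule$k, model = model, reps = reps, seed = seed),
            class = "mc_critical")
}

#' @export
print.mc_critical <- function(x, ...) {
  cat(sprintf("mc_critical: N = %d, k = %d, c = %g -> p_c ~ %.4f [%.4f, %.4f]%s\n",
              x$N, x$k, x$model$c, x$estimate, x$ci[1], x$ci[2],
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}
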