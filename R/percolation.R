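## Neuropercolation core: torus lattice, distance-dependent long edges,
## and the synchronous threshold activation process.
##
## Vertices of the N x N torus are 0-based coordinates (i, j), stored
## row-major: linear index = i * N + j (0-based; +1 for R vectors).

#' L1 (Manhattan) distance on the N x N torus
#'
#' Geodesic distance of the 4-neighbor lattice with periodic boundaries:
#' the sum over axes of the wrapped coordinate difference
#' \code{min(|delta|, N - |delta|)}.
#'
#' @param x,y integer coordinate pairs \code{c(i, j)} with entries in
#'   \code{[0, N)}.
#' @param N lattice side length.
#' @return Non-negative integer distance.
#' @examples
#' torus_l1_distance(c(0, 0), c(7, 7), 8)  # wraps to 1 + 1 = 2
#' @export
torus_l1_distance <- function(x, y, N) {
  check_scalar_number(N, "N", lo = 1)
  x <- as.integer(x); y <- as.integer(y)
  if (length(x) != 2L || length(y) != 2L)
    stop_config("coordinates must be pairs c(i, j)")
  if (any(x < 0L | x >= N) || any(y < 0L | y >= N))
    stop_config("coordinates out of range [0, N)")
  dd <- abs(x - y)
  as.integer(sum(pmin(dd, as.integer(N) - dd)))
}

#' Long-edge model for the torus random graph
#'
#' Long edges between vertices at lattice distance d are present
#' independently with probability \code{min(1, c / (N * d^alpha))}.
#'
#' @param c nonnegative scale constant for the long-edge density.
#' @param alpha distance exponent (default 1).
#' @param d_min minimum distance eligible for a long edge; defaults to 2 so
#'   long edges never duplicate the short lattice edges at distance 1.
#' @return An object of class \code{"long_edge_model"}.
#' @export
long_edge_model <- function(c = 1, alpha = 1, d_min = 2L) {
  check_scalar_number(c, "c", lo = 0)
  check_scalar_number(alpha, "alpha")
  check_scalar_number(d_min, "d_min", lo = 1)
  structure(list(c = c, alpha = alpha, d_min = as.integer(d_min)),
            class = "long_edge_model")
}

#' Probability of a long edge at distance d
#'
#' @param d lattice distance(s), d >= 1 (d = 0 would be a self-loop and is a
#'   domain error).
#' @param N lattice side length.
#' @param model a \code{\link{long_edge_model}}.
#' @return Probabilities in \code{[0, 1]}, clamped at 1.
#' @export
long_edge_probability <- function(d, N, model) {
  if (any(d < 1)) stop_config("d must be >= 1 (no self-loops)")
  pmin(1, model$c / (N * d^model$alpha))
}

#' Exact count of torus vertices at each L1 distance from a fixed vertex
#'
#' Computed by enumeration of all N^2 - 1 offsets, not by the 4d
#' approximation (which overcounts once distances wrap).
#'
#' @param N lattice side length.
#' @return Integer vector \code{S} with \code{S[d]} = number of vertices at
#'   distance d, for d = 1 .. max distance.
#' @export
torus_distance_counts <- function(N) {
  check_scalar_number(N, "N", lo = 2)
  N <- as.integer(N)
  dx <- 0:(N - 1L)
  wrap <- pmin(dx, N - dx)
  dist <- outer(wrap, wrap, `+`)          # distance of offset (dx, dy)
  dist <- as.vector(dist)[-1L]            # drop the (0,0) offset
  tabulate(dist, nbins = max(dist))
}

#' Expected long-edge degree lambda of a vertex
#'
#' \code{lambda = sum_{d >= d_min} S(d) * p_d}, with S(d) the exact torus
#' distance counts. This is the axis on which the simulation meets the
#' mean-field model.
#'
#' @inheritParams long_edge_probability
#' @return Expected number of long edges per vertex.
#' @export
expected_long_degree <- function(N, model) {
  if (model$c == 0) return(0)
  S <- torus_distance_counts(N)
  d <- seq_along(S)
  keep <- d >= model$d_min
  sum(S[keep] * long_edge_probability(d[keep], N, model))
}

#' Scale constant c giving a target expected long degree
#'
#' Inverts \code{\link{expected_long_degree}} in c (monotone; solved by
#' root bracketing to allow for probability clamping at 1).
#'
#' @param N lattice side length.
#' @param lambda target expected long-edge degree.
#' @param alpha distance exponent.
#' @param d_min minimum long-edge distance.
#' @return The scale constant c.
#' @export
lambda_to_c <- function(N, lambda, alpha = 1, d_min = 2L) {
  check_scalar_number(lambda, "lambda", lo = 0)
  if (lambda == 0) return(0)
  f <- function(cc) expected_long_degree(N, long_edge_model(cc, alpha, d_min)) - lambda
  hi <- 1
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e12) stop_config("lambda unattainable on this lattice")
  }
  stats::uniroot(f, c(0, hi), tol = 1e-10)$root
}

#' Build the torus percolation graph
#'
#' Short edges connect each vertex to its 4 lattice neighbors. Each
#' unordered vertex pair at distance d >= \code{model$d_min} independently
#' receives a long edge with probability \code{min(1, c/(N d^alpha))}.
#' Sampling is grouped by translation offset so each unordered pair is
#' considered exactly once; identical \code{(N, model, seed)} always
#' rebuilds the identical edge set.
#'
#' @param N lattice side length (N >= 3).
#' @param model a \code{\link{long_edge_model}}.
#' @param seed integer RNG seed.
#' @return An object of class \code{"percolation_graph"} with fields
#'   \code{N}, \code{model}, \code{seed}, \code{long_edges} (2-column matrix
#'   of 1-based linear vertex indices) and \code{adjacency} (sparse
#'   symmetric 0/1 matrix over all N^2 vertices).
#' @export
build_graph <- function(N, model = long_edge_model(), seed = 0L) {
  check_scalar_number(N, "N", lo = 3)
  N <- as.integer(N)
  n2 <- N * N
  set.seed(seed)

  ## short edges: right and down neighbor of every vertex (each short edge once)
  i0 <- rep(0:(N - 1L), each = N)   # row
  j0 <- rep(0:(N - 1L), times = N)  # col
  v <- i0 * N + j0                  # 0-based linear index
  right <- i0 * N + (j0 + 1L) %% N
  down  <- ((i0 + 1L) %% N) * N + j0
  short_from <- c(v, v)
  short_to <- c(right, down)

  ## long edges, by translation offset class
  le_from <- integer(0); le_to <- integer(0)
  if (model$c > 0) {
    dx <- rep(0:(N - 1L), each = N)
    dy <- rep(0:(N - 1L), times = N)
    wd <- pmin(dx, N - dx) + pmin(dy, N - dy)
    ndx <- (N - dx) %% N; ndy <- (N - dy) %% N   # negated offset
    self_inv <- (dx == ndx) & (dy == ndy)
    ## canonical representative: lexicographically <= its negation
    canon <- (dx < ndx) | (dx == ndx & dy <= ndy)
    keep <- which(wd >= model$d_min & canon & !(dx == 0L & dy == 0L))
    for (o in keep) {
      p <- long_edge_probability(wd[o], N, model)
      if (p <= 0) next
      if (self_inv[o]) {
        ## each pair {u, u+off} appears twice over base vertices; restrict to
        ## bases whose partner has a larger linear index
        partner <- (((i0 + dx[o]) %% N) * N + (j0 + dy[o]) %% N)
        base <- which(v < partner)   # positions (1-based) into v
        m <- stats::rbinom(1L, length(base), p)
        if (m > 0L) {
          pick <- base[sample.int(length(base), m)]
          le_from <- c(le_from, v[pick]); le_to <- c(le_to, partner[pick])
        }
      } else {
        m <- stats::rbinom(1L, n2, p)
        if (m > 0L) {
          pick <- sample.int(n2, m)
          partner <- (((i0[pick] + dx[o]) %% N) * N + (j0[pick] + dy[o]) %% N)
          le_from <- c(le_from, v[pick]); le_to <- c(le_to, partner)
        }
      }
    }
  }

  from <- c(short_from, le_from) + 1L
  to <- c(short_to, le_to) + 1L
  adj <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from), x = 1,
                              dims = c(n2, n2))
  adj@x[] <- 1   # collapse any duplicate-triplet sums back to 0/1

  structure(list(N = N, model = model, seed = seed,
                 long_edges = cbind(from = le_from + 1L, to = le_to + 1L),
                 n_long = length(le_from),
                 adjacency = adj),
            class = "percolation_graph")
}

#' @export
print.percolation_graph <- function(x, ...) {
  cat(sprintf("percolation_graph: %d x %d torus (%d vertices)\n",
              x$N, x$N, x$N^2))
  cat(sprintf("  long-edge model: c = %g, alpha = %g, d_min = %d\n",
              x$model$c, x$model$alpha, x$model$d_min))
  cat(sprintf("  short edges: %d, long edges: %d (mean long degree %.4f)\n",
              2L * x$N^2, x$n_long, 2 * x$n_long / x$N^2))
  invisible(x)
}

#' Threshold update rule
#'
#' A vertex is active at t+1 iff at least k of its neighbors are active at
#' t (the vertex's own state is excluded). With \code{eps > 0} each
#' vertex's computed value is flipped independently with probability eps;
#' \code{eps = 0} recovers the deterministic rule exactly.
#'
#' @param k positive integer activation threshold.
#' @param eps flip probability in \code{[0, 0.5]}, default 0.
#' @return An object of class \code{"update_rule"}.
#' @export
update_rule <- function(k, eps = 0) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop_config("k must be a positive integer")
  check_scalar_number(eps, "eps", lo = 0, hi = 0.5)
  structure(list(k = as.integer(k), eps = eps), class = "update_rule")
}

#' One synchronous step of the activation process
#'
#' @param chi 0/1 integer vector of length N^2 (row-major vertex states).
#' @param graph a \code{\link{build_graph}} result.
#' @param rule an \code{\link{update_rule}}.
#' @return The updated 0/1 state vector.
#' @export
activation_step <- function(chi, graph, rule) {
  if (!inherits(rule, "update_rule")) stop_config("rule must be an update_rule")
  n2 <- graph$N^2
  if (length(chi) != n2) stop_config("state length does not match graph")
  nbr <- as.numeric(graph$adjacency %*% chi)
  out <- as.integer(nbr >= rule$k)
  if (rule$eps > 0) {
    flip <- stats::runif(n2) < rule$eps
    out[flip] <- 1L - out[flip]
  }
  out
}

#' Active fraction of a state vector
#' @param chi 0/1 state vector.
#' @return \code{mean(chi)}.
#' @export
active_fraction <- function(chi) mean(chi)

#' Run the activation process from a random initial state
#'
#' The initial state is i.i.d. Bernoulli(p0) per vertex. The synchronous
#' threshold update is iterated until an absorbing state (all active / all
#' inactive), a repeated state (period 1 or 2, reported as outcome
#' \code{"cycle"}; frozen partial fixed points fall in this class), or
#' \code{max_steps}.
#'
#' @param graph a \code{\link{build_graph}} result.
#' @param p0 initial activation density in \code{[0, 1]}.
#' @param rule an \code{\link{update_rule}}.
#' @param max_steps maximum number of update steps (>= 1).
#' @param seed integer RNG seed (initial state and any eps-noise).
#' @param store_states keep every full lattice state (memory heavy).
#' @return Object of class \code{"activation_trajectory"}: \code{rho}
#'   (densities rho_0 .. rho_T), \code{outcome} in \code{all_active},
#'   \code{all_inactive}, \code{cycle}, \code{timeout}, \code{steps_taken},
#'   \code{final_state}, and optionally \code{states}.
#' @export
run_dynamics <- function(graph, p0, rule, max_steps = 200L, seed = 0L,
                         store_states = FALSE) {
  check_scalar_number(p0, "p0", lo = 0, hi = 1)
  if (max_steps < 1) stop_config("max_steps must be >= 1")
  set.seed(seed)
  n2 <- graph$N^2
  chi <- as.integer(stats::runif(n2) < p0)
  rho <- active_fraction(chi)
  states <- if (store_states) list(chi) else NULL
  prev1 <- chi; prev2 <- NULL
  outcome <- NA_character_; steps <- 0L

  if (rule$eps == 0 && rho == 0) outcome <- "all_inactive"  # absorbing, k >= 1

  while (is.na(outcome) && steps < max_steps) {
    nxt <- activation_step(prev1, graph, rule)
    if (identical(nxt, prev1)) {
      r <- active_fraction(nxt)
      outcome <- if (r == 1) "all_active" else if (r == 0) "all_inactive" else "cycle"
      break
    }
    if (!is.null(prev2) && identical(nxt, prev2)) { outcome <- "cycle"; break }
    steps <- steps + 1L
    rho <- c(rho, active_fraction(nxt))
    if (store_states) states[[steps + 1L]] <- nxt
    prev2 <- prev1; prev1 <- nxt
    r <- rho[length(rho)]
    if (rule$eps == 0) {                # both extremes absorbing when k <= 4
      if (r == 0) outcome <- "all_inactive"
      else if (r == 1 && rule$k <= 4L) outcome <- "all_active"
    }
  }
  if (is.na(outcome)) outcome <- "timeout"

  structure(list(rho = rho, outcome = outcome, steps_taken = steps,
                 final_state = prev1, states = states,
                 p0 = p0, k = rule$k, seed = seed),
            class = "activation_trajectory")
}

#' @export
print.activation_trajectory <- function(x, ...) {
  cat(sprintf("activation_trajectory: p0 = %g, k = %d, %d steps, outcome %s\n",
              x$p0, x$k, x$steps_taken, x$outcome))
  cat(sprintf("  rho: %.4f -> %.4f\n", x$rho[1], x$rho[length(x$rho)]))
  invisible(x)
}

#' Export a trajectory as CSV (step, rho, outcome_flag)
#' @param traj an \code{\link{run_dynamics}} result.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(step = seq_along(traj$rho) - 1L, rho = traj$rho,
                   outcome_flag = traj$outcome)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export the edge list as CSV (x1, y1, x2, y2, type)
#'
#' Coordinates are 0-based (row, col); type is \code{short} or \code{long}.
#' @param graph a \code{\link{build_graph}} result.
#' @param path output file.
#' @export
write_graph_csv <- function(graph, path) {
  N <- graph$N
  idx_rc <- function(idx) {           # 1-based linear -> 0-based (row, col)
    z <- idx - 1L
    cbind(z %/% N, z %% N)
  }
  i0 <- rep(0:(N - 1L), each = N); j0 <- rep(0:(N - 1L), times = N)
  v <- i0 * N + j0 + 1L
  right <- i0 * N + (j0 + 1L) %% N + 1L
  down  <- ((i0 + 1L) %% N) * N + j0 + 1L
  sf <- c(v, v); st <- c(right, down)
  a <- idx_rc(c(sf, graph$long_edges[, 1L]))
  b <- idx_rc(c(st, graph$long_edges[, 2L]))
  df <- data.frame(x1 = a[, 1L], y1 = a[, 2L], x2 = b[, 1L], y2 = b[, 2L],
                   type = c(rep("short", length(sf)),
                            rep("long", nrow(graph$long_edges))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
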