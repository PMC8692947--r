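## Phase-cone fitting on 2-D lattice phase fields.
##
## A phase cone is a radially propagating phase gradient ignited at an
## apex: phi(x) ~ phi0 + gamma * |x - apex|, with the sign of gamma
## encoding expanding vs. contracting propagation. Fitting is a grid
## search over candidate apexes with, per apex, a circular-linear
## regression of phase on Euclidean distance from the apex: for fixed
## gamma the optimal intercept is the circular mean of phi - gamma*d, so
## the profile objective |sum_j exp(i(phi_j - gamma d_j))| is maximized
## over gamma alone (coarse grid + local refinement).

#' Fit a phase cone to a lattice phase field
#'
#' @param phase_grid numeric matrix (>= 8 x 8) of phases in radians.
#' @param apexes optional 2-column matrix of candidate apex coordinates
#'   (0-based row, col); defaults to every lattice point.
#' @param gamma_max slope search range, radians per lattice unit.
#' @param coarse_n coarse slope-grid resolution.
#' @return Object of class \code{"phase_cone_fit"}: \code{apex} (0-based
#'   c(x, y)), \code{gamma}, \code{phi0}, \code{quality} (fraction of
#'   circular variance explained, in \code{[0, 1]}), \code{degenerate}.
#' @examples
#' f <- outer(0:15, 0:15, function(i, j) 0.5 + 0.2 * sqrt((i - 7)^2 + (j - 7)^2))
#' fit_phase_cone(f)
#' @export
fit_phase_cone <- function(phase_grid, apexes = NULL, gamma_max = 1,
                           coarse_n = 41L) {
  if (!is.matrix(phase_grid) || nrow(phase_grid) < 8L || ncol(phase_grid) < 8L)
    stop_config("phase_grid must be a matrix of at least 8 x 8")
  nr <- nrow(phase_grid); nc <- ncol(phase_grid)
  ri <- rep(0:(nr - 1L), times = nc)        # row coordinate per cell
  ci <- rep(0:(nc - 1L), each = nr)         # col coordinate per cell
  phi <- as.vector(phase_grid)
  z <- exp(1i * phi)
  nn <- length(z)

  V_tot <- 1 - Mod(mean(z))
  if (V_tot < 1e-10) {
    return(structure(list(apex = c(NA_real_, NA_real_), gamma = 0,
                          phi0 = Arg(mean(z)), quality = 0,
                          degenerate = TRUE),
                     class = "phase_cone_fit"))
  }

  if (is.null(apexes)) apexes <- cbind(ri, ci)
  apexes <- matrix(apexes, ncol = 2L)
  gammas <- seq(-gamma_max, gamma_max, length.out = coarse_n)
  g_step <- gammas[2] - gammas[1]

  best <- list(A = -1)
  for (a in seq_len(nrow(apexes))) {
    d <- sqrt((ri - apexes[a, 1L])^2 + (ci - apexes[a, 2L])^2)
    E <- exp(-1i * (d %o% gammas))
    A <- Mod(colSums(z * E))
    j <- which.max(A)
    if (A[j] > best$A)
      best <- list(A = A[j], apex = apexes[a, ], d = d, gamma = gammas[j])
  }

  ## refine the slope at the winning apex
  obj <- function(g) Mod(sum(z * exp(-1i * g * best$d)))
  opt <- stats::optimize(obj,
                         interval = c(max(-gamma_max, best$gamma - g_step),
                                      min(gamma_max, best$gamma + g_step)),
                         maximum = TRUE, tol = 1e-6)
  gamma <- opt$maximum
  w <- z * exp(-1i * gamma * best$d)
  phi0 <- Arg(mean(w))
  V_res <- 1 - Mod(mean(w))
  quality <- clamp(1 - V_res / V_tot, 0, 1)

  structure(list(apex = unname(best$apex), gamma = gamma, phi0 = phi0,
                 quality = quality, degenerate = FALSE),
            class = "phase_cone_fit")
}

#' @export
print.phase_cone_fit <- function(x, ...) {
  if (x$degenerate)
    cat("phase_cone_fit: degenerate (constant phase field)\n")
  else
    cat(sprintf(
      "phase_cone_fit: apex (%g, %g), gamma = %.4f, phi0 = %.4f, quality = %.3f\n",
      x$apex[1], x$apex[2], x$gamma, x$phi0, x$quality))
  invisible(x)
}

#' Generate a synthetic phase-cone field
#'
#' \code{phi = phi0 + gamma * dist(apex)} plus i.i.d. Gaussian phase
#' noise, wrapped to (-pi, pi].
#'
#' @param nr,nc grid size.
#' @param apex 0-based \code{c(row, col)} apex.
#' @param gamma radial slope (radians per lattice unit).
#' @param phi0 apex phase.
#' @param noise_sd phase noise SD in radians.
#' @return Phase matrix.
#' @export
make_phase_cone <- function(nr = 16L, nc = 16L, apex = c(7, 7), gamma = 0.2,
                            phi0 = 0.5, noise_sd = 0) {
  ri <- rep(0:(nr - 1L), times = nc)
  ci <- rep(0:(nc - 1L), each = nr)
  d <- sqrt((ri - apex[1])^2 + (ci - apex[2])^2)
  phi <- phi0 + gamma * d
  if (noise_sd > 0) phi <- phi + stats::rnorm(length(phi), sd = noise_sd)
  matrix((phi + pi) %% (2 * pi) - pi, nr, nc)
}
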