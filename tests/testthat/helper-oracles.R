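## Independent oracles used across the suite. These deliberately take
## different computational routes than the package internals.

## threshold update on an N x N torus state matrix via row/column shifts
## (the package uses a sparse adjacency mat-vec; fixtures use nested loops)
oracle_torus_step <- function(M, k) {
  N <- nrow(M)
  up <- M[c(2:N, 1L), , drop = FALSE]
  down <- M[c(N, 1:(N - 1L)), , drop = FALSE]
  left <- M[, c(2:N, 1L), drop = FALSE]
  right <- M[, c(N, 1:(N - 1L)), drop = FALSE]
  matrix(as.integer(up + down + left + right >= k), N, N)
}

## row-major vector <-> matrix converters matching the package's state layout
chi_to_mat <- function(chi, N) matrix(as.integer(chi), N, N, byrow = TRUE)
mat_to_chi <- function(M) as.integer(t(M))

## plain-R Izhikevich explicit-Euler run at fixed sensitivity b_eff,
## constant current, no metabolism; returns spike times (s * dt)
oracle_izhikevich <- function(params, b_eff, I, T, dt) {
  v <- neuroperc::izhikevich_rest(params)
  u <- b_eff * v
  steps <- as.integer(round(T / dt))
  out <- numeric(0)
  for (s in seq_len(steps)) {
    v1 <- v + dt * (0.04 * v * v + 5 * v + 140 - u + I)
    u1 <- u + dt * (params$a * (b_eff * v - u))
    if (v1 >= params$v_peak) {
      out <- c(out, s * dt)
      v1 <- params$c_reset
      u1 <- u1 + params$d
    }
    v <- v1; u <- u1
  }
  out
}

## two-state telegraph label sequence from geometric dwell draws
oracle_telegraph <- function(n_transitions, p_lh, p_hl) {
  dw_low <- stats::rgeom(n_transitions, p_lh) + 1L
  dw_high <- stats::rgeom(n_transitions, p_hl) + 1L
  rep(rep(c("low", "high"), n_transitions),
      times = as.vector(rbind(dw_low, dw_high)))
}

## closed-form mean-field map at lambda = 0 (no long edges)
local_map_closed_form <- function(rho, k) {
  switch(as.character(k),
         "1" = 1 - (1 - rho)^4,
         "2" = 1 - (1 - rho)^4 - 4 * rho * (1 - rho)^3,
         "3" = 4 * rho^3 - 3 * rho^4,
         "4" = rho^4,
         stop("k out of closed-form range"))
}
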