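## Deterministic fixture generation for the test suites: tiny lattice
## states with brute-force next states, telegraph label series, synthetic
## phase cones, and the surrogate bistable system description.

## straight per-vertex neighbor-count update on an N x N torus state
## matrix; intentionally loop-based and independent of the sparse-matrix
## dynamics path
brute_force_next <- function(state_mat, k) {
  N <- nrow(state_mat)
  out <- matrix(0L, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      up <- if (i == 1L) N else i - 1L
      dn <- if (i == N) 1L else i + 1L
      lf <- if (j == 1L) N else j - 1L
      rt <- if (j == N) 1L else j + 1L
      s <- state_mat[up, j] + state_mat[dn, j] +
           state_mat[i, lf] + state_mat[i, rt]
      out[i, j] <- as.integer(s >= k)
    }
  }
  out
}

#' Generate deterministic test fixtures
#'
#' Small ground-truth inputs for validating the other modules:
#' \describe{
#'   \item{tiny_torus_states}{200 random 4x4 torus states with their
#'     brute-force next states for k = 1..4 (states serialized as 16-char
#'     0/1 strings, row-major).}
#'   \item{telegraph_labels}{a two-state telegraph label series with known
#'     switching rates (geometric dwell times).}
#'   \item{synthetic_cones}{100 noisy phase-cone fields with their true
#'     apex, slope and intercept.}
#'   \item{bistable_surrogate}{the parameter set of the relay surrogate of
#'     \code{\link{make_bistable_surrogate}}.}
#' }
#'
#' @param kind fixture family name.
#' @param seed RNG seed.
#' @param dir output directory.
#' @return Character vector of files written (invisibly).
#' @export
make_fixtures <- function(kind = c("tiny_torus_states", "telegraph_labels",
                                   "synthetic_cones", "bistable_surrogate"),
                          seed = 0L, dir = ".") {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  files <- switch(kind,
    tiny_torus_states = {
      rows <- vector("list", 200L * 4L)
      idx <- 0L
      for (s in seq_len(200L)) {
        st <- matrix(stats::rbinom(16L, 1L, 0.5), 4L, 4L)
        chi <- paste(as.integer(t(st)), collapse = "")  # row-major string
        for (k in 1:4) {
          idx <- idx + 1L
          nxt <- brute_force_next(st, k)
          rows[[idx]] <- data.frame(state_id = s, k = k, chi = chi,
                                    next_state = paste(as.integer(t(nxt)),
                                                       collapse = ""))
        }
      }
      path <- file.path(dir, "tiny_torus_states.csv")
      utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                       quote = FALSE)
      path
    },
    telegraph_labels = {
      p_lh <- 0.02; p_hl <- 0.05      # per-step switch probabilities
      n <- 20000L
      lab <- character(n); cur <- "low"
      u <- stats::runif(n)
      for (i in seq_len(n)) {
        if (cur == "low" && u[i] < p_lh) cur <- "high"
        else if (cur == "high" && u[i] < p_hl) cur <- "low"
        lab[i] <- cur
      }
      path <- file.path(dir, "telegraph_labels.csv")
      utils::write.csv(data.frame(step = seq_len(n), label = lab,
                                  p_low_to_high = p_lh, p_high_to_low = p_hl),
                       path, row.names = FALSE, quote = FALSE)
      path
    },
    synthetic_cones = {
      rows <- vector("list", 100L)
      fields <- vector("list", 100L)
      for (i in seq_len(100L)) {
        apex <- c(sample(3:12, 1L), sample(3:12, 1L))
        gamma <- stats::runif(1L, 0.1, 0.4) * sample(c(-1, 1), 1L)
        phi0 <- stats::runif(1L, -1, 1)
        f <- make_phase_cone(16L, 16L, apex, gamma, phi0, noise_sd = 0.2)
        rows[[i]] <- data.frame(cone_id = i, apex_x = apex[1],
                                apex_y = apex[2], gamma = gamma, phi0 = phi0)
        fields[[i]] <- data.frame(cone_id = i,
                                  x = rep(0:15, times = 16L),
                                  y = rep(0:15, each = 16L),
                                  phase = as.vector(f))
      }
      p1 <- file.path(dir, "synthetic_cones_truth.csv")
      p2 <- file.path(dir, "synthetic_cones_fields.csv")
      utils::write.csv(do.call(rbind, rows), p1, row.names = FALSE,
                       quote = FALSE)
      utils::write.csv(do.call(rbind, fields), p2, row.names = FALSE,
                       quote = FALSE)
      c(p1, p2)
    },
    bistable_surrogate = {
      path <- file.path(dir, "bistable_surrogate.json")
      jsonlite::write_json(list(theta_off = 0.3, theta_on = 0.7,
                                R_low = 0.1, R_high = 0.9,
                                note = "relay surrogate; bistable on [theta_off, theta_on]"),
                           path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      path
    })
  invisible(files)
}
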