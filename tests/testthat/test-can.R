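test_that("parameter constructors enforce the model's stated ranges", {
  expect_error(izhikevich_params(omega = 0.5), "omega")
  expect_error(izhikevich_params(beta = 0.6), "beta")
  expect_error(izhikevich_params(b = 0), "b")
  expect_error(metabolic_params(tau = 0), "tau")
  expect_error(metabolic_params(kappa = -1), "kappa")
  expect_error(metabolic_params(drive_mode = "bogus"))
  expect_error(update_rule(0), "positive")
})

test_that("sensitivity modulation is omega*b + beta*m", {
  p <- izhikevich_params(omega = 1, beta = 0)
  expect_equal(sensitivity_modulation(p, 5), 0.2)
  p2 <- izhikevich_params(omega = 0.75, beta = 0.5)
  expect_equal(sensitivity_modulation(p2, 0), 0.15)
  ## strictly increasing in beta at fixed m > 0
  bs <- c(0, 0.1, 0.3, 0.5)
  out <- vapply(bs, function(b)
    sensitivity_modulation(izhikevich_params(beta = b), 0.7), numeric(1))
  expect_true(all(diff(out) > 0))
  expect_error(sensitivity_modulation(p, -1), "m")
})

test_that("rest and threshold potentials solve the nullcline quadratic", {
  p <- izhikevich_params()
  vr <- izhikevich_rest(p)
  vt <- izhikevich_threshold(p)
  expect_equal(vr, -70, tolerance = 1e-10)
  expect_equal(vt, -50, tolerance = 1e-10)
  for (v in c(vr, vt))
    expect_equal(0.04 * v^2 + 5 * v + 140 - 0.2 * v, 0, tolerance = 1e-9)
  ## no equilibrium above rheobase
  expect_true(is.na(izhikevich_rest(p, I = 10)))
})

test_that("izhikevich step resets exactly once past the peak", {
  p <- izhikevich_params()
  st <- izhikevich_step(p$v_peak + 1, 0, 0, 0.2, 0.1, p)
  expect_equal(st$v, p$c_reset)
  expect_true(st$spiked)
  st2 <- izhikevich_step(st$v, st$u, 0, 0.2, 0.1, p)
  expect_false(st2$spiked)
  expect_error(izhikevich_step(Inf, 0, 0, 0.2, 0.1, p), "non-finite")
  expect_error(izhikevich_step(-70, -14, 0, 0.2, 0, p), "dt")
})

test_that("quiescent unit stays quiescent over 1000 steps", {
  p <- izhikevich_params()
  v <- izhikevich_rest(p); u <- 0.2 * v
  for (s in 1:1000) {
    st <- izhikevich_step(v, u, 0, 0.2, 0.1, p)
    v <- st$v; u <- st$u
    expect_false(st$spiked)
  }
  expect_equal(v, izhikevich_rest(p), tolerance = 1e-6)
})

test_that("sliding-window drive handles padding, modes and spike counting", {
  ## a history resting at the reference has no excursion, hence no drive
  expect_equal(sliding_window_drive(rep(-70, 10), 5, 1, "rectified"), 0)
  ## constant rectified excursion x over a full window integrates to x*tau
  h <- rep(-60, 100)
  expect_equal(sliding_window_drive(h, 20, 0.5, "rectified", v_rest = -70),
               10 * 20)
  expect_equal(sliding_window_drive(h, 20, 0.5, "raw"), sum(rep(-60, 40)) * 0.5)
  expect_equal(sliding_window_drive(c(0, 1, 0, 1, 1), 5, 1, "spike_count"), 3)
  ## shorter-than-window history is zero-padded at the start
  expect_equal(sliding_window_drive(c(-60, -60), 10, 1, "rectified",
                                    v_rest = -70), 20)
  expect_error(sliding_window_drive(h, 20, 0.5, "bogus"))
})

test_that("metabolic pools transfer mass and respect capacities", {
  met <- metabolic_params()
  st <- metabolic_step(0, 0, 0, 0.1, met)
  expect_equal(st$g, 0); expect_equal(st$m, 0)

  ## with no drive and no consumption the transfer conserves g + m exactly
  met2 <- metabolic_params(kappa = 0, k_m = 0)
  st2 <- metabolic_step(2, 0.3, 50, 0.1, met2)
  expect_equal(st2$g + st2$m, 2.3, tolerance = 1e-12)
  expect_lt(st2$g, 2)

  ## saturation: conversion stops at full ATP; only consumption drains m
  st3 <- metabolic_step(2, met$m_max, 0, 0.1, met)
  expect_equal(st3$m, met$m_max * (1 - 0.1 * met$k_m))
  expect_lte(st3$m, met$m_max)
  expect_equal(st3$g, 2)                   # psi1 = 0 at m = m_max

  ## clamping under an absurd drive
  st4 <- metabolic_step(met$g_max, 0.5, 1e9, 1, met)
  expect_equal(st4$g, met$g_max)
})

test_that("with beta = 0 spiking is bitwise independent of the metabolic side", {
  pa <- izhikevich_params(beta = 0)
  a <- simulate_unit(pa, metabolic_params(), T = 500, dt = 0.1, I_fn = 10,
                     seed = 4)
  b <- simulate_unit(pa, metabolic_params(kappa = 1e-2, k_g = 0.5, k_m = 0.3,
                                          g_max = 50, m_max = 2),
                     T = 500, dt = 0.1, I_fn = 10, seed = 4)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$v, b$v)
  expect_false(identical(a$m, b$m))    # the metabolic side itself does differ

  ## and matches a plain Izhikevich integration at b_eff = omega * b
  want <- oracle_izhikevich(pa, 0.2, 10, 500, 0.1)
  expect_equal(a$spikes$time, want)
})

test_that("decoupled limit reproduces the pure spiking trajectory", {
  pa <- izhikevich_params(beta = 0.4)       # beta irrelevant when m stays 0
  s <- simulate_unit(pa, metabolic_params(kappa = 0), T = 400, dt = 0.1,
                     I_fn = 8, seed = 1)
  expect_true(all(s$m == 0))
  want <- oracle_izhikevich(pa, pa$omega * pa$b, 8, 400, 0.1)
  expect_equal(s$spikes$time, want)
})

test_that("firing accelerates with the metabolic feedback gain", {
  rates <- vapply(c(0.05, 0.25), function(b) {
    s <- simulate_unit(izhikevich_params(beta = b), metabolic_params(),
                       T = 1500, dt = 0.1, I_fn = 6, seed = 2)
    nrow(s$spikes)
  }, numeric(1))
  expect_gt(rates[2], rates[1])
})

test_that("metabolic pools stay inside capacity along whole trajectories", {
  s <- simulate_unit(izhikevich_params(beta = 0.5),
                     metabolic_params(kappa = 5e-3, k_g = 0.2),
                     T = 800, dt = 0.1, I_fn = 10, seed = 3)
  met <- metabolic_params()
  expect_true(all(s$g >= 0 & s$g <= met$g_max))
  expect_true(all(s$m >= 0 & s$m <= met$m_max))
})

test_that("halving the step changes regular-spiking counts by < 5%", {
  n1 <- nrow(simulate_unit(izhikevich_params(), metabolic_params(kappa = 0),
                           T = 2000, dt = 0.2, I_fn = 10)$spikes)
  n2 <- nrow(simulate_unit(izhikevich_params(), metabolic_params(kappa = 0),
                           T = 2000, dt = 0.1, I_fn = 10)$spikes)
  expect_lt(abs(n1 - n2) / n2, 0.05)
})

test_that("a population of one reduces exactly to the unit simulator", {
  cfg <- population_config(n = 1, w = 0, sigma_noise = 0, I_dc = 7)
  pop <- simulate_population(cfg, izhikevich_params(beta = 0.2),
                             metabolic_params(), T = 600, dt = 0.1, seed = 5)
  unit <- simulate_unit(izhikevich_params(beta = 0.2), metabolic_params(),
                        T = 600, dt = 0.1, I_fn = 7, seed = 5)
  expect_identical(pop$spikes, unit$spikes)
  expect_identical(pop$v, unit$v)
  expect_identical(pop$m, unit$m)
})

test_that("population runs are reproducible and raster-consistent", {
  cfg <- population_config(n = 20, sigma_noise = 0.5, I_dc = 5)
  a <- simulate_population(cfg, izhikevich_params(), metabolic_params(),
                           T = 500, dt = 0.2, seed = 11)
  b <- simulate_population(cfg, izhikevich_params(), metabolic_params(),
                           T = 500, dt = 0.2, seed = 11)
  expect_identical(a$spikes, b$spikes)

  r <- as_spike_raster(a)
  expect_true(!is.unsorted(r$spikes$time))
  expect_true(all(r$spikes$time >= 0 & r$spikes$time <= r$duration))
  expect_true(all(r$spikes$neuron_id %in% seq_len(cfg$n)))
})

test_that("uncoupled noisy neurons are uncorrelated; coupling synchronizes", {
  met0 <- metabolic_params(kappa = 0)
  un <- simulate_population(population_config(n = 50, w = 0, sigma_noise = 2,
                                              I_dc = 5),
                            izhikevich_params(), met0, T = 1500, dt = 0.2,
                            seed = 6)
  expect_lt(abs(spike_coincidence(as_spike_raster(un))), 0.1)

  co <- simulate_population(population_config(n = 50, w = 8, sigma_noise = 2,
                                              I_dc = 5),
                            izhikevich_params(), met0, T = 1500, dt = 0.2,
                            seed = 6)
  R_of <- function(sim) {
    tr <- smoothed_activity(as_spike_raster(sim))
    mean(order_parameter(tr)$R)
  }
  expect_gt(R_of(co), R_of(un))
})

test_that("trace and raster CSV exports round-trip the simulated content", {
  d <- withr::local_tempdir()
  s <- simulate_unit(izhikevich_params(), metabolic_params(), T = 300,
                     dt = 0.1, I_fn = 10, seed = 1)
  write_traces_csv(s, file.path(d, "tr.csv"))
  df <- utils::read.csv(file.path(d, "tr.csv"))
  expect_identical(names(df), c("t", "v_mean", "g_mean", "m_mean"))
  expect_equal(df$v_mean, s$v)

  write_raster_csv(as_spike_raster(s), file.path(d, "ra.csv"))
  ra <- utils::read.csv(file.path(d, "ra.csv"))
  expect_equal(nrow(ra), nrow(s$spikes))
})
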