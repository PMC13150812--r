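e_charge <- swim2dms:::.e_charge
amu <- swim2dms:::.amu

single_traj <- function(q, cfg, x0 = 3e-4, t_end = 4e-3, dt = 2e-8,
                        stride = 4L) {
  mz <- swim2dms:::.mz_from_q(q, cfg)
  swim2dms:::.cpp_single_trajectory(c(x0, 1e-4), c(0, 0), mz * amu, e_charge,
                                    cfg$v_trap, cfg$f_trap, cfg$r0,
                                    numeric(0), 1, dt, round(t_end / dt),
                                    stride)
}

peak_freq <- function(x, dt_sample) {
  sp <- Mod(stats::fft(x - mean(x)))[seq_len(floor(length(x) / 2))]
  pk <- which.max(sp)
  d <- if (pk > 1 && pk < length(sp)) {
    0.5 * (sp[pk - 1] - sp[pk + 1]) / (sp[pk - 1] - 2 * sp[pk] + sp[pk + 1])
  } else 0
  (pk - 1 + d) / (length(x) * dt_sample)
}

test_that("field force: null field, linearity and loss past r0", {
  cfg <- default_cfg()
  st <- trap_ion_state(c(1e-3, 5e-4), c(0, 0, 0), 500, 1)
  off <- swim_config(v_trap = 1e-12)  # vanishing RF
  expect_equal(field_force(st, 0, off, 0), c(0, 0), tolerance = 1e-25)
  f1 <- field_force(st, 1.3e-7, cfg, 0)
  st2 <- st; st2$position <- 2 * st$position
  expect_equal(field_force(st2, 1.3e-7, cfg, 0), 2 * f1)
  st3 <- st; st3$position <- c(cfg$r0, 0)
  expect_error(field_force(st3, 0, cfg, 0), "lost")
})

test_that("verlet step: free flight, dt guard, compiled-core agreement", {
  cfg <- default_cfg()
  off <- swim_config(v_trap = 1e-15)
  st <- trap_ion_state(c(1e-4, 0), c(10, -5, 0), 500, 1)
  for (k in 1:50) st <- verlet_step(st, 1e-8, (k - 1) * 1e-8, off)
  expect_equal(st$position, c(1e-4 + 10 * 5e-7, -5 * 5e-7), tolerance = 1e-10)
  expect_error(verlet_step(st, 1e-6, 0, cfg), "dt too large")
  # the R reference stepper and the compiled integrator agree step-for-step
  dt <- 2e-8; nst <- 500L
  st <- trap_ion_state(c(2e-4, 1e-4), c(3, -2, 0), 922, 1)
  tr <- swim2dms:::.cpp_single_trajectory(st$position, st$velocity[1:2],
                                          922 * amu, e_charge, cfg$v_trap,
                                          cfg$f_trap, cfg$r0, numeric(0), 1,
                                          dt, nst, nst)
  for (k in seq_len(nst)) st <- verlet_step(st, dt, (k - 1) * dt, cfg)
  expect_equal(st$position, tr[nrow(tr), 2:3], tolerance = 1e-9)
})

test_that("trajectory secular frequencies match the continued-fraction beta", {
  cfg <- default_cfg()
  for (q in c(0.05, 0.1, 0.2, 0.3, 0.4)) {
    tr <- single_traj(q, cfg, t_end = 4e-3)
    fs_meas <- peak_freq(tr[, 2], 4 * 2e-8)
    fs_th <- as.numeric(secular_frequency(swim2dms:::.mz_from_q(q, cfg),
                                          cfg, "exact"))
    expect_lt(abs(fs_meas / fs_th - 1), 0.005)
  }
})

test_that("secular amplitude is stable over 1000 RF cycles (no energy drift)", {
  cfg <- default_cfg()
  tr <- single_traj(0.1, cfg, t_end = 1e-3, stride = 1L)
  x <- tr[, 2]
  n <- length(x)
  e1 <- max(abs(x[1:(n / 4)]))
  e2 <- max(abs(x[(3 * n / 4):n]))
  expect_lt(abs(e2 / e1 - 1), 1e-4)
})

test_that("integrator converges at second order in dt", {
  cfg <- default_cfg()
  final_x <- function(dt) {
    tr <- single_traj(0.1, cfg, t_end = 2e-4, dt = dt,
                      stride = round(2e-4 / dt))
    tr[nrow(tr), 2]
  }
  f1 <- final_x(2e-8); f2 <- final_x(1e-8); f3 <- final_x(5e-9)
  err12 <- abs(f1 - f2); err23 <- abs(f2 - f3)
  expect_lt(err23, err12)              # refinement shrinks the change
  expect_gt(err12 / err23, 3)          # consistent with O(dt^2)
  expect_lt(err12 / err23, 5.5)
})

test_that("adiabatic limit: micromotion carries half the kinetic energy", {
  cfg <- default_cfg()
  # at q = 0.1 the pseudopotential picture applies: <v^2> = 2 w_s^2 <x^2>
  tr <- single_traj(0.1, cfg, t_end = 2e-3, stride = 1L)
  x <- tr[, 2]
  v <- diff(x) / 2e-8
  ws <- 2 * pi * as.numeric(secular_frequency(swim2dms:::.mz_from_q(0.1, cfg),
                                              cfg, "exact"))
  ratio <- mean(v^2) / (2 * ws^2 * mean(x^2))
  expect_equal(ratio, 1, tolerance = 0.05)
})

test_that("collisions: off at zero pressure, thermalizing, correct rate", {
  expect_identical(maybe_collide(trap_ion_state(), gas_model(pressure = 0),
                                 1e-6)$velocity, c(0, 0, 0))
  kB <- 1.380649e-23
  gas <- gas_model(pressure = 50, temperature = 300)
  # cold ions relax toward (3/2) kT of the bath
  set.seed(1)
  ions <- replicate(200, trap_ion_state(c(0, 0), c(0, 0, 0), 500, 1),
                    simplify = FALSE)
  for (k in 1:600) ions <- lapply(ions, maybe_collide, gas = gas, dt = 2e-7)
  ke <- vapply(ions, function(s)
    0.5 * 500 * amu * sum(s$velocity^2), numeric(1))
  expect_equal(mean(ke) / (1.5 * kB * 300), 1, tolerance = 0.1)
  # collision rate against the analytic hard-sphere rate n sigma <v_rel>
  set.seed(2)
  v0 <- c(400, 0, 0)
  st0 <- trap_ion_state(c(0, 0), v0, 500, 1)
  dtc <- 2e-9; trials <- 2e5
  events <- 0L
  for (k in seq_len(trials)) {
    if (any(maybe_collide(st0, gas, dtc)$velocity != v0)) events <- events + 1L
  }
  vg <- matrix(stats::rnorm(3e6, 0, sqrt(kB * 300 / gas$mass_kg)), ncol = 3)
  vrel <- sqrt((v0[1] - vg[, 1])^2 + vg[, 2]^2 + vg[, 3]^2)
  rate_th <- gas$n_gas * gas$cross_section * mean(vrel)
  expect_equal(events / (trials * dtc) / rate_th, 1, tolerance = 0.05)
})

test_that("photon exposure: on-axis fluence, distant orbit, circle oracle", {
  laser <- laser_model()
  expect_equal(photon_exposure(matrix(0, 10, 2), laser), laser$F0)
  far <- matrix(rep(c(5e-3, 0), each = 4), ncol = 2)
  expect_lt(photon_exposure(far, laser) / laser$F0, 1e-10)
  # circular orbit through an offset beam vs numeric quadrature of the
  # Gaussian around the circle
  rho <- 3e-4
  off <- laser_model(offset = c(2e-4, 0))
  th <- seq(0, 2 * pi, length.out = 2001)[-2001]
  orbit <- cbind(rho * cos(th), rho * sin(th))
  oracle <- stats::integrate(function(a)
    exp(-((rho * cos(a) - 2e-4)^2 + (rho * sin(a))^2) /
          (2 * off$sigma^2)), 0, 2 * pi)$value / (2 * pi) * off$F0
  expect_equal(photon_exposure(orbit, off), oracle, tolerance = 0.01)
})

test_that("fragmentation fate: survival at zero exposure, binomial count, kick", {
  laser <- laser_model()
  set.seed(3)
  out0 <- fragment_fate(rep(0, 100), laser)
  expect_false(any(out0$fragmented))
  # k_frag is calibrated so the on-axis survival probability is one half
  expo <- rep(laser$F0, 10000)
  out <- fragment_fate(expo, laser)
  expect_equal(out$p[1], 0.5)
  expect_lt(abs(sum(out$fragmented) - 5000), 4 * sqrt(10000 * 0.25))
  # kick speed carries the configured fraction of the photon energy
  kicks <- out$kick[out$fragmented, ]
  speed <- sqrt(rowSums(kicks^2))
  h <- 6.62607015e-34; c0 <- 299792458
  v_expect <- sqrt(2 * 0.1 * h * c0 / laser$wavelength / (200 * amu))
  expect_equal(unname(speed[1]), v_expect, tolerance = 1e-9)
  expect_lt(max(abs(speed - v_expect)), 1e-6 * v_expect)
})

test_that("pulse-sequence tallies modulate at the encoding frequency", {
  cfg <- default_cfg()
  traj <- traj_config(n_ions = 150, n_indices = 32, pulse_duration = 1e-3,
                      T_spread = 0.5e-3, excitation = 0.3)
  tal <- run_pulse_sequence(450, 1, cfg, traj, seed = 2, expectation = TRUE)
  expect_equal(nrow(tal), 32L)
  expect_equal(tal$survivors + tal$fragments + tal$lost, rep(150, 32))
  fe <- attr(tal, "f_e")
  expect_lte(abs(dominant_bin(tal$fragments) - round(fe * 32)), 1)
  # anti-phase: fragment maxima where the excitation (radius) is smallest
  a <- magnitude_profile(attr(tal, "f_s"), tal$n, cfg)
  expect_lt(stats::cor(tal$fragments, a), -0.5)
  # reproducible under the same seed
  tal2 <- run_pulse_sequence(450, 1, cfg, traj, seed = 2, expectation = TRUE)
  expect_identical(tal$fragments, tal2$fragments)
})

test_that("zero-amplitude sequence gives flat tallies", {
  cfg <- default_cfg()
  traj <- traj_config(n_ions = 100, n_indices = 8, pulse_duration = 5e-4,
                      T_spread = 2.5e-4, excitation = 0)
  tal <- run_pulse_sequence(450, 1, cfg, traj, seed = 4, expectation = TRUE)
  expect_lt(stats::sd(tal$fragments) / mean(tal$fragments), 0.05)
  expect_true(all(tal$lost == 0))
})

test_that("laser displacement scan shows a modulation null and phase reversal", {
  cfg <- default_cfg()
  comp <- function(offset) {
    traj <- traj_config(n_ions = 150, n_indices = 16, pulse_duration = 1e-3,
                        T_spread = 0.5e-3, excitation = 0.3,
                        laser = laser_model(offset = c(offset, 0)))
    tal <- run_pulse_sequence(450, 1, cfg, traj, seed = 5, expectation = TRUE)
    trace_component(tal$fragments, attr(tal, "f_e"))
  }
  c_on <- comp(0); c_null <- comp(3e-4); c_far <- comp(9e-4)
  expect_lt(Mod(c_null), 0.5 * Mod(c_on))          # depth minimum in between
  expect_gt(abs(Arg(c_far / c_on)), pi / 2)        # phase reversal beyond it
})

test_that("exit-aperture criterion produces flux-periodic count dips", {
  cfg <- default_cfg()
  traj <- traj_config(n_ions = 120, n_indices = 16, pulse_duration = 1e-3,
                      T_spread = 0.5e-3, excitation = 0.4,
                      laser = laser_model(pulse_energy = 0), exit_frac = 0.12)
  tal <- run_pulse_sequence(450, 1, cfg, traj, seed = 6)
  expect_gt(max(tal$lost), 0)
  # losses peak where the excitation amplitude peaks (in phase with a(n))
  a <- magnitude_profile(attr(tal, "f_s"), tal$n, cfg)
  expect_gt(stats::cor(tal$lost, a), 0.5)
})
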