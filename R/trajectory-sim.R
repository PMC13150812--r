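#' Background-gas model for hard-sphere collisions
#'
#' @param mass_u Gas molecular mass, u (default N2).
#' @param pressure Pressure, Pa.
#' @param temperature Temperature, K.
#' @param cross_section Hard-sphere collision cross-section, m^2.
#' @return A `gas_model` list (includes the derived number density `n_gas`).
#' @export
gas_model <- function(mass_u = 28, pressure = 1e-3, temperature = 300,
                      cross_section = 2e-18) {
  stopifnot(mass_u > 0, pressure >= 0, temperature > 0, cross_section > 0)
  kB <- 1.380649e-23
  structure(list(mass_u = mass_u, mass_kg = mass_u * .amu,
                 pressure = pressure, temperature = temperature,
                 cross_section = cross_section,
                 n_gas = pressure / (kB * temperature)),
            class = "gas_model")
}

#' Coaxial Gaussian laser model for UVPD
#'
#' @param fwhm Beam full width at half maximum, m.
#' @param pulse_energy Pulse energy, J.
#' @param wavelength Wavelength, m.
#' @param offset Beam center `(x, y)` offset from the trap axis, m.
#' @param k_frag Photofragmentation rate constant (per unit path-averaged
#'   fluence). `NULL` calibrates it so an on-axis ion survives with
#'   probability 0.5.
#' @return A `laser_model` list with derived `sigma` (m) and peak fluence
#'   `F0` (J/m^2).
#' @export
laser_model <- function(fwhm = 0.6e-3, pulse_energy = 25e-6,
                        wavelength = 213e-9, offset = c(0, 0),
                        k_frag = NULL) {
  stopifnot(fwhm > 0, pulse_energy >= 0)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  F0 <- if (pulse_energy > 0) pulse_energy / (2 * pi * sigma^2) else 0
  if (is.null(k_frag)) k_frag <- if (F0 > 0) log(2) / F0 else 0
  structure(list(fwhm = fwhm, pulse_energy = pulse_energy,
                 wavelength = wavelength, offset = offset,
                 sigma = sigma, F0 = F0, k_frag = k_frag),
            class = "laser_model")
}

#' Single trapped-ion state
#'
#' @param position `(x, y)` in the radial plane, m.
#' @param velocity `(vx, vy)` or `(vx, vy, vz)`, m/s.
#' @param mz Mass-to-charge, Th.
#' @param z Charge count.
#' @return A `trap_ion_state` list with `alive = TRUE`.
#' @export
trap_ion_state <- function(position = c(0, 0), velocity = c(0, 0, 0),
                           mz = 500, z = 1L) {
  if (length(velocity) == 2) velocity <- c(velocity, 0)
  structure(list(position = position, velocity = velocity,
                 mz = mz, z = as.integer(z), alive = TRUE),
            class = "trap_ion_state")
}

#' Thermalized initial ion cloud
#'
#' A 2D Gaussian cloud with thermal velocities, standing in for the
#' collisionally cooled distribution extracted from a full-optics injection
#' model.
#'
#' @param n Number of ions.
#' @param mz,z Species mass-to-charge (Th) and charge.
#' @param sigma_pos Cloud radial standard deviation, m.
#' @param temperature Kinetic temperature, K.
#' @return List with matrices `pos` (n x 2) and `vel` (n x 3).
#' @export
ion_ensemble <- function(n, mz = 500, z = 1L, sigma_pos = 0.2e-3,
                         temperature = 300) {
  kB <- 1.380649e-23
  m <- mz * z * .amu
  sv <- sqrt(kB * temperature / m)
  list(pos = matrix(stats::rnorm(2 * n, 0, sigma_pos), ncol = 2),
       vel = matrix(stats::rnorm(3 * n, 0, sv), ncol = 3),
       mz = mz, z = as.integer(z))
}

#' Force on a trapped ion
#'
#' Ideal-quadrupole RF field at `f_trap` plus the dipolar excitation field
#' `V_exc(t) / r0` along x:
#' `Fx = -2 z e V cos(2 pi f t) x / r0^2 + z e V_exc / r0`,
#' `Fy = +2 z e V cos(2 pi f t) y / r0^2`.
#' The quadrupole term is linear in position at fixed time.
#'
#' @param state A [trap_ion_state()].
#' @param t Time, s.
#' @param cfg A [swim_config()].
#' @param pulse_value Instantaneous excitation voltage, V.
#' @return Force vector `(Fx, Fy)` in newtons; errors if the ion is outside
#'   the field radius.
#' @export
field_force <- function(state, t, cfg, pulse_value = 0) {
  if (sqrt(sum(state$position^2)) >= cfg$r0)
    stop("ion outside the field radius r0 (lost)")
  ze <- state$z * .e_charge
  c_quad <- 2 * ze * cfg$v_trap * cos(2 * pi * cfg$f_trap * t) / cfg$r0^2
  c(-c_quad * state$position[1] + ze * pulse_value / cfg$r0,
    c_quad * state$position[2])
}

#' One velocity-Verlet integration step
#'
#' Reference (R-level) integrator used by the unit tests; the ensemble
#' simulator runs the same scheme in compiled code. Requires
#' `dt <= 1/(50 f_trap)` so the RF micromotion is resolved.
#'
#' @inheritParams field_force
#' @param dt Time step, s.
#' @param pulse_fn Function of time returning the excitation voltage.
#' @return The advanced [trap_ion_state()].
#' @export
verlet_step <- function(state, dt, t, cfg, pulse_fn = function(t) 0) {
  if (dt > 1 / (50 * cfg$f_trap))
    stop("dt too large: need dt <= 1/(50 f_trap)")
  m <- state$mz * state$z * .amu
  a0 <- field_force(state, t, cfg, pulse_fn(t)) / m
  state$position <- state$position + state$velocity[1:2] * dt + 0.5 * a0 * dt^2
  a1 <- field_force(state, t + dt, cfg, pulse_fn(t + dt)) / m
  state$velocity[1:2] <- state$velocity[1:2] + 0.5 * (a0 + a1) * dt
  if (any(!is.finite(state$position)) || any(!is.finite(state$velocity)))
    stop("integration diverged (non-finite state); reduce dt")
  state
}

#' Stochastic hard-sphere collision with background gas
#'
#' With probability `n_gas * sigma * v_rel * dt` the ion collides elastically
#' with a Maxwell-Boltzmann-sampled gas molecule: the center-of-mass velocity
#' is conserved and the relative velocity is scattered isotropically.
#'
#' @param state A [trap_ion_state()].
#' @param gas A [gas_model()].
#' @param dt Interval over which a collision may occur, s.
#' @return The (possibly velocity-updated) state.
#' @export
maybe_collide <- function(state, gas, dt) {
  if (gas$pressure <= 0) return(state)
  kB <- 1.380649e-23
  m <- state$mz * state$z * .amu
  vg <- stats::rnorm(3, 0, sqrt(kB * gas$temperature / gas$mass_kg))
  rel <- state$velocity - vg
  g <- sqrt(sum(rel^2))
  if (stats::runif(1) < gas$n_gas * gas$cross_section * g * dt) {
    mu <- gas$mass_kg / (m + gas$mass_kg)
    vcom <- state$velocity - mu * rel
    ct <- stats::runif(1, -1, 1); st <- sqrt(1 - ct^2)
    ph <- stats::runif(1, 0, 2 * pi)
    state$velocity <- vcom + mu * g * c(st * cos(ph), st * sin(ph), ct)
  }
  state
}

#' Path-averaged photon exposure
#'
#' Average of the Gaussian beam fluence profile over a sampled trajectory
#' segment (nominally one secular orbit): the quantity controlling the UVPD
#' probability of an ion whose orbit threads the coaxial beam.
#'
#' @param positions Matrix (m x 2) of radial positions, m.
#' @param laser A [laser_model()].
#' @return Path-averaged fluence, J/m^2, in `[0, F0]`.
#' @export
photon_exposure <- function(positions, laser) {
  positions <- rbind(positions)
  d2 <- (positions[, 1] - laser$offset[1])^2 +
    (positions[, 2] - laser$offset[2])^2
  mean(laser$F0 * exp(-d2 / (2 * laser$sigma^2)))
}

#' Monte Carlo fragmentation fate
#'
#' An exposed precursor fragments with probability
#' `1 - exp(-k_frag * exposure)`. On fragmentation the product inherits the
#' precursor velocity plus an isotropic kick in the center-of-mass frame
#' carrying a configurable fraction of the photon energy.
#'
#' @param exposure Path-averaged fluence, J/m^2 (vectorized).
#' @param laser A [laser_model()].
#' @param fragment_mz,fragment_z Product ion m/z (Th) and charge, for the
#'   kick kinematics.
#' @param energy_frac Fraction of one photon's energy released into product
#'   kinetic energy.
#' @return List: `fragmented` (logical), `kick` (matrix of 3D velocity kicks,
#'   m/s, zero rows for survivors).
#' @export
fragment_fate <- function(exposure, laser, fragment_mz = 200, fragment_z = 1L,
                          energy_frac = 0.1) {
  p <- 1 - exp(-laser$k_frag * exposure)
  frag <- stats::runif(length(exposure)) < p
  h <- 6.62607015e-34; c0 <- 299792458
  e_photon <- h * c0 / laser$wavelength
  m <- fragment_mz * fragment_z * .amu
  vkick <- sqrt(2 * energy_frac * e_photon / m)
  kick <- matrix(0, length(exposure), 3)
  nf <- sum(frag)
  if (nf) {
    ct <- stats::runif(nf, -1, 1); st <- sqrt(1 - ct^2)
    ph <- stats::runif(nf, 0, 2 * pi)
    kick[frag, ] <- vkick * cbind(st * cos(ph), st * sin(ph), ct)
  }
  list(fragmented = frag, p = p, kick = kick)
}

#' Trajectory-simulation run parameters
#'
#' Desk-scale defaults: the pulse window, band and sample rate are reduced
#' relative to the acquisition-scale configuration so that a full Monte
#' Carlo index sequence integrates in seconds while keeping the identical
#' physics (the SWIM band and trap RF are unchanged).
#'
#' @param n_ions Ions per trap fill (a fresh fill is sampled every index).
#' @param n_indices SWIM indices simulated.
#' @param dt Integrator step, s (must resolve the RF period).
#' @param pulse_duration,T_spread,dac_rate Reduced-scale pulse parameters.
#' @param excitation Pulse amplitude scale, volts zero-to-peak.
#' @param cloud_sigma Initial cloud radial sd, m.
#' @param temperature Initial kinetic temperature, K.
#' @param gas A [gas_model()] or `NULL` for collision-free runs.
#' @param collision_stride Integrator steps between collision tests.
#' @param laser A [laser_model()] or `NULL` to disable UVPD.
#' @param exit_frac Exit-aperture criterion: ions whose radial excursion in
#'   the final secular orbit exceeds `exit_frac * r0` are counted lost
#'   (flux-periodic loss); set to `Inf` to disable.
#' @return A `traj_config` list.
#' @export
traj_config <- function(n_ions = 200, n_indices = 32, dt = 2e-8,
                        pulse_duration = 2e-3, T_spread = 1e-3,
                        dac_rate = 5e6, excitation = 0.3,
                        cloud_sigma = 0.2e-3, temperature = 300,
                        gas = NULL, collision_stride = 10L,
                        laser = laser_model(), exit_frac = Inf) {
  structure(list(n_ions = as.integer(n_ions), n_indices = as.integer(n_indices),
                 dt = dt, pulse_duration = pulse_duration,
                 T_spread = T_spread, dac_rate = dac_rate,
                 excitation = excitation, cloud_sigma = cloud_sigma,
                 temperature = temperature, gas = gas,
                 collision_stride = as.integer(collision_stride),
                 laser = laser, exit_frac = exit_frac),
            class = "traj_config")
}

#' Monte Carlo SWIM pulse-sequence run
#'
#' For each SWIM index a fresh thermal ion cloud is sampled, integrated
#' through the synthesized excitation pulse in the RF quadrupole (compiled
#' velocity-Verlet core, optional hard-sphere collisions), and scored: ions
#' ejected past `r0` or failing the exit-aperture criterion are lost;
#' surviving precursors are then tested for UVPD using the path-averaged
#' photon exposure of their final secular orbit. The output is the per-index
#' tally of surviving precursors, fragments and losses.
#'
#' @param mz,z Precursor m/z (Th) and charge.
#' @param cfg A [swim_config()] (trap RF, band and geometry).
#' @param traj A [traj_config()].
#' @param seed RNG seed.
#' @param expectation Report the expected (mean) fragment count
#'   `sum(1 - exp(-k_frag * exposure))` instead of a binomial Monte Carlo
#'   draw; removes fate-sampling noise from modulation-depth studies.
#' @return Data frame: `n`, `survivors`, `fragments`, `lost` (rows sum to
#'   `n_ions` up to expectation rounding), with the species' secular and
#'   encoding frequencies as attributes `f_s` and `f_e`.
#' @export
run_pulse_sequence <- function(mz, z, cfg, traj = traj_config(), seed = 1L,
                               expectation = FALSE) {
  validate_swim_config(cfg)
  if (traj$n_ions < 10) stop("ensemble too small")
  fs <- as.numeric(secular_frequency(mz, cfg, "exact"))
  if (fs < cfg$f_min || fs > cfg$f_max)
    stop("species secular frequency outside the SWIM band")
  pcfg <- cfg
  pcfg$pulse_duration <- traj$pulse_duration
  pcfg$T_spread <- traj$T_spread
  pcfg$dac_rate <- traj$dac_rate
  pcfg$amplitude <- traj$excitation
  pcfg$n_indices <- max(2L, traj$n_indices)
  pcfg <- validate_swim_config(pcfg)

  m_kg <- mz * z * .amu
  q_C <- z * .e_charge
  n_steps <- round(traj$pulse_duration / traj$dt)
  tail_steps <- min(n_steps, ceiling(1 / (fs * traj$dt)))
  tail_start <- n_steps - tail_steps
  laser_on <- !is.null(traj$laser) && traj$laser$F0 > 0
  las <- if (laser_on) traj$laser else laser_model(pulse_energy = 0)
  gas_on <- !is.null(traj$gas) && traj$gas$pressure > 0
  gas <- if (gas_on) traj$gas else gas_model(pressure = 0)

  set.seed(seed)
  out <- data.frame(n = seq_len(traj$n_indices) - 1L,
                    survivors = 0, fragments = 0, lost = 0)
  for (i in seq_len(traj$n_indices)) {
    n_idx <- i - 1L
    pulse <- synthesize_pulse(n_idx, pcfg)
    ens <- ion_ensemble(traj$n_ions, mz, z, traj$cloud_sigma,
                        traj$temperature)
    res <- .cpp_ensemble_pulse(ens$pos, ens$vel, m_kg, q_C,
                               cfg$v_trap, cfg$f_trap, cfg$r0,
                               pulse$samples, pcfg$dac_rate,
                               traj$dt, n_steps,
                               gas_on, gas$mass_kg, gas$n_gas,
                               gas$cross_section, gas$temperature,
                               traj$collision_stride,
                               tail_start, las$F0, las$sigma,
                               las$offset[1], las$offset[2])
    lost <- res[, 3] > 0 | res[, 2] > traj$exit_frac * cfg$r0
    alive <- which(!lost)
    nfrag <- 0
    if (laser_on && length(alive)) {
      nfrag <- if (expectation) {
        sum(1 - exp(-las$k_frag * res[alive, 1]))
      } else sum(fragment_fate(res[alive, 1], las)$fragmented)
    }
    out$lost[i] <- sum(lost)
    out$fragments[i] <- nfrag
    out$survivors[i] <- length(alive) - nfrag
  }
  if (all(out$survivors + out$fragments == 0L))
    warning("all ions lost in every fill; excitation too strong?")
  attr(out, "f_s") <- fs
  attr(out, "f_e") <- encoding_frequency(fs, cfg)
  out
}

#' Write pulse-sequence tallies to CSV
#'
#' @param tallies Output of [run_pulse_sequence()].
#' @param path File path.
#' @return `path` invisibly.
#' @export
write_tallies <- function(tallies, path) {
  utils::write.csv(tallies, path, row.names = FALSE)
  invisible(path)
}
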