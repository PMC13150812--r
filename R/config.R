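# Physical constants (CODATA 2018)
.e_charge <- 1.602176634e-19   # C
.amu      <- 1.66053906660e-27 # kg

#' Instrument and SWIM-band configuration
#'
#' Bundles the RF trap parameters and the SWIM excitation band into a single
#' validated object used throughout the package. The defaults reproduce a
#' 2DMS-enabled QToF: a 1 MHz trapping waveform at 240 Vpp (120 V zero-to-peak),
#' a SWIM band from 10 to 500 kHz, 20 ms pulses at 25 Msamples/s and 1024 SWIM
#' indices saved at 1 Hz.
#'
#' @param f_trap Trap RF frequency, Hz.
#' @param v_trap Trap RF amplitude, volts zero-to-peak. (If you know the
#'   peak-to-peak value, halve it; `vpp` is accepted as an alternative.)
#' @param vpp Optional trap RF amplitude, volts peak-to-peak. When given it
#'   overrides `v_trap` with `vpp / 2`.
#' @param r0 Quadrupole field radius, m. Not a directly measured quantity on
#'   most instruments; the default (2.8954 mm) is a synthetic fixture value
#'   back-solved so that the Eq.-5-style prediction for an m/z 449.92
#'   precursor is 0.102 cycles per index under the default trap settings.
#' @param f_min,f_max SWIM band edges, Hz. Secular frequencies inside
#'   `[f_min, f_max]` are modulated; `f_max` must not exceed `f_trap / 2`.
#' @param T_spread Quadratic-phase spreading width, s. The synthesized pulse's
#'   group delay runs from 0 at `f_min` to `T_spread` at `f_max`.
#' @param dac_rate Waveform sample rate, samples/s.
#' @param pulse_duration Duration of each SWIM pulse, s.
#' @param n_indices Number of SWIM indices per acquisition (a power of two).
#' @param index_rate SWIM-index sampling rate, Hz (spectra saved per second).
#' @param amplitude Excitation amplitude scale, volts zero-to-peak of the
#'   largest pulse in the sequence (the n = 1 pulse peak is normalized to
#'   this value).
#' @param mz_display Nominal precursor display range `c(lo, hi)` in Th; decoded
#'   rows mapping outside it are reported with a sentinel (`NA`) precursor m/z
#'   rather than dropped.
#'
#' @return An object of class `swim_config` (a named list).
#' @examples
#' cfg <- swim_config()
#' cfg$v_trap
#' swim_config(vpp = 240)$v_trap  # identical
#' @export
swim_config <- function(f_trap = 1e6, v_trap = 120, vpp = NULL,
                        r0 = 2.8954e-3,
                        f_min = 1e4, f_max = 5e5,
                        T_spread = 10e-3,
                        dac_rate = 25e6, pulse_duration = 20e-3,
                        n_indices = 1024L, index_rate = 1,
                        amplitude = 1,
                        mz_display = c(90, 4500)) {
  if (!is.null(vpp)) v_trap <- vpp / 2
  cfg <- list(f_trap = f_trap, v_trap = v_trap, r0 = r0,
              f_min = f_min, f_max = f_max, T_spread = T_spread,
              dac_rate = dac_rate, pulse_duration = pulse_duration,
              n_indices = as.integer(n_indices), index_rate = index_rate,
              amplitude = amplitude, mz_display = mz_display)
  class(cfg) <- "swim_config"
  validate_swim_config(cfg)
}

#' Validate a `swim_config`
#'
#' Checks the invariants: `0 < f_min < f_max <= f_trap/2`, positive voltages
#' and geometry, and a power-of-two index count.
#'
#' @param cfg A `swim_config`.
#' @return The config, invisibly unchanged, or an error.
#' @export
validate_swim_config <- function(cfg) {
  stopifnot(inherits(cfg, "swim_config"))
  with(cfg, {
    if (!(f_min > 0 && f_min < f_max)) stop("need 0 < f_min < f_max")
    if (f_max > f_trap / 2) stop("f_max must not exceed f_trap/2 (secular Nyquist)")
    if (v_trap <= 0) stop("v_trap must be positive")
    if (r0 <= 0) stop("r0 must be positive")
    if (T_spread <= 0) stop("T_spread must be positive")
    if (n_indices < 1 || bitwAnd(n_indices, n_indices - 1L) != 0L)
      stop("n_indices must be a power of two")
    if (index_rate <= 0) stop("index_rate must be positive")
    if (pulse_duration <= 0 || dac_rate <= 0) stop("pulse timing must be positive")
  })
  cfg
}

#' @export
print.swim_config <- function(x, ...) {
  cat("SWIM instrument configuration\n")
  cat(sprintf("  trap RF        : %.6g Hz, %.6g V zero-to-peak, r0 = %.4g mm\n",
              x$f_trap, x$v_trap, 1e3 * x$r0))
  cat(sprintf("  SWIM band      : %.6g - %.6g Hz, T = %.3g ms\n",
              x$f_min, x$f_max, 1e3 * x$T_spread))
  cat(sprintf("  pulses         : %d indices, %.3g ms at %.3g Msamples/s, %.3g V max\n",
              x$n_indices, 1e3 * x$pulse_duration, 1e-6 * x$dac_rate, x$amplitude))
  cat(sprintf("  index rate     : %.3g Hz  (encoding band 0 - 0.5 cycles/index)\n",
              x$index_rate))
  invisible(x)
}

#' Total acquisition time for a 2D spectrum
#'
#' Each SWIM index is repeated for a number of trap-and-release fills before
#' the summed spectrum is saved, so the wall-clock acquisition time is
#' `n_indices * fills_per_index * pulse_duration`.
#'
#' @param cfg A `swim_config`.
#' @param fills_per_index Trap-and-release cycles summed per SWIM index.
#' @return Acquisition time in seconds.
#' @examples
#' acquisition_time(swim_config())  # 1024 s, about 17 minutes
#' @export
acquisition_time <- function(cfg, fills_per_index = 50) {
  validate_swim_config(cfg)
  cfg$n_indices * fills_per_index * cfg$pulse_duration
}

#' Read/write a `swim_config` as JSON
#'
#' @param cfg A `swim_config`.
#' @param path File path.
#' @return `write_swim_config` returns `path` invisibly; `read_swim_config`
#'   returns a validated `swim_config`.
#' @export
write_swim_config <- function(cfg, path) {
  validate_swim_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_swim_config
#' @export
read_swim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("f_trap", "v_trap", "r0", "f_min", "f_max")
  miss <- setdiff(needed, names(raw))
  if (length(miss)) stop("config file is missing fields: ", paste(miss, collapse = ", "))
  do.call(swim_config, raw[names(raw) %in% names(formals(swim_config))])
}

# internal cache key for per-config derived scalars (pulse amplitude scale)
.cfg_key <- function(cfg) {
  paste(format(c(cfg$f_trap, cfg$f_min, cfg$f_max, cfg$T_spread,
                 cfg$dac_rate, cfg$pulse_duration, cfg$amplitude),
               digits = 17), collapse = "|")
}
.swim_cache <- new.env(parent = emptyenv())
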