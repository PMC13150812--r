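#' SWIM spectral magnitude profile
#'
#' The per-frequency amplitude of SWIM pulse `n`:
#' `M(f, n) = (1 + sin(n * pi * (f - f_min)/(f_max - f_min) - pi/2)) / 2`.
#' As `n` increments, the amplitude at a fixed frequency follows a sampled
#' sinusoid, which is what encodes each secular frequency as a modulation
#' frequency in the index domain. `M` is identically zero for `n = 0` (the
#' unexcited pulse) and at the lower band edge.
#'
#' @param f Frequency, Hz. Must lie inside `[f_min, f_max]`.
#' @param n SWIM index (integer >= 0). `f` and `n` are recycled.
#' @param cfg A [swim_config()].
#' @return Magnitude in `[0, 1]`.
#' @examples
#' cfg <- swim_config()
#' magnitude_profile((cfg$f_min + cfg$f_max) / 2, 0:3, cfg)  # 0, 0.5, 1, 0.5
#' @export
magnitude_profile <- function(f, n, cfg) {
  validate_swim_config(cfg)
  if (any(f < cfg$f_min | f > cfg$f_max))
    stop("frequency outside the SWIM band [f_min, f_max]")
  if (any(n < 0)) stop("SWIM index n must be >= 0")
  x <- (f - cfg$f_min) / (cfg$f_max - cfg$f_min)
  m <- 0.5 * (1 + sin(n * pi * x - pi / 2))
  pmin(pmax(m, 0), 1)
}

#' Quadratic spreading phase
#'
#' Phase applied to the frequency-domain prescription before the inverse
#' transform so the pulse energy is spread over the acquisition window,
#' reducing the peak voltage demanded of the DAC and amplifier. The adopted
#' convention scales the quadratic so that the group delay
#' `(1/2pi) dphi/df` runs linearly from 0 at `f_min` to `T_spread` at `f_max`:
#' `phi(f) = pi * T * (f - f_min)^2 / (f_max - f_min)`.
#' `literal = TRUE` returns the bare quadratic `T (f - f_min)^2 / (f_max - f_min)`
#' (same shape, dimensionally s*Hz) for cross-checking.
#'
#' @inheritParams magnitude_profile
#' @param literal Use the unnormalized quadratic instead of the group-delay
#'   convention.
#' @return Phase in radians (or s*Hz when `literal = TRUE`).
#' @export
quadratic_phase <- function(f, cfg, literal = FALSE) {
  validate_swim_config(cfg)
  if (any(f < cfg$f_min | f > cfg$f_max))
    stop("frequency outside the SWIM band [f_min, f_max]")
  quad <- (f - cfg$f_min)^2 / (cfg$f_max - cfg$f_min)
  if (literal) cfg$T_spread * quad else pi * cfg$T_spread * quad
}

# unscaled time-domain pulse: inverse DFT of M * exp(i phi) on the DFT grid
# of the pulse window. Out-of-band bins are exactly zero.
.pulse_samples_raw <- function(n, cfg, literal_phase = FALSE) {
  ns <- round(cfg$pulse_duration * cfg$dac_rate)
  freqs <- (seq_len(ns) - 1) / ns * cfg$dac_rate
  spec <- complex(length.out = ns)
  inband <- which(freqs >= cfg$f_min & freqs <= cfg$f_max & freqs <= cfg$dac_rate / 2)
  if (n > 0 && length(inband)) {
    m <- magnitude_profile(freqs[inband], n, cfg)
    ph <- quadratic_phase(freqs[inband], cfg, literal = literal_phase)
    spec[inband] <- m * exp(1i * ph)
    # hermitian mirror so the inverse transform is real
    mirror <- ns - (inband - 1) + 1
    ok <- mirror >= 1 & mirror <= ns & mirror != inband
    spec[mirror[ok]] <- Conj(spec[inband][ok])
  }
  Re(stats::fft(spec, inverse = TRUE)) / ns
}

# volts-per-unit scale such that the n = 1 pulse peaks at cfg$amplitude
.pulse_scale <- function(cfg, literal_phase = FALSE) {
  key <- paste0(.cfg_key(cfg), if (literal_phase) "|lit")
  hit <- .swim_cache[[key]]
  if (!is.null(hit)) return(hit)
  ref <- max(abs(.pulse_samples_raw(1L, cfg, literal_phase)))
  sc <- if (ref > 0) cfg$amplitude / ref else 1
  assign(key, sc, envir = .swim_cache)
  sc
}

#' Synthesize one SWIM excitation pulse
#'
#' Builds the frequency-domain prescription `M(f, n) * exp(i * phi(f))` on the
#' DFT grid of the pulse window (magnitude zero outside the SWIM band), applies
#' the inverse Fourier transform and takes the real part. The voltage scale is
#' normalized once per configuration so the n = 1 pulse peaks at
#' `cfg$amplitude` volts zero-to-peak. The polarity-inverted channel of a
#' dipolar pair is simply `-samples` and is not generated separately.
#'
#' @inheritParams magnitude_profile
#' @param n SWIM index (single integer >= 0). Index 0 yields the all-zero,
#'   unexcited pulse.
#' @param literal_phase Use the literal quadratic phase (see
#'   [quadratic_phase()]).
#' @return A `swim_pulse`: list with `n`, `samples` (volts), `sample_rate`,
#'   `duration`.
#' @examples
#' cfg <- swim_config(dac_rate = 2e6, pulse_duration = 5e-3, T_spread = 2e-3)
#' p <- synthesize_pulse(3, cfg)
#' max(abs(p$samples))
#' @export
synthesize_pulse <- function(n, cfg, literal_phase = FALSE) {
  validate_swim_config(cfg)
  if (length(n) != 1 || n < 0) stop("n must be a single index >= 0")
  if (cfg$dac_rate < 2 * cfg$f_max)
    stop("dac_rate below 2*f_max: the excitation band would alias")
  x <- .pulse_samples_raw(as.integer(n), cfg, literal_phase)
  x <- x * .pulse_scale(cfg, literal_phase)
  structure(list(n = as.integer(n), samples = x,
                 sample_rate = cfg$dac_rate,
                 duration = length(x) / cfg$dac_rate),
            class = "swim_pulse")
}

#' @export
print.swim_pulse <- function(x, ...) {
  cat(sprintf("SWIM pulse n = %d: %d samples at %.3g Msamples/s (%.3g ms), peak %.4g V\n",
              x$n, length(x$samples), 1e-6 * x$sample_rate,
              1e3 * x$duration, max(abs(x$samples))))
  invisible(x)
}

#' Synthesize the full SWIM pulse sequence
#'
#' @inheritParams synthesize_pulse
#' @return A list of `cfg$n_indices` [synthesize_pulse()] objects for
#'   `n = 0 .. n_indices - 1` (the first is the unexcited, all-zero pulse).
#'   Deterministic: regenerating from the same configuration is bit-identical.
#' @export
pulse_sequence <- function(cfg, literal_phase = FALSE) {
  validate_swim_config(cfg)
  lapply(seq_len(cfg$n_indices) - 1L, synthesize_pulse,
         cfg = cfg, literal_phase = literal_phase)
}

#' Single-frequency probe of a pulse
#'
#' Magnitude of the discrete Fourier component of a pulse at probe frequency
#' `f`, scaled so that (for an on-grid frequency) it equals the synthesized
#' spectral magnitude in volts. Used to verify the encoding property: across
#' the index sequence this magnitude follows `M(f, n)`.
#'
#' @param pulse A `swim_pulse`.
#' @param f Probe frequency, Hz.
#' @return Magnitude (volts).
#' @export
probe_magnitude <- function(pulse, f) {
  t <- (seq_along(pulse$samples) - 1) / pulse$sample_rate
  abs(sum(pulse$samples * exp(-2i * pi * f * t)))
}

#' Export a pulse waveform
#'
#' Writes a single pulse either as raw little-endian 32-bit floats or as
#' two-column text `(t, V)`, with a JSON sidecar recording the configuration.
#'
#' @param pulse A `swim_pulse`.
#' @param path Output file path.
#' @param format `"f32"` (raw float32) or `"txt"` (two-column text).
#' @param cfg Optional [swim_config()] stored in the JSON sidecar
#'   (`<path>.json`).
#' @return `path`, invisibly.
#' @export
write_pulse <- function(pulse, path, format = c("f32", "txt"), cfg = NULL) {
  format <- match.arg(format)
  if (format == "f32") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(pulse$samples), con, size = 4, endian = "little")
  } else {
    t <- (seq_along(pulse$samples) - 1) / pulse$sample_rate
    utils::write.table(data.frame(t = t, V = pulse$samples), path,
                       row.names = FALSE, col.names = FALSE)
  }
  side <- list(n = pulse$n, sample_rate = pulse$sample_rate,
               duration = pulse$duration, format = format)
  if (!is.null(cfg)) side$config <- unclass(cfg)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
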