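# Shared fixtures: all synthetic, built in code.

# acquisition-scale configuration (paper-like defaults)
default_cfg <- function(...) swim_config(...)

# reduced-rate pulse configuration so waveform tests run in milliseconds
pulse_cfg <- function(...) {
  args <- utils::modifyList(list(dac_rate = 2e6, pulse_duration = 5e-3,
                                 T_spread = 2e-3, n_indices = 64L),
                            list(...))
  do.call(swim_config, args)
}

# single-frequency component of an index-domain trace (mean removed)
trace_component <- function(x, fe) {
  n <- seq_along(x) - 1
  sum((x - mean(x)) * exp(-2i * pi * fe * n))
}

# index of the dominant FFT bin (excluding DC) of a trace
dominant_bin <- function(x) {
  sp <- Mod(stats::fft(x - mean(x)))[seq_len(floor(length(x) / 2))]
  which.max(sp[-1])  # bin k corresponds to frequency k/length(x)
}

# a simple fragmenting species
frag_species <- function(mz, frags, mechanism = "uvpd", z = 1, abundance = 1,
                         yield = 0.5) {
  ion_species(mz, z, abundance,
              channels = lapply(frags, function(f)
                frag_channel(f, 1, mechanism, yield / length(frags))))
}

# decode pipeline used by the end-to-end checks
decode_cube <- function(cube, cfg, axis = "eq6", order = 2, snr_cal = 10,
                        tol_ppm = 20000) {
  spec <- transform_cube(cube)
  spec <- first_pass_axis(spec, cfg, axis)
  pairs <- detect_autocorrelation_peaks(spec, snr_threshold = snr_cal,
                                        tol_ppm = tol_ppm)
  recalibrate(spec, cfg, pairs = pairs, order = order)
}

# fraction of fragment channels whose strongest picked peak points at the
# right precursor (nearest-species assignment on the calibrated axis)
assignment_accuracy <- function(peaks, species, bin_tol) {
  truth <- vapply(species, function(s) s$mz, numeric(1))
  tot <- 0L; ok <- 0L
  for (i in seq_along(species)) {
    for (ch in species[[i]]$channels) {
      tot <- tot + 1L
      cand <- peaks[abs(peaks$product_mz - ch$product_mz) <= bin_tol &
                      !peaks$on_autocorrelation, ]
      if (!nrow(cand)) next
      cand <- cand[which.max(cand$height), ]
      if (which.min(abs(truth - cand$precursor_mz)) == i) ok <- ok + 1L
    }
  }
  c(correct = ok, total = tot)
}

# number of well-separated local maxima above a height fraction
count_peaks_1d <- function(x, thr_frac = 0.3, min_sep = 10L) {
  thr <- thr_frac * max(x)
  idx <- which(x > thr & x >= c(-Inf, x[-length(x)]) & x >= c(x[-1], -Inf))
  if (!length(idx)) return(0L)
  keep <- idx[c(TRUE, diff(idx) >= min_sep)]
  length(keep)
}
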