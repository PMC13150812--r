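#' Fourier transform of a data cube
#'
#' Converts a cube of per-index product-ion spectra into an (uncalibrated)
#' 2D magnitude spectrum: per product-m/z column the column mean is
#' subtracted (so unmodulated background stays in row 0), the series is
#' zero-filled once (N to 2N), discrete-Fourier transformed, and the N
#' non-negative-frequency magnitude rows are kept. Row r corresponds to
#' encoding frequency `r / (2N)` cycles/index.
#'
#' @param cube A `data_cube` (see [generate_cube()] or [read_cube()]).
#' @param window `"rectangular"` (default) or `"hann"` apodization applied
#'   before zero-filling.
#' @param subtract_mean Subtract each column's mean before the transform.
#' @return A `spectrum2d`: list with `magnitude` (`N` x `n_bins`),
#'   `fe_axis` (cycles/index), `product_axis`, `precursor_axis` (`NULL`
#'   until [first_pass_axis()]), `calibration`, `meta`.
#' @export
transform_cube <- function(cube, window = c("rectangular", "hann"),
                           subtract_mean = TRUE) {
  window <- match.arg(window)
  stopifnot(inherits(cube, "data_cube"))
  x <- cube$intensities
  if (!all(is.finite(x))) stop("cube contains non-finite values")
  N <- nrow(x)
  if (N < 8) stop("need at least 8 SWIM indices")
  if (subtract_mean) x <- sweep(x, 2, colMeans(x))
  if (window == "hann")
    x <- x * (0.5 - 0.5 * cos(2 * pi * (seq_len(N) - 1) / N))
  padded <- rbind(x, matrix(0, nrow = N, ncol = ncol(x)))
  mag <- Mod(stats::mvfft(padded))[seq_len(N), , drop = FALSE]
  structure(list(magnitude = mag,
                 fe_axis = (seq_len(N) - 1) / (2 * N),
                 product_axis = cube$product_axis,
                 precursor_axis = NULL,
                 axis_method = NULL,
                 calibration = NULL,
                 meta = cube$meta),
            class = "spectrum2d")
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat(sprintf("2D mass spectrum: %d encoding-frequency rows x %d product bins\n",
              nrow(x$magnitude), ncol(x$magnitude)))
  if (!is.null(x$precursor_axis))
    cat(sprintf("  precursor axis (%s%s): m/z %.4g - %.4g\n",
                x$axis_method,
                if (is.null(x$calibration)) ", first pass" else ", recalibrated",
                min(x$precursor_axis, na.rm = TRUE),
                max(x$precursor_axis, na.rm = TRUE)))
  invisible(x)
}

#' Assign the first-pass precursor m/z axis
#'
#' Re-expresses each encoding-frequency row as precursor m/z through
#' [mz_from_encoding()]. Because the map is reciprocal, precursor bins are
#' narrower at low m/z than at high m/z and the axis decreases with row
#' index. Row 0 (f_e = 0) and rows mapping outside the nominal display range
#' are assigned the sentinel `NA` rather than dropped.
#'
#' @param spec A `spectrum2d` from [transform_cube()].
#' @param cfg A [swim_config()].
#' @param method `"eq6"` (Koizumi form, default), `"eq5"` (reciprocal Dehmelt
#'   form) or `"exact"`.
#' @return The spectrum with `precursor_axis` set.
#' @export
first_pass_axis <- function(spec, cfg, method = c("eq6", "eq5", "exact")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "spectrum2d"))
  mz <- rep(NA_real_, length(spec$fe_axis))
  pos <- spec$fe_axis > 0
  mz[pos] <- mz_from_encoding(spec$fe_axis[pos], cfg, method)
  rng <- cfg$mz_display
  mz[!is.na(mz) & (mz < rng[1] | mz > rng[2])] <- NA_real_
  spec$precursor_axis <- mz
  spec$axis_method <- method
  spec$calibration <- NULL
  spec
}

# 2D local maxima above a column-wise SNR threshold.
# noise per column: 1.4826 * MAD (stats::mad default scaling).
# Window sidelobes of the rectangular transform (and the noise ridge under an
# intense precursor) ride in the same column as the genuine peak, so a
# candidate is dropped when a much stronger peak sits within sidelobe_rows of
# it in its own column (relative height < sidelobe_frac).
.find_peaks2d <- function(spec, snr_threshold = 5, neighborhood = 1L,
                          sidelobe_frac = 0.25, sidelobe_rows = 100L) {
  m <- spec$magnitude
  nr <- nrow(m); nc <- ncol(m)
  noise <- apply(m, 2, stats::mad)
  if (all(noise <= 0)) noise[] <- .Machine$double.eps
  else noise[noise <= 0] <- max(stats::median(noise[noise > 0]),
                                .Machine$double.eps)
  r <- as.integer(neighborhood)
  keep <- matrix(TRUE, nr, nc)
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0 && dc == 0) next
    shifted <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    shifted[rs, cs] <- m[rs - dr, cs - dc]
    keep <- keep & (m > shifted | (m == shifted & (dr > 0 | (dr == 0 & dc > 0))))
  }
  snr <- sweep(m, 2, noise, "/")
  keep <- keep & (snr >= snr_threshold)
  keep[1, ] <- FALSE                      # DC row is not a modulation peak
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(row = idx[, 1], col = idx[, 2],
                    height = m[idx], snr = snr[idx])
  if (nrow(out) > 1 && sidelobe_frac > 0) {
    drop <- logical(nrow(out))
    for (cc in unique(out$col)) {
      ii <- which(out$col == cc)
      if (length(ii) < 2) next
      for (a in ii) {
        near <- ii[abs(out$row[ii] - out$row[a]) <= sidelobe_rows]
        if (any(out$height[near] * sidelobe_frac > out$height[a]))
          drop[a] <- TRUE
      }
    }
    out <- out[!drop, , drop = FALSE]
  }
  out
}

# 7-point intensity-weighted centroid along the precursor axis, in m/z
# coordinates; falls back to the fe axis when the m/z axis is unavailable.
.centroid_precursor <- function(spec, row, col, half = 3L) {
  rows <- max(2L, row - half):min(nrow(spec$magnitude), row + half)
  w <- spec$magnitude[rows, col]
  ax <- if (!is.null(spec$precursor_axis)) spec$precursor_axis[rows] else NULL
  fe <- spec$fe_axis[rows]
  fe_c <- sum(w * fe) / sum(w)
  mz_c <- if (!is.null(ax) && !anyNA(ax)) sum(w * ax) / sum(w) else NA_real_
  c(fe = fe_c, mz = mz_c)
}

#' Detect autocorrelation-line peaks
#'
#' Every peak on the diagonal `precursor m/z = product m/z` is an intact
#' precursor, so these peaks tie the (approximate) first-pass precursor axis
#' to the accurate product axis and seed the recalibration. A peak qualifies
#' when its first-pass precursor m/z matches its product m/z within
#' `tol_ppm`.
#'
#' @param spec A `spectrum2d` with a first-pass axis.
#' @param snr_threshold Minimum signal-to-noise for candidate peaks.
#' @param tol_ppm Diagonal matching tolerance, ppm of the product m/z.
#' @param dedup Keep only the strongest pair per frequency-row cluster and
#'   per product peak (recommended for calibration); `FALSE` returns every
#'   diagonal peak, e.g. one per isotopologue.
#' @return Data frame of calibration pairs: `fe`, `product_mz` (truth),
#'   `precursor_mz_firstpass`, `height`, `snr`.
#' @export
detect_autocorrelation_peaks <- function(spec, snr_threshold = 10,
                                         tol_ppm = 20000, dedup = TRUE) {
  stopifnot(inherits(spec, "spectrum2d"))
  if (is.null(spec$precursor_axis)) stop("assign a first-pass axis first")
  pk <- .find_peaks2d(spec, snr_threshold)
  if (nrow(pk)) {
    cen <- t(vapply(seq_len(nrow(pk)), function(i)
      .centroid_precursor(spec, pk$row[i], pk$col[i]), numeric(2)))
    prod_mz <- spec$product_axis[pk$col]
    dev <- abs(cen[, "mz"] - prod_mz) / prod_mz * 1e6
    on_line <- !is.na(dev) & dev <= tol_ppm
    pk <- data.frame(fe = cen[on_line, "fe"], product_mz = prod_mz[on_line],
                     precursor_mz_firstpass = cen[on_line, "mz"],
                     height = pk$height[on_line], snr = pk$snr[on_line])
    if (dedup) {
      # one pair per frequency row cluster (isotopologues share a row; keep
      # the strongest), and one per product peak
      fe_bin <- spec$fe_axis[2] - spec$fe_axis[1]
      pk <- pk[order(-pk$height), ]
      pk <- pk[!duplicated(round(pk$fe / (2 * fe_bin))), ]
      pk <- pk[!duplicated(round(pk$product_mz * 100)), ]
    }
    pk <- pk[order(pk$fe), ]
  } else pk <- data.frame()
  if (!nrow(pk))
    stop("no autocorrelation-line peaks found: calibration impossible")
  rownames(pk) <- NULL
  pk
}

#' Recalibrate the precursor axis
#'
#' Fits the modified calibration law
#' `mz = c0 + c1 * (k1/(fe + k0)) + ...` to the autocorrelation pairs (see
#' [fit_calibration()]) and remaps the whole precursor axis through it.
#'
#' @param spec A `spectrum2d` with a first-pass axis.
#' @param cfg A [swim_config()].
#' @param pairs Calibration pairs as from [detect_autocorrelation_peaks()];
#'   autodetected when `NULL`.
#' @param order Polynomial order of the correction (1-3).
#' @param trim Robustness pass: pairs whose residual against an initial fit
#'   exceeds `trim` times the residual rms are dropped once and the fit is
#'   repeated (guards against near-diagonal fragment peaks); `Inf` disables.
#' @param ... Passed to [detect_autocorrelation_peaks()] when autodetecting.
#' @return The spectrum with a recalibrated `precursor_axis` and the
#'   `calibration` fit stored.
#' @export
recalibrate <- function(spec, cfg, pairs = NULL, order = 2, trim = 3, ...) {
  stopifnot(inherits(spec, "spectrum2d"))
  if (is.null(spec$precursor_axis)) stop("assign a first-pass axis first")
  if (is.null(pairs)) pairs <- detect_autocorrelation_peaks(spec, ...)
  fit <- fit_calibration(pairs$fe, pairs$product_mz, cfg, order = order)
  if (is.finite(trim) && nrow(pairs) > order + 2) {
    resid <- pairs$product_mz - apply_calibration(fit, pairs$fe)
    keep <- abs(resid) <= trim * max(fit$residual_rms, 1e-12)
    if (any(!keep) && sum(keep) >= order + 2)
      fit <- fit_calibration(pairs$fe[keep], pairs$product_mz[keep], cfg,
                             order = order)
  }
  mz <- rep(NA_real_, length(spec$fe_axis))
  pos <- spec$fe_axis > 0
  mz[pos] <- apply_calibration(fit, spec$fe_axis[pos])
  rng <- cfg$mz_display
  mz[!is.na(mz) & (mz < rng[1] | mz > rng[2])] <- NA_real_
  spec$precursor_axis <- mz
  spec$calibration <- fit
  spec
}

#' Pick peaks in a 2D mass spectrum
#'
#' Genuine peaks are required to be 2D local maxima with signal-to-noise
#' above a threshold (noise estimated per product column as 1.4826 x the
#' median absolute deviation), which also suppresses the vertical streaks
#' that broad-spectrum noise paints under intense precursors. The precursor
#' coordinate of each peak is refined with a 7-point intensity-weighted
#' centroid (apex row plus/minus 3 rows) in m/z coordinates.
#'
#' @param spec A calibrated (or first-pass) `spectrum2d`.
#' @param snr_threshold Minimum SNR (default 5).
#' @param neighborhood Local-maximum neighborhood radius in bins (1 = 3x3).
#' @param diagonal_tol_ppm Tolerance for flagging a peak as lying on the
#'   autocorrelation line.
#' @return A `peaks2d` data frame: `product_mz`, `precursor_mz`, `fe`,
#'   `height`, `snr`, `harmonic_order` (`NA` until [flag_harmonics()]),
#'   `on_autocorrelation`. The encoding-frequency bin width is carried in
#'   attribute `fe_bin`.
#' @export
pick_peaks <- function(spec, snr_threshold = 5, neighborhood = 1L,
                       diagonal_tol_ppm = 1000) {
  stopifnot(inherits(spec, "spectrum2d"))
  pk <- .find_peaks2d(spec, snr_threshold, neighborhood)
  if (!nrow(pk)) {
    out <- data.frame(product_mz = numeric(0), precursor_mz = numeric(0),
                      fe = numeric(0), height = numeric(0), snr = numeric(0),
                      harmonic_order = integer(0),
                      on_autocorrelation = logical(0))
  } else {
    cen <- t(vapply(seq_len(nrow(pk)), function(i)
      .centroid_precursor(spec, pk$row[i], pk$col[i]), numeric(2)))
    prod_mz <- spec$product_axis[pk$col]
    on_line <- !is.na(cen[, "mz"]) &
      abs(cen[, "mz"] - prod_mz) / prod_mz * 1e6 <= diagonal_tol_ppm
    out <- data.frame(product_mz = prod_mz, precursor_mz = cen[, "mz"],
                      fe = cen[, "fe"], height = pk$height, snr = pk$snr,
                      harmonic_order = NA_integer_,
                      on_autocorrelation = on_line)
    out <- out[order(-out$height), ]
    rownames(out) <- NULL
  }
  attr(out, "fe_bin") <- spec$fe_axis[2] - spec$fe_axis[1]
  class(out) <- c("peaks2d", class(out))
  out
}

#' Flag harmonic peaks
#'
#' Non-sinusoidal modulation waveforms put spurious peaks at integer
#' multiples of a precursor's encoding frequency. A peak whose `fe` is within
#' `tol_bins` frequency bins of `k * fe'` (k >= 2) of a stronger peak that
#' shares its product m/z (within `product_tol_ppm`) is labeled
#' `harmonic_order = k`; all others are fundamentals (order 1).
#'
#' @param peaks A `peaks2d` data frame from [pick_peaks()].
#' @param tol_bins Frequency tolerance in zero-filled bins (default 1.5).
#' @param product_tol_ppm Product-m/z sharing tolerance, ppm.
#' @param kmax Highest harmonic order searched.
#' @return The peaks with `harmonic_order` filled in.
#' @export
flag_harmonics <- function(peaks, tol_bins = 1.5, product_tol_ppm = 50,
                           kmax = 4L) {
  stopifnot(inherits(peaks, "peaks2d"))
  fe_bin <- attr(peaks, "fe_bin")
  ord <- rep(1L, nrow(peaks))
  if (nrow(peaks) > 1) {
    for (i in seq_len(nrow(peaks))) {
      stronger <- which(peaks$height > peaks$height[i] &
        abs(peaks$product_mz - peaks$product_mz[i]) /
          peaks$product_mz[i] * 1e6 <= product_tol_ppm)
      for (k in 2:kmax) {
        hit <- stronger[abs(peaks$fe[i] - k * peaks$fe[stronger]) <=
                          tol_bins * fe_bin]
        if (length(hit)) { ord[i] <- k; break }
      }
    }
  }
  peaks$harmonic_order <- ord
  peaks
}

#' Horizontal slice: product-ion spectrum of one precursor
#'
#' Sums the row(s) nearest the requested precursor m/z, i.e. extracts the
#' tandem-MS spectrum of that precursor from the 2D map.
#'
#' @param spec A `spectrum2d` with a precursor axis.
#' @param precursor_mz Requested precursor m/z, Th.
#' @param half_width Extra rows summed on each side of the nearest row.
#' @return Data frame `product_mz`, `intensity`.
#' @export
slice_horizontal <- function(spec, precursor_mz, half_width = 0L) {
  stopifnot(inherits(spec, "spectrum2d"))
  if (is.null(spec$precursor_axis)) stop("assign a precursor axis first")
  ax <- spec$precursor_axis
  if (all(is.na(ax)) || precursor_mz > max(ax, na.rm = TRUE) ||
      precursor_mz < min(ax, na.rm = TRUE))
    stop("requested precursor m/z outside the precursor axis")
  row <- which.min(abs(ax - precursor_mz))
  rows <- max(2L, row - half_width):min(nrow(spec$magnitude), row + half_width)
  data.frame(product_mz = spec$product_axis,
             intensity = colSums(spec$magnitude[rows, , drop = FALSE]))
}

#' Vertical slice: precursor scan at one product m/z
#'
#' Sums the column(s) within `tol` of the product m/z: the equivalent of a
#' precursor-ion scan in conventional tandem MS, revealing every precursor
#' that yields that fragment.
#'
#' @param spec A `spectrum2d` with a precursor axis.
#' @param product_mz Product m/z, Th.
#' @param tol Column matching tolerance, Th.
#' @return Data frame `precursor_mz`, `fe`, `intensity` (one row per
#'   encoding-frequency row).
#' @export
slice_vertical <- function(spec, product_mz, tol = 0.02) {
  stopifnot(inherits(spec, "spectrum2d"))
  if (is.null(spec$precursor_axis)) stop("assign a precursor axis first")
  cols <- which(abs(spec$product_axis - product_mz) <= tol)
  if (!length(cols)) {
    if (product_mz < min(spec$product_axis) || product_mz > max(spec$product_axis))
      stop("product m/z outside the product axis")
    cols <- which.min(abs(spec$product_axis - product_mz))
  }
  data.frame(precursor_mz = spec$precursor_axis, fe = spec$fe_axis,
             intensity = rowSums(spec$magnitude[, cols, drop = FALSE]))
}

#' Autocorrelation-line spectrum
#'
#' Samples the 2D magnitude along the diagonal `precursor m/z = product m/z`.
#' This section behaves like a precursor (MS1) spectrum, though intensities
#' also reflect fragmentation efficiency: a heavily fragmenting species has a
#' reduced diagonal peak.
#'
#' Because the reciprocal precursor axis is far coarser than the ToF-limited
#' product peaks, each row contributes the strongest product column inside
#' its own precursor bin (a point-sampled diagonal would thread between the
#' narrow peaks).
#'
#' @param spec A `spectrum2d` with a precursor axis.
#' @return Data frame `mz` (the precursor axis), `intensity` (0 where the
#'   diagonal leaves the product axis or the precursor axis is the
#'   out-of-band sentinel).
#' @export
autocorrelation_spectrum <- function(spec) {
  stopifnot(inherits(spec, "spectrum2d"))
  if (is.null(spec$precursor_axis)) stop("assign a precursor axis first")
  ax <- spec$precursor_axis
  pax <- spec$product_axis
  n <- length(ax)
  inten <- numeric(n)
  ok <- which(!is.na(ax) & ax >= min(pax) & ax <= max(pax))
  for (r in ok) {
    # local precursor bin half-width at this row
    nb <- c(if (r > 1) ax[r - 1], if (r < n) ax[r + 1])
    nb <- nb[!is.na(nb)]
    hw <- if (length(nb)) max(abs(nb - ax[r])) / 2 else diff(pax[1:2])
    cols <- which(pax >= ax[r] - hw & pax <= ax[r] + hw)
    if (!length(cols)) cols <- which.min(abs(pax - ax[r]))
    inten[r] <- max(spec$magnitude[r, cols])
  }
  data.frame(mz = ax, intensity = inten)
}

#' FWHM resolving power on the precursor axis
#'
#' Measures M / dM (FWHM definition) of the strongest modulation peak in the
#' product column nearest `product_mz`: the half-maximum crossings of the
#' peak are located by linear interpolation along the frequency rows and
#' converted to m/z through the spectrum's precursor axis.
#'
#' @param spec A `spectrum2d` with a precursor axis.
#' @param product_mz Product column to evaluate, Th (usually the precursor's
#'   own m/z for an autocorrelation peak).
#' @return Resolving power (dimensionless), with the peak m/z and FWHM (Th)
#'   as attributes `mz` and `fwhm`.
#' @export
precursor_resolving_power <- function(spec, product_mz) {
  stopifnot(inherits(spec, "spectrum2d"))
  if (is.null(spec$precursor_axis)) stop("assign a precursor axis first")
  col <- which.min(abs(spec$product_axis - product_mz))
  y <- spec$magnitude[, col]
  r <- which.max(y[-1]) + 1L
  half <- y[r] / 2
  hi <- r; while (hi < length(y) && y[hi] > half) hi <- hi + 1L
  lo <- r; while (lo > 2L && y[lo] > half) lo <- lo - 1L
  if (y[hi] > half || y[lo] > half) stop("peak too close to the axis edge")
  fe_hi <- stats::approx(y[c(hi - 1L, hi)], spec$fe_axis[c(hi - 1L, hi)],
                         xout = half)$y
  fe_lo <- stats::approx(y[c(lo, lo + 1L)], spec$fe_axis[c(lo, lo + 1L)],
                         xout = half)$y
  ok <- which(!is.na(spec$precursor_axis))
  to_mz <- function(fe) stats::approx(spec$fe_axis[ok],
                                      spec$precursor_axis[ok], xout = fe)$y
  mz_peak <- to_mz(spec$fe_axis[r])
  fwhm <- abs(to_mz(fe_lo) - to_mz(fe_hi))
  structure(mz_peak / fwhm, mz = mz_peak, fwhm = fwhm)
}
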