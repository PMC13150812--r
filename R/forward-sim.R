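#' Fragmentation channel of a precursor
#'
#' @param product_mz Product-ion m/z, Th.
#' @param product_z Product charge count.
#' @param mechanism `"uvpd"` (Gaussian laser overlap, anti-phase with the
#'   precursor), `"intrap_cid"` (threshold collisional activation, anti-phase)
#'   or `"beam_cid"` (downstream collision cell, in phase with the
#'   transmitted precursor).
#' @param max_yield Relative channel weight in `[0, 1]`. Weights are
#'   normalized within each mechanism so that precursor plus fragments
#'   conserve the ion flux.
#' @return A `frag_channel` list.
#' @export
frag_channel <- function(product_mz, product_z = 1L,
                         mechanism = c("uvpd", "intrap_cid", "beam_cid"),
                         max_yield = 0.1) {
  mechanism <- match.arg(mechanism)
  stopifnot(product_mz > 0, product_z >= 1, max_yield >= 0, max_yield <= 1)
  structure(list(product_mz = product_mz, product_z = as.integer(product_z),
                 mechanism = mechanism, max_yield = max_yield),
            class = "frag_channel")
}

#' An ion species for the forward simulator
#'
#' @param mz Precursor m/z, Th.
#' @param z Charge count.
#' @param abundance Abundance in arbitrary intensity units.
#' @param isotopologues Data frame with columns `offset` (Th, strictly
#'   increasing, first usually 0; adjacent isotopologues of charge z are
#'   spaced about 1.003355/z) and `abundance` (relative, summing to 1).
#'   Default: a single monoisotopic peak.
#' @param channels List of [frag_channel()] objects.
#' @return An `ion_species` list.
#' @export
ion_species <- function(mz, z = 1L, abundance = 1,
                        isotopologues = data.frame(offset = 0, abundance = 1),
                        channels = list()) {
  stopifnot(mz > 0, z >= 1, abundance >= 0)
  iso <- as.data.frame(isotopologues)
  if (!all(c("offset", "abundance") %in% names(iso)))
    stop("isotopologues needs columns offset and abundance")
  if (is.unsorted(iso$offset, strictly = TRUE))
    stop("isotopologue offsets must be strictly increasing")
  if (abs(sum(iso$abundance) - 1) > 1e-8)
    stop("isotopologue relative abundances must sum to 1")
  if (length(channels)) {
    if (!all(vapply(channels, inherits, logical(1), "frag_channel")))
      stop("channels must be frag_channel objects")
    tot <- sum(vapply(channels, `[[`, numeric(1), "max_yield"))
    if (tot > 1 + 1e-8) stop("sum of channel max_yield must be <= 1")
  }
  structure(list(mz = mz, z = as.integer(z), abundance = abundance,
                 isotopologues = iso, channels = channels),
            class = "ion_species")
}

#' Standard isotopologue pattern helper
#'
#' Three-peak approximate isotope cluster for a charge-z ion: offsets
#' `k * 1.003355 / z` for `k = 0 .. n - 1`.
#'
#' @param z Charge count.
#' @param abundances Relative abundances (normalized internally).
#' @return Data frame usable as `isotopologues` in [ion_species()].
#' @export
isotope_pattern <- function(z, abundances = c(0.45, 0.35, 0.20)) {
  data.frame(offset = (seq_along(abundances) - 1) * 1.003355 / z,
             abundance = abundances / sum(abundances))
}

#' Forward-simulation configuration
#'
#' Signal-level model parameters for the modulated-cloud simulator. The ion
#' cloud radius is represented by the scalar excitation amplitude
#' `a(n) = excitation_scale * M(f_s, n)` (resonant-response proxy).
#'
#' @param excitation_scale Peak dipolar excitation amplitude, volts zero-to-peak
#'   (the paper-scale outcome is about 1 V).
#' @param v_crit Loss threshold, volts: above it a portion of the cloud fails
#'   to exit the trap (flux-periodic mode). `Inf` selects flux-constant
#'   operation.
#' @param loss_max Maximum fraction of the cloud lost at high excitation.
#' @param loss_width Width (volts) of the smooth loss roll-off above `v_crit`.
#' @param cid_threshold In-trap CID onset amplitude, volts.
#' @param cid_ramp Amplitude interval (volts) over which the in-trap CID
#'   probability ramps from 0 to `cid_pmax`.
#' @param cid_pmax Maximum in-trap CID fragmentation probability.
#' @param laser_sigma_frac Laser Gaussian width as a fraction of the maximum
#'   modulated radius (i.e. of `excitation_scale` in amplitude units).
#' @param uvpd_pmax Peak UVPD fragmentation probability (beam center).
#' @param beam_cid_frac Fraction of transmitted precursors fragmented in the
#'   downstream collision cell.
#' @param noise_prop Proportional noise coefficient (noise sd =
#'   `noise_prop * signal`).
#' @param noise_floor Additive noise floor, as a fraction of the maximum
#'   noiseless cube intensity.
#' @param peak_width_ppm Product-axis peak FWHM in ppm (ToF-like,
#'   ppm-constant).
#' @param product_axis `c(mz_lo, mz_hi, n_bins)` for the product-ion axis.
#' @param upstream_frac Fraction of each channel emitted as pre-trap
#'   (upstream) fragments: these are trapped as independent species modulated
#'   at their own secular frequency and therefore land on the
#'   autocorrelation line.
#' @param fs_method Secular-frequency route used for the modulation truth
#'   (`"exact"` emulates the real trap physics; `"dehmelt"` makes the
#'   closed-form encoding-law predictions exact instead).
#' @param seed RNG seed making the noisy cube reproducible bit-for-bit.
#' @return A `sim_config` list.
#' @export
sim_config <- function(excitation_scale = 1, v_crit = Inf,
                       loss_max = 0.5, loss_width = 0.25,
                       cid_threshold = 0.5, cid_ramp = 0.5, cid_pmax = 0.5,
                       laser_sigma_frac = 0.3, uvpd_pmax = 0.5,
                       beam_cid_frac = 0.2,
                       noise_prop = 0.05, noise_floor = 0.001,
                       peak_width_ppm = 20,
                       product_axis = c(100, 1500, 4096),
                       upstream_frac = 0.02,
                       fs_method = c("exact", "koizumi", "dehmelt"),
                       seed = 1L) {
  fs_method <- match.arg(fs_method)
  fr <- c(loss_max, cid_pmax, laser_sigma_frac, uvpd_pmax, beam_cid_frac,
          upstream_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (!(v_crit > 0)) stop("v_crit must be positive")
  if (length(product_axis) != 3 || product_axis[1] >= product_axis[2])
    stop("product_axis must be c(mz_lo, mz_hi, n_bins)")
  structure(list(excitation_scale = excitation_scale, v_crit = v_crit,
                 loss_max = loss_max, loss_width = loss_width,
                 cid_threshold = cid_threshold, cid_ramp = cid_ramp,
                 cid_pmax = cid_pmax,
                 laser_sigma_frac = laser_sigma_frac, uvpd_pmax = uvpd_pmax,
                 beam_cid_frac = beam_cid_frac,
                 noise_prop = noise_prop, noise_floor = noise_floor,
                 peak_width_ppm = peak_width_ppm,
                 product_axis = product_axis,
                 upstream_frac = upstream_frac,
                 fs_method = fs_method, seed = as.integer(seed)),
            class = "sim_config")
}

#' Excitation amplitude seen by a species at index n
#'
#' `a(n) = excitation_scale * M(f_s, n)`: the dipolar drive amplitude at the
#' species' secular frequency, which is the proxy for its modulated cloud
#' radius. Zero at n = 0.
#'
#' @param sp An [ion_species()].
#' @param n SWIM index (vectorized).
#' @param cfg A [swim_config()].
#' @param sim A [sim_config()].
#' @return Amplitude in volts.
#' @export
modulation_amplitude <- function(sp, n, cfg, sim) {
  fs <- as.numeric(secular_frequency(sp$mz, cfg, sim$fs_method))
  if (fs < cfg$f_min || fs > cfg$f_max)
    stop(sprintf("species m/z %.4g has secular frequency %.4g Hz outside the SWIM band",
                 sp$mz, fs))
  sim$excitation_scale * magnitude_profile(fs, n, cfg)
}

#' UVPD survival model
#'
#' Photofragmentation is strongest at zero radius, where the coaxial Gaussian
#' beam is most intense: `p(a) = uvpd_pmax * exp(-a^2 / (2 sigma^2))` with
#' `sigma = laser_sigma_frac * excitation_scale`. The fragment yield is
#' therefore 180 degrees out of phase with the radius modulation.
#'
#' @param a Excitation amplitude, volts (vectorized).
#' @param sim A [sim_config()].
#' @param yields Optional per-channel weights; when given, per-channel
#'   fragment fractions `p * yields / sum(yields)` are returned.
#' @return List with `survival`, `p` and (optionally) matrix `fragments`
#'   (length(a) x channels).
#' @export
uvpd_survival <- function(a, sim, yields = NULL) {
  stopifnot(all(a >= 0))
  sigma <- sim$laser_sigma_frac * sim$excitation_scale
  p <- sim$uvpd_pmax * exp(-a^2 / (2 * sigma^2))
  out <- list(survival = 1 - p, p = p)
  if (!is.null(yields) && length(yields))
    out$fragments <- outer(p, yields / sum(yields))
  out
}

#' In-trap CID survival model
#'
#' Collisional activation requires a threshold kinetic energy, so
#' fragmentation only occurs above a threshold amplitude:
#' `p(a) = cid_pmax * clamp((a - cid_threshold) / cid_ramp, 0, 1)`.
#' The clipped waveform is periodic but asymmetric, which is what feeds
#' harmonic peaks at multiples of the encoding frequency.
#'
#' @inheritParams uvpd_survival
#' @return List with `survival`, `p` and optionally `fragments`.
#' @export
intrap_cid_survival <- function(a, sim, yields = NULL) {
  stopifnot(all(a >= 0))
  p <- sim$cid_pmax * pmin(pmax((a - sim$cid_threshold) / sim$cid_ramp, 0), 1)
  out <- list(survival = 1 - p, p = p)
  if (!is.null(yields) && length(yields))
    out$fragments <- outer(p, yields / sum(yields))
  out
}

#' Exit transmission under radial excitation
#'
#' Below `v_crit` the whole cloud passes the exit aperture. Above it, a
#' portion of the cloud is lost; the loss is modeled as a smooth roll-off
#' rather than a hard step:
#' `T(a) = 1` for `a <= v_crit`, otherwise
#' `T(a) = (1 - loss_max) + loss_max * exp(-((a - v_crit)/loss_width)^2)`.
#' The same factor applies to precursors and to beam-CID fragments, so their
#' traces share frequency and phase.
#'
#' @inheritParams uvpd_survival
#' @return Transmitted fraction in `(0, 1]`.
#' @export
flux_transmission <- function(a, sim) {
  stopifnot(all(a >= 0))
  over <- pmax(a - sim$v_crit, 0)
  ifelse(over > 0,
         (1 - sim$loss_max) + sim$loss_max * exp(-(over / sim$loss_width)^2),
         1)
}

# peak list and index-domain traces for a species set.
# Returns list(peaks = data.frame(mz, label, species, kind),
#              traces = matrix [n_indices x n_peaks])
.species_peaks_traces <- function(species, cfg, sim) {
  if (inherits(species, "ion_species")) species <- list(species)
  N <- cfg$n_indices
  n <- seq_len(N) - 1L
  mzs <- c(); labs <- c(); spid <- c(); kind <- c()
  traces <- list()
  add <- function(mz, trace, lab, id, kd) {
    mzs <<- c(mzs, mz); labs <<- c(labs, lab); spid <<- c(spid, id)
    kind <<- c(kind, kd); traces[[length(traces) + 1L]] <<- trace
  }
  for (i in seq_along(species)) {
    sp <- species[[i]]
    a <- modulation_amplitude(sp, n, cfg, sim)
    Tn <- flux_transmission(a, sim)
    mech <- vapply(sp$channels, `[[`, character(1), "mechanism")
    yl <- vapply(sp$channels, `[[`, numeric(1), "max_yield")
    p_uv <- if (any(mech == "uvpd")) uvpd_survival(a, sim)$p else 0
    p_cid <- if (any(mech == "intrap_cid")) intrap_cid_survival(a, sim)$p else 0
    tot <- p_uv + p_cid
    sc <- ifelse(tot > 1, 1 / tot, 1)   # joint clamp keeps probabilities <= 1
    p_uv <- p_uv * sc; p_cid <- p_cid * sc
    surv <- 1 - p_uv - p_cid
    p_beam <- if (any(mech == "beam_cid")) sim$beam_cid_frac else 0
    for (j in seq_len(nrow(sp$isotopologues))) {
      add(sp$mz + sp$isotopologues$offset[j],
          sp$abundance * sp$isotopologues$abundance[j] * Tn * surv * (1 - p_beam),
          sprintf("precursor_iso%d", j - 1L), i, "precursor")
    }
    for (m in c("uvpd", "intrap_cid", "beam_cid")) {
      idx <- which(mech == m)
      if (!length(idx)) next
      w <- yl[idx] / sum(yl[idx])
      pm <- switch(m, uvpd = p_uv, intrap_cid = p_cid,
                   beam_cid = surv * p_beam)
      for (k in seq_along(idx)) {
        ch <- sp$channels[[idx[k]]]
        add(ch$product_mz, sp$abundance * Tn * pm * w[k],
            sprintf("%s_frag", m), i, "fragment")
      }
      # pre-trap (upstream) fragments: independent trapped species that
      # modulate at their own secular frequency -> autocorrelation line
      if (sim$upstream_frac > 0) {
        for (k in seq_along(idx)) {
          ch <- sp$channels[[idx[k]]]
          q <- mathieu_q(ch$product_mz, cfg, check = FALSE)
          if (q >= 0.908) next              # not trapped
          fs <- mathieu_beta(q, sim$fs_method) * cfg$f_trap / 2
          tr <- if (fs >= cfg$f_min && fs <= cfg$f_max) {
            au <- sim$excitation_scale * magnitude_profile(fs, n, cfg)
            flux_transmission(au, sim)
          } else rep(1, N)                  # unmodulated background
          add(ch$product_mz,
              sp$abundance * sim$upstream_frac * w[k] * tr,
              "upstream_frag", i, "upstream")
        }
      }
    }
  }
  if (!length(traces))
    return(list(peaks = data.frame(mz = numeric(0), label = character(0),
                                   species = integer(0), kind = character(0)),
                traces = matrix(0, nrow = N, ncol = 0)))
  list(peaks = data.frame(mz = mzs, label = labs, species = spid,
                          kind = kind, stringsAsFactors = FALSE),
       traces = do.call(cbind, traces))
}

# bin-integrated Gaussian peak templates: matrix [n_peaks x n_bins]
.peak_templates <- function(peak_mz, cfg, sim) {
  ax <- sim$product_axis
  edges <- seq(ax[1], ax[2], length.out = ax[3] + 1)
  out <- matrix(0, nrow = length(peak_mz), ncol = ax[3])
  drop_any <- FALSE
  for (i in seq_along(peak_mz)) {
    mz <- peak_mz[i]
    sigma <- mz * sim$peak_width_ppm * 1e-6 / (2 * sqrt(2 * log(2)))
    if (mz < ax[1] || mz > ax[2]) { drop_any <- TRUE; next }
    out[i, ] <- diff(stats::pnorm(edges, mean = mz, sd = sigma))
  }
  if (drop_any) warning("species/fragment peaks outside the product axis were dropped")
  out
}

#' Render one product-ion spectrum
#'
#' Paints bin-integrated Gaussian peaks (ppm-constant width) for all
#' precursors and fragments surviving at SWIM index `n`, optionally adding
#' signal-proportional plus floor noise.
#'
#' @param species An [ion_species()] or list of them.
#' @param n Single SWIM index.
#' @param cfg A [swim_config()].
#' @param sim A [sim_config()].
#' @param noise Add noise? (Uses the current RNG state; [generate_cube()]
#'   manages seeding.)
#' @param noise_ref Reference intensity for the noise floor (defaults to the
#'   spectrum's own maximum).
#' @return Intensity vector over the product axis bins.
#' @export
render_spectrum <- function(species, n, cfg, sim, noise = FALSE,
                            noise_ref = NULL) {
  pt <- .species_peaks_traces(species, cfg, sim)
  tmpl <- .peak_templates(pt$peaks$mz, cfg, sim)
  y <- drop(pt$traces[n + 1L, , drop = FALSE] %*% tmpl)
  if (noise) {
    if (is.null(noise_ref)) noise_ref <- max(y)
    y <- y + sim$noise_prop * y * stats::rnorm(length(y)) +
      sim$noise_floor * noise_ref * stats::rnorm(length(y))
    y <- pmax(y, 0)
  }
  y
}

#' Generate a synthetic 2D data cube
#'
#' Runs the signal-level forward model for a full SWIM index sequence and
#' returns the matrix of product-ion spectra (one row per index), emulating
#' summed ToF spectra saved once per index. Noise is proportional to the
#' signal plus a floor, both applied per bin per index; with the same seed
#' the cube is reproducible bit-for-bit.
#'
#' @inheritParams render_spectrum
#' @param noise Logical; `FALSE` gives the noiseless expectation cube.
#' @return A `data_cube`: list with `intensities`
#'   (`n_indices` x `n_bins`), `product_axis` (bin centers, Th),
#'   `index_axis`, and `meta` (configs, seed, peak bookkeeping).
#' @export
generate_cube <- function(species, cfg, sim, noise = TRUE) {
  validate_swim_config(cfg)
  if (inherits(species, "ion_species")) species <- list(species)
  pt <- .species_peaks_traces(species, cfg, sim)
  tmpl <- .peak_templates(pt$peaks$mz, cfg, sim)
  mat <- pt$traces %*% tmpl
  if (noise) {
    if (exists(".Random.seed", envir = globalenv()))
      old_seed <- get(".Random.seed", envir = globalenv())
    else { stats::runif(1); old_seed <- get(".Random.seed", envir = globalenv()) }
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(sim$seed)
    ref <- max(mat)
    noise_mat <- sim$noise_prop * mat * stats::rnorm(length(mat)) +
      sim$noise_floor * ref * stats::rnorm(length(mat))
    mat <- pmax(mat + noise_mat, 0)
  }
  ax <- sim$product_axis
  edges <- seq(ax[1], ax[2], length.out = ax[3] + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  structure(list(intensities = mat,
                 product_axis = centers,
                 index_axis = seq_len(cfg$n_indices) - 1L,
                 meta = list(config = unclass(cfg), sim = unclass(sim),
                             species = lapply(species, unclass),
                             peaks = pt$peaks, noise = noise)),
            class = "data_cube")
}

#' @export
print.data_cube <- function(x, ...) {
  cat(sprintf("2DMS data cube: %d SWIM indices x %d product bins (m/z %.4g - %.4g)\n",
              nrow(x$intensities), ncol(x$intensities),
              min(x$product_axis), max(x$product_axis)))
  invisible(x)
}

#' Demonstration peptide-like mixture
#'
#' A canned four-component mixture emulating a peptide standard mix analyzed
#' by 2DMS: four multiply charged precursors (m/z 402.23 3+, 449.92 3+,
#' 474.92 3+ and 570.17 5+), each with a three-peak isotope cluster and
#' 9-12 fragment channels. Fragment m/z values are synthetic but arranged
#' like b/y-ion series. Intended as the default input for end-to-end
#' simulate-and-decode demonstrations.
#'
#' @param mechanism Fragmentation mechanism given to every channel.
#' @return List of four [ion_species()].
#' @export
demo_species <- function(mechanism = c("uvpd", "intrap_cid", "beam_cid")) {
  mechanism <- match.arg(mechanism)
  mk <- function(mz, z, ab, frags) {
    ion_species(mz, z, ab, isotope_pattern(z),
                channels = lapply(frags, function(f)
                  frag_channel(f, 1L, mechanism, max_yield = 0.6 / length(frags))))
  }
  list(
    polymyxin_like = mk(402.23, 3, 1.0,
      c(202.12, 241.18, 341.22, 458.29, 532.32, 595.37, 663.40,
        760.45, 860.51, 963.58)),
    substanceP_like = mk(449.92, 3, 0.8,
      c(226.15, 354.21, 425.25, 543.31, 625.36, 741.41, 853.47,
        966.55, 1104.60)),
    bacitracin_like = mk(474.92, 3, 0.6,
      c(213.09, 299.16, 397.24, 486.28, 580.33, 669.38, 756.42,
        869.50, 982.59, 1086.63, 1199.71)),
    melittin_like = mk(570.17, 5, 0.7,
      c(249.16, 318.19, 432.26, 514.30, 602.35, 685.42, 773.47,
        887.52, 999.61, 1127.67, 1240.75, 1339.82))
  )
}
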