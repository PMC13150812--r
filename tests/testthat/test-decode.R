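cfgN <- swim_config(n_indices = 256L)

# one flux-periodic species plus UVPD fragments, reused across blocks
basic_sim <- function(...) {
  args <- utils::modifyList(list(upstream_frac = 0,
                                 product_axis = c(150, 1000, 2048)),
                            list(...))
  do.call(sim_config, args)
}

test_that("column transform: mean removal, zero-fill bookkeeping, sinusoid", {
  sim <- basic_sim(product_axis = c(150, 400, 64))
  cube <- generate_cube(list(), cfgN, sim, noise = FALSE)
  cube$intensities <- cube$intensities + 3.7    # constant cube
  spec <- transform_cube(cube)
  expect_equal(nrow(spec$magnitude), 256L)
  expect_equal(spec$fe_axis[2] - spec$fe_axis[1], 1 / 512)  # zero-filled once
  expect_lt(max(spec$magnitude), 1e-9)
  # a pure cosine at 0.25 cycles/index lights up the 0.25 row of its column
  cube$intensities[, 10] <- cube$intensities[, 10] +
    cos(2 * pi * 0.25 * (0:255))
  spec <- transform_cube(cube)
  expect_equal(which.max(spec$magnitude[, 10]),
               which.min(abs(spec$fe_axis - 0.25)))
  cube$intensities[3, 4] <- NaN
  expect_error(transform_cube(cube), "non-finite")
})

test_that("first-pass axis: reciprocity, sentinels, monotonicity, curvature", {
  sim <- basic_sim()
  sp <- ion_species(449.92, 3)
  cube <- generate_cube(sp, cfgN, sim, noise = FALSE)
  spec5 <- first_pass_axis(transform_cube(cube), cfgN, "eq5")
  spec6 <- first_pass_axis(transform_cube(cube), cfgN, "eq6")
  expect_true(is.na(spec5$precursor_axis[1]))   # fe = 0 row sentinel
  ax5 <- spec5$precursor_axis; ax6 <- spec6$precursor_axis
  expect_true(all(diff(ax5[!is.na(ax5)]) < 0))
  expect_true(all(diff(ax6[!is.na(ax6)]) < 0))
  # eq5 rows invert the reciprocal law exactly
  kk <- encoding_constants(cfgN)
  r <- which(!is.na(ax5))
  expect_equal(ax5[r], unname(kk["k1"] / (spec5$fe_axis[r] + kk["k0"])),
               tolerance = 1e-12)
  # the two axes diverge increasingly below m/z 400
  ok <- !is.na(ax5) & !is.na(ax6)
  rel <- abs(ax5[ok] - ax6[ok]) / ax6[ok]
  expect_lt(stats::cor(rel, ax6[ok], method = "spearman"), -0.95)
  expect_gt(max(rel[ax6[ok] < 400]), 0.02)
  expect_lt(max(rel[ax6[ok] > 2000]), 0.002)
})

test_that("autocorrelation detection: isotopologues, diagonal-only cubes", {
  # no fragmentation: every isotopologue of the species is a diagonal peak
  sim <- basic_sim(v_crit = 0.5, product_axis = c(440, 460, 2048))
  sp <- ion_species(449.92, 3, isotopologues = isotope_pattern(3))
  cube <- generate_cube(sp, cfgN, sim, noise = FALSE)
  spec <- first_pass_axis(transform_cube(cube), cfgN, "eq6")
  pairs_all <- detect_autocorrelation_peaks(spec, dedup = FALSE)
  expect_equal(nrow(pairs_all), 3L)
  expect_equal(sort(pairs_all$product_mz), 449.92 + (0:2) * 1.003355 / 3,
               tolerance = 1e-4)
  expect_equal(nrow(detect_autocorrelation_peaks(spec)), 1L)
  # impossible calibration: zero tolerance leaves no pairs
  expect_error(detect_autocorrelation_peaks(spec, tol_ppm = 0), "impossible")
  # fragmentation-free multi-species cube: every picked peak is diagonal
  sim2 <- basic_sim(v_crit = 0.5, product_axis = c(350, 650, 2048))
  mix <- list(ion_species(402.23, 3), ion_species(474.92, 3),
              ion_species(570.17, 5))
  cube2 <- generate_cube(mix, cfgN, sim2, noise = FALSE)
  spec2 <- first_pass_axis(transform_cube(cube2), cfgN, "eq6")
  pk <- pick_peaks(spec2, snr_threshold = 10, diagonal_tol_ppm = 20000)
  pk <- flag_harmonics(pk)
  expect_gt(nrow(pk), 0)
  expect_true(all(pk$on_autocorrelation[pk$harmonic_order == 1]))
})

test_that("recalibration: identity stability and quadratic gain", {
  cfg1k <- swim_config()
  sim <- basic_sim(v_crit = 0.5, fs_method = "dehmelt",
                   product_axis = c(180, 650, 3072))
  mix <- list(ion_species(200.5, 1), ion_species(402.23, 3),
              ion_species(474.92, 3), ion_species(570.17, 5),
              ion_species(350.3, 2), ion_species(250.2, 1))
  cube <- generate_cube(mix, cfg1k, sim, noise = FALSE)
  # identity case: simulated with the Dehmelt law and first-passed with the
  # matching reciprocal axis, the fit must reduce to (0, 1) and leave the
  # axis unchanged
  spec5 <- first_pass_axis(transform_cube(cube), cfg1k, "eq5")
  ax_before <- spec5$precursor_axis
  cal5 <- recalibrate(spec5, cfg1k, order = 1)
  expect_lt(cal5$calibration$residual_rms, 0.3)   # centroid scatter only
  expect_equal(cal5$precursor_axis, ax_before, tolerance = 2e-3)
  # model mismatch: same cube first-passed through eq6; quadratic correction
  # beats linear (wide tolerance keeps the low-mass pairs where the Dehmelt
  # truth and the closed-form axis disagree the most)
  spec6 <- first_pass_axis(transform_cube(cube), cfg1k, "eq6")
  pairs <- detect_autocorrelation_peaks(spec6, tol_ppm = 150000)
  f1 <- fit_calibration(pairs$fe, pairs$product_mz, cfg1k, order = 1)
  f2 <- fit_calibration(pairs$fe, pairs$product_mz, cfg1k, order = 2)
  expect_lt(f2$residual_rms, f1$residual_rms)
})

test_that("peak picking: counts, thresholds, centroids", {
  sim <- basic_sim(uvpd_pmax = 0.3, laser_sigma_frac = 0.5)
  mix <- list(frag_species(402.23, c(202.12, 241.18, 341.22, 532.32)),
              frag_species(474.92, c(213.09, 299.16, 397.24, 869.50)),
              frag_species(570.17, c(249.16, 318.19, 432.26, 887.52)))
  cube <- generate_cube(mix, swim_config(n_indices = 512L), sim, noise = FALSE)
  spec <- first_pass_axis(transform_cube(cube), swim_config(n_indices = 512L),
                          "eq6")
  pk <- flag_harmonics(pick_peaks(spec, snr_threshold = 5))
  # exactly 3 precursors + 12 fragments at the fundamental
  expect_equal(sum(pk$harmonic_order == 1), 15L)
  expect_equal(nrow(pick_peaks(spec, snr_threshold = Inf)), 0L)
  # centroid of the strongest diagonal peak sits within a row of the apex
  top <- pk[pk$on_autocorrelation, ][1, ]
  apex_row <- which.min(abs(spec$fe_axis - top$fe))
  expect_lt(abs(spec$precursor_axis[apex_row] - top$precursor_mz),
            abs(spec$precursor_axis[apex_row - 1] -
                  spec$precursor_axis[apex_row + 1]) / 2)
})

test_that("harmonic flagging: mixed-mode 2 f_e and a synthetic 3 f_e ladder", {
  sim <- basic_sim(v_crit = 0.5, uvpd_pmax = 0.15,
                   product_axis = c(380, 420, 256))
  sp <- frag_species(402.23, 402.9, "uvpd")  # fragment kept off-axis peaks
  cube <- generate_cube(ion_species(402.23, 1), swim_config(n_indices = 512L),
                        sim, noise = FALSE)
  cfg512 <- swim_config(n_indices = 512L)
  spec <- first_pass_axis(transform_cube(cube), cfg512, "eq6")
  pk <- flag_harmonics(pick_peaks(spec, snr_threshold = 5))
  fund <- pk$fe[which.max(pk$height)]
  two <- pk[abs(pk$fe - 2 * fund) < 2 / 1024, ]
  expect_gt(nrow(two), 0)
  expect_true(all(two$harmonic_order == 2))
  # synthetic three-harmonic trace in one column
  sim0 <- basic_sim(product_axis = c(150, 400, 32))
  cube2 <- generate_cube(list(), cfg512, sim0, noise = FALSE)
  n <- 0:511
  cube2$intensities[, 16] <- 10 + 5 * cos(2 * pi * 0.1 * n) +
    1.5 * cos(2 * pi * 0.2 * n) + 0.5 * cos(2 * pi * 0.3 * n)
  spec2 <- first_pass_axis(transform_cube(cube2), cfg512, "eq6")
  pk2 <- flag_harmonics(pick_peaks(spec2, snr_threshold = 5))
  pk2 <- pk2[order(pk2$fe), ]
  expect_equal(pk2$harmonic_order[1:3], c(1L, 2L, 3L))
  # a purely flux-constant near-sinusoidal cube carries no strong harmonics
  simfc <- basic_sim(uvpd_pmax = 0.1, laser_sigma_frac = 1,
                     product_axis = c(380, 460, 128))
  cube3 <- generate_cube(frag_species(402.23, 440.0, "uvpd"), cfg512, simfc,
                         noise = FALSE)
  spec3 <- first_pass_axis(transform_cube(cube3), cfg512, "eq6")
  pk3 <- flag_harmonics(pick_peaks(spec3, snr_threshold = 50))
  expect_true(all(pk3$harmonic_order == 1))
})

test_that("slices: product-ion spectra, precursor scans, artifacts", {
  cfg512 <- swim_config(n_indices = 512L)
  sim <- basic_sim(uvpd_pmax = 0.3, product_axis = c(150, 700, 2048))
  sp <- frag_species(449.92, c(226.15, 354.21, 600.30), z = 3)
  cube <- generate_cube(sp, cfg512, sim, noise = FALSE)
  spec <- first_pass_axis(transform_cube(cube), cfg512, "eq6")
  sl <- slice_horizontal(spec, 450.5, half_width = 1)
  for (mz in c(226.15, 354.21, 600.30, 449.92)) {
    near <- abs(sl$product_mz - mz) < 0.3
    expect_gt(max(sl$intensity[near]), 10 * stats::median(sl$intensity))
  }
  # a slice between species rows of a noiseless cube is essentially empty
  sl0 <- slice_horizontal(spec, 800)
  expect_lt(max(sl0$intensity), 0.02 * max(sl$intensity))
  expect_error(slice_horizontal(spec, 9000), "outside")

  # a shared fragment seen from three charge states = three-peak precursor scan
  shared <- 350.18
  mix <- list(frag_species(402.23, shared, z = 3),
              frag_species(474.92, shared, z = 3),
              frag_species(570.17, shared, z = 5),
              frag_species(620.33, 500.27, z = 2))
  cube2 <- generate_cube(mix, cfg512, sim, noise = FALSE)
  spec2 <- first_pass_axis(transform_cube(cube2), cfg512, "eq6")
  vs <- slice_vertical(spec2, shared, tol = 0.3)
  expect_equal(count_peaks_1d(vs$intensity), 3L)
  vs1 <- slice_vertical(spec2, 500.27, tol = 0.3)
  expect_equal(count_peaks_1d(vs1$intensity), 1L)
  # empty column
  vs0 <- slice_vertical(spec2, 680, tol = 0.2)
  expect_lt(max(vs0$intensity), 1e-3 * max(vs$intensity))
  expect_error(slice_vertical(spec2, 5, tol = 0.2), "outside")
})

test_that("autocorrelation spectrum: precursor content and depletion", {
  cfg512 <- swim_config(n_indices = 512L)
  sim <- basic_sim(v_crit = 0.5, product_axis = c(380, 620, 2048))
  mix <- list(ion_species(402.23, 3), ion_species(474.92, 3),
              ion_species(570.17, 5))
  cube <- generate_cube(mix, cfg512, sim, noise = FALSE)
  spec <- first_pass_axis(transform_cube(cube), cfg512, "eq6")
  ac <- autocorrelation_spectrum(spec)
  for (mz in c(402.23, 474.92, 570.17)) {
    sel <- !is.na(ac$mz) & abs(ac$mz - mz) < 10
    expect_gt(max(ac$intensity[sel]), 0.2 * max(ac$intensity))
  }
  # diagonal intensity drops as the fragment yield rises
  diag_peak <- function(pmax) {
    s <- basic_sim(v_crit = 0.5, uvpd_pmax = pmax,
                   product_axis = c(380, 430, 512))
    cb <- suppressWarnings(generate_cube(frag_species(402.23, 202.1), cfg512,
                                         s, noise = FALSE))
    sp <- first_pass_axis(transform_cube(cb), cfg512, "eq6")
    a <- autocorrelation_spectrum(sp)
    max(a$intensity[!is.na(a$mz) & abs(a$mz - 402.23) < 10])
  }
  d <- vapply(c(0, 0.3, 0.6), diag_peak, numeric(1))
  expect_true(all(diff(d) < 0))
  # empty cube
  sim0 <- basic_sim(product_axis = c(150, 400, 64))
  cube0 <- generate_cube(list(), cfg512, sim0, noise = FALSE)
  spec0 <- first_pass_axis(transform_cube(cube0), cfg512, "eq6")
  expect_true(all(autocorrelation_spectrum(spec0)$intensity == 0))
})

test_that("magnitude spectrum is invariant to a circular index shift", {
  cfg512 <- swim_config(n_indices = 512L)
  sim <- basic_sim(product_axis = c(180, 650, 512))
  sp <- frag_species(402.23, 202.1)
  cube <- generate_cube(sp, cfg512, sim, noise = FALSE)
  k <- 137
  cube2 <- cube
  cube2$intensities <- rbind(cube$intensities[(k + 1):512, ],
                             cube$intensities[1:k, ])
  s1 <- transform_cube(cube); s2 <- transform_cube(cube2)
  # at the unpadded transform rows the shift is a pure phase: magnitudes match
  orig_rows <- seq(1, 512, by = 2)
  expect_equal(s1$magnitude[orig_rows, ], s2$magnitude[orig_rows, ],
               tolerance = 1e-9)
})

test_that("end to end: a noisy four-species mixture decodes correctly", {
  cfg1k <- swim_config()
  species <- demo_species("uvpd")
  sim <- sim_config(product_axis = c(150, 1400, 4096))
  bin_tol <- (1400 - 150) / 4096
  for (noisy in c(FALSE, TRUE)) {
    cube <- generate_cube(species, cfg1k, sim, noise = noisy)
    spec <- decode_cube(cube, cfg1k)
    pk <- pick_peaks(spec, snr_threshold = 5)
    acc <- assignment_accuracy(pk, species, bin_tol)
    expect_equal(acc[["total"]], 42L)
    if (!noisy) expect_equal(acc[["correct"]], 42L)
    else expect_gte(acc[["correct"]], ceiling(0.95 * 42))
    # precursor centroids land within one local bin of the truth
    for (sp in species) {
      row <- which.min(abs(spec$precursor_axis - sp$mz))
      binw <- abs(spec$precursor_axis[row - 1] -
                    spec$precursor_axis[row + 1]) / 2
      dpk <- pk[pk$on_autocorrelation &
                  abs(pk$product_mz - sp$mz) < 2 * bin_tol, ]
      expect_gt(nrow(dpk), 0)
      expect_lt(abs(dpk$precursor_mz[which.max(dpk$height)] - sp$mz), binw)
    }
    # product-axis fidelity: peak columns carry the cube's own axis values
    expect_true(all(pk$product_mz %in% cube$product_axis))
  }
})
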