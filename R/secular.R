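#' Mathieu stability parameter q
#'
#' For an RF-only linear quadrupole, `q = z e V_trap / (pi^2 m r0^2 f_trap^2)`
#' with `V_trap` the zero-to-peak RF amplitude and `m` the ion mass; expressed
#' per mass-to-charge this depends only on m/z. Ions with `q >= 0.908` fall
#' outside the first stability region and are ejected.
#'
#' @param mz Mass-to-charge ratio, Th.
#' @param cfg A [swim_config()].
#' @param check Reject unstable species (`q >= 0.908`) with an error. Set to
#'   `FALSE` to obtain the raw value, e.g. when mapping an axis.
#' @return Dimensionless q (vectorized over `mz`).
#' @examples
#' mathieu_q(922, swim_config())
#' @export
mathieu_q <- function(mz, cfg, check = TRUE) {
  validate_swim_config(cfg)
  if (any(mz <= 0)) stop("mz must be positive")
  q <- .e_charge * cfg$v_trap / (pi^2 * .amu * mz * cfg$r0^2 * cfg$f_trap^2)
  if (check && any(q >= 0.908))
    stop("unstable/ejected species: Mathieu q >= 0.908 for m/z ",
         paste(signif(mz[q >= 0.908], 6), collapse = ", "))
  q
}

# inverse of mathieu_q (no stability check)
.mz_from_q <- function(q, cfg) {
  .e_charge * cfg$v_trap / (pi^2 * .amu * q * cfg$r0^2 * cfg$f_trap^2)
}

# one side of the continued fraction for the characteristic exponent (a = 0)
.beta_cf_side <- function(beta, q, depth = 60L, sign = 1) {
  acc <- 0
  for (k in depth:1) acc <- q^2 / ((beta + sign * 2 * k)^2 - acc)
  acc
}

#' Mathieu beta from q
#'
#' Three routes from the stability parameter to the frequency parameter
#' `beta` (secular frequency `f_s = beta * f_trap / 2`):
#' \describe{
#'   \item{dehmelt}{`beta = q / sqrt(2)`, the adiabatic approximation, usable
#'     for `q < 0.4`.}
#'   \item{koizumi}{closed form valid over the whole first stability region:
#'     `cos(pi beta) = 1 - (pi^2/4) q^2 + (pi^4/1120) q^4`, equivalently
#'     `q^2 = (4/pi^2) (35 - sqrt(1225 - 70 (1 - cos(pi beta))))`.}
#'   \item{exact}{the standard continued-fraction expansion of the
#'     characteristic exponent, truncated when terms fall below 1e-12; used
#'     as the oracle for both approximations.}
#' }
#'
#' @param q Mathieu q in `(0, 0.908)`.
#' @param method One of `"exact"`, `"dehmelt"`, `"koizumi"`.
#' @return beta in `(0, 1)`, vectorized over `q`.
#' @export
mathieu_beta <- function(q, method = c("exact", "dehmelt", "koizumi")) {
  method <- match.arg(method)
  if (any(q <= 0)) stop("q must be positive")
  if (any(q >= 0.908)) stop("unstable: q >= 0.908")
  switch(method,
    dehmelt = q / sqrt(2),
    koizumi = {
      cb <- 1 - pi^2 / 4 * q^2 + pi^4 / 1120 * q^4
      acos(pmin(1, pmax(-1, cb))) / pi
    },
    exact = vapply(q, function(qi) {
      g <- function(b) b^2 - .beta_cf_side(b, qi, sign = 1) - .beta_cf_side(b, qi, sign = -1)
      stats::uniroot(g, c(1e-10, 1 - 1e-10), tol = 1e-13)$root
    }, numeric(1))
  )
}

# inverse: q from beta for the closed-form route (radicand is >= 1085 for all
# stable beta, so the root is always real)
.koizumi_q_from_beta <- function(beta) {
  y <- 1 - cos(pi * beta)
  sqrt(4 / pi^2 * (35 - sqrt(1225 - 70 * y)))
}

#' Secular frequency of an ion
#'
#' `f_s = beta * f_trap / 2` with `beta` computed by the requested method.
#' When the Dehmelt approximation is used outside its `q < 0.4` comfort zone
#' the result carries attribute `dehmelt_valid = FALSE`.
#'
#' @inheritParams mathieu_q
#' @param method beta approximation; see [mathieu_beta()].
#' @return Secular frequency in Hz (vectorized), decreasing in m/z.
#' @export
secular_frequency <- function(mz, cfg, method = c("dehmelt", "koizumi", "exact")) {
  method <- match.arg(method)
  q <- mathieu_q(mz, cfg)
  fs <- mathieu_beta(q, method) * cfg$f_trap / 2
  if (method == "dehmelt") attr(fs, "dehmelt_valid") <- all(q < 0.4)
  fs
}

#' Encoding frequency from secular frequency
#'
#' The index-domain modulation frequency of a precursor whose secular
#' frequency is `f_s`: `f_e = (f_s - f_min) / (2 (f_max - f_min))`, in cycles
#' per SWIM index (numerically equal to Hz at a 1 Hz index rate). Spans 0 at
#' `f_min` to the Nyquist limit 0.5 at `f_max`.
#'
#' @param f_s Secular frequency, Hz, inside `[f_min, f_max]`.
#' @param cfg A [swim_config()].
#' @return Encoding frequency in cycles/index.
#' @examples
#' cfg <- swim_config()
#' encoding_frequency(cfg$f_max, cfg)  # 0.5: the Nyquist limit at 1 Hz
#' @export
encoding_frequency <- function(f_s, cfg) {
  validate_swim_config(cfg)
  if (any(f_s < cfg$f_min | f_s > cfg$f_max))
    stop("secular frequency outside the SWIM band [f_min, f_max]")
  (f_s - cfg$f_min) / (2 * (cfg$f_max - cfg$f_min))
}

#' Expected encoding frequency of a precursor
#'
#' Composition of [mathieu_q()], [mathieu_beta()] and [encoding_frequency()]:
#' with the Dehmelt route this is the closed form linear in z/m,
#' `f_e = k1' / mz - k0` (see [encoding_constants()]).
#'
#' @inheritParams secular_frequency
#' @return Encoding frequency in cycles/index.
#' @examples
#' encoding_from_mz(449.92, swim_config())  # ~0.102
#' @export
encoding_from_mz <- function(mz, cfg, method = c("dehmelt", "koizumi", "exact")) {
  fs <- secular_frequency(mz, cfg, method)
  encoding_frequency(as.numeric(fs), cfg)
}

#' Encoding-law constants k0 and k1
#'
#' The Dehmelt-route encoding law inverts to `mz = k1 / (f_e + k0)` with
#' `k0 = f_min / (2 (f_max - f_min))` and
#' `k1 = e V_trap / (4 sqrt(2) pi^2 u r0^2 f_trap (f_max - f_min))` (Th per
#' cycles/index). These constants seed the first-pass precursor axis and the
#' autocorrelation-line calibration.
#'
#' @param cfg A [swim_config()].
#' @return Named numeric vector `c(k0, k1)`.
#' @export
encoding_constants <- function(cfg) {
  validate_swim_config(cfg)
  df <- cfg$f_max - cfg$f_min
  k0 <- cfg$f_min / (2 * df)
  k1 <- .e_charge * cfg$v_trap /
    (4 * sqrt(2) * pi^2 * .amu * cfg$r0^2 * cfg$f_trap * df)
  c(k0 = k0, k1 = k1)
}

#' Precursor m/z from encoding frequency
#'
#' Inverts the encoding law. Three routes:
#' \describe{
#'   \item{eq5}{the reciprocal Dehmelt form `mz = k1 / (f_e + k0)`; exhibits
#'     curvature error below about m/z 400 where q is no longer small.}
#'   \item{eq6}{the Koizumi closed form, accurate over the whole stability
#'     region; this is the recommended first-pass axis.}
#'   \item{exact}{numerical inversion of the continued-fraction route
#'     (relative tolerance < 1e-10).}
#' }
#'
#' @param f_e Encoding frequency, cycles/index, in `[0, 0.5]`.
#' @param cfg A [swim_config()].
#' @param method `"eq6"` (default), `"eq5"` or `"exact"`.
#' @return Precursor m/z in Th (vectorized).
#' @export
mz_from_encoding <- function(f_e, cfg, method = c("eq6", "eq5", "exact")) {
  method <- match.arg(method)
  validate_swim_config(cfg)
  if (any(f_e < 0 | f_e > 0.5))
    stop("encoding frequency outside [0, 0.5] cycles/index")
  kk <- encoding_constants(cfg)
  if (method == "eq5") return(unname(kk["k1"] / (f_e + kk["k0"])))
  fs <- 2 * f_e * (cfg$f_max - cfg$f_min) + cfg$f_min
  if (method == "eq6") {
    beta <- 2 * fs / cfg$f_trap
    q <- .koizumi_q_from_beta(beta)
    return(.mz_from_q(q, cfg))
  }
  vapply(fs, function(f1) {
    beta <- 2 * f1 / cfg$f_trap
    g <- function(q) mathieu_beta(q, "exact") - beta
    q <- stats::uniroot(g, c(1e-8, 0.908 - 1e-9), tol = 1e-13)$root
    .mz_from_q(q, cfg)
  }, numeric(1))
}

#' Fit the autocorrelation-line mass calibration
#'
#' Peaks on the autocorrelation line of a 2D spectrum are intact precursors,
#' so their accurately known product-axis m/z can recalibrate the precursor
#' axis. The fit is a least-squares polynomial of order 1-3 in the first-pass
#' mass `m1 = k1 / (f_e + k0)` (not in `f_e`):
#' `mz = c0 + c1 m1 + c2 m1^2 + ...`. An exact reciprocal law therefore fits
#' with `c0 = 0, c1 = 1` and zero residual.
#'
#' @param f_e Encoding frequencies of the calibration peaks, cycles/index.
#' @param mz_known Known precursor m/z values (Th), e.g. product-axis
#'   positions of autocorrelation peaks.
#' @param cfg A [swim_config()] supplying `k0`/`k1`; alternatively pass
#'   `k = c(k0, k1)` directly.
#' @param order Polynomial order, 1, 2 or 3.
#' @param k Optional explicit `c(k0, k1)` overriding `cfg`.
#' @return A `calibration_fit`: list with `k0`, `k1`, `coeffs`
#'   (length `order + 1`, intercept first), `order`, `residual_rms` (Th) and
#'   `n_pairs`.
#' @export
fit_calibration <- function(f_e, mz_known, cfg = NULL, order = 1, k = NULL) {
  if (is.null(k)) {
    if (is.null(cfg)) stop("supply either cfg or k = c(k0, k1)")
    k <- encoding_constants(cfg)
  }
  order <- as.integer(order)
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  ok <- is.finite(f_e) & is.finite(mz_known)
  f_e <- f_e[ok]; mz_known <- mz_known[ok]
  if (length(f_e) < order + 2)
    stop("need at least order + 2 calibration pairs")
  if (anyDuplicated(signif(f_e, 12)))
    stop("calibration encoding frequencies must be distinct")
  m1 <- k[["k1"]] / (f_e + k[["k0"]])
  fit <- stats::lm(mz_known ~ stats::poly(m1, order, raw = TRUE))
  co <- unname(stats::coef(fit))
  if (anyNA(co)) stop("rank-deficient calibration design")
  structure(list(k0 = k[["k0"]], k1 = k[["k1"]], coeffs = co, order = order,
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 n_pairs = length(f_e)),
            class = "calibration_fit")
}

#' Apply a calibration fit to encoding frequencies
#'
#' @param fit A `calibration_fit` from [fit_calibration()].
#' @param f_e Encoding frequencies, cycles/index.
#' @return Calibrated precursor m/z (Th).
#' @export
apply_calibration <- function(fit, f_e) {
  stopifnot(inherits(fit, "calibration_fit"))
  m1 <- fit$k1 / (f_e + fit$k0)
  drop(outer(m1, 0:fit$order, `^`) %*% fit$coeffs)
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Autocorrelation-line calibration (order %d, %d pairs)\n",
              x$order, x$n_pairs))
  cat("  k0 =", format(x$k0, digits = 8), " k1 =", format(x$k1, digits = 8), "\n")
  cat("  coeffs:", paste(format(x$coeffs, digits = 8), collapse = ", "), "\n")
  cat("  residual rms:", format(x$residual_rms, digits = 4), "Th\n")
  invisible(x)
}

#' Serialize a calibration fit to JSON
#'
#' @inheritParams apply_calibration
#' @param path File path.
#' @return `path` invisibly / a `calibration_fit`.
#' @export
write_calibration <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  miss <- setdiff(c("k0", "k1", "coeffs", "order"), names(raw))
  if (length(miss)) stop("calibration file missing fields: ", paste(miss, collapse = ", "))
  structure(raw, class = "calibration_fit")
}
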