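# Two-compartment forward signal model:
#   S/S0 = f_in * S_in(d_mean, D_in; waveform) + (1 - f_in) * exp(-b * D_ex)
# with S_in the Gaussian-phase-distribution (GPD) attenuation of water
# restricted in an impermeable sphere, evaluated in the frequency domain:
#   ln S_in = -(1/pi) * integral_0^Inf |q~(w)|^2 D(w) dw
# where D(w) is the sphere's velocity-autocorrelation spectrum
#   D(w) = sum_k B_k a_k w^2 / (a_k^2 + w^2),
#   a_k = mu_k^2 D_in / R^2,  B_k = 2 R^2 / (mu_k^2 (mu_k^2 - 2)),
# and mu_k the positive roots of (mu^2 - 2) sin mu + 2 mu cos mu = 0.

#' Roots of the sphere restriction eigen-equation
#'
#' First `K` positive roots of `(mu^2 - 2) sin(mu) + 2 mu cos(mu) = 0`
#' (the Neumann condition for diffusion in an impermeable sphere). The
#' first root is ~2.0816; subsequent roots interlace multiples of pi.
#'
#' @param K number of roots (>= 1)
#' @return numeric vector of length `K`, strictly increasing
#' @export
sphere_roots <- function(K) {
  stopifnot(K >= 1)
  f <- function(mu) (mu^2 - 2) * sin(mu) + 2 * mu * cos(mu)
  grid <- seq(0.5, (K + 2) * pi, by = 0.05)
  fg <- f(grid)
  sgn <- which(fg[-1] * fg[-length(fg)] < 0)
  roots <- vapply(sgn[seq_len(K)], function(i)
    stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root, 0)
  roots
}

.sphere_roots_cache <- new.env(parent = emptyenv())

.sphere_roots_memo <- function(K) {
  key <- as.character(K)
  if (is.null(.sphere_roots_cache[[key]]))
    .sphere_roots_cache[[key]] <- sphere_roots(K)
  .sphere_roots_cache[[key]]
}

#' Sphere restriction spectrum object
#'
#' Eigen-expansion of the diffusion spectrum of water restricted in an
#' impermeable sphere of diameter `d_mean`: rate constants
#' `a_k = mu_k^2 D_in / R^2` (1/ms) and geometric weights
#' `B_k = 2 R^2 / (mu_k^2 (mu_k^2 - 2))` (um^2). `sum(B_k a_k)` converges
#' to `D_in` as `K` grows.
#'
#' @param d_mean sphere diameter (um)
#' @param D_in intrinsic intracellular diffusivity (um^2/ms)
#' @param K number of eigen-terms retained
#' @return a `sphere_spectrum` object with fields `R`, `D_in`, `mu`, `a`, `B`
#' @export
sphere_modes <- function(d_mean, D_in = 1.58, K = 50) {
  stopifnot(d_mean > 0, D_in > 0)
  R <- d_mean / 2
  mu <- .sphere_roots_memo(K)
  structure(list(R = R, D_in = D_in, K = K, mu = mu,
                 a = mu^2 * D_in / R^2,
                 B = 2 * R^2 / (mu^2 * (mu^2 - 2))),
            class = "sphere_spectrum")
}

#' Dispersive diffusivity D(omega) of a restricted sphere
#'
#' @param d_mean sphere diameter (um)
#' @param D_in intracellular diffusivity (um^2/ms)
#' @param omega angular frequencies (rad/ms), vectorized
#' @param K number of eigen-terms
#' @return `D(omega)` in um^2/ms; 0 at omega = 0, -> `D_in` as omega -> Inf
#' @export
sphere_spectrum <- function(d_mean, D_in = 1.58, omega, K = 50) {
  m <- sphere_modes(d_mean, D_in, K)
  spectrum_D(m, omega)
}

#' Evaluate a `sphere_spectrum` at angular frequencies
#' @param modes a `sphere_spectrum` from [sphere_modes()]
#' @param omega angular frequencies (rad/ms)
#' @return numeric vector
#' @export
spectrum_D <- function(modes, omega) {
  w2 <- omega^2
  out <- numeric(length(omega))
  for (k in seq_along(modes$a)) {
    ak <- modes$a[k]
    out <- out + modes$B[k] * ak * w2 / (ak^2 + w2)
  }
  out
}

# Folded one-sided power spectrum of q(t) on the zero-padded FFT grid.
# Returns omega (rad/ms), P = |q~|^2 (rad^2 um^-2 ms^2) and fold weights,
# truncated once cumulative energy reaches (1 - energy_tol) of the total
# (the spectrum decays ~ omega^-4, so the kept grid is short).
.q_power_spectrum <- function(w, gamma = GAMMA_PROTON, pad = 8, energy_tol = 1e-6) {
  q <- q_of_t(w, gamma)
  n <- length(q)
  M <- 2^ceiling(log2(pad * n))
  Q <- stats::fft(c(q, numeric(M - n)))
  dw <- 2 * pi / (M * w$dt)
  half <- M / 2 + 1
  P <- (abs(Q[seq_len(half)]) * w$dt)^2
  wt <- c(1, rep(2, half - 2), 1)
  cum <- cumsum(P * wt)
  J <- which(cum >= (1 - energy_tol) * cum[half])[1]
  list(omega = (seq_len(J) - 1) * dw, P = P[seq_len(J)], wt = wt[seq_len(J)],
       dw = dw)
}

#' GPD attenuation of restricted (or dispersive) diffusion
#'
#' Gaussian-phase-distribution signal for an arbitrary effective gradient
#' waveform and an arbitrary diffusion spectrum:
#' `ln(S/S0) = -(1/pi) integral_0^Inf |q~(w)|^2 D(w) dw`, evaluated by FFT
#' of `q(t)` on the zero-padded waveform grid. With a constant spectrum
#' `D(w) = D0` this reduces to `exp(-b D0)` (Parseval).
#'
#' @param w a `gradient_waveform`
#' @param spectrum a `sphere_spectrum` object, a function `D(omega)`, or a
#'   single non-negative number (constant spectrum)
#' @param gamma gyromagnetic ratio (rad s^-1 T^-1)
#' @param pad zero-padding factor for the FFT grid
#' @param energy_tol spectral-energy truncation tolerance
#' @return `S/S0` in (0, 1]
#' @export
gpd_attenuation <- function(w, spectrum, gamma = GAMMA_PROTON, pad = 8,
                            energy_tol = 1e-6) {
  ps <- .q_power_spectrum(w, gamma, pad, energy_tol)
  D <- if (inherits(spectrum, "sphere_spectrum")) spectrum_D(spectrum, ps$omega)
       else if (is.function(spectrum)) spectrum(ps$omega)
       else rep(spectrum, length(ps$omega))
  lnS <- -(ps$dw / (2 * pi)) * sum(ps$wt * ps$P * D)
  exp(lnS)
}

#' Tissue parameter vector of the two-compartment model
#'
#' @param d_mean mean cell diameter (um), in (4, 30)
#' @param f_in intracellular signal fraction, in (0, 1)
#' @param D_ex extracellular diffusivity (um^2/ms), in (0, 3.5)
#' @param D_in intracellular diffusivity (um^2/ms), fixed at 1.58 by default
#' @return a `tissue_params` object
#' @export
tissue_params <- function(d_mean, f_in, D_ex, D_in = 1.58) {
  if (!(d_mean > 4 && d_mean < 30))
    stop("d_mean must lie in (4, 30) um", call. = FALSE)
  if (!(f_in > 0 && f_in < 1)) stop("f_in must lie in (0, 1)", call. = FALSE)
  if (!(D_ex > 0 && D_ex < 3.5))
    stop("D_ex must lie in (0, 3.5) um^2/ms", call. = FALSE)
  structure(list(d_mean = d_mean, f_in = f_in, D_ex = D_ex, D_in = D_in),
            class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf(
    "<tissue_params> d_mean=%.3g um f_in=%.3g D_ex=%.3g um^2/ms (D_in=%.3g)\n",
    x$d_mean, x$f_in, x$D_ex, x$D_in))
  invisible(x)
}

#' Forward two-compartment signal over a protocol
#'
#' `S/S0 = f_in * S_in + (1 - f_in) * exp(-b D_ex)` for every
#' (sequence, b) of the protocol; `S_in` is the GPD sphere attenuation of
#' the scaled waveform. Signals are normalized per sequence (S = 1 at b = 0).
#'
#' @param p a `tissue_params` object (or list with the same fields)
#' @param prot a `dmri_protocol`
#' @param kernel optional precomputed [impulsed_kernel()]; when supplied the
#'   intracellular signal is spline-interpolated from the kernel tables
#'   (fast path used by the fitting routines)
#' @param K eigen-terms for the direct GPD path
#' @return data.frame with columns `sequence`, `family`, `b`, `S_over_S0`
#' @export
two_compartment_signal <- function(p, prot, kernel = NULL, K = 50) {
  tab <- acquisition_table(prot)
  b_ms <- tab$b / 1000  # s/mm^2 -> ms/um^2
  if (!is.null(kernel)) {
    S_in <- exp(kernel_lnSin(kernel, p$d_mean))
    key <- paste0(tab$sequence, ":", tab$b)
    Sin_all <- rep(1, nrow(tab))
    Sin_all[match(names(S_in), key)] <- S_in
  } else {
    modes <- sphere_modes(p$d_mean, p$D_in, K)
    wfs <- .protocol_waveforms(prot)
    Sin_all <- rep(1, nrow(tab))
    key <- paste0(tab$sequence, ":", tab$b)
    for (nm in names(wfs))
      Sin_all[key == nm] <- gpd_attenuation(wfs[[nm]], modes, prot$gamma)
  }
  S <- p$f_in * Sin_all + (1 - p$f_in) * exp(-b_ms * p$D_ex)
  data.frame(sequence = tab$sequence, family = tab$family, b = tab$b,
             S_over_S0 = S, row.names = NULL)
}
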