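# Acquisition protocol: effective diffusion-gradient waveforms for PGSE and
# cosine-modulated OGSE, numerical b-values, and effective diffusion times.
#
# Internal unit system: time ms, length um, gradient mT/m.
# gamma is supplied in SI (rad s^-1 T^-1) and converted so that
# q(t) = gamma' * integral(g dt) is in rad/um and b = integral(q^2 dt) is in
# ms/um^2 (multiplied by 1000 to report s/mm^2).

#' Proton gyromagnetic ratio (rad s^-1 T^-1)
#' @export
GAMMA_PROTON <- 2.675e8

# SI gamma -> rad ms^-1 (mT/m)^-1 um^-1
.gamma_internal <- function(gamma) gamma * 1e-12

.trapz <- function(y, dt) dt * (sum(y) - (y[1] + y[length(y)]) / 2)

.cumtrapz <- function(y, dt) c(0, cumsum((y[-1] + y[-length(y)]) / 2) * dt)

.new_waveform <- function(dt, g_eff, family, delta, Delta, n_cycles, f_nominal,
                          f_realized, TE, G, label = NA_character_) {
  structure(
    list(dt = dt, g_eff = g_eff, family = family, delta = delta, Delta = Delta,
         n_cycles = n_cycles, f_nominal = f_nominal, f_realized = f_realized,
         TE = TE, G = G, label = label),
    class = "gradient_waveform")
}

#' @export
print.gradient_waveform <- function(x, ...) {
  cat(sprintf(
    "<gradient_waveform> %s family=%s G=%.3g mT/m delta=%.4g Delta=%.4g TE=%.4g ms",
    ifelse(is.na(x$label), "", x$label), x$family, x$G, x$delta, x$Delta, x$TE))
  if (x$family == "ogse")
    cat(sprintf(" cycles=%d f=%.4g Hz", x$n_cycles, 1000 * x$f_realized))
  cat(sprintf("\n  %d samples, dt=%.4g ms, b=%.4g s/mm^2\n",
              length(x$g_eff), x$dt, b_value(x)))
  invisible(x)
}

# Place two lobes of n_lobe samples each on a uniform grid over [0, TE] such
# that the lobe pair is centred on TE/2 and all lobe edges fall on grid points
# (Delta and the start time are snapped to the grid; the snap is < dt/2).
.lobe_grid <- function(delta, Delta, TE, dt) {
  n_lobe <- max(2L, as.integer(round(delta / dt)))
  dt <- delta / n_lobe
  n <- as.integer(floor(TE / dt + 1e-9))
  i0 <- as.integer(round(((TE - (Delta + delta)) / 2) / dt))
  idelta <- as.integer(round(Delta / dt))
  if (i0 < 0L || i0 + idelta + n_lobe > n)
    stop("protocol error: gradient lobes (delta=", delta, ", Delta=", Delta,
         " ms) do not fit inside TE=", TE, " ms", call. = FALSE)
  list(dt = dt, n = n, i0 = i0, idelta = idelta, n_lobe = n_lobe)
}

#' Pulsed gradient spin-echo effective waveform
#'
#' Builds the effective (sign-flipped after the refocusing pulse) gradient
#' time course of a PGSE pair: a rectangular lobe of amplitude `+G` of
#' duration `delta`, and an effective `-G` lobe starting `Delta` later, the
#' pair centred on `TE/2`. Samples at lobe edges take the half-amplitude
#' value so that trapezoidal integration of the rectangle is exact.
#'
#' @param G gradient amplitude (mT/m)
#' @param delta lobe duration (ms)
#' @param Delta lobe separation, onset to onset (ms)
#' @param TE echo time (ms); the waveform grid spans `[0, TE]`
#' @param dt sample interval (ms); default `delta/200`, must be `<= delta/50`
#' @param label optional sequence label carried through to reports
#' @return a `gradient_waveform` object
#' @export
make_pgse <- function(G, delta, Delta, TE, dt = delta / 200, label = NA_character_) {
  stopifnot(delta > 0, Delta >= delta, TE > 0, dt > 0)
  if (delta + Delta > TE)
    stop("protocol error: delta + Delta = ", delta + Delta, " ms exceeds TE = ",
         TE, " ms", call. = FALSE)
  if (dt > delta / 50) stop("dt must be <= delta/50 for a PGSE lobe", call. = FALSE)
  gr <- .lobe_grid(delta, Delta, TE, dt)
  g <- numeric(gr$n + 1L)
  lobe <- c(0.5, rep(1, gr$n_lobe - 1L), 0.5)
  i <- gr$i0 + seq_len(gr$n_lobe + 1L)             # first lobe samples
  j <- gr$i0 + gr$idelta + seq_len(gr$n_lobe + 1L) # second (refocused) lobe
  g[i] <- g[i] + G * lobe
  g[j] <- g[j] - G * lobe
  .new_waveform(gr$dt, g, "pgse", delta, Delta, 0L, 0, 0, TE, G, label)
}

#' Cosine-modulated oscillating gradient spin-echo effective waveform
#'
#' Each lobe is `g(t) = G cos(2 pi f t)` with `f = n_cycles/delta` (the
#' realized frequency), the second lobe sign-flipped. An integer number of
#' cycles per lobe guarantees zero net first moment. A nominal frequency
#' (e.g. the protocol's advertised 17 or 33 Hz) can be recorded alongside
#' the realized one; all computations use the realized frequency.
#'
#' @inheritParams make_pgse
#' @param n_cycles integer number of oscillation cycles per lobe (>= 1)
#' @param f_nominal nominal frequency in Hz (stored, not used)
#' @param dt sample interval (ms); must resolve >= 100 samples per cycle
#' @return a `gradient_waveform` object
#' @export
make_ogse <- function(G, delta, Delta, n_cycles, TE,
                      dt = delta / (100 * n_cycles), f_nominal = NA_real_,
                      label = NA_character_) {
  stopifnot(delta > 0, Delta >= delta, TE > 0, dt > 0)
  if (n_cycles < 1 || n_cycles != round(n_cycles))
    stop("n_cycles must be a positive integer (non-integer cycles leave a net q)",
         call. = FALSE)
  n_cycles <- as.integer(n_cycles)
  if (delta + Delta > TE)
    stop("protocol error: delta + Delta = ", delta + Delta, " ms exceeds TE = ",
         TE, " ms", call. = FALSE)
  if (dt > delta / (100 * n_cycles) * (1 + 1e-9))
    stop("dt must resolve at least 100 samples per oscillation cycle", call. = FALSE)
  gr <- .lobe_grid(delta, Delta, TE, dt)
  f <- n_cycles / delta  # cycles per ms
  tl <- (0:gr$n_lobe) * gr$dt
  lobe <- cos(2 * pi * f * tl)
  lobe[c(1L, gr$n_lobe + 1L)] <- lobe[c(1L, gr$n_lobe + 1L)] / 2  # edge jumps 0 -> G
  g <- numeric(gr$n + 1L)
  i <- gr$i0 + seq_len(gr$n_lobe + 1L)
  j <- gr$i0 + gr$idelta + seq_len(gr$n_lobe + 1L)
  g[i] <- g[i] + G * lobe
  g[j] <- g[j] - G * lobe
  .new_waveform(gr$dt, g, "ogse", delta, Delta, n_cycles,
                ifelse(is.na(f_nominal), NA_real_, f_nominal / 1000), f, TE, G,
                label)
}

#' First moment q(t) of a waveform (rad/um)
#'
#' @param w a `gradient_waveform`
#' @param gamma gyromagnetic ratio (rad s^-1 T^-1)
#' @return numeric vector, same length as `w$g_eff`
#' @export
q_of_t <- function(w, gamma = GAMMA_PROTON) {
  .gamma_internal(gamma) * .cumtrapz(w$g_eff, w$dt)
}

#' Numerical b-value of an arbitrary effective waveform
#'
#' `b = integral q(t)^2 dt` with `q(t) = gamma * integral g_eff dt`,
#' evaluated by trapezoidal quadrature and reported in s/mm^2.
#'
#' @inheritParams q_of_t
#' @return b-value in s/mm^2
#' @export
b_value <- function(w, gamma = GAMMA_PROTON) {
  q <- q_of_t(w, gamma)
  1000 * .trapz(q^2, w$dt)
}

#' Scale a waveform's amplitude to reach a target b-value
#'
#' The gradient amplitude is multiplied by `sqrt(b_target/b_current)`; an
#' error is raised when the required amplitude exceeds the system limit.
#' The default limit is the all-axes-combined maximum `45*sqrt(3)` mT/m for
#' a scanner with 45 mT/m per axis; pass `g_max = 45` for a strict
#' single-axis check.
#'
#' @inheritParams q_of_t
#' @param b_target target b-value (s/mm^2, >= 0)
#' @param g_max maximum allowed gradient amplitude (mT/m)
#' @return the rescaled `gradient_waveform`
#' @export
scale_to_b <- function(w, b_target, gamma = GAMMA_PROTON, g_max = 45 * sqrt(3)) {
  stopifnot(b_target >= 0)
  if (b_target == 0) {
    w$g_eff <- 0 * w$g_eff
    w$G <- 0
    return(w)
  }
  b0 <- b_value(w, gamma)
  if (b0 <= 0) stop("cannot scale a zero waveform to a nonzero b", call. = FALSE)
  s <- sqrt(b_target / b0)
  G_req <- abs(w$G) * s
  if (G_req > g_max + 1e-9)
    stop(sprintf(
      "protocol error: sequence %s needs G = %.2f mT/m for b = %g s/mm^2 (limit %.2f)",
      ifelse(is.na(w$label), w$family, w$label), G_req, b_target, g_max),
      call. = FALSE)
  w$g_eff <- w$g_eff * s
  w$G <- w$G * s
  w
}

#' Effective diffusion time of a waveform
#'
#' `Delta - delta/3` for PGSE; `1/(4 f)` for cosine OGSE, with `f` the
#' realized oscillation frequency.
#'
#' @param w a `gradient_waveform`
#' @return effective diffusion time (ms)
#' @export
effective_diffusion_time <- function(w) {
  switch(w$family,
         pgse = w$Delta - w$delta / 3,
         ogse = 1 / (4 * w$f_realized),
         stop("unknown waveform family: ", w$family))
}

#' Check waveform invariants
#'
#' Verifies the rephasing condition (zero net first moment), positive dt and
#' a non-negative b-value.
#'
#' @inheritParams q_of_t
#' @return TRUE invisibly; error otherwise
#' @export
validate_waveform <- function(w, gamma = GAMMA_PROTON) {
  stopifnot(inherits(w, "gradient_waveform"), w$dt > 0)
  net <- abs(.trapz(w$g_eff, w$dt))
  if (max(abs(w$g_eff)) > 0 && net >= 1e-9 * max(abs(w$g_eff)) * w$TE)
    stop("waveform violates the rephasing condition (net gradient moment ",
         net, ")", call. = FALSE)
  if (b_value(w, gamma) < 0) stop("negative b-value", call. = FALSE)
  invisible(TRUE)
}

.template_waveform <- function(s) {
  G_ref <- 10
  if (identical(s$family, "pgse"))
    make_pgse(G_ref, s$delta_ms, s$Delta_ms, s$TE_ms, label = s$label)
  else
    make_ogse(G_ref, s$delta_ms, s$Delta_ms, s$n_cycles, s$TE_ms,
              f_nominal = if (is.null(s$f_nominal_hz)) NA_real_ else s$f_nominal_hz,
              label = s$label)
}

#' Load an acquisition protocol from JSON
#'
#' The JSON holds one object per sequence with fields `label`, `family`
#' (`"pgse"` or `"ogse"`), `delta_ms`, `Delta_ms`, `n_cycles` (OGSE only),
#' `TE_ms` and `b_values_s_mm2` (strictly increasing, starting at 0).
#' Each sequence's b-list is checked for realizability under the gradient
#' limit.
#'
#' @param path JSON file path
#' @param gamma gyromagnetic ratio (rad s^-1 T^-1)
#' @param g_max gradient amplitude limit (mT/m); see [scale_to_b()]
#' @return a `dmri_protocol` object
#' @export
load_protocol <- function(path, gamma = GAMMA_PROTON, g_max = 45 * sqrt(3)) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  gamma <- if (!is.null(cfg$gamma)) cfg$gamma else gamma
  seqs <- lapply(seq_len(nrow(cfg$sequences)), function(i) {
    s <- as.list(cfg$sequences[i, ])
    s$b_values_s_mm2 <- cfg$sequences$b_values_s_mm2[[i]]
    b <- s$b_values_s_mm2
    if (b[1] != 0 || any(diff(b) <= 0))
      stop("b-value list of ", s$label,
           " must start at 0 and be strictly increasing", call. = FALSE)
    tmpl <- .template_waveform(s)
    validate_waveform(tmpl, gamma)
    for (bv in b[b > 0]) scale_to_b(tmpl, bv, gamma, g_max)  # realizability
    list(label = s$label, family = s$family, template = tmpl, b_values = b,
         td_printed_ms = if (is.null(s$td_printed_ms)) NA_real_ else s$td_printed_ms)
  })
  names(seqs) <- vapply(seqs, `[[`, "", "label")
  structure(list(sequences = seqs, gamma = gamma, g_max = g_max, source = path),
            class = "dmri_protocol")
}

#' The packaged three-frequency breast protocol
#'
#' Conventional DWI-style PGSE, long-Delta PGSE, and cosine OGSE at nominal
#' 17 and 33 Hz, with the per-sequence b-value lists of the packaged
#' `table1.json` fixture.
#'
#' @inheritParams load_protocol
#' @return a `dmri_protocol` object
#' @export
default_protocol <- function(gamma = GAMMA_PROTON, g_max = 45 * sqrt(3)) {
  load_protocol(system.file("extdata", "table1.json", package = "impulsedr",
                            mustWork = TRUE),
                gamma = gamma, g_max = g_max)
}

#' @export
print.dmri_protocol <- function(x, ...) {
  cat("<dmri_protocol>", length(x$sequences), "sequences\n")
  for (s in x$sequences)
    cat(sprintf("  %-10s %s td=%.1f ms b: %s\n", s$label, s$family,
                effective_diffusion_time(s$template),
                paste(s$b_values, collapse = "/")))
  invisible(x)
}

#' Flattened acquisition table of a protocol
#'
#' One row per (sequence, b-value) in protocol order; this is the canonical
#' ordering of the 4th dimension of simulated/fitted volumes.
#'
#' @param prot a `dmri_protocol`
#' @return data.frame with columns `sequence`, `family`, `b`
#' @export
acquisition_table <- function(prot) {
  do.call(rbind, lapply(prot$sequences, function(s)
    data.frame(sequence = s$label, family = s$family, b = s$b_values,
               row.names = NULL)))
}

# List of scaled waveforms for every b > 0 acquisition, names "<label>:<b>"
.protocol_waveforms <- function(prot) {
  out <- list()
  for (s in prot$sequences)
    for (bv in s$b_values[s$b_values > 0])
      out[[paste0(s$label, ":", bv)]] <-
        scale_to_b(s$template, bv, prot$gamma, prot$g_max)
  out
}
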