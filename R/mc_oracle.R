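# Monte-Carlo random-walk oracle for restricted diffusion in a sphere.
# Serves as the independent ground truth for the GPD signal model.

#' @useDynLib impulsedr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.mc_gvec <- function(w, step_dt) {
  n_steps <- max(1L, as.integer(floor(w$TE / step_dt)))
  t_mid <- (seq_len(n_steps) - 0.5) * step_dt
  t_w <- (seq_along(w$g_eff) - 1) * w$dt
  stats::approx(t_w, w$g_eff, xout = t_mid, yleft = 0, yright = 0)$y
}

#' Monte-Carlo signal of diffusion restricted in a sphere
#'
#' Simulates `n_walkers` random walkers inside an impermeable sphere of
#' diameter `d_mean` under the effective gradient waveform `w` and returns
#' the magnitude signal `<cos(phi)>` with its Monte-Carlo standard error.
#' Walkers step a fixed length `sqrt(6 D_in step_dt)` in uniform random
#' directions with elastic specular reflection at the boundary; the spatial
#' step must satisfy `sqrt(6 D_in step_dt) <= R/10` (pass a smaller
#' `step_dt` for small spheres).
#'
#' @param d_mean sphere diameter (um)
#' @param D_in diffusivity (um^2/ms)
#' @param w a `gradient_waveform`
#' @param n_walkers number of walkers
#' @param step_dt MC time step (ms)
#' @param seed integer seed of the simulator's private RNG; identical seeds
#'   give bit-identical output
#' @param gamma gyromagnetic ratio (rad s^-1 T^-1)
#' @param axis gradient axis (1, 2 or 3); the signal is axis-invariant by
#'   spherical symmetry
#' @return list with `S` (signal), `se` (standard error), `n_walkers`,
#'   `step_dt`
#' @export
simulate_sphere_signal <- function(d_mean, D_in, w, n_walkers = 20000,
                                   step_dt = 0.05, seed = 1,
                                   gamma = GAMMA_PROTON, axis = 3) {
  R <- d_mean / 2
  if (sqrt(6 * D_in * step_dt) > R / 10)
    stop("oracle error: step length sqrt(6 D dt) = ",
         signif(sqrt(6 * D_in * step_dt), 4), " um exceeds R/10 = ",
         signif(R / 10, 4), " um; use a finer step_dt", call. = FALSE)
  g <- .mc_gvec(w, step_dt)
  phases <- .mc_walk_phases(R, D_in, g, step_dt, as.integer(n_walkers),
                            .gamma_internal(gamma), as.integer(seed),
                            as.integer(axis) - 1L)
  cphi <- cos(phases)
  list(S = mean(cphi), se = stats::sd(cphi) / sqrt(length(cphi)),
       n_walkers = n_walkers, step_dt = step_dt)
}

#' Largest MC time step compatible with the step-length precondition
#' @param d_mean sphere diameter (um)
#' @param D_in diffusivity (um^2/ms)
#' @param step_dt_max upper cap (ms)
#' @return step (ms)
#' @export
mc_step_dt <- function(d_mean, D_in = 1.58, step_dt_max = 0.05) {
  min(step_dt_max, 0.99 * (d_mean / 20)^2 / (6 * D_in))
}

#' Monte-Carlo intracellular signals across a protocol
#'
#' One trajectory set is simulated per sequence at the largest-b waveform;
#' signals at the other shells of that sequence reuse the phases (phase
#' scales linearly with gradient amplitude), which makes a full protocol
#' sweep cheap while keeping shells statistically coupled within a
#' sequence.
#'
#' @inheritParams simulate_sphere_signal
#' @param prot a `dmri_protocol`
#' @param b_max only shells with `b <= b_max` (s/mm^2) are evaluated
#' @return data.frame with columns `sequence`, `b`, `S_mc`, `mc_se`
#' @export
mc_protocol_signal <- function(d_mean, D_in, prot, n_walkers = 20000,
                               step_dt = NULL, seed = 1, b_max = Inf) {
  if (is.null(step_dt)) step_dt <- mc_step_dt(d_mean, D_in)
  out <- list()
  si <- 0L
  for (s in prot$sequences) {
    b <- s$b_values[s$b_values > 0 & s$b_values <= b_max]
    if (!length(b)) next
    si <- si + 1L
    w_ref <- scale_to_b(s$template, max(b), prot$gamma, prot$g_max)
    R <- d_mean / 2
    g <- .mc_gvec(w_ref, step_dt)
    phases <- .mc_walk_phases(R, D_in, g, step_dt, as.integer(n_walkers),
                              .gamma_internal(prot$gamma),
                              as.integer(seed + si), 2L)
    for (bv in b) {
      sc <- sqrt(bv / max(b))
      cphi <- cos(sc * phases)
      out[[paste0(s$label, ":", bv)]] <-
        data.frame(sequence = s$label, b = bv, S_mc = mean(cphi),
                   mc_se = stats::sd(cphi) / sqrt(length(cphi)))
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
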