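# Inverse problem: per-voxel ADC fits and bounded multi-start nonlinear
# least-squares fits of the two-compartment model, plus map-level fitting
# with ROI aggregation.

.IMPULSED_LOWER <- c(d_mean = 4, f_in = 0, D_ex = 0)
.IMPULSED_UPPER <- c(d_mean = 30, f_in = 1, D_ex = 3.5)

# report column name of a sequence's ADC ("OGSE_17Hz" -> "ADC_17Hz")
.adc_col <- function(label) paste0("ADC_", sub("^OGSE_", "", label))

#' Fitting options for [fit_impulsed()]
#'
#' @param d_starts,f_starts,D_starts coarse multi-start grid (the full grid
#'   is their cross product; objective is evaluated at every node)
#' @param n_refine number of best grid nodes refined by bounded
#'   quasi-Newton iterations
#' @param rel_tol,max_iter convergence controls per restart
#' @param identifiability_f fitted `f_in` below which the diameter
#'   identifiability profile is computed
#' @param identifiability_rms RMS signal level under which two diameters are
#'   considered indistinguishable by the profile
#' @return list of options
#' @export
impulsed_fit_opts <- function(d_starts = c(6, 10, 14, 18, 22, 26),
                              f_starts = c(0.1, 0.3, 0.5, 0.7),
                              D_starts = c(0.5, 1.5, 2.5),
                              n_refine = 6, rel_tol = 1e-8, max_iter = 500,
                              identifiability_f = 0.15,
                              identifiability_rms = 0.005) {
  list(d_starts = d_starts, f_starts = f_starts, D_starts = D_starts,
       n_refine = n_refine, rel_tol = rel_tol, max_iter = max_iter,
       identifiability_f = identifiability_f,
       identifiability_rms = identifiability_rms)
}

#' Mono-exponential ADC fit
#'
#' Least-squares line through `(b, ln S)`; `ADC = -slope`, reported in
#' um^2/ms for b given in s/mm^2. Negative slopes are clipped to zero and
#' flagged. Voxels with any non-positive signal are flagged (and excluded
#' from ROI summaries by [fit_maps()]).
#'
#' @param b b-values (s/mm^2), at least two distinct
#' @param S signals (same length), normalized or not (the intercept absorbs
#'   the scale)
#' @param sequence_label carried through to the result
#' @return an `adc_fit` list: `adc` (um^2/ms), `s0`, `r_squared`,
#'   `sequence_label`, `flagged`, `clipped`
#' @export
fit_adc <- function(b, S, sequence_label = NA_character_) {
  stopifnot(length(b) == length(S), length(unique(b)) >= 2)
  flagged <- any(!is.finite(S) | S <= 0)
  if (flagged) {
    return(structure(list(adc = NA_real_, s0 = NA_real_, r_squared = NA_real_,
                          sequence_label = sequence_label, flagged = TRUE,
                          clipped = FALSE), class = "adc_fit"))
  }
  y <- log(S)
  fit <- stats::lm.fit(cbind(1, b), y)
  slope <- fit$coefficients[2]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  adc <- -slope * 1000  # (1/(s/mm^2)) -> um^2/ms
  clipped <- adc < 0
  if (clipped) adc <- 0
  structure(list(adc = unname(adc), s0 = unname(exp(fit$coefficients[1])),
                 r_squared = unname(r2), sequence_label = sequence_label,
                 flagged = FALSE, clipped = clipped), class = "adc_fit")
}

# Normalize a raw acquisition-ordered signal vector per sequence by its
# b = 0 entry; returns list(obs = data.frame for b>0 rows, s0 = named vec).
.normalize_signals <- function(signals) {
  stopifnot(all(c("sequence", "b", "S") %in% names(signals)))
  out <- NULL
  for (sq in unique(signals$sequence)) {
    rows <- signals[signals$sequence == sq, ]
    if (any(rows$b == 0)) {
      s0 <- rows$S[rows$b == 0][1]
      rows$S <- rows$S / s0
    }
    out <- rbind(out, rows[rows$b > 0, ])
  }
  out
}

#' Voxelwise two-compartment model fit
#'
#' Bounded nonlinear least squares for `(d_mean, f_in, D_ex)` with `D_in`
#' fixed, minimizing the sum of squared differences between the model and
#' the observed per-sequence-normalized signals at all b > 0 shells.
#' The objective is evaluated on a coarse multi-start grid
#' (see [impulsed_fit_opts()]); the best nodes are refined with `nlminb`
#' under the box constraints `4 < d_mean < 30`, `0 < f_in < 1`,
#' `0 < D_ex < 3.5`. Ties are broken toward the smallest `d_mean`.
#'
#' @param signals data.frame with columns `sequence`, `b` (s/mm^2), `S`;
#'   must cover at least two sequence families / diffusion times
#' @param prot a `dmri_protocol`
#' @param opts from [impulsed_fit_opts()]
#' @param kernel optional precomputed [impulsed_kernel()] (built and cached
#'   automatically otherwise)
#' @param D_in fixed intracellular diffusivity (um^2/ms)
#' @return an `impulsed_fit` list: `params` (tissue_params), `cellularity`
#'   (`f_in/d_mean`, 1/um), `residual_rms`, `converged`, `n_restarts_used`,
#'   `on_boundary`, `d_spread` (relative width of the set of diameters whose
#'   profile fit is indistinguishable from the optimum; > 0.2 flags an
#'   unidentifiable diameter, profiled when the fitted `f_in` is small),
#'   `objective`
#' @export
fit_impulsed <- function(signals, prot, opts = impulsed_fit_opts(),
                         kernel = NULL, D_in = 1.58) {
  if (length(unique(signals$sequence[signals$b > 0])) < 2)
    stop("identifiability requires signals from >= 2 sequences with distinct diffusion times",
         call. = FALSE)
  if (is.null(kernel)) kernel <- .cached_kernel(prot, D_in = D_in)
  obs <- .normalize_signals(signals)
  key <- paste0(obs$sequence, ":", obs$b)
  idx <- match(key, kernel$labels)
  if (anyNA(idx))
    stop("signals contain acquisitions absent from the protocol: ",
         paste(key[is.na(idx)], collapse = ", "), call. = FALSE)
  b_ms <- obs$b / 1000
  S_obs <- obs$S
  splines <- kernel$splines[idx]

  model <- function(par) {
    lnSin <- vapply(splines, function(f) f(par[1]), 0)
    par[2] * exp(lnSin) + (1 - par[2]) * exp(-b_ms * par[3])
  }
  objective <- function(par) sum((model(par) - S_obs)^2)

  grid <- as.matrix(expand.grid(d_mean = opts$d_starts, f_in = opts$f_starts,
                                D_ex = opts$D_starts))
  g_obj <- apply(grid, 1, objective)
  ord <- order(g_obj, grid[, 1])
  n_ref <- min(opts$n_refine, nrow(grid))
  eps <- 1e-9
  lower <- .IMPULSED_LOWER + c(eps, eps, eps)
  upper <- .IMPULSED_UPPER - c(eps, eps, eps)
  fits <- lapply(ord[seq_len(n_ref)], function(i) {
    res <- tryCatch(
      stats::nlminb(grid[i, ], objective, lower = lower, upper = upper,
                    control = list(rel.tol = opts$rel_tol,
                                   iter.max = opts$max_iter)),
      error = function(e) NULL)
    res
  })
  fits <- Filter(Negate(is.null), fits)
  converged <- length(fits) > 0 && any(vapply(fits, `[[`, 0L, "convergence") == 0L)
  if (!length(fits)) {  # all restarts failed: best grid node
    best_par <- grid[ord[1], ]
    best_obj <- g_obj[ord[1]]
  } else {
    objs <- vapply(fits, `[[`, 0, "objective")
    pars <- t(vapply(fits, `[[`, numeric(3), "par"))
    best_obj <- min(objs)
    cand <- which(objs <= best_obj * (1 + 1e-9) + 1e-15)
    best_i <- cand[which.min(pars[cand, 1])]  # tie-break: smallest d_mean
    best_par <- pars[best_i, ]
  }
  # identifiability of d: width of the d-set whose profile fit (f_in, D_ex
  # re-optimized at fixed d) stays within `identifiability_rms` of the data;
  # a wide set means the diameter carries no information (typical at small
  # f_in). Profiled only in that regime to keep map fitting cheap.
  d_spread <- 0
  if (length(fits) && best_par[[2]] < opts$identifiability_f) {
    d_prof <- sort(unique(c(opts$d_starts, best_par[[1]])))
    prof_obj <- vapply(d_prof, function(dfix) {
      lnSin <- vapply(splines, function(f) f(dfix), 0)
      Sin <- exp(lnSin)
      o2 <- function(q) sum((q[1] * Sin + (1 - q[1]) * exp(-b_ms * q[2]) -
                               S_obs)^2)
      stats::nlminb(best_par[2:3], o2, lower = c(eps, eps),
                    upper = c(1 - eps, 3.5 - eps))$objective
    }, 0)
    flat <- d_prof[sqrt(prof_obj / length(S_obs)) <= opts$identifiability_rms]
    if (length(flat) > 1) d_spread <- (max(flat) - min(flat)) / mean(flat)
  }
  best_par <- pmin(pmax(best_par, lower), upper)
  on_boundary <- any(best_par <= lower + 1e-6 * (upper - lower) |
                     best_par >= upper - 1e-6 * (upper - lower))
  p <- structure(list(d_mean = best_par[[1]], f_in = best_par[[2]],
                      D_ex = best_par[[3]], D_in = D_in),
                 class = "tissue_params")
  structure(list(params = p, cellularity = p$f_in / p$d_mean,
                 residual_rms = sqrt(best_obj / length(S_obs)),
                 converged = converged,
                 n_restarts_used = length(fits),
                 on_boundary = on_boundary, d_spread = d_spread,
                 objective = best_obj, grid_objectives = g_obj),
            class = "impulsed_fit")
}

#' @export
print.impulsed_fit <- function(x, ...) {
  cat(sprintf(
    "<impulsed_fit> d_mean=%.3f um f_in=%.3f D_ex=%.3f um^2/ms cellularity=%.4g /um\n",
    x$params$d_mean, x$params$f_in, x$params$D_ex, x$cellularity))
  cat(sprintf("  rms=%.3g converged=%s restarts=%d boundary=%s d_spread=%.3g\n",
              x$residual_rms, x$converged, x$n_restarts_used, x$on_boundary,
              x$d_spread))
  invisible(x)
}

#' Voxelwise parameter maps with ROI aggregation
#'
#' Runs [fit_impulsed()] and per-sequence [fit_adc()] in every voxel of the
#' mask, producing parameter maps and a per-ROI summary. The cellularity
#' index is computed voxelwise and then averaged (not as a ratio of means).
#' Voxels with a flagged ADC (non-positive signal) are excluded from that
#' sequence's ROI summary and counted.
#'
#' @param vol4d 4D array `(x, y, z, acquisition)`; the 4th axis must follow
#'   the protocol's flattened (sequence, b) order, see [acquisition_table()]
#' @param mask 3D 0/1 array on the same spatial grid
#' @param prot a `dmri_protocol`
#' @param opts fitting options
#' @param kernel optional precomputed kernel
#' @param lesion_id label used in the summary
#' @return a `parameter_maps` list: `maps` (named list of 3D arrays),
#'   `roi_summary` (data.frame: lesion_id, parameter, mean, sd, n_voxels,
#'   n_flagged), `acq`
#' @export
fit_maps <- function(vol4d, mask, prot, opts = impulsed_fit_opts(n_refine = 3),
                     kernel = NULL, lesion_id = "lesion_1") {
  tab <- acquisition_table(prot)
  if (length(dim(vol4d)) != 4)
    stop("vol4d must be a 4D array (x, y, z, acquisition); got ",
         length(dim(vol4d)), "D", call. = FALSE)
  if (dim(vol4d)[4] != nrow(tab))
    stop("4th dimension (", dim(vol4d)[4], ") does not match the protocol's ",
         nrow(tab), " acquisitions", call. = FALSE)
  if (!identical(dim(mask), dim(vol4d)[1:3]))
    stop("mask grid does not match the volume", call. = FALSE)
  if (!all(mask %in% c(0, 1))) stop("mask must contain only 0/1", call. = FALSE)
  vox <- which(mask == 1, arr.ind = TRUE)
  if (nrow(vox) == 0) stop("empty mask", call. = FALSE)
  if (is.null(kernel)) kernel <- .cached_kernel(prot)

  seqs <- unique(tab$sequence)
  par_names <- c("d_mean", "f_in", "D_ex", "cellularity", .adc_col(seqs))
  maps <- lapply(par_names, function(p) array(NA_real_, dim(mask)))
  names(maps) <- par_names
  flagged <- setNames(integer(length(seqs)), seqs)

  for (v in seq_len(nrow(vox))) {
    i <- vox[v, 1]; j <- vox[v, 2]; k <- vox[v, 3]
    sig <- data.frame(sequence = tab$sequence, b = tab$b,
                      S = vol4d[i, j, k, ])
    fit <- fit_impulsed(sig, prot, opts, kernel = kernel)
    maps$d_mean[i, j, k] <- fit$params$d_mean
    maps$f_in[i, j, k] <- fit$params$f_in
    maps$D_ex[i, j, k] <- fit$params$D_ex
    maps$cellularity[i, j, k] <- fit$cellularity
    for (sq in seqs) {
      rows <- sig[sig$sequence == sq, ]
      af <- fit_adc(rows$b, rows$S, sq)
      if (af$flagged) flagged[sq] <- flagged[sq] + 1L
      maps[[.adc_col(sq)]][i, j, k] <- af$adc
    }
  }
  roi <- do.call(rbind, lapply(par_names, function(p) {
    vals <- maps[[p]][mask == 1]
    vals <- vals[!is.na(vals)]
    data.frame(lesion_id = lesion_id, parameter = p, mean = mean(vals),
               sd = if (length(vals) > 1) stats::sd(vals) else 0,
               n_voxels = length(vals),
               n_flagged = if (startsWith(p, "ADC_"))
                 unname(flagged[seqs[.adc_col(seqs) == p]]) else 0L,
               row.names = NULL)
  }))
  structure(list(maps = maps, roi_summary = roi, acq = tab, mask = mask),
            class = "parameter_maps")
}
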