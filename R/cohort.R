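# Synthetic cohort generator: enrollment roster with exclusion flags,
# group/immunohistochemistry labels allocated to match the study-style
# printed marginals exactly, per-lesion ground-truth tissue parameters,
# and noisy lesion phantoms under the acquisition protocol.

#' Cohort specification
#'
#' Defaults encode the emulated study: 236 collected, exclusions 10 (lesion
#' < 8 mm) / 5 (no pathology) / 8 (poor image quality), 213 enrolled split
#' 83 benign / 130 malignant with 117 invasive breast cancers (IBC), IBC
#' marginals ER+ 87, PR+ 73, HER-2+ 46, Ki-67-high 104, grades 4/67/46 and
#' subtype labels 8/71/26/12 (Luminal A/B, HER-2 overexpression, triple
#' negative), and group-level tissue parameter distributions
#' (mean, SD) for d_mean (um), f_in and D_ex (um^2/ms).
#'
#' Note the printed subtype counts are jointly infeasible with the HER-2
#' marginal under the receptor-based typing rule; the generator matches all
#' marginals exactly and reports the number of rule-inconsistent records
#' (see [generate_roster()]).
#'
#' @param n_collected patients collected
#' @param exclusions named counts `small_lesion`, `no_pathology`,
#'   `poor_quality` (disjoint, one criterion per excluded patient)
#' @param n_benign,n_malignant enrolled group sizes
#' @param benign_histology,malignant_histology named integer vectors of
#'   histology labels; `ibc_labels` names the malignant labels counted as IBC
#' @param ihc named list of IBC marginals
#' @param params per-group `(mean, sd)` for `d`, `f`, `Dex`
#' @param jitter_cv within-lesion coefficient of variation of the tissue
#'   parameters
#' @param obs_noise_ratio observer-noise to between-lesion variance ratio
#'   used when simulating two raters (0.2 targets ICC ~ 0.83)
#' @return a `cohort_spec` list
#' @export
cohort_spec <- function(
    n_collected = 236,
    exclusions = c(small_lesion = 10, no_pathology = 5, poor_quality = 8),
    n_benign = 83, n_malignant = 130,
    benign_histology = c(Fibroadenoma = 47, Adenopathy = 15,
                         Inflammatory = 6, IntraductalPapilloma = 5,
                         FoliateTumor = 10),
    malignant_histology = c(InvasiveCarcinoma = 113, InvasiveLobular = 4,
                            DCIS = 11, Lymphoma = 2),
    ihc = list(er_pos = 87, pr_pos = 73, her2_pos = 46, ki67_high = 104,
               grade = c(I = 4, II = 67, III = 46),
               subtype = c(LuminalA = 8, LuminalB = 71, HER2over = 26, TN = 12)),
    params = list(
      benign = list(d = c(14.38, 4.645), f = c(0.279, 0.212),
                    Dex = c(2.378, 0.332), rho_fd = 0.616,
                    cellularity = c(0.01938, 0.01487)),
      malignant = list(d = c(15.74, 2.677), f = c(0.346, 0.125),
                       Dex = c(2.119, 0.395), rho_fd = 0.9,
                       cellularity = c(0.02119, 0.03954))),
    jitter_cv = 0.05, obs_noise_ratio = 0.2) {
  n_excluded <- sum(exclusions)
  if (n_benign + n_malignant != n_collected - n_excluded)
    stop("infeasible spec: group sizes (", n_benign + n_malignant,
         ") must sum to n_collected - exclusions (",
         n_collected - n_excluded, ")", call. = FALSE)
  if (sum(benign_histology) != n_benign ||
      sum(malignant_histology) != n_malignant)
    stop("histology counts must sum to the group sizes", call. = FALSE)
  n_ibc <- sum(malignant_histology[names(malignant_histology) %in%
                                     c("InvasiveCarcinoma", "InvasiveLobular")])
  if (!is.null(ihc)) {
    if (sum(ihc$grade) != n_ibc || sum(ihc$subtype) != n_ibc)
      stop("grade and subtype counts must sum to the IBC count (", n_ibc, ")",
           call. = FALSE)
    if (any(unlist(ihc[c("er_pos", "pr_pos", "her2_pos", "ki67_high")]) > n_ibc))
      stop("IHC-positive counts cannot exceed the IBC count", call. = FALSE)
  }
  structure(list(n_collected = n_collected, exclusions = exclusions,
                 n_benign = n_benign, n_malignant = n_malignant,
                 n_ibc = n_ibc, benign_histology = benign_histology,
                 malignant_histology = malignant_histology, ihc = ihc,
                 params = params, jitter_cv = jitter_cv,
                 obs_noise_ratio = obs_noise_ratio),
            class = "cohort_spec")
}

# Subtype implied by receptor status under the standard typing rule
.subtype_rule <- function(er, pr, her2) {
  hr <- er == "pos" | pr == "pos"
  ifelse(hr & her2 == "neg", "LuminalA",
  ifelse(hr & her2 == "pos", "LuminalB",
  ifelse(!hr & her2 == "pos", "HER2over", "TN")))
}

# allocate `n_pos` positives across records, preferring earlier priority
# classes; within a class the order is the (already shuffled) record order
.alloc_binary <- function(class_priority, n_pos) {
  out <- rep("neg", length(class_priority))
  remaining <- n_pos
  for (lvl in sort(unique(class_priority))) {
    idx <- which(class_priority == lvl)
    take <- min(length(idx), remaining)
    if (take > 0) out[idx[seq_len(take)]] <- "pos"
    remaining <- remaining - take
  }
  out
}

#' Generate the enrollment roster
#'
#' Produces exactly `spec$n_collected` patient records. Exclusion flags are
#' assigned disjointly to exactly the specified counts (each excluded
#' patient fails a single criterion); the remaining records are enrolled
#' and receive group, histology and (for IBC) immunohistochemistry labels
#' allocated to match the spec marginals exactly, then shuffled by seed.
#' Ground-truth tissue parameters are drawn per group from the spec
#' distributions (truncated to the physical bounds).
#'
#' Subtype labels are allocated to the printed subtype marginal with a
#' deterministic priority coupling to (ER, PR, HER-2) that maximizes
#' agreement with the receptor-based rule; the count of records whose
#' label disagrees with the rule is reported in
#' `attr(roster, "n_subtype_inconsistent")`.
#'
#' @param spec a [cohort_spec()]
#' @param seed integer seed
#' @return data.frame roster, one row per collected patient
#' @export
generate_roster <- function(spec = cohort_spec(), seed = 1) {
  set.seed(seed)
  n <- spec$n_collected
  ex <- spec$exclusions
  n_en <- n - sum(ex)

  excl_reason <- c(rep("small_lesion", ex[["small_lesion"]]),
                   rep("no_pathology", ex[["no_pathology"]]),
                   rep("poor_quality", ex[["poor_quality"]]),
                   rep("none", n_en))

  group <- c(rep(NA_character_, sum(ex)),
             rep("benign", spec$n_benign), rep("malignant", spec$n_malignant))
  histology <- c(rep(NA_character_, sum(ex)),
                 rep(names(spec$benign_histology), spec$benign_histology),
                 rep(names(spec$malignant_histology), spec$malignant_histology))
  is_ibc <- !is.na(histology) &
    histology %in% c("InvasiveCarcinoma", "InvasiveLobular")

  # --- IBC immunohistochemistry, allocated to exact marginals ------------
  er <- pr <- her2 <- ki67 <- grade <- subtype <- rep(NA_character_, n)
  n_inconsistent <- 0L
  if (spec$n_ibc > 0 && !is.null(spec$ihc)) {
    ibc_idx <- sample(which(is_ibc))  # seeded coupling order
    m <- length(ibc_idx)
    st <- rep(names(spec$ihc$subtype), spec$ihc$subtype)
    st <- st[seq_len(m)]
    # HER-2: rule-consistent first (HER2over, LuminalB), then others
    her2_prio <- match(st, c("HER2over", "LuminalB", "LuminalA", "TN"))
    h <- .alloc_binary(her2_prio, spec$ihc$her2_pos)
    # hormone receptors: luminal first, then HER2over, then TN
    hr_prio <- match(st, c("LuminalA", "LuminalB", "HER2over", "TN"))
    e <- .alloc_binary(hr_prio, spec$ihc$er_pos)
    p <- .alloc_binary(hr_prio, spec$ihc$pr_pos)
    k <- .alloc_binary(sample(rep(1L, m)), spec$ihc$ki67_high)
    k <- ifelse(k == "pos", "high", "low")
    g <- sample(rep(names(spec$ihc$grade), spec$ihc$grade))[seq_len(m)]
    er[ibc_idx] <- e; pr[ibc_idx] <- p; her2[ibc_idx] <- h
    ki67[ibc_idx] <- k; grade[ibc_idx] <- g; subtype[ibc_idx] <- st
    n_inconsistent <- sum(.subtype_rule(e, p, h) != st)
  }

  # --- ground-truth tissue parameters ------------------------------------
  d <- f <- Dex <- rep(NA_real_, n)
  for (grp in c("benign", "malignant")) {
    idx <- which(!is.na(group) & group == grp)
    if (length(idx)) {
      tp <- draw_tissue_params(spec, grp, length(idx), seed = NULL)
      d[idx] <- tp$d_mean; f[idx] <- tp$f_in; Dex[idx] <- tp$D_ex
    }
  }

  diameter <- ifelse(excl_reason == "small_lesion",
                     stats::runif(n, 3, 7.9),
                     exp(stats::rnorm(n, log(22), 0.5)) + 8)
  roster <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = round(pmax(18, stats::rnorm(n, 45.12, 12))),
    lesion_diameter_mm = round(diameter, 1),
    pathology_available = excl_reason != "no_pathology",
    image_quality_ok = excl_reason != "poor_quality",
    group = group, histology = histology, is_ibc = is_ibc,
    er = er, pr = pr, her2 = her2, ki67 = ki67, grade = grade,
    subtype = subtype,
    d_mean_truth = d, f_in_truth = f, D_ex_truth = Dex,
    stringsAsFactors = FALSE)
  roster$enrolled <- roster$lesion_diameter_mm >= 8 &
    roster$pathology_available & roster$image_quality_ok
  roster <- roster[sample(n), , drop = FALSE]
  rownames(roster) <- NULL
  attr(roster, "n_subtype_inconsistent") <- n_inconsistent
  attr(roster, "seed") <- seed
  roster
}

#' Apply the enrollment exclusion rules
#'
#' Filters the roster by the three exclusion rules in order (lesion
#' diameter < 8 mm; no pathology; poor image quality); a record failing
#' several rules is counted once, under the first.
#'
#' @param roster from [generate_roster()]
#' @return list with `cohort` (enrolled records) and `report` (named counts
#'   per rule plus `n_collected` / `n_enrolled`)
#' @export
apply_exclusions <- function(roster) {
  if (nrow(roster) == 0)
    return(list(cohort = roster,
                report = c(small_lesion = 0L, no_pathology = 0L,
                           poor_quality = 0L, n_collected = 0L,
                           n_enrolled = 0L)))
  small <- roster$lesion_diameter_mm < 8
  nopath <- !small & !roster$pathology_available
  poorq <- !small & !nopath & !roster$image_quality_ok
  keep <- !(small | nopath | poorq)
  list(cohort = roster[keep, , drop = FALSE],
       report = c(small_lesion = sum(small), no_pathology = sum(nopath),
                  poor_quality = sum(poorq), n_collected = nrow(roster),
                  n_enrolled = sum(keep)))
}

#' Draw ground-truth tissue parameters for a group
#'
#' Normal draws with the group's (mean, SD), clipped just inside the
#' physical bounds `4 < d_mean < 30`, `0 < f_in < 1`, `0 < D_ex < 3.5`.
#' Within a group, `d_mean` and `f_in` are drawn from a Gaussian copula
#' with correlation `rho_fd`; the default correlations are calibrated once
#' so that the population mean of the voxel-level cellularity index
#' `f_in/d_mean` matches the group's printed cellularity row (independent
#' draws would contradict it, because the heavy-tailed benign diameter
#' distribution inflates `E[f/d]`). `D_ex` is drawn independently.
#'
#' @param spec a [cohort_spec()]
#' @param group `"benign"` or `"malignant"` (or any stratum named in
#'   `spec$params`)
#' @param n number of draws
#' @param seed optional seed (NULL continues the current RNG stream)
#' @return data.frame with columns `d_mean`, `f_in`, `D_ex`
#' @export
draw_tissue_params <- function(spec, group, n = 1, seed = NULL) {
  if (!group %in% names(spec$params))
    stop("unknown stratum: ", group, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pg <- spec$params[[group]]
  rho <- if (is.null(pg$rho_fd)) 0 else pg$rho_fd
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  data.frame(
    d_mean = clip(pg$d[1] + pg$d[2] * z1, 4.02, 29.98),
    f_in = clip(pg$f[1] + pg$f[2] * z2, 0.005, 0.995),
    D_ex = clip(stats::rnorm(n, pg$Dex[1], pg$Dex[2]), 0.01, 3.49))
}

#' Rician-corrupt a signal
#' @param S noiseless magnitude signal
#' @param sigma Gaussian noise level per channel (S0/SNR)
#' @return magnitude of `(S + e1, e2)` with `e ~ N(0, sigma)`
#' @export
rician_noise <- function(S, sigma) {
  if (sigma == 0 || !is.finite(sigma)) return(S)
  sqrt((S + stats::rnorm(length(S), 0, sigma))^2 +
         stats::rnorm(length(S), 0, sigma)^2)
}

# jittered copies of a truth row: multiplicative N(1, cv), clipped
.jitter_params <- function(truth, n_vox, cv) {
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  data.frame(
    d_mean = clip(truth$d_mean * stats::rnorm(n_vox, 1, cv), 4.02, 29.98),
    f_in = clip(truth$f_in * stats::rnorm(n_vox, 1, cv), 0.005, 0.995),
    D_ex = clip(truth$D_ex * stats::rnorm(n_vox, 1, cv), 0.01, 3.49))
}

# noiseless voxel signal matrix (n_vox x n_acq) for jittered params
.voxel_signals <- function(vox_params, kernel) {
  tab <- kernel$acq
  b_ms <- tab$b / 1000
  key <- paste0(tab$sequence, ":", tab$b)
  pos <- match(kernel$labels, key)
  t(vapply(seq_len(nrow(vox_params)), function(v) {
    Sin <- rep(1, nrow(tab))
    Sin[pos] <- exp(kernel_lnSin(kernel, vox_params$d_mean[v]))
    vox_params$f_in[v] * Sin + (1 - vox_params$f_in[v]) * exp(-b_ms * vox_params$D_ex[v])
  }, numeric(nrow(tab))))
}

#' Synthesize a noisy 4D lesion phantom
#'
#' Embeds a lesion mask in a small volume; voxels inside the mask carry the
#' forward two-compartment signal of the (optionally jittered) truth
#' parameters, voxels outside are noise-only. Rician noise at the given
#' SNR (sigma = S0/snr with S0 = 1) is applied to all voxels;
#' `snr = Inf` gives the noiseless forward signal exactly.
#'
#' @param truth list/row with `d_mean`, `f_in`, `D_ex`
#' @param prot a `dmri_protocol`
#' @param shape 3D volume dimensions
#' @param snr signal-to-noise ratio at b = 0 (Inf for noiseless)
#' @param seed integer seed
#' @param jitter_cv within-lesion parameter coefficient of variation
#' @param mask optional 3D 0/1 array; default: central box of ~1/3 extent
#' @param kernel optional precomputed kernel
#' @return list: `vol` (4D array), `mask`, `truth_maps` (named list of 3D
#'   arrays), `acq` (acquisition table), `snr`
#' @export
generate_lesion_image <- function(truth, prot, shape = c(8, 8, 3), snr = 50,
                                  seed = 1, jitter_cv = 0.05, mask = NULL,
                                  kernel = NULL) {
  stopifnot(snr > 0)
  set.seed(seed)
  if (is.null(kernel)) kernel <- .cached_kernel(prot)
  tab <- kernel$acq
  if (is.null(mask)) {
    mask <- array(0, shape)
    ctr <- pmax(1, floor(shape / 2))
    half <- pmax(0, floor(shape / 6))
    mask[(ctr[1] - half[1]):(ctr[1] + half[1]),
         (ctr[2] - half[2]):(ctr[2] + half[2]),
         (ctr[3] - half[3]):(ctr[3] + half[3])] <- 1
  }
  vox <- which(mask == 1)
  vp <- .jitter_params(truth, length(vox), jitter_cv)
  sig <- .voxel_signals(vp, kernel)
  vol <- array(0, c(dim(mask), nrow(tab)))
  plane <- prod(dim(mask))
  for (a in seq_len(nrow(tab))) {
    slab <- numeric(plane)
    slab[vox] <- sig[, a]
    vol[, , , a] <- slab
  }
  if (is.finite(snr)) {
    sigma <- 1 / snr
    vol <- array(rician_noise(as.vector(vol), sigma), dim(vol))
  }
  truth_maps <- lapply(c("d_mean", "f_in", "D_ex"), function(p) {
    m <- array(NA_real_, dim(mask)); m[vox] <- vp[[p]]; m
  })
  names(truth_maps) <- c("d_mean", "f_in", "D_ex")
  list(vol = vol, mask = mask, truth_maps = truth_maps, acq = tab, snr = snr)
}

#' Simulate, fit and summarize a full cohort
#'
#' For every enrolled lesion: jittered voxelwise forward signals at the
#' given SNR, voxelwise two-compartment and ADC fits, ROI (mean) summaries,
#' plus two simulated observer measurements per fitted parameter (lesion
#' value + independent noise with variance `obs_noise_ratio` times the
#' between-lesion variance). The returned table is the cohort analysis
#' input: labels, ground truth, fitted summaries, observer columns.
#'
#' @param spec a [cohort_spec()]
#' @param prot a `dmri_protocol`
#' @param seed integer seed
#' @param snr signal-to-noise ratio (Inf for noiseless)
#' @param n_vox voxels per lesion ROI
#' @param opts fitting options (reduced restarts by default for speed)
#' @param kernel optional precomputed kernel
#' @param progress print a progress message every 50 lesions
#' @return list: `cohort` (one row per enrolled lesion), `roster`,
#'   `exclusion_report`, `n_subtype_inconsistent`
#' @export
run_cohort_analysis <- function(spec = cohort_spec(), prot = default_protocol(),
                                seed = 1, snr = 50, n_vox = 5,
                                opts = impulsed_fit_opts(n_refine = 3),
                                kernel = NULL, progress = FALSE) {
  if (is.null(kernel)) kernel <- .cached_kernel(prot)
  roster <- generate_roster(spec, seed)
  exc <- apply_exclusions(roster)
  cohort <- exc$cohort
  tab <- kernel$acq
  seqs <- unique(tab$sequence)
  set.seed(seed + 1L)
  sigma <- if (is.finite(snr)) 1 / snr else 0

  fit_cols <- NULL
  for (li in seq_len(nrow(cohort))) {
    if (progress && li %% 50 == 0) message("  lesion ", li, "/", nrow(cohort))
    truth <- cohort[li, c("d_mean_truth", "f_in_truth", "D_ex_truth")]
    names(truth) <- c("d_mean", "f_in", "D_ex")
    vp <- .jitter_params(truth, n_vox, spec$jitter_cv)
    sig <- .voxel_signals(vp, kernel)
    if (sigma > 0) sig <- matrix(rician_noise(as.vector(sig), sigma), nrow(sig))
    vals <- matrix(NA_real_, n_vox, 4 + length(seqs))
    for (v in seq_len(n_vox)) {
      sdf <- data.frame(sequence = tab$sequence, b = tab$b, S = sig[v, ])
      fit <- fit_impulsed(sdf, prot, opts, kernel = kernel)
      vals[v, 1:4] <- c(fit$params$d_mean, fit$params$f_in, fit$params$D_ex,
                        fit$cellularity)
      for (si in seq_along(seqs)) {
        rows <- sdf[sdf$sequence == seqs[si], ]
        vals[v, 4 + si] <- fit_adc(rows$b, rows$S, seqs[si])$adc
      }
    }
    fit_cols <- rbind(fit_cols, colMeans(vals, na.rm = TRUE))
  }
  colnames(fit_cols) <- c("d_mean", "f_in", "D_ex", "cellularity",
                          .adc_col(seqs))
  cohort <- cbind(cohort, as.data.frame(fit_cols))

  # two simulated observers per parameter
  for (p in colnames(fit_cols)) {
    tau <- sqrt(spec$obs_noise_ratio * stats::var(cohort[[p]]))
    cohort[[paste0(p, "_obs1")]] <- cohort[[p]] +
      stats::rnorm(nrow(cohort), 0, tau)
    cohort[[paste0(p, "_obs2")]] <- cohort[[p]] +
      stats::rnorm(nrow(cohort), 0, tau)
  }
  list(cohort = cohort, roster = roster, exclusion_report = exc$report,
       n_subtype_inconsistent = attr(roster, "n_subtype_inconsistent"))
}
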