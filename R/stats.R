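# Cohort-level statistical battery: Levene + independent-samples t tests,
# ICC(2,1) reliability, empirical ROC with Youden cutoffs, logistic
# combinations, composition summaries and report tables.

.sig_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p <= 0.001, "***",
                       ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", ""))))
}

#' Levene's test for homogeneity of variance (center = mean)
#'
#' One-way ANOVA F test on the absolute deviations from the group means.
#'
#' @param x,y the two samples
#' @return list with `statistic`, `p_value`
#' @export
levene_test <- function(x, y) {
  z <- c(abs(x - mean(x)), abs(y - mean(y)))
  g <- factor(rep(1:2, c(length(x), length(y))))
  if (stats::var(z) == 0) return(list(statistic = 0, p_value = 1))
  ft <- stats::oneway.test(z ~ g, var.equal = TRUE)
  list(statistic = unname(ft$statistic), p_value = unname(ft$p.value))
}

#' Two-group comparison (Levene-gated t test)
#'
#' Levene's test (center = mean) selects between the pooled-variance and
#' Welch t test at the 0.05 level; the two-sided t test is then applied.
#' Zero variance in both groups with equal means returns `p = 1`, flagged.
#'
#' @param values_a,values_b the two samples (each n >= 2)
#' @param label parameter label carried into reports
#' @param levene_alpha threshold for the pooled/Welch switch
#' @return a `group_comparison` list: means, SDs, `t_stat`, `p_value`,
#'   `levene_p`, `n_a`, `n_b`, `var_equal`, `stars`, `degenerate`
#' @export
compare_groups <- function(values_a, values_b, label = NA_character_,
                           levene_alpha = 0.05) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    same <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    return(structure(list(
      parameter = label, mean_a = mean(values_a), sd_a = 0,
      mean_b = mean(values_b), sd_b = 0,
      t_stat = if (same) 0 else Inf, p_value = if (same) 1 else 0,
      levene_p = 1, n_a = length(values_a), n_b = length(values_b),
      var_equal = TRUE, stars = "", degenerate = TRUE),
      class = "group_comparison"))
  }
  lev <- levene_test(values_a, values_b)
  var_equal <- lev$p_value >= levene_alpha
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  structure(list(
    parameter = label,
    mean_a = mean(values_a), sd_a = stats::sd(values_a),
    mean_b = mean(values_b), sd_b = stats::sd(values_b),
    t_stat = unname(tt$statistic), p_value = unname(tt$p.value),
    levene_p = lev$p_value, n_a = length(values_a), n_b = length(values_b),
    var_equal = var_equal, stars = .sig_stars(tt$p.value), degenerate = FALSE),
    class = "group_comparison")
}

.as_positive <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.null(positive)) positive <- sort(unique(labels))[2]
  labels == positive
}

#' Empirical ROC analysis with Youden-optimal cutoff
#'
#' Trapezoidal AUC over the empirical ROC (ties in score produce diagonal
#' segments, i.e. tied pairs count 1/2, matching the Mann-Whitney
#' concordance exactly). If the raw AUC is below 0.5 the marker orientation
#' is inverted (`orientation = "lower_positive"`) and the reported AUC,
#' sensitivity and specificity refer to the inverted score; the cutoff is
#' reported in original marker units, at the midpoint between the adjacent
#' distinct scores of the Youden-optimal threshold.
#'
#' @param scores numeric marker values
#' @param labels class labels (logical, or 2-level factor/character)
#' @param positive value of `labels` treated as positive (default: TRUE for
#'   logical labels, else the second sorted unique value)
#' @param label marker name carried into reports
#' @return a `roc_result` list: `auc`, `sensitivity` (%), `specificity`
#'   (%), `cutoff`, `orientation`, `label`, `n_pos`, `n_neg`
#' @export
roc_analysis <- function(scores, labels, positive = NULL,
                         label = NA_character_) {
  y <- .as_positive(labels, positive)
  stopifnot(length(scores) == length(y))
  keep <- is.finite(scores) & !is.na(y)
  scores <- scores[keep]; y <- y[keep]
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present for ROC analysis", call. = FALSE)

  roc_curve <- function(s) {
    thr <- sort(unique(s), decreasing = TRUE)
    tp <- vapply(thr, function(t) sum(s >= t & y), 0)
    fp <- vapply(thr, function(t) sum(s >= t & !y), 0)
    sens <- c(0, tp / n_pos, 1)
    fpr <- c(0, fp / n_neg, 1)
    auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
    list(thr = thr, sens = sens, fpr = fpr, auc = auc)
  }
  rc <- roc_curve(scores)
  orientation <- "higher_positive"
  s_used <- scores
  if (rc$auc < 0.5) {
    orientation <- "lower_positive"
    s_used <- -scores
    rc <- roc_curve(s_used)
  }
  youden <- rc$sens[-c(1, length(rc$sens))] -
    rc$fpr[-c(1, length(rc$fpr))]
  bi <- which.max(youden)
  thr_val <- rc$thr[bi]  # smallest score classified positive
  below <- s_used[s_used < thr_val]
  cutoff_used <- if (length(below)) (thr_val + max(below)) / 2 else thr_val
  cutoff <- if (orientation == "lower_positive") -cutoff_used else cutoff_used
  structure(list(
    label = label, auc = rc$auc,
    sensitivity = 100 * rc$sens[bi + 1], specificity = 100 * (1 - rc$fpr[bi + 1]),
    cutoff = cutoff, orientation = orientation, n_pos = n_pos, n_neg = n_neg),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> %s AUC=%.3f sens=%.2f%% spec=%.2f%% cutoff=%.4g (%s)\n",
    ifelse(is.na(x$label), "", x$label), x$auc, x$sensitivity, x$specificity,
    x$cutoff, x$orientation))
  invisible(x)
}

# ridge-penalized logistic IRLS fallback for separated data
.ridge_logistic <- function(X, y, lambda = 1e-3, max_iter = 100) {
  beta <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(X, X * w) + diag(lambda, ncol(X))
    beta_new <- solve(A, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  drop(beta)
}

#' Logistic-regression combination of markers
#'
#' Maximum-likelihood logistic fit on standardized features; the combined
#' score is the fitted linear predictor, whose (in-sample) ROC is reported.
#' Perfect separation triggers a small-ridge penalized fallback, flagged.
#'
#' @param feature_matrix numeric matrix/data.frame, one column per marker
#' @param labels class labels (see [roc_analysis()])
#' @param positive positive class
#' @param label combination name carried into reports
#' @return list: `coefficients`, `score`, `roc` (a `roc_result`),
#'   `separation` flag
#' @export
logistic_combination <- function(feature_matrix, labels, positive = NULL,
                                 label = NA_character_) {
  X <- as.matrix(feature_matrix)
  stopifnot(ncol(X) >= 1, !anyNA(X))
  y <- .as_positive(labels, positive)
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  Xd <- cbind(`(Intercept)` = 1, Xs)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(Xd, as.numeric(y), family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients
  if (separation || anyNA(beta) || max(abs(beta)) > 1e3) {
    separation <- TRUE
    beta <- .ridge_logistic(Xd, as.numeric(y))
  }
  score <- drop(Xd %*% beta)
  roc <- roc_analysis(score, y, positive = TRUE, label = label)
  list(coefficients = beta, score = score, roc = roc, separation = separation)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation between two raters, with the F-based 95% confidence interval
#' (McGraw & Wong A,1).
#'
#' @param ratings_1,ratings_2 paired ratings (n >= 3)
#' @param conf confidence level
#' @param label parameter label
#' @return an `icc_result` list: `icc`, `ci_low`, `ci_high`, `label`,
#'   `flagged` (TRUE when ratings are constant and the ICC is undefined)
#' @export
icc_reliability <- function(ratings_1, ratings_2, conf = 0.95,
                            label = NA_character_) {
  stopifnot(length(ratings_1) == length(ratings_2), length(ratings_1) >= 3)
  M <- cbind(ratings_1, ratings_2)
  n <- nrow(M); k <- 2
  grand <- mean(M)
  if (stats::var(as.vector(M)) == 0)
    return(structure(list(icc = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, label = label, flagged = TRUE),
                     class = "icc_result"))
  SSR <- k * sum((rowMeans(M) - grand)^2)
  SSC <- n * sum((colMeans(M) - grand)^2)
  SST <- sum((M - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1); MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  # McGraw & Wong CI for ICC(A,1)
  alpha <- 1 - conf
  if (MSE <= 0) {
    lo <- hi <- icc
  } else {
    Fj <- MSC / MSE
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    vn <- (k - 1) * (n - 1) *
      (k * icc * Fj + n * (1 + (k - 1) * icc) - k * icc)^2
    vd <- (n - 1) * k^2 * icc^2 * Fj^2 +
      (n * (1 + (k - 1) * icc) - k * icc)^2
    v <- vn / vd
    FU <- stats::qf(1 - alpha / 2, n - 1, v)
    FL <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (MSR - FU * MSE) /
      (FU * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (FL * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FL * MSR)
  }
  structure(list(icc = unname(icc), ci_low = unname(min(lo, icc)),
                 ci_high = unname(max(hi, icc)), label = label,
                 flagged = FALSE),
            class = "icc_result")
}

#' Cohort composition summary
#'
#' Counts and percentages per label, rounded to two decimals. The
#' denominator is the IBC count for the immunohistochemistry fields
#' (`er`, `pr`, `her2`, `ki67`, `grade`, `subtype`) and the enrolled count
#' otherwise.
#'
#' @param cohort enrolled cohort data.frame (from [apply_exclusions()] or
#'   [run_cohort_analysis()])
#' @return data.frame with columns `field`, `level`, `count`, `denom`, `pct`
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0) stop("empty cohort table", call. = FALSE)
  ibc <- cohort[cohort$is_ibc %in% TRUE, , drop = FALSE]
  rows <- list()
  add <- function(field, values, denom) {
    values <- values[!is.na(values)]
    for (lvl in sort(unique(values)))
      rows[[length(rows) + 1]] <<- data.frame(
        field = field, level = lvl, count = sum(values == lvl),
        denom = denom, pct = round(100 * sum(values == lvl) / denom, 2))
  }
  add("group", cohort$group, nrow(cohort))
  add("histology", cohort$histology, nrow(cohort))
  for (f in c("er", "pr", "her2", "ki67", "grade", "subtype"))
    if (f %in% names(cohort)) add(f, ibc[[f]], nrow(ibc))
  do.call(rbind, rows)
}

# contrasts of the report battery: list(name, subset fn, split fn -> logical
# (TRUE = group a))
.report_contrasts <- function(cohort) {
  ibc <- function(d) d[d$is_ibc %in% TRUE, , drop = FALSE]
  list(
    benign_vs_malignant = list(
      data = cohort, a = function(d) d$group == "malignant",
      a_name = "malignant", b_name = "benign"),
    ER = list(data = ibc(cohort), a = function(d) d$er == "pos",
              a_name = "ER+", b_name = "ER-"),
    PR = list(data = ibc(cohort), a = function(d) d$pr == "pos",
              a_name = "PR+", b_name = "PR-"),
    HER2 = list(data = ibc(cohort), a = function(d) d$her2 == "pos",
                a_name = "HER2+", b_name = "HER2-"),
    Ki67 = list(data = ibc(cohort), a = function(d) d$ki67 == "high",
                a_name = "Ki67-high", b_name = "Ki67-low"),
    grade = list(data = ibc(cohort), a = function(d) d$grade %in% c("I", "II"),
                 a_name = "grade I-II", b_name = "grade III"))
}

.REPORT_PARAMS <- function(cohort)
  intersect(c("d_mean", "f_in", "D_ex", "cellularity",
              "ADC_DWI", "ADC_PGSE", "ADC_17Hz", "ADC_33Hz"), names(cohort))

# named marker sets of the report's logistic combinations
.combinations <- list(
  Comb1 = list(contrast = "benign_vs_malignant",
               features = c("d_mean", "f_in", "D_ex", "cellularity")),
  Comb2 = list(contrast = "benign_vs_malignant",
               features = c("d_mean", "f_in", "D_ex", "cellularity",
                            "ADC_PGSE", "ADC_17Hz", "ADC_33Hz")),
  Comb3 = list(contrast = "ER", features = c("D_ex", "ADC_17Hz")),
  Comb4 = list(contrast = "PR", features = c("f_in", "cellularity", "ADC_17Hz")),
  Comb5 = list(contrast = "HER2",
               features = c("f_in", "ADC_DWI", "ADC_17Hz", "ADC_33Hz")))

#' Build the group-comparison and ROC report tables
#'
#' For each contrast (benign/malignant on the enrolled cohort; ER, PR,
#' HER-2, Ki-67 and grade I-II vs III on the IBC subset) and each fitted
#' parameter: Levene-gated t test rows (with a Benjamini-Hochberg column,
#' informational only), and ROC rows for each parameter significant at
#' 0.05 plus the five named logistic combinations. A contrast with an
#' empty arm is skipped with a warning.
#'
#' @param cohort_with_fits cohort table containing the fitted summary
#'   columns (from [run_cohort_analysis()])
#' @return list: `table4` (comparisons), `table5` (ROC rows)
#' @export
build_reports <- function(cohort_with_fits) {
  params <- .REPORT_PARAMS(cohort_with_fits)
  if (!length(params)) stop("no fitted parameter columns found", call. = FALSE)
  contrasts <- .report_contrasts(cohort_with_fits)
  t4 <- list(); t5 <- list()
  for (cn in names(contrasts)) {
    ct <- contrasts[[cn]]
    d <- ct$data
    d <- d[stats::complete.cases(d[, params, drop = FALSE]), , drop = FALSE]
    if (!nrow(d)) { warning("contrast ", cn, " has no data; skipped"); next }
    in_a <- ct$a(d)
    if (!any(in_a) || all(in_a)) {
      warning("contrast ", cn, " has an empty arm; skipped"); next
    }
    for (p in params) {
      gc <- compare_groups(d[[p]][in_a], d[[p]][!in_a], label = p)
      t4[[length(t4) + 1]] <- data.frame(
        contrast = cn, group_a = ct$a_name, group_b = ct$b_name,
        parameter = p, mean_a = gc$mean_a, sd_a = gc$sd_a,
        mean_b = gc$mean_b, sd_b = gc$sd_b, t_stat = gc$t_stat,
        p_value = gc$p_value, levene_p = gc$levene_p, n_a = gc$n_a,
        n_b = gc$n_b, stars = gc$stars)
      if (!is.na(gc$p_value) && gc$p_value < 0.05) {
        rr <- roc_analysis(d[[p]], in_a, positive = TRUE, label = p)
        t5[[length(t5) + 1]] <- data.frame(
          contrast = cn, marker = p, auc = rr$auc,
          sensitivity = rr$sensitivity, specificity = rr$specificity,
          cutoff = rr$cutoff, orientation = rr$orientation)
      }
    }
    for (cb in names(.combinations)) {
      if (.combinations[[cb]]$contrast != cn) next
      feats <- intersect(.combinations[[cb]]$features, params)
      lc <- logistic_combination(d[, feats, drop = FALSE], in_a,
                                 positive = TRUE, label = cb)
      t5[[length(t5) + 1]] <- data.frame(
        contrast = cn, marker = cb, auc = lc$roc$auc,
        sensitivity = lc$roc$sensitivity, specificity = lc$roc$specificity,
        cutoff = NA_real_, orientation = lc$roc$orientation)
    }
  }
  table4 <- do.call(rbind, t4)
  table4$p_bh <- stats::p.adjust(table4$p_value, method = "BH")
  list(table4 = table4, table5 = do.call(rbind, t5))
}

#' Intraclass correlations for all observer-rated parameters
#'
#' @param cohort cohort table with `<param>_obs1` / `<param>_obs2` columns
#' @return data.frame: parameter, icc, ci_low, ci_high
#' @export
icc_report <- function(cohort) {
  obs1 <- grep("_obs1$", names(cohort), value = TRUE)
  do.call(rbind, lapply(obs1, function(c1) {
    p <- sub("_obs1$", "", c1)
    r <- icc_reliability(cohort[[c1]], cohort[[paste0(p, "_obs2")]], label = p)
    data.frame(parameter = p, icc = r$icc, ci_low = r$ci_low,
               ci_high = r$ci_high)
  }))
}
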