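#' Two-group comparison (independent-samples t-test)
#'
#' Thin wrapper around [stats::t.test()] used for all cohort, coculture and
#' cell-subtype style comparisons. Welch (unequal-variance) by default, with
#' a pooled-variance option.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal use the pooled-variance test.
#' @return list with `t_statistic` and `p_value` (two-sided).
#' @export
compare_groups <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs n >= 2", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Squared Pearson correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return R-squared.
#' @export
correlation_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need paired vectors of length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance", call. = FALSE)
  stats::cor(x, y)^2
}

#' ROC curve with trapezoid AUC
#'
#' Classification rule: `score >= threshold` is called positive. One curve
#' point per distinct score value, plus the all-negative endpoint.
#'
#' @param scores numeric test scores.
#' @param labels logical (or coercible) disease labels, `TRUE` = diseased.
#' @return list with `points` (`data.frame`: `threshold`, `sensitivity`,
#'   `specificity`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("NA in scores or labels", call. = FALSE)
  if (!any(labels) || all(labels))
    stop("both classes must be present", call. = FALSE)
  thr <- sort(unique(scores))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  sens <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & !labels) / n_neg, numeric(1))
  pts <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  # trapezoid over (FPR, TPR), endpoints (0,0) and (1,1)
  fpr <- c(0, rev(1 - spec), 1)
  tpr <- c(0, rev(sens), 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Two-axis cut-off point
#'
#' A point in the (average intensity, % positive cells) plane defining the
#' quadrant classifier: only the lower-left quadrant (both statistics
#' strictly below the cut) is negative.
#'
#' @param x_intensity intensity cut (grey-value units).
#' @param y_pct percentage-positive cut in \[0, 100\].
#' @param name optional label.
#' @return an object of class `cutoff_point`.
#' @export
cutoff_point <- function(x_intensity, y_pct, name = NA_character_) {
  if (!is.na(y_pct) && (y_pct < 0 || (is.finite(y_pct) && y_pct > 100)))
    stop("y_pct must lie in [0, 100] (or Inf to disable the axis)",
         call. = FALSE)
  structure(list(x_intensity = x_intensity, y_pct = y_pct, name = name),
            class = "cutoff_point")
}

#' The study's three evaluated cut-off points
#'
#' A (63.50, 40.00), B (90.28, 53.34) and C (117.20, 63.38) on the
#' (average intensity, % positive) plane.
#'
#' @return named list of [cutoff_point()]s.
#' @export
stau2_cutoffs <- function() {
  list(A = cutoff_point(63.50, 40.00, "A"),
       B = cutoff_point(90.28, 53.34, "B"),
       C = cutoff_point(117.20, 63.38, "C"))
}

#' Quadrant classification of samples
#'
#' Positive iff `avg_intensity >= x_intensity` OR `pct_positive >= y_pct`
#' (inclusive on the positive side); negative only when both statistics are
#' strictly below the cut.
#'
#' @param avg_intensity,pct_positive numeric vectors (recycled pairwise).
#' @param cut a [cutoff_point()].
#' @return logical vector, `TRUE` = screen-positive.
#' @export
quadrant_classify <- function(avg_intensity, pct_positive, cut) {
  stopifnot(inherits(cut, "cutoff_point"))
  if (anyNA(avg_intensity) || anyNA(pct_positive))
    stop("undefined sample statistics", call. = FALSE)
  avg_intensity >= cut$x_intensity | pct_positive >= cut$y_pct
}

#' 2x2 confusion table
#'
#' @param tp,fn,tn,fp non-negative integer counts (diseased split into
#'   tp + fn, healthy into tn + fp).
#' @return an object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fn, tn, fp) {
  cells <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(cells < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(as.list(cells), class = "confusion_table")
}

round_half_up <- function(x) floor(x + 0.5)

#' Reconstruct a 2x2 table from printed rates and group sizes
#'
#' `tp = round(sensitivity * n_diseased)` and
#' `tn = round(specificity * n_healthy)` (round half up), complements fill
#' `fn` / `fp`. This is the canonical route from published
#' sensitivity/specificity to the underlying counts.
#'
#' @param sensitivity,specificity rates in \[0, 1\].
#' @param n_diseased,n_healthy group sizes.
#' @return a [confusion_table()].
#' @export
confusion_from_rates <- function(sensitivity, specificity,
                                 n_diseased, n_healthy) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            n_diseased >= 0, n_healthy >= 0)
  tp <- round_half_up(sensitivity * n_diseased)
  tn <- round_half_up(specificity * n_healthy)
  confusion_table(tp = tp, fn = n_diseased - tp, tn = tn, fp = n_healthy - tn)
}

#' Full screening-metric set for a 2x2 table
#'
#' Sensitivity, specificity, PPV, NPV, accuracy, the sample odds ratio
#' `(tp * tn) / (fp * fn)` with Woolf 95% confidence interval
#' (`log OR +/- 1.96 * sqrt(1/tp + 1/fp + 1/fn + 1/tn)`), and a chi-squared
#' p-value (no continuity correction). When any cell is zero the
#' Haldane-Anscombe +0.5 correction is applied to the odds ratio and its
#' interval and flagged in the output.
#'
#' @param tab a [confusion_table()].
#' @return list: `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`,
#'   `odds_ratio`, `or_ci_95` (low, high), `p_value`,
#'   `haldane_corrected`.
#' @export
screening_metrics <- function(tab) {
  stopifnot(inherits(tab, "confusion_table"))
  tp <- tab$tp; fn <- tab$fn; tn <- tab$tn; fp <- tab$fp
  if ((tp + fn) == 0 || (tn + fp) == 0 || (tp + fp) == 0 || (tn + fn) == 0)
    stop("zero row or column total", call. = FALSE)
  total <- tp + fn + tn + fp
  haldane <- any(c(tp, fn, tn, fp) == 0)
  h <- if (haldane) 0.5 else 0
  or <- ((tp + h) * (tn + h)) / ((fp + h) * (fn + h))
  se_log <- sqrt(1 / (tp + h) + 1 / (fp + h) + 1 / (fn + h) + 1 / (tn + h))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se_log)
  p <- suppressWarnings(stats::chisq.test(
    matrix(c(tp, fp, fn, tn), nrow = 2), correct = FALSE)$p.value)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       ppv = tp / (tp + fp), npv = tn / (tn + fn),
       accuracy = (tp + tn) / total,
       odds_ratio = or, or_ci_95 = c(low = ci[1], high = ci[2]),
       p_value = p, haldane_corrected = haldane)
}

#' Evaluate quadrant cut-offs on a cohort
#'
#' Applies [quadrant_classify()] per sample for each cut-off point,
#' tabulates the 2x2 against the group labels (`cancer` = diseased) and
#' returns the full metric set per cut. When the cohort has a
#' `replicate_set` column a per-set breakdown is attached as the
#' `by_replicate` attribute.
#'
#' @param cohort `data.frame` with columns `group` (`"cancer"`/`"normal"`),
#'   `avg_intensity`, `pct_positive` and optionally `replicate_set`.
#' @param cuts list of [cutoff_point()]s.
#' @return `data.frame`, one row per cut, with the counts and metrics.
#' @export
evaluate_cutoffs <- function(cohort, cuts) {
  if (!all(c("group", "avg_intensity", "pct_positive") %in% names(cohort)))
    stop("cohort needs group, avg_intensity, pct_positive", call. = FALSE)
  if (!all(cohort$group %in% c("cancer", "normal")))
    stop("group labels must be 'cancer' or 'normal'", call. = FALSE)
  if (length(unique(cohort$group)) < 2)
    stop("cohort must contain both groups", call. = FALSE)
  one <- function(dat, cut) {
    pos <- quadrant_classify(dat$avg_intensity, dat$pct_positive, cut)
    dis <- dat$group == "cancer"
    tab <- confusion_table(tp = sum(pos & dis), fn = sum(!pos & dis),
                           tn = sum(!pos & !dis), fp = sum(pos & !dis))
    m <- screening_metrics(tab)
    data.frame(cut = cut$name, x_intensity = cut$x_intensity,
               y_pct = cut$y_pct,
               tp = tab$tp, fn = tab$fn, tn = tab$tn, fp = tab$fp,
               sensitivity = m$sensitivity, specificity = m$specificity,
               ppv = m$ppv, npv = m$npv, accuracy = m$accuracy,
               odds_ratio = m$odds_ratio,
               or_ci_low = m$or_ci_95[["low"]],
               or_ci_high = m$or_ci_95[["high"]],
               p_value = m$p_value)
  }
  out <- do.call(rbind, lapply(cuts, one, dat = cohort))
  rownames(out) <- NULL
  if ("replicate_set" %in% names(cohort)) {
    sets <- sort(unique(cohort$replicate_set))
    by_rep <- do.call(rbind, lapply(sets, function(s) {
      sub <- cohort[cohort$replicate_set == s, , drop = FALSE]
      if (length(unique(sub$group)) < 2) return(NULL)
      res <- do.call(rbind, lapply(cuts, one, dat = sub))
      res$replicate_set <- s
      res
    }))
    attr(out, "by_replicate") <- by_rep
  }
  out
}
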