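# ROC analysis and threshold classification metrics. Acidosis is the
# positive class; higher scores (e.g. higher FSI) indicate acidosis, and a
# case is called positive when its score exceeds the threshold.

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) return(as.integer(labels) - 1L)
  if (all(labels %in% c(0, 1))) return(as.integer(labels))
  stop("labels must be logical, 0/1, or a two-level factor")
}

# Mid-rank (ties count 1/2) concordance AUC.
auc_rank <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

delong_ci <- function(scores, labels, conf = 0.95) {
  y <- as_binary_labels(labels)
  xs <- scores[y == 1L]; ys <- scores[y == 0L]
  n1 <- length(xs); n0 <- length(ys)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(xs, function(a) mean(psi(a, ys)), numeric(1))
  v01 <- vapply(ys, function(b) mean(psi(xs, b)), numeric(1))
  auc <- mean(v10)
  v <- if (n1 > 1L) stats::var(v10) / n1 else 0
  v <- v + if (n0 > 1L) stats::var(v01) / n0 else 0
  z <- stats::qnorm(1 - (1 - conf) / 2)
  pmin(1, pmax(0, auc + c(-1, 1) * z * sqrt(v)))
}

#' Empirical ROC analysis
#'
#' Computes the empirical ROC curve, the concordance-probability AUC (ties
#' count one half), a DeLong (default) or bootstrap 95% CI, and a chosen
#' operating threshold with its confusion matrix (Youden-optimal by
#' default, or user-supplied).
#'
#' @param scores Numeric predictor (higher = more likely positive).
#' @param labels Binary outcome (logical, 0/1, or two-level factor with the
#'   positive class second).
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param threshold `"youden"` or a numeric threshold.
#' @param n_boot Bootstrap replicates when `ci_method = "bootstrap"`.
#' @return List of class `roc_result`: `auc`, `ci95`, `curve` (data.frame
#'   `threshold`, `se`, `sp`), `threshold`, `confusion`.
#' @export
roc_analysis <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                         threshold = "youden", n_boot = 2000) {
  ci_method <- match.arg(ci_method)
  y <- as_binary_labels(labels)
  ok <- stats::complete.cases(scores, y)
  scores <- scores[ok]; y <- y[ok]
  if (length(unique(y)) < 2L) stop("both classes must be present")
  auc <- auc_rank(scores, y)
  ci <- if (ci_method == "delong") {
    delong_ci(scores, y)
  } else {
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(y), replace = TRUE)
      if (length(unique(y[idx])) < 2L) return(NA_real_)
      auc_rank(scores[idx], y[idx])
    }, numeric(1))
    stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  thr <- sort(unique(scores))
  cand <- c(-Inf, (thr[-1] + thr[-length(thr)]) / 2, Inf)
  curve <- do.call(rbind, lapply(cand, function(t) {
    cm <- evaluate_threshold(scores, y, t)
    data.frame(threshold = t, se = cm$se, sp = cm$sp)
  }))
  chosen <- if (identical(threshold, "youden")) {
    curve$threshold[which.max(curve$se + curve$sp - 1)]
  } else {
    as.numeric(threshold)
  }
  structure(list(auc = auc, ci95 = ci, curve = curve,
                 threshold = chosen,
                 confusion = evaluate_threshold(scores, y, chosen)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.2f (95%% CI %.2f-%.2f), threshold %.3g\n",
              x$auc, x$ci95[1], x$ci95[2], x$threshold))
  print(x$confusion)
  invisible(x)
}

#' Classify scores at a threshold
#'
#' Positive (acidosis) call when `score > threshold`.
#'
#' @inheritParams roc_analysis
#' @param threshold Numeric decision threshold.
#' @return A `confusion_matrix` (see [metrics_from_counts]).
#' @export
evaluate_threshold <- function(scores, labels, threshold) {
  y <- as_binary_labels(labels)
  pred <- scores > threshold
  metrics_from_counts(tp = sum(pred & y == 1L),
                      fp = sum(pred & y == 0L),
                      tn = sum(!pred & y == 0L),
                      fn = sum(!pred & y == 1L))
}

round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Confusion matrix with derived classification metrics
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`.
#' Zero-denominator PPV/NPV are `NA`. The print method reports rates to
#' 2 decimal places (half-up), the conventional presentation.
#'
#' @param tp,fp,tn,fn Non-negative counts; `tp+fn` and `tn+fp` must be
#'   positive.
#' @return List of class `confusion_matrix` with the counts and `se`, `sp`,
#'   `ppv`, `npv`.
#' @examples
#' m <- metrics_from_counts(tp = 14, fp = 6, tn = 95, fn = 15)
#' round(m$se, 2)  # 0.48
#' @export
metrics_from_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (tp + fn == 0 || tn + fp == 0) stop("both classes must be represented")
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    se = tp / (tp + fn),
    sp = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp %d fp %d tn %d fn %d | Se %.2f Sp %.2f PPV %.2f NPV %.2f\n",
              x$tp, x$fp, x$tn, x$fn,
              round_half_up(x$se), round_half_up(x$sp),
              round_half_up(x$ppv), round_half_up(x$npv)))
  invisible(x)
}
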