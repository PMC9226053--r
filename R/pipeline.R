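# End-to-end orchestration: cohort generation -> descriptive summary ->
# correlation screen -> PCA-varimax reduction -> univariable logistic ->
# bootstrap stepwise selection -> ROC and threshold metrics -> CHAID and
# CART trees. Deterministic under a single seed.

summarise_group <- function(x, type) {
  if (type == "normal") {
    sprintf("%.2f ± %.2f", mean(x, na.rm = TRUE), stats::sd(x, na.rm = TRUE))
  } else {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
    sprintf("%.2f [%.2f to %.2f]", q[2], q[1], q[3])
  }
}

#' Two-group descriptive summary of a feature table
#'
#' Mean +/- SD for the (near-)normal variables and median [IQR] for the
#' skewed ones, per group. Which presentation a variable gets is fixed by
#' the marginal-spec list rather than re-tested each run, so the report
#' layout is reproducible.
#'
#' @param table Cohort feature table.
#' @return Data.frame with `variable`, `type`, `non_acidosis`, `acidosis`.
#' @export
group_summary <- function(table) {
  specs <- cohort_marginal_specs()
  vars <- c(fhrv_feature_names(), "ph")
  type <- c(ifelse(specs$dist[match(fhrv_feature_names(), specs$variable)] ==
                     "normal", "normal", "skewed"), "skewed")
  g <- table$acidosis
  data.frame(
    variable = vars,
    type = type,
    non_acidosis = vapply(seq_along(vars), function(i) {
      summarise_group(table[[vars[i]]][!g], type[i])
    }, character(1)),
    acidosis = vapply(seq_along(vars), function(i) {
      summarise_group(table[[vars[i]]][g], type[i])
    }, character(1))
  )
}

#' Run the full acidosis-prediction analysis
#'
#' Generates (or accepts) a cohort feature table and runs the complete
#' multivariable pipeline: descriptive two-group summary, Pearson
#' correlation screen, PCA-varimax variable reduction, univariable
#' logistic regressions on the retained variables (OR per 0.1 for
#' Delta_HFnu), bootstrap stepwise backward selection, ROC analysis of the
#' resulting score with DeLong CI and threshold metrics, and CHAID and
#' CART trees on the retained variables with resubstitution evaluation.
#'
#' The classification score is the single selected variable when exactly
#' one survives selection (the FSI decision threshold default 67.8 applies
#' when that variable is FSI), the final logistic model's linear predictor
#' when several survive, and FSI as a fallback when none does.
#'
#' @param seed Integer seed; every stochastic stage derives from it.
#' @param table Optional pre-built feature table; when `NULL` one is
#'   generated from `cohort`.
#' @param cohort A [cohort_params] (its `seed` is overridden by `seed`).
#' @param n_boot Bootstrap resamples for selection (500).
#' @param alpha_remove,retain Stepwise removal and retention thresholds.
#' @param fsi_threshold Decision threshold used when FSI is the selected
#'   score (67.8).
#' @param out_dir Optional directory; when given, tables, ROC points,
#'   retention frequencies, trees (JSON) and a metrics JSON are written.
#' @return List of class `fhrv_report`.
#' @export
run_full_analysis <- function(seed = 1, table = NULL,
                              cohort = cohort_params(),
                              n_boot = 500, alpha_remove = 0.05,
                              retain = 0.70, fsi_threshold = 67.8,
                              out_dir = NULL) {
  if (is.null(table)) {
    cohort$seed <- seed
    table <- generate_cohort_table(cohort)
  }
  summary_tab <- group_summary(table)
  screen <- correlation_screen(table)
  fact <- pca_varimax_select(table)
  retained <- fact$retained

  uni <- do.call(rbind, lapply(retained, function(v) {
    u <- univariable_logistic(table, v, per = if (v == "Delta_HFnu") 0.1 else 1)
    data.frame(variable = v, or = u$or, ci_low = u$ci95[1],
               ci_high = u$ci95[2], p = u$p, per = u$per)
  }))

  sel <- bootstrap_backward_selection(table, retained, n_boot = n_boot,
                                      alpha_remove = alpha_remove,
                                      retain = retain, seed = seed + 1L)

  if (length(sel$selected) == 1L) {
    score_name <- sel$selected
    scores <- table[[score_name]]
  } else if (length(sel$selected) > 1L) {
    score_name <- "linear_predictor"
    fit <- stats::glm(stats::reformulate(sel$selected, "acidosis"),
                      data = table, family = stats::binomial())
    scores <- as.numeric(stats::predict(fit, type = "link"))
  } else {
    score_name <- "FSI"
    scores <- table$FSI
  }
  thr <- if (score_name == "FSI") fsi_threshold else "youden"
  roc <- roc_analysis(scores, table$acidosis, threshold = thr)

  chaid <- chaid_fit(table, retained)
  cart <- cart_fit(table, retained)
  chaid_cm <- tree_evaluate(chaid, table)
  cart_cm <- tree_evaluate(cart, table)

  report <- structure(list(
    seed = seed, table = table, group_summary = summary_tab,
    correlation = screen, factor_solution = fact, retained = retained,
    univariable = uni, selection = sel,
    score_name = score_name, roc = roc,
    chaid = chaid, chaid_confusion = chaid_cm,
    cart = cart, cart_confusion = cart_cm
  ), class = "fhrv_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.fhrv_report <- function(x, ...) {
  cat(sprintf("<fhrv_report> seed %d, %d recordings (%d acidosis)\n",
              x$seed, nrow(x$table), sum(x$table$acidosis)))
  cat(sprintf("retained after PCA-varimax (%d): %s\n", length(x$retained),
              paste(x$retained, collapse = ", ")))
  cat(sprintf("selected by bootstrap stepwise: %s\n",
              if (length(x$selection$selected))
                paste(x$selection$selected, collapse = ", ") else "(none)"))
  cat(sprintf("score %s: AUC %.2f (95%% CI %.2f-%.2f), threshold %.3g -> Se %.2f Sp %.2f\n",
              x$score_name, x$roc$auc, x$roc$ci95[1], x$roc$ci95[2],
              x$roc$threshold, x$roc$confusion$se, x$roc$confusion$sp))
  cat(sprintf("CHAID: Se %.2f Sp %.2f | CART: Se %.2f Sp %.2f (resubstitution)\n",
              x$chaid_confusion$se, x$chaid_confusion$sp,
              x$cart_confusion$se, x$cart_confusion$sp))
  invisible(x)
}

cm_as_list <- function(cm) {
  list(tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
       se = round_half_up(cm$se), sp = round_half_up(cm$sp),
       ppv = round_half_up(cm$ppv), npv = round_half_up(cm$npv))
}

#' Write a report bundle to a directory
#'
#' Writes the feature table, group summary, correlation matrix, rotated
#' loadings, univariable results, retention frequencies, ROC curve points
#' (CSV), both trees (JSON) and a metrics JSON including the seed.
#'
#' @param report An `fhrv_report`.
#' @param out_dir Output directory (created if needed).
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                       row.names = FALSE)
  w(report$table, "feature_table.csv")
  w(report$group_summary, "group_summary.csv")
  utils::write.csv(report$correlation$correlation,
                   file.path(out_dir, "correlations.csv"))
  utils::write.csv(report$factor_solution$loadings,
                   file.path(out_dir, "loadings.csv"))
  w(report$univariable, "univariable.csv")
  w(data.frame(variable = names(report$selection$retention_frequency),
               frequency = as.numeric(report$selection$retention_frequency)),
    "retention.csv")
  w(report$roc$curve, "roc_points.csv")
  write_tree_json(report$chaid, file.path(out_dir, "tree_chaid.json"))
  write_tree_json(report$cart, file.path(out_dir, "tree_cart.json"))
  metrics <- list(
    seed = report$seed,
    retained = report$retained,
    selected = report$selection$selected,
    score = report$score_name,
    auc = report$roc$auc,
    auc_ci95 = report$roc$ci95,
    threshold = report$roc$threshold,
    threshold_metrics = cm_as_list(report$roc$confusion),
    chaid = cm_as_list(report$chaid_confusion),
    cart = cm_as_list(report$cart_confusion),
    explained_variance = report$factor_solution$explained_variance
  )
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
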