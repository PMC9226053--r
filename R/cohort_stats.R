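# Variable-reduction and logistic-modelling pipeline: Pearson correlation
# screen, PCA + varimax factor selection, univariable logistic regression,
# and bootstrap stepwise backward selection with a 70% retention rule.

#' Pearson correlation screen of the feature table
#'
#' Computes the full Pearson correlation matrix of the feature columns
#' (pairwise complete observations) and flags the pairs whose absolute
#' correlation exceeds the threshold. Zero-variance columns yield `NA`
#' correlations for their pairs.
#'
#' @param table Cohort feature table (see [generate_cohort_table]).
#' @param variables Columns to screen; default the canonical 23.
#' @param threshold Flagging threshold on `|r|` (default 0.70).
#' @return List with `correlation` (matrix) and `flagged` (data.frame of
#'   pairs with `var1`, `var2`, `r`).
#' @export
correlation_screen <- function(table, variables = fhrv_feature_names(),
                               threshold = 0.70) {
  variables <- intersect(variables, names(table))
  if (nrow(table) < 3L) stop("correlation screen needs at least 3 rows")
  x <- as.matrix(table[, variables, drop = FALSE])
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  r[sds == 0, ] <- NA
  r[, sds == 0] <- NA
  diag(r)[sds > 0] <- 1
  idx <- which(upper.tri(r) & abs(r) > threshold, arr.ind = TRUE)
  flagged <- data.frame(
    var1 = variables[idx[, 1L]],
    var2 = variables[idx[, 2L]],
    r = r[idx]
  )
  flagged <- flagged[order(-abs(flagged$r)), ]
  rownames(flagged) <- NULL
  list(correlation = r, flagged = flagged, threshold = threshold)
}

# Clinically motivated preference ranking used to pick one representative
# per correlated set: prefer the absolute index over its delta, the
# clinically established index within a family (LF over HF, STV over LTV,
# SDNN over RMSSD, FHRmax over FHRmean), and the morphology pair
# Duration/AUCdec over Slope.
default_preference <- function() {
  c("FSI", "Delta_FSI", "Delta_HFnu", "LF", "STV", "SDNN", "FHRmax",
    "FHRmin", "Amplitude", "Duration", "AUCdec", "Slope", "HFnu",
    "FHRmean", "HF", "RMSSD", "LTV", "Delta_LF", "Delta_HF",
    "Delta_SDNN", "Delta_RMSSD", "Delta_STV", "Delta_LTV")
}

#' PCA-varimax variable reduction
#'
#' Standardises the candidate variables, retains the principal components
#' with eigenvalue above 1, varimax-rotates their loadings, and assigns a
#' variable to a factor when its absolute rotated loading exceeds
#' `loading_threshold` on exactly one factor. Within each factor the
#' assigned variables are walked in clinical preference order and one is
#' kept unless it correlates above `cor_threshold` (absolute Pearson) with
#' a variable already kept for that factor — so near-orthogonal variables
#' sharing a factor (e.g. a deceleration-area and a duration measure) can
#' both survive.
#'
#' @param table Cohort feature table.
#' @param candidates Variables entering the PCA (default all 23).
#' @param loading_threshold Assignment threshold on rotated loadings (0.6).
#' @param eigen_threshold Factor retention threshold on eigenvalues (1).
#' @param cor_threshold Redundancy threshold within a factor (0.70).
#' @param preference Preference ranking; default [default_preference()]
#'   restricted to `candidates`.
#' @return List of class `factor_solution`: `loadings` (rotated),
#'   `eigenvalues`, `retained_factors`, `explained_variance`, `assignments`
#'   (named factor index, NA when unassigned), `retained` (character
#'   vector of selected variables).
#' @export
pca_varimax_select <- function(table, candidates = fhrv_feature_names(),
                               loading_threshold = 0.6,
                               eigen_threshold = 1,
                               cor_threshold = 0.70,
                               preference = default_preference()) {
  candidates <- intersect(candidates, names(table))
  x <- table[stats::complete.cases(table[, candidates]), candidates]
  if (nrow(x) < length(candidates) + 1L) {
    stop("PCA needs more complete rows than candidate variables")
  }
  if (any(apply(x, 2, stats::sd) == 0)) stop("zero-variance candidate variable")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  k <- sum(eig > eigen_threshold)
  if (k < 2L) stop("fewer than two factors with eigenvalue above threshold")
  raw_load <- pc$rotation[, seq_len(k)] %*% diag(pc$sdev[seq_len(k)])
  rot <- stats::varimax(raw_load)
  loadings <- unclass(rot$loadings)
  dimnames(loadings) <- list(candidates, paste0("Factor", seq_len(k)))

  hits <- abs(loadings) > loading_threshold
  assignments <- apply(hits, 1, function(h) {
    if (sum(h) == 1L) which(h) else NA_integer_
  })

  pref <- c(intersect(preference, candidates),
            setdiff(candidates, preference))
  r <- suppressWarnings(stats::cor(x))
  retained <- character(0)
  for (f in seq_len(k)) {
    members <- names(assignments)[!is.na(assignments) & assignments == f]
    members <- pref[pref %in% members]
    kept <- character(0)
    for (v in members) {
      if (!length(kept) || all(abs(r[v, kept]) < cor_threshold)) {
        kept <- c(kept, v)
      }
    }
    retained <- c(retained, kept)
  }
  structure(list(loadings = loadings, eigenvalues = eig,
                 retained_factors = k,
                 explained_variance = sum(eig[seq_len(k)]) / length(eig),
                 assignments = assignments,
                 retained = retained),
            class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf(
    "<factor_solution> %d factors (eigenvalue > 1), %.0f%% of variance\nretained: %s\n",
    x$retained_factors, 100 * x$explained_variance,
    paste(x$retained, collapse = ", ")))
  invisible(x)
}

# Bare-metal logistic fit on a design matrix (intercept added), returning
# Wald statistics; used heavily inside the bootstrap loop.
fast_logit <- function(X, y) {
  D <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(stats::glm.fit(D, y, family = stats::binomial()))
  p <- fit$rank
  if (!fit$converged || p < ncol(D)) return(list(converged = FALSE))
  cov <- tryCatch(chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]),
                  error = function(e) NULL)
  if (is.null(cov)) return(list(converged = FALSE))
  piv <- fit$qr$pivot[seq_len(p)]
  se <- sqrt(diag(cov))
  coef <- fit$coefficients[piv]
  z <- coef / se
  pv <- 2 * stats::pnorm(-abs(z))
  names(pv) <- names(coef) <- colnames(D)[piv]
  list(converged = TRUE, coef = coef, se = se, p = pv)
}

#' Univariable logistic regression for acidosis
#'
#' Maximum-likelihood logistic fit of the acidosis label on one variable,
#' reporting the odds ratio per `per` units (use `per = 0.1` for
#' Delta_HFnu, whose natural unit is 0.1), its Wald 95% CI and p-value.
#'
#' @param table Feature table with logical column `acidosis`.
#' @param variable Predictor column name.
#' @param per Unit for the reported OR (default 1).
#' @return List with `variable`, `or`, `ci95`, `p`, `per`, `separation`
#'   (TRUE when the fit is unstable due to complete separation).
#' @export
univariable_logistic <- function(table, variable, per = 1) {
  y <- as.integer(table$acidosis)
  x <- table[[variable]]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  if (stats::sd(x[y == 0]) == 0 && stats::sd(x[y == 1]) == 0) {
    stop("predictor has no variation")
  }
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  beta <- sm["x", "Estimate"] * per
  se <- sm["x", "Std. Error"] * per
  separation <- !fit$converged || se > 100 * abs(beta) + 100
  list(variable = variable,
       or = exp(beta),
       ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
       p = sm["x", "Pr(>|z|)"],
       per = per,
       separation = separation)
}

#' Variance inflation factors
#'
#' `1 / (1 - R^2)` of each candidate regressed on the others; the standard
#' collinearity pre-check before multivariable selection.
#'
#' @param table Feature table.
#' @param candidates Variable names.
#' @return Named numeric vector.
#' @export
variance_inflation <- function(table, candidates) {
  x <- as.matrix(table[, candidates, drop = FALSE])
  vapply(seq_along(candidates), function(j) {
    r2 <- summary(stats::lm(x[, j] ~ x[, -j, drop = FALSE]))$r.squared
    1 / max(1 - r2, .Machine$double.eps)
  }, numeric(1)) |> stats::setNames(candidates)
}

# One stepwise-backward pass: drop the predictor with the largest Wald p
# while it exceeds alpha. Returns retained names, or NULL on failure.
stepwise_backward <- function(X, y, alpha) {
  vars <- colnames(X)
  repeat {
    if (!length(vars)) return(character(0))
    fit <- fast_logit(X[, vars, drop = FALSE], y)
    if (!fit$converged) return(NULL)
    pv <- fit$p[vars]  # by name; excludes the intercept
    worst <- which.max(pv)
    if (pv[worst] > alpha) {
      vars <- setdiff(vars, names(pv)[worst])
    } else {
      return(vars)
    }
  }
}

#' Bootstrap stepwise backward selection
#'
#' Draws `n_boot` bootstrap resamples of the rows; in each, fits a logistic
#' model of acidosis on all candidates and iteratively removes the
#' predictor with the largest Wald p-value while it exceeds `alpha_remove`.
#' A candidate is selected when retained in at least `retain` of the
#' successful resamples. The final model is a logistic fit of the selected
#' set on the full data. This guards a small-sample stepwise procedure
#' against over-optimism.
#'
#' @param table Feature table with logical `acidosis` column.
#' @param candidates Candidate predictor names.
#' @param n_boot Number of bootstrap resamples (500).
#' @param alpha_remove Removal criterion on Wald p-values (0.05).
#' @param retain Retention-frequency threshold (0.70).
#' @param seed Optional RNG seed (selection is deterministic given it).
#' @return List of class `selection_result`: `retention_frequency` (named,
#'   sorted), `selected`, `final_model` (data.frame of OR and 95% CI per
#'   selected variable, or `NULL`), `n_boot`, `n_failed`, `vif`.
#' @export
bootstrap_backward_selection <- function(table, candidates, n_boot = 500,
                                         alpha_remove = 0.05, retain = 0.70,
                                         seed = NULL) {
  stopifnot(all(candidates %in% names(table)))
  if (!is.null(seed)) set.seed(seed)
  keep <- stats::complete.cases(table[, c(candidates, "acidosis")])
  X <- as.matrix(table[keep, candidates, drop = FALSE])
  y <- as.integer(table$acidosis[keep])
  n <- nrow(X)
  vif <- variance_inflation(table[keep, ], candidates)

  counts <- stats::setNames(numeric(length(candidates)), candidates)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[idx])) < 2L) { n_failed <- n_failed + 1L; next }
    res <- stepwise_backward(X[idx, , drop = FALSE], y[idx], alpha_remove)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    counts[res] <- counts[res] + 1L
  }
  n_ok <- n_boot - n_failed
  if (n_failed > 0.10 * n_boot) {
    warning(sprintf("%d of %d bootstrap fits failed", n_failed, n_boot))
  }
  freq <- counts / n_ok
  selected <- names(freq)[freq >= retain]

  final <- NULL
  if (length(selected)) {
    fit <- suppressWarnings(stats::glm(
      y ~ ., data = data.frame(y = y, X[, selected, drop = FALSE]),
      family = stats::binomial()))
    sm <- summary(fit)$coefficients[-1L, , drop = FALSE]
    final <- data.frame(
      variable = selected,
      or = exp(sm[, "Estimate"]),
      ci_low = exp(sm[, "Estimate"] - stats::qnorm(0.975) * sm[, "Std. Error"]),
      ci_high = exp(sm[, "Estimate"] + stats::qnorm(0.975) * sm[, "Std. Error"]),
      p = sm[, "Pr(>|z|)"],
      row.names = NULL
    )
  }
  structure(list(retention_frequency = sort(freq, decreasing = TRUE),
                 selected = selected, final_model = final,
                 n_boot = n_boot, n_failed = n_failed, vif = vif),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d/%d bootstrap fits ok; selected: %s\n",
              x$n_boot - x$n_failed, x$n_boot,
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(none)"))
  print(round(x$retention_frequency, 3))
  invisible(x)
}
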