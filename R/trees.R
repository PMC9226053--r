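# Binary classification trees on continuous predictors, sharing one node
# type: a CHAID-style tree splitting on the variable/threshold maximising
# the 2x2 Pearson chi-square (stopping when no split is significant at the
# alpha level), and a CART-style tree maximising Gini impurity decrease
# with cost-complexity pruning.

# 2x2 Pearson chi-square without continuity correction:
# n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)).
chi2_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  out <- ifelse(den > 0, n * (a * d - b * c)^2 / den, 0)
  out
}

#' Best chi-square binary split of a continuous predictor
#'
#' Exhaustively scans the midpoints between consecutive distinct sorted
#' values of `x`; at each, forms the 2x2 table of `x <= threshold` against
#' the binary label and computes the Pearson chi-square (no continuity
#' correction, df = 1). Returns the threshold with the largest statistic
#' (ties broken towards the lower threshold).
#'
#' @param x Continuous predictor.
#' @param y Binary labels (logical / 0-1).
#' @param min_child Minimum number of cases on each side of the split.
#' @return List with `threshold`, `chi2`, `p`, `n_left`, `n_right`, or
#'   `NULL` when no admissible split exists (constant `x`, one class, or
#'   child-size constraint unsatisfiable).
#' @export
best_binary_split <- function(x, y, min_child = 1L) {
  x <- unname(as.numeric(x))
  y <- as_binary_labels(y)
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  n <- length(xs)
  if (n < 2L || length(unique(y)) < 2L) return(NULL)
  # split after position i admissible only between distinct x values
  cuts <- which(diff(xs) > 0)
  cuts <- cuts[cuts >= min_child & (n - cuts) >= min_child]
  if (!length(cuts)) return(NULL)
  cum_pos <- cumsum(ys)
  a <- cum_pos[cuts]                 # left positives
  b <- cuts - a                      # left negatives
  c2 <- sum(ys) - a                  # right positives
  d <- (n - cuts) - c2               # right negatives
  stat <- chi2_2x2(a, b, c2, d)
  best <- which.max(stat)            # first max = lowest threshold
  i <- cuts[best]
  list(threshold = (xs[i] + xs[i + 1L]) / 2,
       chi2 = stat[best],
       p = stats::pchisq(stat[best], df = 1, lower.tail = FALSE),
       n_left = i, n_right = n - i)
}

# Best Gini split: maximises the impurity decrease
# G(parent) - (nL G_L + nR G_R)/n with G = 2 p (1 - p).
best_gini_split <- function(x, y, min_child = 1L) {
  x <- unname(as.numeric(x))
  y <- as_binary_labels(y)
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  n <- length(xs)
  if (n < 2L || length(unique(y)) < 2L) return(NULL)
  cuts <- which(diff(xs) > 0)
  cuts <- cuts[cuts >= min_child & (n - cuts) >= min_child]
  if (!length(cuts)) return(NULL)
  cum_pos <- cumsum(ys)
  nl <- cuts; nr <- n - cuts
  pl <- cum_pos[cuts] / nl
  pr <- (sum(ys) - cum_pos[cuts]) / nr
  p0 <- mean(ys)
  decrease <- 2 * p0 * (1 - p0) -
    (nl * 2 * pl * (1 - pl) + nr * 2 * pr * (1 - pr)) / n
  best <- which.max(decrease)
  i <- cuts[best]
  list(threshold = (xs[i] + xs[i + 1L]) / 2,
       gini_decrease = decrease[best],
       n_left = i, n_right = n - i)
}

new_node <- function(y, depth) {
  y <- as_binary_labels(y)
  n_pos <- sum(y); n_neg <- length(y) - n_pos
  structure(list(
    leaf = TRUE,
    n_acidosis = n_pos, n_no_acidosis = n_neg,
    predicted = n_pos > n_neg,       # ties predict the majority class "no"
    depth = depth,
    variable = NULL, threshold = NULL, split_stat = NULL, p = NULL,
    left = NULL, right = NULL
  ), class = "fhrv_tree_node")
}

#' Fit a CHAID-style chi-square decision tree
#'
#' At each node, every candidate gets its best binary chi-square split
#' ([best_binary_split]); the node splits on the candidate with the
#' largest chi-square whose p-value is below `alpha` and whose children
#' satisfy `min_node_size`, and recursion continues in each child until no
#' significant split remains.
#'
#' @param table Feature table with logical `acidosis` column.
#' @param candidates Predictor names.
#' @param alpha Significance level of the stopping rule (0.05).
#' @param min_node_size Minimum cases in a child node (5).
#' @param max_depth Maximum tree depth (`Inf`).
#' @param bonferroni Multiply split p-values by the number of candidate
#'   thresholds (classic CHAID multiplicity adjustment); off by default.
#' @return An `fhrv_tree` (root `fhrv_tree_node` with fit metadata).
#' @export
chaid_fit <- function(table, candidates, alpha = 0.05, min_node_size = 5L,
                      max_depth = Inf, bonferroni = FALSE) {
  stopifnot(all(candidates %in% names(table)))
  keep <- stats::complete.cases(table[, c(candidates, "acidosis")])
  X <- as.matrix(table[keep, candidates, drop = FALSE])
  y <- as_binary_labels(table$acidosis[keep])

  grow <- function(idx, depth) {
    node <- new_node(y[idx], depth)
    if (depth >= max_depth || length(unique(y[idx])) < 2L) return(node)
    best <- NULL; best_var <- NULL
    for (v in candidates) {
      s <- best_binary_split(X[idx, v], y[idx], min_child = min_node_size)
      if (is.null(s)) next
      if (bonferroni) {
        m <- length(unique(X[idx, v])) - 1L
        s$p <- min(1, s$p * m)
      }
      if (is.null(best) || s$chi2 > best$chi2) { best <- s; best_var <- v }
    }
    if (is.null(best) || best$p >= alpha) return(node)
    node$leaf <- FALSE
    node$variable <- best_var
    node$threshold <- best$threshold
    node$split_stat <- best$chi2
    node$p <- best$p
    go_left <- X[idx, best_var] <= best$threshold
    node$left <- grow(idx[go_left], depth + 1L)
    node$right <- grow(idx[!go_left], depth + 1L)
    node
  }
  root <- grow(seq_along(y), 0L)
  structure(list(root = root, algorithm = "chaid", candidates = candidates,
                 alpha = alpha, min_node_size = min_node_size),
            class = "fhrv_tree")
}

# Leaves and misclassification risk of a subtree (counts).
tree_risk <- function(node) {
  if (node$leaf) {
    r <- if (node$predicted) node$n_no_acidosis else node$n_acidosis
    return(list(risk = r, leaves = 1L))
  }
  l <- tree_risk(node$left); r <- tree_risk(node$right)
  list(risk = l$risk + r$risk, leaves = l$leaves + r$leaves)
}

# Weakest-link cost-complexity pruning: repeatedly collapse the internal
# node with the smallest per-split risk improvement g = (R(t) - R(T_t)) /
# (leaves(T_t) - 1) while g < cp * R(root).
prune_tree <- function(node, cp_risk) {
  collapse_weakest <- function(n) {
    if (n$leaf) return(list(node = n, g = Inf))
    own_risk <- if (n$predicted) n$n_no_acidosis else n$n_acidosis
    sub <- tree_risk(n)
    g_here <- (own_risk - sub$risk) / (sub$leaves - 1L)
    l <- collapse_weakest(n$left)
    r <- collapse_weakest(n$right)
    n$left <- l$node; n$right <- r$node
    g_min <- min(g_here, l$g, r$g)
    list(node = n, g = g_min, g_here = g_here)
  }
  repeat {
    sweep <- collapse_weakest(node)
    node <- sweep$node
    if (sweep$g >= cp_risk) break
    node <- collapse_at(node, sweep$g)
  }
  node
}

# Collapse every internal node whose own g equals the weakest-link value.
collapse_at <- function(n, g_target) {
  if (n$leaf) return(n)
  own_risk <- if (n$predicted) n$n_no_acidosis else n$n_acidosis
  sub <- tree_risk(n)
  g_here <- (own_risk - sub$risk) / (sub$leaves - 1L)
  if (g_here <= g_target + 1e-12) {
    n$leaf <- TRUE
    n$left <- n$right <- NULL
    n$variable <- n$threshold <- n$split_stat <- n$p <- NULL
    return(n)
  }
  n$left <- collapse_at(n$left, g_target)
  n$right <- collapse_at(n$right, g_target)
  n
}

#' Fit a CART-style Gini decision tree
#'
#' Grows a binary tree by maximising the Gini impurity decrease at each
#' node (nodes with fewer than `min_node_size` cases, or children below
#' `min_node_size %/% 3`, are not split), then applies weakest-link
#' cost-complexity pruning: subtrees whose misclassification-risk
#' improvement per split is below `complexity` times the root risk are
#' collapsed, mirroring the convention of the classic recursive
#' partitioning implementation.
#'
#' @inheritParams chaid_fit
#' @param min_node_size Minimum cases in a node eligible for splitting (20).
#' @param complexity Cost-complexity parameter (0.01).
#' @return An `fhrv_tree`.
#' @export
cart_fit <- function(table, candidates, min_node_size = 20L,
                     max_depth = Inf, complexity = 0.01) {
  stopifnot(all(candidates %in% names(table)))
  keep <- stats::complete.cases(table[, c(candidates, "acidosis")])
  X <- as.matrix(table[keep, candidates, drop = FALSE])
  y <- as_binary_labels(table$acidosis[keep])
  min_child <- max(1L, min_node_size %/% 3L)

  grow <- function(idx, depth) {
    node <- new_node(y[idx], depth)
    if (depth >= max_depth || length(idx) < min_node_size ||
        length(unique(y[idx])) < 2L) {
      return(node)
    }
    best <- NULL; best_var <- NULL
    for (v in candidates) {
      s <- best_gini_split(X[idx, v], y[idx], min_child = min_child)
      if (is.null(s)) next
      if (is.null(best) || s$gini_decrease > best$gini_decrease) {
        best <- s; best_var <- v
      }
    }
    if (is.null(best) || best$gini_decrease <= 0) return(node)
    node$leaf <- FALSE
    node$variable <- best_var
    node$threshold <- best$threshold
    node$split_stat <- best$gini_decrease
    go_left <- X[idx, best_var] <= best$threshold
    node$left <- grow(idx[go_left], depth + 1L)
    node$right <- grow(idx[!go_left], depth + 1L)
    node
  }
  root <- grow(seq_along(y), 0L)
  root_risk <- min(sum(y), sum(1 - y))
  root <- prune_tree(root, cp_risk = complexity * root_risk)
  structure(list(root = root, algorithm = "cart", candidates = candidates,
                 min_node_size = min_node_size, complexity = complexity),
            class = "fhrv_tree")
}

route_row <- function(node, row) {
  while (!node$leaf) {
    v <- row[[node$variable]]
    if (is.na(v)) stop("missing predictor value; trees require complete cases")
    node <- if (v <= node$threshold) node$left else node$right
  }
  node$predicted
}

#' Predict acidosis with a fitted tree
#'
#' @param object An `fhrv_tree`.
#' @param newdata Data.frame with the tree's candidate columns.
#' @param ... Unused.
#' @return Logical vector of acidosis predictions.
#' @export
predict.fhrv_tree <- function(object, newdata, ...) {
  vapply(seq_len(nrow(newdata)), function(i) {
    route_row(object$root, newdata[i, , drop = FALSE])
  }, logical(1))
}

#' Evaluate a fitted tree on a labelled table
#'
#' Routes every row to its leaf and compares the leaf majority class with
#' the label. When the table is the fitting sample this is the
#' resubstitution (training-set) performance, the convention used for
#' small-cohort tree reporting.
#'
#' @param tree An `fhrv_tree`.
#' @param table Feature table with logical `acidosis` column.
#' @return A `confusion_matrix`.
#' @export
tree_evaluate <- function(tree, table) {
  pred <- predict(tree, table)
  y <- as_binary_labels(table$acidosis)
  metrics_from_counts(tp = sum(pred & y == 1L), fp = sum(pred & y == 0L),
                      tn = sum(!pred & y == 0L), fn = sum(!pred & y == 1L))
}

tree_depth <- function(node) {
  if (node$leaf) return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

#' @export
print.fhrv_tree <- function(x, ...) {
  cat(sprintf("<fhrv_tree> %s, depth %d\n", x$algorithm, tree_depth(x$root)))
  show <- function(n, indent) {
    pad <- strrep("  ", indent)
    lab <- sprintf("[%d | %d] -> %s", n$n_acidosis, n$n_no_acidosis,
                   if (n$predicted) "acidosis" else "no acidosis")
    if (n$leaf) {
      cat(pad, "* ", lab, "\n", sep = "")
    } else {
      cat(pad, sprintf("%s <= %.4g (stat %.3g) %s", n$variable, n$threshold,
                       n$split_stat, lab), "\n", sep = "")
      show(n$left, indent + 1L)
      show(n$right, indent + 1L)
    }
  }
  show(x$root, 0L)
  invisible(x)
}

node_as_list <- function(n) {
  out <- list(n_acidosis = n$n_acidosis, n_no_acidosis = n$n_no_acidosis,
              predicted = if (n$predicted) "acidosis" else "no_acidosis")
  if (!n$leaf) {
    out$variable <- n$variable
    out$threshold <- n$threshold
    out$split_stat <- n$split_stat
    if (!is.null(n$p)) out$p <- n$p
    out$left <- node_as_list(n$left)
    out$right <- node_as_list(n$right)
  }
  out
}

#' Export a fitted tree
#'
#' `write_tree_json` writes the nested node structure (counts, thresholds,
#' split statistics) as JSON; `tree_to_dot` renders Graphviz DOT source.
#'
#' @param tree An `fhrv_tree`.
#' @param path Output path.
#' @export
write_tree_json <- function(tree, path) {
  jsonlite::write_json(
    list(algorithm = tree$algorithm, candidates = tree$candidates,
         root = node_as_list(tree$root)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tree_json
#' @return `tree_to_dot` returns the DOT source as a character scalar.
#' @export
tree_to_dot <- function(tree) {
  lines <- c("digraph tree {", "  node [shape=box];")
  counter <- 0L
  emit <- function(n) {
    counter <<- counter + 1L
    id <- counter
    lab <- if (n$leaf) {
      sprintf("%s\\n%d | %d", if (n$predicted) "acidosis" else "no acidosis",
              n$n_acidosis, n$n_no_acidosis)
    } else {
      sprintf("%s <= %.4g\\n%d | %d", n$variable, n$threshold,
              n$n_acidosis, n$n_no_acidosis)
    }
    lines <<- c(lines, sprintf("  n%d [label=\"%s\"];", id, lab))
    if (!n$leaf) {
      lid <- emit(n$left)
      rid <- emit(n$right)
      lines <<- c(lines,
                  sprintf("  n%d -> n%d [label=\"yes\"];", id, lid),
                  sprintf("  n%d -> n%d [label=\"no\"];", id, rid))
    }
    id
  }
  emit(tree$root)
  paste(c(lines, "}"), collapse = "\n")
}
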