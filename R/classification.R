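ATTRIBUTES <- c("z", "phi_sr", "phi_std", "phi_max", "p_s")

as_label_factor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.logical(x)) x <- ifelse(x, "positive", "negative")
  x <- tolower(as.character(x))
  x[x %in% c("yes", "pos", "1", "true", "hypertensive")] <- "positive"
  x[x %in% c("no", "neg", "0", "false", "healthy")] <- "negative"
  if (!all(x %in% c("positive", "negative"))) {
    abort("Labels must be codeable as positive/negative (Yes/No accepted).")
  }
  # negative first so that majority ties in a leaf resolve to the healthy class
  factor(x, levels = c("negative", "positive"))
}

#' Fit a CART classification tree
#'
#' Greedy binary splitting on Gini impurity, candidate thresholds at the
#' midpoints between consecutive sorted distinct attribute values. Growth
#' stops only at pure nodes or when no admissible split remains
#' (`min_leaf = 1` by default, i.e. no minimum node size), producing the
#' maximal tree that cost-complexity pruning then works on. Leaf majority
#' ties resolve to the negative (healthy) class. rpart provides the
#' recursive partitioning engine.
#'
#' @param table Data frame with attribute columns (any subset of
#'   `z`, `phi_sr`, `phi_std`, `phi_max`, `p_s`) and a label column.
#' @param min_leaf Minimum observations in a leaf (default 1).
#' @param label Name of the label column (default `"hypertension"`);
#'   values codeable as positive/negative (Yes/No accepted).
#' @param attributes Attribute columns to use; default every recognised
#'   attribute present in `table`.
#' @return A `cart_model`.
#' @export
fit_cart <- function(table, min_leaf = 1L, label = "hypertension",
                     attributes = intersect(ATTRIBUTES, names(table))) {
  if (!label %in% names(table)) {
    abort(sprintf("Label column '%s' is missing.", label))
  }
  if (length(attributes) == 0L) abort("No attribute columns found.")
  missing_attr <- setdiff(attributes, names(table))
  if (length(missing_attr) > 0L) {
    abort(sprintf("Attribute column(s) missing: %s", paste(missing_attr, collapse = ", ")))
  }
  df <- as.data.frame(table)[, c(attributes, label)]
  if (anyNA(df)) abort("The feature table must not contain missing values.")
  df$.label <- as_label_factor(df[[label]])
  df[[label]] <- NULL
  if (length(unique(df$.label)) < 2L) {
    # single-class table: the tree is a single leaf predicting that class
    return(structure(
      list(fit = NULL, data = df, attributes = attributes, label = label,
           majority = as.character(df$.label[1])),
      class = "cart_model"
    ))
  }
  # embed the data in the call so rpart's cross-validation helpers can
  # re-evaluate it outside this frame
  fit <- do.call(rpart::rpart, list(
    formula = .label ~ ., data = df, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(
      minsplit = max(2L, 2L * min_leaf), minbucket = min_leaf,
      cp = 0, xval = 0, maxcompete = 0, maxsurrogate = 0
    )
  ))
  structure(
    list(fit = fit, data = df, attributes = attributes, label = label),
    class = "cart_model"
  )
}

n_leaves <- function(fit) {
  if (is.null(fit)) 1L else sum(fit$frame$var == "<leaf>")
}

model_predictions <- function(model, newdata = model$data) {
  if (is.null(model$fit)) {
    rep(model$majority, nrow(newdata))
  } else {
    as.character(predict(model$fit, newdata, type = "class"))
  }
}

#' Root split of a fitted tree
#'
#' @param model A `cart_model`.
#' @return One-row tibble (`attribute`, `threshold`) or zero rows for a
#'   single-leaf tree.
#' @export
root_split <- function(model) {
  if (is.null(model$fit)) {
    return(tibble(attribute = character(), threshold = double()))
  }
  fr <- model$fit$frame
  if (nrow(fr) == 0L || fr$var[1] == "<leaf>") {
    return(tibble(attribute = character(), threshold = double()))
  }
  sp <- model$fit$splits
  tibble(attribute = as.character(fr$var[1]), threshold = unname(sp[1, "index"]))
}

#' Stratified cross-validation folds
#'
#' Shuffles each class with the given seed and deals its members round-robin
#' over the folds, so fold class ratios stay within one member of the global
#' ratio (e.g. 40 negatives + 12 positives at k = 3 gives folds of 18/17/17
#' with 4 positives each).
#'
#' @param labels Class vector.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer fold assignment (1..k) aligned with `labels`.
#' @export
stratified_folds <- function(labels, k, seed) {
  if (k < 2) abort("`k` must be at least 2.")
  if (k > length(labels)) abort("More folds than subjects.")
  labels <- as.character(labels)
  assignment <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    pos <- 0L
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      # continue the deal across classes so every fold fills evenly
      assignment[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
      pos <- pos + length(idx)
    }
  })
  assignment
}

# cross-validated misclassification cost per cptable subtree, using
# out-of-fold predictions from rpart's xpred machinery with our stratified
# fold assignment; returns per-subtree mean fold error, its SE, and the
# pooled out-of-fold predicted classes
cv_costs <- function(model, folds_assignment) {
  fit <- model$fit
  cptab <- fit$cptable
  xp <- rpart::xpred.rpart(fit, xval = folds_assignment)
  truth <- as.integer(model$data$.label)
  k <- max(folds_assignment)
  n_sub <- nrow(cptab)
  fold_err <- matrix(NA_real_, k, n_sub)
  for (f in seq_len(k)) {
    in_f <- folds_assignment == f
    fold_err[f, ] <- colMeans(xp[in_f, , drop = FALSE] != truth[in_f])
  }
  mean_err <- colMeans(fold_err)
  se_err <- apply(fold_err, 2, sd) / sqrt(k)
  list(cptable = cptab, mean_err = mean_err, se_err = se_err, xpred = xp)
}

#' Cost-complexity pruning with the one-standard-error rule
#'
#' Computes the cost-complexity (alpha-path) subtree sequence of the fitted
#' tree, estimates the misclassification cost of every subtree by stratified
#' k-fold cross-validation, and returns the smallest subtree whose CV cost
#' does not exceed the minimum CV cost plus one standard error of that
#' minimum (SE taken over the per-fold costs).
#'
#' @param model A `cart_model` from [fit_cart()].
#' @param folds Number of folds (default 3).
#' @param seed Integer seed for the stratified fold assignment.
#' @return A `cart_model` with the pruned tree; the selection table is kept
#'   in `$pruning` and the pooled out-of-fold predictions at the chosen
#'   complexity in `$oof_prediction`.
#' @export
prune_1se <- function(model, folds = 3L, seed = 1L) {
  stopifnot(inherits(model, "cart_model"))
  n <- nrow(model$data)
  if (n < folds) abort("Fewer subjects than folds.")
  if (n_leaves(model$fit) == 1L) {
    model$pruning <- tibble(
      cp = if (is.null(model$fit)) 0 else model$fit$cptable[1, "CP"],
      n_splits = 0L, cv_cost = NA_real_, cv_se = NA_real_, chosen = TRUE
    )
    model$oof_prediction <- model_predictions(model)
    return(model)
  }
  fa <- stratified_folds(model$data$.label, folds, seed)
  cv <- cv_costs(model, fa)
  i_min <- which.min(cv$mean_err)
  cutoff <- cv$mean_err[i_min] + cv$se_err[i_min]
  # smallest admissible subtree = fewest splits = smallest cptable row index
  chosen <- which(cv$mean_err <= cutoff + 1e-12)[1]
  pruned <- rpart::prune(model$fit, cp = cv$cptable[chosen, "CP"])
  model$fit <- pruned
  model$pruning <- tibble(
    cp = cv$cptable[, "CP"], n_splits = as.integer(cv$cptable[, "nsplit"]),
    cv_cost = cv$mean_err, cv_se = cv$se_err,
    chosen = seq_len(nrow(cv$cptable)) == chosen
  )
  model$oof_prediction <- levels(model$data$.label)[cv$xpred[, chosen]]
  model
}

#' @export
print.cart_model <- function(x, ...) {
  cat(sprintf(
    "<cart_model> %d leaves, attributes: %s%s\n",
    n_leaves(x$fit), paste(x$attributes, collapse = ", "),
    if (!is.null(x$pruning)) " (pruned)" else ""
  ))
  if (is.null(x$fit)) {
    cat(sprintf("single-class leaf: %s\n", x$majority))
  } else {
    print(x$fit)
  }
  invisible(x)
}

#' Tidy a fitted CART model
#'
#' @param x A `cart_model`.
#' @param ... Unused.
#' @return Tibble of nodes: `node`, `var`, `n`, `is_leaf`, `prediction`,
#'   plus split `threshold` where applicable.
#' @export
tidy.cart_model <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(node = 1L, var = "<leaf>", n = nrow(x$data), is_leaf = TRUE,
                  prediction = x$majority, threshold = NA_real_))
  }
  fr <- x$fit$frame
  lev <- attr(x$fit, "ylevels")
  out <- tibble(
    node = as.integer(rownames(fr)),
    var = as.character(fr$var),
    n = fr$n,
    is_leaf = fr$var == "<leaf>",
    prediction = lev[fr$yval],
    threshold = NA_real_
  )
  sp <- x$fit$splits
  if (!is.null(sp) && nrow(sp) > 0L) {
    internal <- which(!out$is_leaf)
    out$threshold[internal] <- sp[seq_along(internal), "index"]
  }
  out
}

#' Summarise a fitted CART model
#'
#' @param x A `cart_model`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `n_leaves`, `depth`, `training_accuracy`,
#'   and (after [prune_1se()]) `cv_cost` of the chosen subtree.
#' @export
glance.cart_model <- function(x, ...) {
  pred <- model_predictions(x)
  depth <- if (is.null(x$fit)) 0 else {
    max(floor(log2(as.integer(rownames(x$fit$frame))))) # rpart node numbering
  }
  tibble(
    n = nrow(x$data),
    n_leaves = n_leaves(x$fit),
    depth = depth,
    training_accuracy = mean(pred == x$data$.label),
    cv_cost = if (!is.null(x$pruning)) x$pruning$cv_cost[x$pruning$chosen] else NA_real_
  )
}

#' Confusion counts
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || any(v != round(v))) abort("Counts must be non-negative integers.")
  structure(as.list(v), class = "confusion_counts")
}

counts_from_predictions <- function(truth, pred) {
  confusion_counts(
    tp = sum(truth == "positive" & pred == "positive"),
    tn = sum(truth == "negative" & pred == "negative"),
    fp = sum(truth == "negative" & pred == "positive"),
    fn = sum(truth == "positive" & pred == "negative")
  )
}

#' Confusion-panel metrics
#'
#' Sensitivity `TPR = TP/(TP+FN)`, `FPR = FP/(FP+TN)`, accuracy
#' `ACC = (TP+TN)/n`, specificity `SPC = TN/(FP+TN)`, `PPV = TP/(TP+FP)`,
#' `NPV = TN/(TN+FN)`, `FDR = FP/(FP+TP)`, and `fn_rate_percent =
#' 100*FN/(TP+FN)` (the miss rate among positives). Ratios with a zero
#' denominator are returned as `NA` with a warning, never silently zeroed.
#'
#' @param c A [confusion_counts()].
#' @return One-row tibble with the metric panel and the raw counts.
#' @export
confusion_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  tp <- c$tp; tn <- c$tn; fp <- c$fp; fn <- c$fn
  n <- tp + tn + fp + fn
  if (n == 0) abort("All confusion counts are zero; metrics undefined.")
  ratio <- function(num, den, name) {
    if (den == 0) {
      warn(sprintf("%s undefined (zero denominator); returning NA.", name))
      return(NA_real_)
    }
    num / den
  }
  tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    tpr = ratio(tp, tp + fn, "TPR"),
    fpr = ratio(fp, fp + tn, "FPR"),
    acc = (tp + tn) / n,
    spc = ratio(tn, fp + tn, "SPC"),
    ppv = ratio(tp, tp + fp, "PPV"),
    npv = ratio(tn, tn + fn, "NPV"),
    fdr = ratio(fp, fp + tp, "FDR"),
    fn_rate_percent = 100 * ratio(fn, tp + fn, "FN rate")
  )
}

#' Two-sided Student-t critical value
#'
#' The `1 - alpha/2` quantile of the t distribution, as used for the
#' confidence bands separating the healthy and hypertensive groups.
#'
#' @param confidence_alpha Two-sided significance level in (0, 1).
#' @param df Degrees of freedom (>= 1).
#' @return The critical value.
#' @export
t_critical <- function(confidence_alpha, df) {
  if (df < 1) abort("`df` must be at least 1.")
  if (confidence_alpha <= 0 || confidence_alpha >= 1) {
    abort("`confidence_alpha` must lie in (0, 1).")
  }
  qt(1 - confidence_alpha / 2, df)
}

#' Group confidence bands and their separation
#'
#' Each group's band is `mean +/- t_crit(alpha, n-1) * sd / sqrt(n)`. The
#' groups are declared separated when the lower bound of the higher-mean
#' group exceeds the upper bound of the lower-mean group.
#'
#' @param stats_a,stats_b Numeric `(mean, sd, n)` per group (`n >= 2`,
#'   `sd >= 0`).
#' @param alpha Two-sided significance level (default 0.001).
#' @param groups Character names for the two groups.
#' @return A `separation_bands` list: `$bands` tibble (group, mean, sd, n,
#'   df, t_crit, lower, upper) and `$disjoint`.
#' @export
separation_bands <- function(stats_a, stats_b, alpha = 0.001,
                             groups = c("a", "b")) {
  one <- function(s, g) {
    if (s[3] < 2) abort("Each group needs n >= 2.")
    if (s[2] < 0) abort("Standard deviations must be non-negative.")
    tc <- t_critical(alpha, s[3] - 1)
    half <- tc * s[2] / sqrt(s[3])
    tibble(
      group = g, mean = s[1], sd = s[2], n = as.integer(s[3]),
      df = as.integer(s[3] - 1), t_crit = tc,
      lower = s[1] - half, upper = s[1] + half
    )
  }
  bands <- dplyr::bind_rows(one(stats_a, groups[1]), one(stats_b, groups[2]))
  hi <- which.max(bands$mean); lo <- 3L - hi
  disjoint <- bands$lower[hi] > bands$upper[lo]
  structure(list(bands = bands, disjoint = disjoint), class = "separation_bands")
}

#' @export
print.separation_bands <- function(x, ...) {
  print(x$bands)
  cat(sprintf("bands disjoint: %s\n", x$disjoint))
  invisible(x)
}

#' @export
tidy.separation_bands <- function(x, ...) x$bands

#' Evaluate single-attribute and all-attribute trees
#'
#' Builds six trees — one per attribute plus one on all five attributes —
#' each fitted on the full table, pruned with the one-standard-error rule,
#' and scored by pooling the out-of-fold predictions of the chosen subtree
#' into one confusion panel. The same stratified fold assignment (derived
#' from `seed`) is used for every tree. The best tree is the one with
#' minimal misclassification; ties resolve to the tree using the fewest
#' attributes.
#'
#' @param table Feature table with the five attribute columns and a label
#'   column.
#' @param seed Integer seed for the fold assignment.
#' @param folds Number of folds (default 3).
#' @param label Label column name (default `"hypertension"`).
#' @return A `tree_evaluation`: `$summary` tibble (tree, attributes, counts,
#'   acc, n_leaves, root attribute/threshold, best flag) and `$models`.
#' @export
evaluate_attribute_trees <- function(table, seed, folds = 3L,
                                     label = "hypertension") {
  missing_attr <- setdiff(ATTRIBUTES, names(table))
  if (length(missing_attr) > 0L) {
    abort(sprintf(
      "Feature table must contain the five attributes; missing: %s",
      paste(missing_attr, collapse = ", ")
    ))
  }
  sets <- c(as.list(ATTRIBUTES), list(ATTRIBUTES))
  names(sets) <- c(ATTRIBUTES, "all")
  models <- purrr::imap(sets, function(attrs, nm) {
    m <- fit_cart(table, label = label, attributes = attrs)
    prune_1se(m, folds = folds, seed = seed)
  })
  rows <- purrr::imap(models, function(m, nm) {
    truth <- as.character(m$data$.label)
    cc <- counts_from_predictions(truth, m$oof_prediction)
    rs <- root_split(m)
    dplyr::bind_cols(
      tibble(
        tree = nm, n_attributes = length(m$attributes),
        n_leaves = n_leaves(m$fit),
        root_attribute = if (nrow(rs)) rs$attribute else NA_character_,
        root_threshold = if (nrow(rs)) rs$threshold else NA_real_
      ),
      # NA columns already flag undefined ratios (e.g. a tree that never
      # predicts positive); the per-call warning would only repeat that
      suppressWarnings(confusion_metrics(cc))
    )
  })
  summary <- dplyr::bind_rows(rows)
  misclass <- summary$fp + summary$fn
  best_idx <- order(misclass, summary$n_attributes)[1]
  summary$best <- seq_len(nrow(summary)) == best_idx
  structure(list(summary = summary, models = models, seed = seed, folds = folds),
            class = "tree_evaluation")
}

#' @export
print.tree_evaluation <- function(x, ...) {
  cols <- c("tree", "tp", "tn", "fp", "fn", "acc", "n_leaves",
            "root_attribute", "root_threshold", "best")
  print(x$summary[, cols])
  invisible(x)
}

#' @export
tidy.tree_evaluation <- function(x, ...) x$summary

#' Plot per-tree accuracies
#'
#' @param object A `tree_evaluation`.
#' @param ... Unused.
#' @return A ggplot of pooled cross-validated accuracy per tree.
#' @export
autoplot.tree_evaluation <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$tree, .data$acc), y = .data$acc, fill = .data$best
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::coord_flip(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "pooled cross-validated accuracy") +
    ggplot2::theme_minimal()
}

#' Simulate a subject cohort with the study's group statistics
#'
#' Draws a feature table whose `phi_max` separates the classes (negatives
#' `Normal(6.8, 5.1)`, positives `Normal(24.3, 3.0)` degrees by default,
#' rounded to whole degrees and clamped to \[0, 90] as histogram modes are)
#' while the remaining attributes are class-independent nuisance draws on
#' scales resembling healthy-range morphometry. Group sizes default to 40
#' negatives and 12 positives.
#'
#' @param seed Integer seed.
#' @param n_negative,n_positive Group sizes.
#' @param phi_max_negative,phi_max_positive `(mean, sd)` of `phi_max` per
#'   class; pass identical values for a pure-noise cohort.
#' @return Tibble with `subject`, the five attributes and `hypertension`
#'   (`"Yes"`/`"No"`).
#' @export
simulate_cohort <- function(seed, n_negative = 40L, n_positive = 12L,
                            phi_max_negative = c(6.8, 5.1),
                            phi_max_positive = c(24.3, 3.0)) {
  n <- n_negative + n_positive
  withr::with_seed(as.integer(seed), {
    lab <- c(rep("No", n_negative), rep("Yes", n_positive))
    phi_max <- c(
      rnorm(n_negative, phi_max_negative[1], phi_max_negative[2]),
      rnorm(n_positive, phi_max_positive[1], phi_max_positive[2])
    )
    tibble(
      subject = seq_len(n),
      z = rpois(n, 15),
      phi_sr = pmax(rnorm(n, 25, 8), 0),
      phi_std = pmax(rnorm(n, 18, 6), 0),
      phi_max = as.integer(pmin(pmax(round(phi_max), 0), 90)),
      p_s = pmax(rnorm(n, 9, 4), 0.1),
      hypertension = lab
    )
  })
}
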