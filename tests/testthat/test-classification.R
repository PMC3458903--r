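test_that("fit_cart finds the exact midpoint split on separable data", {
  d <- tibble::tibble(phi_max = c(1, 2, 9, 10),
                      hypertension = c("No", "No", "Yes", "Yes"))
  m <- fit_cart(d)
  rs <- root_split(m)
  expect_equal(rs$attribute, "phi_max")
  expect_equal(rs$threshold, 5.5)
  expect_equal(glance(m)$training_accuracy, 1)
  expect_equal(glance(m)$n_leaves, 2L)
})

test_that("the root split equals exhaustive Gini search on small tables", {
  withr::with_seed(31, {
    for (rep in 1:8) {
      n <- sample(6:12, 1)
      d <- tibble::tibble(
        phi_max = round(runif(n, 0, 30), 2),
        p_s = round(runif(n, 0, 40), 2),
        hypertension = sample(c("Yes", "No"), n, replace = TRUE)
      )
      if (length(unique(d$hypertension)) < 2) next
      m <- fit_cart(d)
      rs <- root_split(m)
      oracle <- oracle_best_split(d, c("phi_max", "p_s"), d$hypertension)
      if (oracle$improve <= 1e-9) {
        expect_equal(nrow(rs), 0L)
      } else {
        expect_true(oracle_split_matches(oracle, rs))
      }
    }
  })
})

test_that("degenerate tables resolve deterministically", {
  # identical rows, opposite labels: a leaf predicting the negative class
  d <- tibble::tibble(phi_max = c(5, 5), hypertension = c("Yes", "No"))
  m <- fit_cart(d)
  expect_equal(glance(m)$n_leaves, 1L)
  expect_equal(unname(as.character(predict(m$fit, type = "class"))),
               rep("negative", 2))
  # single-class table: a single-leaf tree, not an error
  d1 <- tibble::tibble(phi_max = c(1, 2, 3), hypertension = rep("No", 3))
  expect_equal(glance(fit_cart(d1))$n_leaves, 1L)
})

test_that("stratified folds preserve the class ratio and are reproducible", {
  labels <- c(rep("No", 40), rep("Yes", 12))
  f <- stratified_folds(labels, 3, seed = 5)
  expect_equal(sort(as.integer(table(f)), decreasing = TRUE), c(18L, 17L, 17L))
  expect_true(all(table(f[labels == "Yes"]) == 4))
  expect_identical(f, stratified_folds(labels, 3, seed = 5))
  expect_false(identical(f, stratified_folds(labels, 3, seed = 6)))
  # leave-one-out
  loo <- stratified_folds(labels, length(labels), seed = 1)
  expect_equal(sort(unique(loo)), 1:52)
  expect_error(stratified_folds(labels, 1, seed = 1), "at least 2")
})

test_that("1-SE pruning shrinks overfit trees and keeps perfect splits", {
  # a single leaf is returned unchanged
  d1 <- tibble::tibble(phi_max = c(5, 5), hypertension = c("No", "No"))
  m1 <- prune_1se(fit_cart(d1), folds = 2, seed = 1)
  expect_equal(glance(m1)$n_leaves, 1L)

  # perfectly separable data keep the single separating split
  d2 <- tibble::tibble(phi_max = c(1:10, 21:32),
                       hypertension = rep(c("No", "Yes"), c(10, 12)))
  m2 <- prune_1se(fit_cart(d2), folds = 3, seed = 2)
  expect_equal(glance(m2)$n_leaves, 2L)
  expect_true(root_split(m2)$threshold > 10 && root_split(m2)$threshold < 21)

  # noisy overlapping classes: the pruned tree is smaller than the full one
  # in nearly every replicate
  shrunk <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      d <- tibble::tibble(
        phi_max = c(rnorm(20, 0), rnorm(20, 2)),
        hypertension = rep(c("No", "Yes"), each = 20)
      )
    })
    full <- fit_cart(d)
    pruned <- prune_1se(full, folds = 5, seed = s)
    c(glance(pruned)$n_leaves, glance(full)$n_leaves)
  }, c(0, 0))
  expect_gte(mean(shrunk[1, ] < shrunk[2, ]), 0.9)
  # selection respects the 1-SE bound by construction
  m <- prune_1se(fit_cart(tibble::tibble(
    phi_max = c(rnorm(20, 0), rnorm(20, 2)),
    hypertension = rep(c("No", "Yes"), each = 20)
  )), folds = 5, seed = 3)
  tab <- m$pruning
  expect_lte(tab$cv_cost[tab$chosen],
             min(tab$cv_cost) + tab$cv_se[which.min(tab$cv_cost)] + 1e-12)
})

test_that("confusion metrics reproduce the arithmetic of the counts", {
  p <- confusion_metrics(confusion_counts(tp = 10, tn = 40, fp = 0, fn = 2))
  expect_equal(round(p$acc, 2), 0.96)
  expect_equal(round(p$tpr, 2), 0.83)
  expect_equal(p$spc, 1)
  expect_equal(round(p$npv, 2), 0.95)
  expect_equal(p$ppv, 1)
  expect_equal(p$fdr, 0)
  expect_equal(p$fpr, 0)
  expect_equal(round(p$fn_rate_percent, 1), 16.7)

  expect_equal(round(confusion_metrics(
    confusion_counts(tp = 12, tn = 37, fp = 3, fn = 0))$acc, 2), 0.94)

  sym <- confusion_metrics(confusion_counts(1, 1, 1, 1))
  expect_true(all(unlist(sym[c("tpr", "fpr", "acc", "spc", "ppv", "npv", "fdr")]) == 0.5))

  # identities: SPC + FPR = 1, PPV + FDR = 1, TPR + miss rate = 1
  withr::with_seed(2, {
    for (rep in 1:5) {
      cc <- confusion_counts(sample(1:20, 1), sample(1:20, 1),
                             sample(1:20, 1), sample(1:20, 1))
      q <- confusion_metrics(cc)
      expect_equal(q$spc + q$fpr, 1)
      expect_equal(q$ppv + q$fdr, 1)
      expect_equal(q$tpr + q$fn_rate_percent / 100, 1)
    }
  })

  # undefined ratios are NA with warnings, never zero
  w <- capture_warnings(u <- confusion_metrics(confusion_counts(0, 5, 0, 0)))
  expect_true(any(grepl("TPR", w)) && any(grepl("PPV", w)))
  expect_true(is.na(u$tpr) && is.na(u$ppv) && is.na(u$fdr))
  expect_equal(u$spc, 1)
  expect_error(confusion_metrics(confusion_counts(0, 0, 0, 0)), "zero")
})

test_that("t critical values match published tables and the normal limit", {
  # reference tables truncate at two decimals (3.558 -> 3.55, 4.437 -> 4.43)
  expect_equal(trunc(t_critical(0.001, 39) * 100) / 100, 3.55)
  expect_equal(trunc(t_critical(0.001, 11) * 100) / 100, 4.43)
  expect_equal(t_critical(0.001, 39), 3.55, tolerance = 0.005)
  expect_equal(t_critical(0.001, 11), 4.43, tolerance = 0.005)
  expect_equal(t_critical(0.001, 1e6), qnorm(1 - 0.001 / 2), tolerance = 1e-4)
  # monotone decreasing in df, increasing as alpha decreases
  expect_true(all(diff(vapply(c(5, 10, 20, 50), t_critical,
                              confidence_alpha = 0.01, 0)) < 0))
  expect_gt(t_critical(0.001, 10), t_critical(0.01, 10))
  expect_error(t_critical(0.001, 0), "df")
})

test_that("confidence bands separate the groups as published", {
  sb <- separation_bands(c(6.8, 5.1, 40), c(21.6, 7.6, 12), alpha = 0.001,
                         groups = c("healthy", "hypertensive"))
  b <- tidy(sb)
  expect_equal(b$upper[b$group == "healthy"], 9.66, tolerance = 0.002)
  expect_equal(b$lower, b$mean - b$t_crit * b$sd / sqrt(b$n))
  expect_true(sb$disjoint)
  # identical groups are never disjoint
  expect_false(separation_bands(c(5, 2, 10), c(5, 2, 10))$disjoint)
  # zero-sd groups collapse to points
  sb0 <- separation_bands(c(1, 0, 5), c(9, 0, 5))
  expect_true(sb0$disjoint)
  expect_equal(sb0$bands$lower, sb0$bands$upper)
})

test_that("attribute-wise evaluation finds the separating attribute", {
  cohort <- simulate_cohort(seed = 11)
  ev <- evaluate_attribute_trees(cohort, seed = 11)
  s <- tidy(ev)
  expect_equal(nrow(s), 6L)
  best <- s[s$best, ]
  expect_equal(best$tree, "phi_max")
  expect_equal(best$root_attribute, "phi_max")
  expect_true(best$root_threshold > 10 && best$root_threshold < 22)
  expect_gte(best$acc, 0.9)

  # a perfectly separating attribute yields pooled accuracy 1
  sep <- cohort
  sep$p_s <- ifelse(sep$hypertension == "Yes", 100, 1)
  ev2 <- evaluate_attribute_trees(sep, seed = 3)
  expect_equal(tidy(ev2)$acc[tidy(ev2)$tree == "p_s"], 1)
})

test_that("a pure-noise cohort falls back to the majority-class rate", {
  accs <- vapply(1:5, function(s) {
    noise <- simulate_cohort(seed = 100 + s,
                             phi_max_positive = c(6.8, 5.1))  # same as negatives
    tidy(evaluate_attribute_trees(noise, seed = s))$acc[6]
  }, 0)
  expect_gt(mean(accs), 40 / 52 - 0.12)
  expect_lt(mean(accs), 40 / 52 + 0.12)
})
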