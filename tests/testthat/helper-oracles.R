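# Independent brute-force oracles. These deliberately use the most naive
# possible formulation of each operation so they share no code path with the
# implementation they check.

# per-pixel sort-and-pick 3x3 median with replicate borders
oracle_median3 <- function(m) {
  M <- nrow(m); N <- ncol(m)
  out <- matrix(0, M, N)
  for (i in 1:M) for (j in 1:N) {
    nb <- numeric(9); k <- 0
    for (a in -1:1) for (b in -1:1) {
      k <- k + 1
      nb[k] <- m[min(max(i + a, 1), M), min(max(j + b, 1), N)]
    }
    out[i, j] <- sort(nb)[5]
  }
  out
}

# naive double-loop centred cross-correlation with replicate borders
oracle_correlate <- function(img, kernel) {
  M <- nrow(img); N <- ncol(img)
  hr <- (nrow(kernel) - 1) / 2; hc <- (ncol(kernel) - 1) / 2
  out <- matrix(0, M, N)
  for (i in 1:M) for (j in 1:N) {
    s <- 0
    for (a in -hr:hr) for (b in -hc:hc) {
      s <- s + img[min(max(i + a, 1), M), min(max(j + b, 1), N)] *
        kernel[a + hr + 1, b + hc + 1]
    }
    out[i, j] <- s
  }
  out
}

# exhaustive search over all 256 candidate thresholds maximising the
# between-class variance of the 256-level rescaled sample
oracle_otsu <- function(v) {
  mn <- min(v); mx <- max(v)
  lev <- round((v - mn) / (mx - mn) * 255)
  best_t <- NA; best_var <- -Inf
  for (t in 0:255) {
    lo <- lev[lev <= t]; hi <- lev[lev > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(lev); w1 <- 1 - w0
    bv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bv > best_var + 1e-12) { best_var <- bv; best_t <- t }
  }
  mn + (best_t + 0.5) / 255 * (mx - mn)
}

gini_impurity <- function(labels) {
  p <- table(labels) / length(labels)
  1 - sum(p^2)
}

# exhaustive search over every (attribute, midpoint) pair scored by Gini
# impurity decrease; returns every maximizer, since distinct split points can
# tie exactly on small tables
oracle_best_split <- function(df, attrs, labels) {
  n <- nrow(df)
  parent <- gini_impurity(labels)
  rows <- list()
  for (a in attrs) {
    vals <- sort(unique(df[[a]]))
    if (length(vals) < 2) next
    mids <- (head(vals, -1) + vals[-1]) / 2
    for (m in mids) {
      left <- df[[a]] < m
      imp <- parent - (sum(left) / n) * gini_impurity(labels[left]) -
        (sum(!left) / n) * gini_impurity(labels[!left])
      rows[[length(rows) + 1L]] <- data.frame(attr = a, threshold = m, improve = imp)
    }
  }
  all_splits <- do.call(rbind, rows)
  best <- max(all_splits$improve)
  list(
    improve = best,
    maximizers = all_splits[all_splits$improve > best - 1e-9, , drop = FALSE]
  )
}

oracle_split_matches <- function(oracle, rs) {
  any(oracle$maximizers$attr == rs$attribute &
        abs(oracle$maximizers$threshold - rs$threshold) < 1e-9)
}

# fold an angular difference into [0, 90] (independent re-statement)
oracle_fold <- function(d) {
  d <- abs(d) %% 180
  ifelse(d > 90, 180 - d, d)
}

# radial direction (mod 180) of every masked pixel, in the linear order used
# by logical subsetting of the angle matrix
radial_dir_for_test <- function(lk, center) {
  idx <- which(lk$mask, arr.ind = TRUE)
  (atan2(-(idx[, 1] - center[1]), idx[, 2] - center[2]) * 180 / pi) %% 180
}
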