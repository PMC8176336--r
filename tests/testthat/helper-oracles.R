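# Independent brute-force oracles, written directly from the definitions and
# kept free of the package's own code paths.

# Metrics computed cell by cell from the confusion-matrix definitions.
oracle_metrics <- function(m) {
  n <- sum(m)
  acc <- (m[1, 1] + m[2, 2] + m[3, 3]) / n
  prec <- rec <- numeric(3)
  for (c in 1:3) {
    colsum <- m[1, c] + m[2, c] + m[3, c]
    rowsum <- m[c, 1] + m[c, 2] + m[c, 3]
    prec[c] <- if (colsum > 0) m[c, c] / colsum else 0
    rec[c] <- if (rowsum > 0) m[c, c] / rowsum else 0
  }
  P <- (prec[1] + prec[2] + prec[3]) / 3
  R <- (rec[1] + rec[2] + rec[3]) / 3
  pe <- 0
  for (c in 1:3) pe <- pe + sum(m[c, ]) * sum(m[, c])
  pe <- pe / n^2
  kap <- if (pe < 1) (acc - pe) / (1 - pe) else if (acc == 1) 1 else 0
  list(accuracy = acc,
       kappa = kap,
       macro_precision = P, macro_recall = R,
       macro_f1 = if (P + R > 0) 2 * P * R / (P + R) else 0)
}

# Micro-averaged one-vs-rest precision/recall/F1 (pooled TP/FP/FN).
oracle_micro <- function(m) {
  tp <- fp <- fn <- 0
  for (c in 1:3) {
    tp <- tp + m[c, c]
    fp <- fp + sum(m[, c]) - m[c, c]
    fn <- fn + sum(m[c, ]) - m[c, c]
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0   # 0/0 -> 0, as documented
  c(precision = p, recall = r, f1 = f1)
}

# Forward pass by scalar loops over the layer list (no matrix products).
oracle_forward <- function(layers, x) {
  a <- x
  for (l in seq_along(layers)) {
    W <- layers[[l]]$W
    b <- layers[[l]]$b
    z <- numeric(ncol(W))
    for (j in seq_len(ncol(W))) {
      s <- b[j]
      for (i in seq_len(nrow(W))) s <- s + a[i] * W[i, j]
      z[j] <- s
    }
    a <- if (l < length(layers)) ifelse(z > 0, z, 0) else z
  }
  a
}

oracle_softmax <- function(l) exp(l - max(l)) / sum(exp(l - max(l)))

# Exhaustive-search kNN mean: all pairwise distances, donors complete in the
# target field, ties by lower row index.
oracle_knn_value <- function(Ds, x, i, k) {
  donors <- which(!is.na(x) & seq_along(x) != i)
  d <- sapply(donors, function(j) sqrt(sum((Ds[i, ] - Ds[j, ])^2)))
  ord <- order(d, donors)
  mean(x[donors[ord[seq_len(k)]]])
}
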