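#' 3x3 confusion matrix for the ternary outcome
#'
#' Rows are actual classes, columns predicted, both in the canonical order
#' subtherapeutic / normal / supratherapeutic.
#'
#' @param actual,predicted vectors (factor or character) of equal length with
#'   values among [therapeutic_classes()].
#' @return Integer 3x3 matrix of class `confusion_matrix3`.
#' @export
confusion_matrix3 <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("actual and predicted lengths differ")
  if (length(actual) == 0) stop("empty input")
  lv <- therapeutic_classes()
  a <- factor(as.character(actual), levels = lv)
  p <- factor(as.character(predicted), levels = lv)
  if (anyNA(a) || anyNA(p)) stop("values outside the three therapeutic classes")
  m <- table(actual = a, predicted = p)
  structure(matrix(as.integer(m), 3, 3, dimnames = dimnames(m)),
            class = c("confusion_matrix3", "matrix"))
}

#' Classification metrics from a 3x3 confusion matrix
#'
#' Computes the metric set used to gauge ternary outcome prediction:
#' accuracy, Cohen's kappa, and macro-averaged precision, recall and F1.
#' With diagonal cells A, E, I and total N, accuracy = (A+E+I)/N; per-class
#' precision is the diagonal over the column sum and recall the diagonal over
#' the row sum, macro-averaged as their unweighted three-class means P and R;
#' the macro F1 is 2PR/(P+R). Kappa is (p_o - p_e)/(1 - p_e) with p_o the
#' accuracy and p_e the chance agreement from the marginal products.
#' Per-class ratios with a zero denominator (a class never present or never
#' predicted) contribute 0. Micro-averaged precision/recall/F1 all coincide
#' with accuracy for a single multi-class confusion matrix and are therefore
#' not reported separately.
#'
#' @param cm a [confusion_matrix3()] or plain nonnegative 3x3 matrix.
#' @return A list of class `metrics_report` with elements `accuracy`, `kappa`,
#'   `macro_precision`, `macro_recall`, `macro_f1`, `n`.
#' @examples
#' cm <- confusion_matrix3(rep(therapeutic_classes(), 10),
#'                         rep(therapeutic_classes(), 10))
#' compute_metrics(cm)
#' @export
compute_metrics <- function(cm) {
  m <- unclass(cm)
  if (!is.matrix(m) || any(dim(m) != c(3, 3))) stop("cm must be a 3x3 matrix")
  if (any(m < 0)) stop("confusion matrix cells must be nonnegative")
  n <- sum(m)
  if (n <= 0) stop("confusion matrix is empty")
  diagm <- diag(m)
  rows <- rowSums(m)
  cols <- colSums(m)
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  prec <- safe_div(diagm, cols)
  rec  <- safe_div(diagm, rows)
  P <- mean(prec)
  R <- mean(rec)
  f1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  acc <- sum(diagm) / n
  pe <- sum(rows * cols) / n^2
  # pe == 1 only when all mass sits in a single cell; chance correction is
  # then undefined and kappa is set to 1 for perfect agreement, else 0
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else if (acc == 1) 1 else 0
  structure(list(accuracy = acc, kappa = kappa,
                 macro_precision = P, macro_recall = R, macro_f1 = f1,
                 n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("classification metrics (n=%d)\n",
                     "  accuracy        %.4f\n  kappa           %.4f\n",
                     "  macro precision %.4f\n  macro recall    %.4f\n",
                     "  macro F1        %.4f\n"),
              x$n, x$accuracy, x$kappa,
              x$macro_precision, x$macro_recall, x$macro_f1))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(accuracy = x$accuracy, kappa = x$kappa,
             macro_precision = x$macro_precision,
             macro_recall = x$macro_recall, macro_f1 = x$macro_f1, n = x$n)
}
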