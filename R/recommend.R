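#' Candidate dosage grid
#'
#' An ordered, strictly increasing set of candidate total dosages to sweep
#' during counterfactual recommendation. The default construction spans
#' \[0, max_dose\] in `steps` equal increments (steps + 1 candidates).
#'
#' @param max_dose upper end of the grid, typically the maximum total dose
#'   observed in the training rows.
#' @param steps number of equal increments (default 200).
#' @return Numeric vector of class `dose_grid`.
#' @export
dose_grid <- function(max_dose, steps = 200) {
  stopifnot(max_dose > 0, steps >= 1)
  structure(seq(0, max_dose, length.out = steps + 1), class = "dose_grid")
}

#' Normal-therapeutic probability under a counterfactual dose
#'
#' Replaces the patient's total-dose feature (on the raw scale) with `alpha`,
#' re-applies the model's training normalization and returns the softmax
#' probability of the normal-therapeutic class, M(x, alpha). The input row is
#' not mutated.
#'
#' @param model a `hepadose_model`.
#' @param row a single data-frame row with the model's raw feature columns.
#' @param alpha candidate dose(s); vectorized.
#' @return Numeric vector of normal-class probabilities, one per `alpha`.
#' @export
counterfactual_prob <- function(model, row, alpha) {
  stopifnot(inherits(model, "hepadose_model"))
  if (any(alpha < 0)) stop("candidate dose must be nonnegative")
  X <- as.matrix(row[rep(1, length(alpha)), model$features, drop = FALSE])
  storage.mode(X) <- "double"
  X[, model$dose] <- alpha
  P <- nn_softmax(nn_forward(model$net, normalize_matrix(X, model$minmax)))
  unname(P[, 2])
}

#' Recommend the dosage maximizing the normal-therapeutic probability
#'
#' Evaluates M(x, alpha) exhaustively over the grid and returns
#' sigma(x) = argmax_alpha M(x, alpha). Exact ties are broken toward the
#' candidate closest to the actual dose, then toward the lower dose.
#'
#' @param model a `hepadose_model`.
#' @param row a single patient row (raw scale) including the actual dose in
#'   the model's dose column.
#' @param grid a [dose_grid()] or numeric vector of candidates.
#' @return A one-row data frame: `patient_id` (if present), `actual_dose`,
#'   `recommended_dose`, `normal_prob_at_recommended`,
#'   `normal_prob_at_actual`, `direction` (increase/decrease/unchanged).
#' @export
recommend_dose <- function(model, row, grid) {
  if (length(grid) == 0) stop("empty dose grid")
  actual <- as.numeric(row[[model$dose]])
  probs <- counterfactual_prob(model, row, as.numeric(grid))
  best_p <- max(probs)
  cand <- which(probs == best_p)
  if (length(cand) > 1) {
    d <- abs(as.numeric(grid)[cand] - actual)
    cand <- cand[d == min(d)]
    cand <- cand[which.min(as.numeric(grid)[cand])]
  }
  rec <- as.numeric(grid)[cand[1]]
  data.frame(
    patient_id = if (!is.null(row$patient_id)) row$patient_id else NA,
    actual_dose = actual,
    recommended_dose = rec,
    normal_prob_at_recommended = best_p,
    normal_prob_at_actual = counterfactual_prob(model, row, actual),
    direction = if (rec > actual) "increase" else if (rec < actual) "decrease" else "unchanged"
  )
}

#' Recommend dosages for every patient in a table
#'
#' @param model a `hepadose_model`.
#' @param rows data frame of patient rows (raw scale).
#' @param grid a [dose_grid()]; default spans \[0, max observed dose\] in 200
#'   steps.
#' @return Data frame of recommendations (one row per patient) with the
#'   model-predicted class attached as `predicted_label`.
#' @export
recommend_doses <- function(model, rows, grid = NULL) {
  if (is.null(grid)) grid <- dose_grid(max(rows[[model$dose]]))
  recs <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    recommend_dose(model, rows[i, , drop = FALSE], grid)
  }))
  recs$predicted_label <- predict_classes(model, rows)
  if (!is.null(rows$label)) recs$actual_label <- rows$label
  recs
}

#' Audit recommendation reasonableness against actual doses
#'
#' A recommendation for a subtherapeutic patient is reasonable when the
#' recommended dose exceeds the actual dose; for a supratherapeutic patient
#' when it is lower. Normal-therapeutic patients are excluded. The
#' subtherapeutic/supratherapeutic subsets are defined by the model-predicted
#' class by default, or by the actual outcome label with `by = "actual"`.
#'
#' @param recs recommendations from [recommend_doses()].
#' @param by `"predicted"` or `"actual"`.
#' @return A list: `sub_n`, `sub_increase`, `sub_increase_frac`, `supra_n`,
#'   `supra_decrease`, `supra_decrease_frac` (fractions are `NA` when the
#'   subset is empty).
#' @export
audit_recommendations <- function(recs, by = c("predicted", "actual")) {
  by <- match.arg(by)
  lab <- if (by == "predicted") recs$predicted_label else recs$actual_label
  if (is.null(lab)) stop(sprintf("recommendations carry no %s label", by))
  lab <- as.character(lab)
  sub <- recs[lab == "subtherapeutic", , drop = FALSE]
  sup <- recs[lab == "supratherapeutic", , drop = FALSE]
  sub_up <- sum(sub$recommended_dose > sub$actual_dose)
  sup_dn <- sum(sup$recommended_dose < sup$actual_dose)
  list(sub_n = nrow(sub), sub_increase = sub_up,
       sub_increase_frac = if (nrow(sub) > 0) sub_up / nrow(sub) else NA_real_,
       supra_n = nrow(sup), supra_decrease = sup_dn,
       supra_decrease_frac = if (nrow(sup) > 0) sup_dn / nrow(sup) else NA_real_)
}

#' Oracle dose recommendation from the generative mechanism
#'
#' Uses the generator's exact band probabilities (see
#' [oracle_probabilities()]) instead of a trained network to pick the
#' candidate dose maximizing the normal-therapeutic probability. Serves as
#' ground truth for recommendation-direction tests.
#'
#' @param record one row of a cohort's `patients` table carrying the hidden
#'   mechanism columns.
#' @param actual_dose the patient's actual total dose.
#' @param grid candidate doses.
#' @param cohort the `hepadose_cohort`.
#' @return A one-row data frame matching [recommend_dose()]'s shape.
#' @export
oracle_recommend <- function(record, actual_dose, grid, cohort) {
  probs <- vapply(as.numeric(grid), function(a) {
    oracle_probabilities(record, a, cohort)[["normal"]]
  }, numeric(1))
  best <- which.max(probs)
  rec <- as.numeric(grid)[best]
  data.frame(patient_id = record$patient_id, actual_dose = actual_dose,
             recommended_dose = rec, normal_prob_at_recommended = probs[best],
             normal_prob_at_actual = oracle_probabilities(record, actual_dose, cohort)[["normal"]],
             direction = if (rec > actual_dose) "increase"
                         else if (rec < actual_dose) "decrease" else "unchanged")
}
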