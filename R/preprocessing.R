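#' Apply the cohort inclusion criteria to raw event-level records
#'
#' Retains patients with age >= 18 years, at least one heparin dose event, at
#' least one aPTT measurement strictly before the first dose, and at least one
#' aPTT measurement in the 8-24 h therapeutic window after the first dose.
#' Exclusions are tallied per reason in the order they are checked:
#' `age`, `no_heparin`, `aptt_unavailable` (a record failing several criteria
#' counts under the first).
#'
#' @param cohort a `hepadose_cohort`.
#' @return A list with `cohort` (the filtered `hepadose_cohort`) and `tally`
#'   (named integer vector of exclusion counts, plus `included`).
#' @export
apply_inclusion <- function(cohort) {
  stopifnot(inherits(cohort, "hepadose_cohort"))
  pats <- cohort$patients
  ev <- cohort$events
  by_pat <- split(ev[, c("event_type", "time_h")],
                  factor(ev$patient_id, levels = pats$patient_id))
  reasons <- character(nrow(pats))
  for (i in seq_len(nrow(pats))) {
    e <- by_pat[[i]]
    doses <- e[e$event_type == "dose", , drop = FALSE]
    aptts <- e[e$event_type == "aptt", , drop = FALSE]
    if (is.na(pats$age[i]) || pats$age[i] < 18) {
      reasons[i] <- "age"
    } else if (nrow(doses) == 0) {
      reasons[i] <- "no_heparin"
    } else {
      t0 <- min(doses$time_h)
      has_pre <- any(aptts$time_h < t0)
      has_post <- any(aptts$time_h >= t0 + 8 & aptts$time_h <= t0 + 24)
      if (!has_pre || !has_post) reasons[i] <- "aptt_unavailable"
    }
  }
  keep <- reasons == ""
  tally <- c(age = sum(reasons == "age"),
             no_heparin = sum(reasons == "no_heparin"),
             aptt_unavailable = sum(reasons == "aptt_unavailable"),
             included = sum(keep))
  out <- cohort
  out$patients <- pats[keep, , drop = FALSE]
  out$events <- ev[ev$patient_id %in% pats$patient_id[keep], , drop = FALSE]
  list(cohort = out, tally = tally)
}

#' Filter rows with continuous features outside mean +/- 3 SD
#'
#' For each listed feature the mean mu and standard deviation sigma are
#' computed once over the input rows; the admissible range is
#' \[max(0, mu - 3 sigma), mu + 3 sigma\] and a row is removed when ANY listed
#' feature falls outside its range. Bounds are not re-estimated after
#' removals.
#'
#' @param rows data frame.
#' @param continuous_features character vector of column names.
#' @return A list with `rows` (the survivors), `bounds` (data frame: feature,
#'   mu, sigma, low, high, n_removed) and `removed` (row indices of the input
#'   that were dropped).
#' @export
filter_outliers <- function(rows, continuous_features) {
  if (nrow(rows) == 0) stop("no rows to filter")
  bad <- rep(FALSE, nrow(rows))
  bounds <- vector("list", length(continuous_features))
  for (j in seq_along(continuous_features)) {
    f <- continuous_features[j]
    x <- rows[[f]]
    if (is.null(x) || !is.numeric(x)) stop(sprintf("feature '%s' absent or non-numeric", f))
    mu <- mean(x)
    sigma <- stats::sd(x)
    if (is.na(sigma)) sigma <- 0
    low <- max(0, mu - 3 * sigma)
    high <- mu + 3 * sigma
    out <- x < low | x > high
    bounds[[j]] <- data.frame(feature = f, mu = mu, sigma = sigma,
                              low = low, high = high, n_removed = sum(out))
    bad <- bad | out
  }
  list(rows = rows[!bad, , drop = FALSE],
       bounds = do.call(rbind, bounds),
       removed = which(bad))
}

#' k-nearest-neighbour imputation of missing values
#'
#' Each missing entry of a target field is replaced by the mean of that field
#' over the `k` rows nearest in Euclidean distance. Distances are computed on
#' `distance_features`, min-max scaled (on the observed rows) so that no
#' single feature dominates; donor rows must be complete in the target field
#' being imputed. Distance ties are broken by the lower row position, so the
#' result is deterministic.
#'
#' @param rows data frame.
#' @param target_fields character vector of columns whose `NA`s are imputed.
#' @param k number of donors (default 3).
#' @param distance_features columns defining the distance space; they must be
#'   complete and numeric.
#' @return The data frame with all target fields completed.
#' @export
impute_knn <- function(rows, target_fields, k = 3,
                       distance_features = NULL) {
  n <- nrow(rows)
  if (is.null(distance_features)) {
    distance_features <- setdiff(names(rows)[vapply(rows, is.numeric, TRUE)],
                                 target_fields)
  }
  D <- as.matrix(rows[, distance_features, drop = FALSE])
  if (anyNA(D)) stop("distance features must be complete")
  rng <- apply(D, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  Ds <- sweep(sweep(D, 2, rng[1, ]), 2, span, "/")
  out <- rows
  for (f in target_fields) {
    x <- rows[[f]]
    miss <- which(is.na(x))
    if (length(miss) == 0) next
    donors <- which(!is.na(x))
    if (length(donors) < k) stop(sprintf("fewer than %d complete rows for '%s'", k, f))
    for (i in miss) {
      d2 <- colSums((t(Ds[donors, , drop = FALSE]) - Ds[i, ])^2)
      nearest <- donors[order(d2, donors)[seq_len(k)]]
      out[[f]][i] <- mean(x[nearest])
    }
  }
  out
}

#' One-hot encode categorical features
#'
#' Each categorical column is replaced by one indicator column per level of
#' its vocabulary. The vocabulary is fitted from the data (sorted unique
#' values) unless supplied; transforming a value outside the vocabulary is an
#' error.
#'
#' @param rows data frame.
#' @param categorical_features character vector of column names.
#' @param vocab optional named list of level vectors from a previous fit.
#' @return A list with `rows` (encoded data frame), `vocab` and `groups`
#'   (named list mapping each categorical to its indicator column names).
#' @export
one_hot_encode <- function(rows, categorical_features, vocab = NULL) {
  if (is.null(vocab)) {
    vocab <- lapply(rows[categorical_features], function(x) sort(unique(as.character(x))))
    names(vocab) <- categorical_features
  }
  out <- rows
  groups <- list()
  for (f in categorical_features) {
    lv <- vocab[[f]]
    x <- as.character(rows[[f]])
    unseen <- setdiff(unique(x), lv)
    if (length(unseen) > 0) {
      stop(sprintf("unseen category in '%s': %s", f, paste(unseen, collapse = ", ")))
    }
    cols <- paste0(f, "_", lv)
    for (j in seq_along(lv)) out[[cols[j]]] <- as.numeric(x == lv[j])
    out[[f]] <- NULL
    groups[[f]] <- cols
  }
  list(rows = out, vocab = vocab, groups = groups)
}

#' Min-max normalization parameters
#'
#' `fit_minmax()` records the observed minimum and maximum of each continuous
#' feature on the fitting rows (training data only, to avoid leakage);
#' `apply_minmax()` maps x to (x - min) / (max - min), clipping values outside
#' the fitted range into \[0, 1\]. A constant feature (max == min) maps to 0.
#'
#' @param rows data frame of fitting rows.
#' @param continuous_features character vector of column names.
#' @return `fit_minmax()`: an object of class `minmax_params` (named list of
#'   `c(min, max)` per feature). `apply_minmax()`: the transformed data frame.
#' @export
fit_minmax <- function(rows, continuous_features) {
  prm <- lapply(continuous_features, function(f) {
    x <- rows[[f]]
    if (is.null(x) || !is.numeric(x)) stop(sprintf("feature '%s' absent or non-numeric", f))
    c(min = min(x, na.rm = TRUE), max = max(x, na.rm = TRUE))
  })
  names(prm) <- continuous_features
  structure(prm, class = "minmax_params")
}

#' @rdname fit_minmax
#' @param params a `minmax_params` object from `fit_minmax()`.
#' @export
apply_minmax <- function(rows, params) {
  stopifnot(inherits(params, "minmax_params"))
  out <- rows
  for (f in names(params)) {
    if (is.null(rows[[f]])) stop(sprintf("feature '%s' missing from rows", f))
    lo <- params[[f]]["min"]
    hi <- params[[f]]["max"]
    if (hi > lo) {
      out[[f]] <- pmin(1, pmax(0, (rows[[f]] - lo) / (hi - lo)))
    } else {
      out[[f]] <- rep(0, nrow(rows))
    }
  }
  out
}

# Feature schema per dialect: which labelled-table columns are continuous
# model inputs, which are categorical, and which carry the dose.
feature_schema <- function(dialect) {
  cont <- c("age", "weight", "initial_aptt", "creatinine", "liver_enzyme",
            "sofa_coag", "sofa_liver", "sofa_cardio", "sofa_renal", "total_dose")
  cats <- if (dialect == "mimic") c("gender", "ethnicity", "admission_type") else "gender"
  list(continuous = cont, categorical = cats, dose = "total_dose",
       sofa = c("sofa_coag", "sofa_liver", "sofa_cardio", "sofa_renal"),
       outlier_filter = c("weight", "initial_aptt", "creatinine",
                          "liver_enzyme", "total_dose"),
       knn_distance = c("age", "weight", "initial_aptt", "creatinine",
                        "liver_enzyme", "total_dose"))
}

#' Run the full cohort-construction chain on a raw cohort
#'
#' Pipeline order: inclusion criteria, removal of records with missing
#' non-imputable values (weight / liver enzyme), mean +/- 3 SD outlier
#' filtering on the continuous features, 3-NN imputation of missing SOFA
#' sub-scores, one-hot encoding of the categorical features. Min-max
#' normalization is deliberately NOT applied here: it is fitted on training
#' rows only, inside [cross_validate()] / [train_network()] workflows.
#'
#' @param cohort a raw `hepadose_cohort`.
#' @param scheme optional [label_scheme()] override.
#' @param k imputation neighbour count.
#' @return A list of class `hepadose_dataset` with `rows` (encoded feature
#'   table including `label` and raw `total_dose`), `schema` (feature names,
#'   one-hot groups, continuous features), and `report` (exclusion tally,
#'   outlier bounds, imputation count).
#' @export
preprocess_cohort <- function(cohort, scheme = NULL, k = 3) {
  stopifnot(inherits(cohort, "hepadose_cohort"))
  dialect <- cohort$config$dialect
  sch <- feature_schema(dialect)

  inc <- apply_inclusion(cohort)
  labelled <- label_cohort(inc$cohort, scheme)

  complete_req <- c("age", "weight", "liver_enzyme", "creatinine")
  miss_req <- !stats::complete.cases(labelled[, complete_req])
  n_missing_removed <- sum(miss_req)
  labelled <- labelled[!miss_req, , drop = FALSE]

  filt <- filter_outliers(labelled, sch$outlier_filter)
  rows <- filt$rows

  n_imputed <- sum(is.na(as.matrix(rows[, sch$sofa])))
  rows <- impute_knn(rows, sch$sofa, k = k, distance_features = sch$knn_distance)

  enc <- one_hot_encode(rows, sch$categorical)
  rows <- enc$rows

  feature_cols <- c(sch$continuous, unlist(enc$groups, use.names = FALSE))
  structure(list(
    rows = rows,
    schema = list(dialect = dialect, features = feature_cols,
                  continuous = sch$continuous, groups = enc$groups,
                  vocab = enc$vocab, dose = sch$dose),
    report = list(exclusion_tally = as.list(inc$tally),
                  n_missing_removed = n_missing_removed,
                  outlier_bounds = filt$bounds,
                  n_outlier_removed = length(filt$removed),
                  n_imputed = n_imputed,
                  n_final = nrow(rows))
  ), class = "hepadose_dataset")
}

#' @export
print.hepadose_dataset <- function(x, ...) {
  cat(sprintf("preprocessed heparin dataset: %d patients, %d model features (dialect '%s')\n",
              nrow(x$rows), length(x$schema$features), x$schema$dialect))
  invisible(x)
}
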