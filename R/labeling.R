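#' Therapeutic aPTT band scheme
#'
#' The activated partial thromboplastin time (aPTT) bands that define the
#' three heparin treatment outcomes differ by institution. The `mimic` scheme
#' uses 0-60 s (subtherapeutic), 60-100 s (normal therapeutic) and >100 s
#' (supratherapeutic); the `pumch` scheme uses 0-35, 35-45 and >45 s.
#'
#' Band boundaries are resolved as subtherapeutic = \[0, sub_upper),
#' normal = \[sub_upper, normal_upper\], supratherapeutic = (normal_upper, Inf):
#' the supratherapeutic band is printed strictly "greater than", so the shared
#' endpoints belong to the normal band.
#'
#' @param name `"mimic"` or `"pumch"`, or `"custom"` with explicit bounds.
#' @param sub_upper,normal_upper custom band edges in seconds (only used when
#'   `name = "custom"`).
#' @return An object of class `label_scheme` with fields `name`, `sub_upper`,
#'   `normal_upper`.
#' @examples
#' label_scheme("mimic")
#' classify_aptt(c(59.9, 60, 100, 100.01), label_scheme("mimic"))
#' @export
label_scheme <- function(name = c("mimic", "pumch", "custom"),
                         sub_upper = NULL, normal_upper = NULL) {
  name <- match.arg(name)
  bounds <- switch(name,
    mimic  = c(60, 100),
    pumch  = c(35, 45),
    custom = c(sub_upper, normal_upper)
  )
  if (length(bounds) != 2 || !is.numeric(bounds)) {
    stop("custom scheme requires numeric sub_upper and normal_upper")
  }
  if (!(bounds[1] > 0 && bounds[1] < bounds[2])) {
    stop("label scheme requires 0 < sub_upper < normal_upper")
  }
  structure(list(name = name, sub_upper = bounds[1], normal_upper = bounds[2]),
            class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat(sprintf("aPTT label scheme '%s': sub [0, %g), normal [%g, %g], supra (%g, Inf)\n",
              x$name, x$sub_upper, x$sub_upper, x$normal_upper, x$normal_upper))
  invisible(x)
}

#' Therapeutic class levels
#'
#' Canonical ordering of the three outcome classes used throughout the
#' package: subtherapeutic, normal, supratherapeutic.
#' @return Character vector of the three class names.
#' @export
therapeutic_classes <- function() c("subtherapeutic", "normal", "supratherapeutic")

#' Classify a therapeutic aPTT value into an outcome band
#'
#' @param aptt numeric vector of aPTT values in seconds (must be >= 0).
#' @param scheme a [label_scheme()].
#' @return Factor with levels `subtherapeutic`, `normal`, `supratherapeutic`.
#' @export
classify_aptt <- function(aptt, scheme) {
  stopifnot(inherits(scheme, "label_scheme"))
  if (any(!is.finite(aptt)) || any(aptt < 0)) {
    stop("aptt values must be finite and nonnegative")
  }
  cls <- ifelse(aptt < scheme$sub_upper, "subtherapeutic",
         ifelse(aptt <= scheme$normal_upper, "normal", "supratherapeutic"))
  factor(cls, levels = therapeutic_classes())
}

#' Initial aPTT: last measurement strictly before the first dose
#'
#' @param aptt_events data frame or list with `time_h` and `value` columns
#'   (hours relative to an arbitrary origin, aPTT seconds).
#' @param first_dose_time time of the first heparin dose, hours.
#' @return The aPTT value of the latest measurement with
#'   `time_h < first_dose_time`.
#' @export
initial_aptt <- function(aptt_events, first_dose_time) {
  t <- aptt_events$time_h
  v <- aptt_events$value
  pre <- t < first_dose_time
  if (!any(pre)) stop("no aPTT measurement strictly before the first dose")
  v[pre][which.max(t[pre])]
}

#' Total heparin dose within 8 hours of the first infusion
#'
#' Sums dose amounts with event time in the half-open window
#' \[t0, t0 + 8) where t0 is the first dose time.
#'
#' @param dose_events data frame or list with `time_h` and `value` columns.
#' @return Total dose in the native dose unit of the record.
#' @export
total_dose_8h <- function(dose_events) {
  t <- dose_events$time_h
  v <- dose_events$value
  if (length(t) == 0) stop("no dose events")
  t0 <- min(t)
  sum(v[t >= t0 & t < t0 + 8])
}

#' Therapeutic aPTT: mean of measurements 8-24 h after the first infusion
#'
#' Averages all aPTT values with time in the closed window
#' \[t0 + 8, t0 + 24\].
#'
#' @param aptt_events data frame or list with `time_h` and `value` columns.
#' @param t0 time of the first dose, hours.
#' @return Mean aPTT in seconds.
#' @export
therapeutic_aptt <- function(aptt_events, t0) {
  t <- aptt_events$time_h
  v <- aptt_events$value
  inwin <- t >= t0 + 8 & t <= t0 + 24
  if (!any(inwin)) stop("no aPTT measurement in the 8-24 h window")
  mean(v[inwin])
}

#' Derive model target and dose feature for every patient in a cohort
#'
#' Adds the four derived columns to the static patient table: `initial_aptt`
#' (last pre-dose measurement), `total_dose` (8-h dose sum),
#' `therapeutic_aptt` (mean aPTT 8-24 h after first infusion) and `label`
#' (ternary outcome under `scheme`).
#'
#' @param cohort a `hepadose_cohort` from [generate_cohort()] or
#'   [read_cohort()].
#' @param scheme a [label_scheme()]; defaults to the cohort's dialect scheme.
#' @return A data frame, one row per patient.
#' @export
label_cohort <- function(cohort, scheme = NULL) {
  stopifnot(inherits(cohort, "hepadose_cohort"))
  if (is.null(scheme)) scheme <- label_scheme(cohort$config$dialect)
  pats <- cohort$patients
  ev <- cohort$events
  n <- nrow(pats)
  by_pat <- split(ev[, c("event_type", "time_h", "value")],
                  factor(ev$patient_id, levels = pats$patient_id))
  ia <- td <- ta <- numeric(n)
  for (i in seq_len(n)) {
    e <- by_pat[[i]]
    doses <- e[e$event_type == "dose", c("time_h", "value")]
    aptts <- e[e$event_type == "aptt", c("time_h", "value")]
    t0 <- min(doses$time_h)
    ia[i] <- initial_aptt(aptts, t0)
    td[i] <- total_dose_8h(doses)
    ta[i] <- therapeutic_aptt(aptts, t0)
  }
  out <- pats
  out$initial_aptt <- ia
  out$total_dose <- td
  out$therapeutic_aptt <- ta
  out$label <- classify_aptt(ta, scheme)
  out
}
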