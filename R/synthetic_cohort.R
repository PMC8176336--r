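# Truncated-normal helpers. Sampling uses the inverse-CDF transform so a
# single uniform draw per value keeps the stream deterministic; moments use
# the standard closed forms and feed the mechanism calibration below.

rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

tnorm_stats <- function(mean, sd, lo = -Inf, hi = Inf) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  mu <- mean + sd * (da - db) / Z
  t1 <- (ifelse(is.finite(a), a * da, 0) - ifelse(is.finite(b), b * db, 0)) / Z
  v <- sd^2 * (1 + t1 - ((da - db) / Z)^2)
  list(mean = mu, var = v)
}

# Per-dialect generator parameters: class-conditional feature distributions
# (per-class cohort summary statistics of the two source populations),
# categorical proportions, dose summary, label bands, and the coefficients of
# the hidden dose-response mechanism. Continuous features are truncated
# normals on plausible supports.
dialect_params <- function(dialect) {
  if (dialect == "mimic") {
    list(
      class_mix = c(1718, 1266, 623) / 3607,
      cont = list(
        age          = list(mean = c(65.4, 67.8, 70.6), sd = c(14.2, 15.0, 13.9), lo = 18,   hi = 110),
        weight       = list(mean = c(84.5, 81.3, 80.5), sd = c(21.8, 21.3, 21.8), lo = 25,   hi = 250),
        initial_aptt = list(mean = c(39.5, 45.5, 40.4), sd = c(22.0, 26.8, 21.2), lo = 12,   hi = 150),
        creatinine   = list(mean = c(1.4, 1.5, 1.7),    sd = c(1.0, 1.1, 1.2),    lo = 0.2,  hi = 15),
        liver_enzyme = list(mean = c(1.6, 1.7, 1.6),    sd = c(1.1, 1.2, 1.0),    lo = 0.1,  hi = 12)
      ),
      sofa = list(
        sofa_coag   = list(mean = c(0.5, 0.4, 0.4), sd = c(0.8, 0.7, 0.7)),
        sofa_liver  = list(mean = c(0.4, 0.4, 0.4), sd = c(0.8, 0.7, 0.8)),
        sofa_cardio = list(mean = c(1.5, 1.5, 1.7), sd = c(1.2, 1.3, 1.3)),
        sofa_renal  = list(mean = c(0.8, 1.1, 1.3), sd = c(1.1, 1.2, 1.2))
      ),
      cats = list(
        gender = list(levels = c("male", "female"),
                      prob = rbind(c(0.622, 0.378), c(0.592, 0.408), c(0.514, 0.486))),
        ethnicity = list(levels = c("white", "black", "latin", "asian", "others"),
                         prob = rbind(c(0.712, 0.057, 0.024, 0.014, 0.193),
                                      c(0.733, 0.088, 0.017, 0.020, 0.143),
                                      c(0.708, 0.114, 0.026, 0.040, 0.112))),
        admission_type = list(levels = c("elective", "emergency", "urgent"),
                              prob = rbind(c(0.110, 0.858, 0.032),
                                           c(0.055, 0.910, 0.036),
                                           c(0.035, 0.949, 0.016)))
      ),
      dose = list(mean = c(8449.7, 11299.9, 12667.3),
                  sd = c(6773.0, 7550.8, 6932.3), lo = 500, hi = 60000,
                  unit = "IU"),
      mech = list(beta_iaptt = 0.6, beta_age = 0.5, beta_creat = 8, beta_weight = -0.25,
                  center_iaptt = 42, center_age = 67, center_creat = 1.5, center_weight = 82,
                  w_ref = 82, anchor_normal = 90, halfwidth = c(12, 9, 7)),
      noise_sd = 22, dose_coefficient = 0.013,
      scheme = label_scheme("mimic")
    )
  } else if (dialect == "pumch") {
    list(
      class_mix = c(434, 754, 361) / 1549,
      cont = list(
        age          = list(mean = c(55.1, 57.8, 60.9), sd = c(15.9, 15.5, 14.9), lo = 18,  hi = 110),
        weight       = list(mean = c(68.1, 67.3, 66.5), sd = c(12.6, 12.2, 12.4), lo = 30,  hi = 150),
        initial_aptt = list(mean = c(29.5, 34.6, 39.4), sd = c(5.5, 5.8, 9.2),    lo = 12,  hi = 120),
        creatinine   = list(mean = c(107.4, 117.2, 128.0), sd = c(73.7, 78.7, 86.3), lo = 10, hi = 900),
        liver_enzyme = list(mean = c(45.1, 47.1, 55.7), sd = c(91.7, 104.5, 141.9), lo = 2, hi = 1500)
      ),
      sofa = list(
        sofa_coag   = list(mean = c(0.9, 1.0, 1.1), sd = c(0.9, 1.0, 1.0)),
        sofa_liver  = list(mean = c(0.6, 0.7, 0.8), sd = c(0.8, 0.9, 1.0)),
        sofa_cardio = list(mean = c(2.9, 3.0, 3.1), sd = c(1.6, 1.5, 1.5)),
        sofa_renal  = list(mean = c(0.5, 0.6, 0.8), sd = c(0.9, 1.0, 1.0))
      ),
      cats = list(
        gender = list(levels = c("male", "female"),
                      prob = rbind(c(0.590, 0.410), c(0.601, 0.399), c(0.618, 0.382)))
      ),
      dose = list(mean = c(7.5, 7.8, 9.6), sd = c(4.3, 4.4, 5.6),
                  lo = 0.5, hi = 60, unit = "IU/kg"),
      mech = list(beta_iaptt = 0.6, beta_age = 0.3, beta_creat = 0.05, beta_weight = -0.2,
                  center_iaptt = 34, center_age = 58, center_creat = 115, center_weight = 67,
                  w_ref = 67, anchor_normal = 40, halfwidth = c(2.5, 3.5, 6)),
      noise_sd = 8, dose_coefficient = 11.5,
      scheme = label_scheme("pumch")
    )
  } else {
    stop(sprintf("unknown dialect '%s'", dialect))
  }
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the per-class feature summaries (means/SDs, categorical
#' proportions) of the two source ICU populations and embed a monotone
#' dose-to-aPTT mechanism so that outcome labels are learnable and the
#' direction of a dose recommendation has ground truth.
#'
#' @param n_patients number of patients to generate (>= 1).
#' @param dialect `"mimic"` (dose in IU; gender, ethnicity and admission type
#'   present) or `"pumch"` (dose in IU/kg; gender only).
#' @param seed integer seed; fixes the whole cohort.
#' @param noise_sd aPTT measurement noise SD in seconds. The default per
#'   dialect is calibrated so that the Bayes accuracy of the band label given
#'   the observed features is about 0.95.
#' @param dose_coefficient mechanism slope scale, aPTT seconds per dose unit
#'   at the reference weight.
#' @param class_mix length-3 proportions (sub, normal, supra) summing to 1.
#' @param missing_sofa_rate probability in \[0,1) that any one SOFA sub-score
#'   is missing.
#' @param outlier_rate fraction in \[0,1) of patients given one implanted
#'   extreme recording error (a continuous feature multiplied by 10).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_patients, dialect = c("mimic", "pumch"),
                             seed = 1L, noise_sd = NULL,
                             dose_coefficient = NULL, class_mix = NULL,
                             missing_sofa_rate = 0.08, outlier_rate = 0.02) {
  dialect <- match.arg(dialect)
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1) {
    stop("n_patients must be a single number >= 1")
  }
  pars <- dialect_params(dialect)
  if (is.null(noise_sd)) noise_sd <- pars$noise_sd
  if (is.null(dose_coefficient)) dose_coefficient <- pars$dose_coefficient
  if (is.null(class_mix)) class_mix <- pars$class_mix
  if (length(class_mix) != 3 || abs(sum(class_mix) - 1) > 1e-9) {
    stop("class_mix must be 3 proportions summing to 1")
  }
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (missing_sofa_rate < 0 || missing_sofa_rate >= 1) stop("missing_sofa_rate must be in [0,1)")
  if (outlier_rate < 0 || outlier_rate >= 1) stop("outlier_rate must be in [0,1)")
  structure(list(n_patients = as.integer(n_patients), dialect = dialect,
                 seed = as.integer(seed), noise_sd = noise_sd,
                 dose_coefficient = dose_coefficient, class_mix = class_mix,
                 missing_sofa_rate = missing_sofa_rate,
                 outlier_rate = outlier_rate, params = pars),
            class = "generator_config")
}

# Mechanism intercept f(x): linear in baseline aPTT, age, creatinine and
# (negatively) weight around fixed centres, plus a dialect base constant.
mech_intercept <- function(m, base, iaptt, age, creat, weight) {
  base +
    m$beta_iaptt  * (iaptt  - m$center_iaptt) +
    m$beta_age    * (age    - m$center_age) +
    m$beta_creat  * (creat  - m$center_creat) +
    m$beta_weight * (weight - m$center_weight)
}

# Closed-form calibration of the per-class therapeutic-aPTT target centres.
# With slope g(x) = g0 * w_ref / weight the implied dose for target a* is
# (a* - f(x)) * weight / (g0 * w_ref), so
#   E[dose | class] = ((abar - fbar) * wbar - beta_w * wvar) / (g0 * w_ref)
# using truncated-normal moments. Solving for abar makes each class's mean
# implied dose equal the configured class dose mean; the base constant is
# anchored so the normal class centre sits at `anchor_normal`.
calibrate_targets <- function(config) {
  p <- config$params
  m <- p$mech
  g0 <- config$dose_coefficient
  fbar_nobase <- wbar <- wvar <- numeric(3)
  for (c in 1:3) {
    mom <- function(f) tnorm_stats(p$cont[[f]]$mean[c], p$cont[[f]]$sd[c],
                                   p$cont[[f]]$lo, p$cont[[f]]$hi)
    ia <- mom("initial_aptt"); ag <- mom("age"); cr <- mom("creatinine"); wt <- mom("weight")
    fbar_nobase[c] <- mech_intercept(m, 0, ia$mean, ag$mean, cr$mean, wt$mean)
    wbar[c] <- wt$mean
    wvar[c] <- wt$var
  }
  delta <- (g0 * m$w_ref * p$dose$mean + m$beta_weight * wvar) / wbar
  base <- m$anchor_normal - fbar_nobase[2] - delta[2]
  abar <- base + fbar_nobase + delta
  scheme <- p$scheme
  lo_edge <- c(0, scheme$sub_upper, scheme$normal_upper)
  hi_edge <- c(scheme$sub_upper, scheme$normal_upper, Inf)
  w <- m$halfwidth
  if (any(abar - w < lo_edge) || any(abar + w > hi_edge)) {
    stop("calibrated aPTT targets fall outside their label bands; adjust dose_coefficient or class_mix")
  }
  list(base = base, abar = abar, halfwidth = w)
}

#' Generate a seeded synthetic event-level cohort
#'
#' Each patient receives: static features drawn from class-conditional
#' truncated normals / multinomials; a hidden linear dose-response
#' `aPTT = intercept(x) + slope(x) * dose` whose intercept and slope are
#' deterministic functions of the observed features (slope is positive and
#' inversely proportional to weight, so the mechanism is strictly increasing
#' in dose); a total dose solved so the mechanism lands on a class-banded
#' target aPTT, delivered as 1-4 boluses within \[0, 8) h; one pre-dose aPTT
#' measurement at -1 h and hourly noisy measurements over \[8, 24\] h. The
#' per-class mean of the implied dose equals the configured class dose mean by
#' construction. A configured fraction of SOFA sub-scores is set missing and a
#' configured fraction of patients gets its recorded weight inflated x10 (an
#' implanted unit-entry recording error; the mechanism uses the uncorrupted
#' value, and the corrupted rows are flagged in `true_outlier_feature`).
#'
#' @param config a [generator_config()].
#' @return An object of class `hepadose_cohort`: a list with `patients` (static
#'   features plus hidden `true_*` mechanism columns retained for test
#'   oracles), `events` (long table: `patient_id`, `event_type` in dose/aptt,
#'   `time_h`, `value`) and `config`.
#' @examples
#' coh <- generate_cohort(generator_config(50, "mimic", seed = 7))
#' head(coh$patients)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  p <- config$params
  m <- p$mech
  n <- config$n_patients
  set.seed(config$seed)
  cal <- calibrate_targets(config)

  cls <- sample.int(3, n, replace = TRUE, prob = config$class_mix)

  cont <- list()
  for (f in names(p$cont)) {
    d <- p$cont[[f]]
    cont[[f]] <- rtnorm(n, d$mean[cls], d$sd[cls], d$lo, d$hi)
  }
  sofa <- list()
  for (f in names(p$sofa)) {
    d <- p$sofa[[f]]
    sofa[[f]] <- pmin(4L, pmax(0L, as.integer(round(stats::rnorm(n, d$mean[cls], d$sd[cls])))))
  }
  cats <- list()
  for (f in names(p$cats)) {
    d <- p$cats[[f]]
    u <- stats::runif(n)
    cum <- t(apply(d$prob, 1, cumsum))
    idx <- sapply(seq_len(n), function(i) 1L + sum(u[i] > cum[cls[i], ]))
    cats[[f]] <- d$levels[idx]
  }

  intercept <- mech_intercept(m, cal$base, cont$initial_aptt, cont$age,
                              cont$creatinine, cont$weight)
  slope <- config$dose_coefficient * m$w_ref / cont$weight
  target <- cal$abar[cls] + stats::runif(n, -1, 1) * cal$halfwidth[cls]
  dose <- pmin(p$dose$hi, pmax(p$dose$lo, (target - intercept) / slope))
  mech_aptt <- intercept + slope * dose

  # missing SOFA fields
  for (f in names(sofa)) {
    miss <- stats::runif(n) < config$missing_sofa_rate
    sofa[[f]][miss] <- NA_integer_
  }

  # implanted extreme recording errors (after the mechanism is fixed)
  outlier_feature <- rep(NA_character_, n)
  n_out <- round(n * config$outlier_rate)
  if (n_out > 0) {
    who <- sample.int(n, n_out)
    outlier_feature[who] <- "weight"
    cont$weight[who] <- cont$weight[who] * 10
  }

  patients <- data.frame(patient_id = seq_len(n), age = cont$age,
                         weight = cont$weight, gender = cats$gender,
                         stringsAsFactors = FALSE)
  if (config$dialect == "mimic") {
    patients$ethnicity <- cats$ethnicity
    patients$admission_type <- cats$admission_type
  }
  patients$creatinine <- cont$creatinine
  patients$liver_enzyme <- cont$liver_enzyme
  for (f in names(sofa)) patients[[f]] <- sofa[[f]]
  patients$true_class <- therapeutic_classes()[cls]
  patients$true_intercept <- intercept
  patients$true_slope <- slope
  patients$true_mech_aptt <- mech_aptt
  patients$true_outlier_feature <- outlier_feature

  # events: 1-4 boluses in [0, 8) summing to the total dose; aPTT at -1 h
  # (the initial value, noise-free by construction) and hourly on [8, 24]
  aptt_times <- 8:24
  ev <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample.int(4, 1)
    times <- c(0, sort(stats::runif(k - 1, 0.5, 7.9)))
    prop <- stats::runif(k, 0.2, 1)
    amounts <- dose[i] * prop / sum(prop)
    noise <- stats::rnorm(length(aptt_times), 0, config$noise_sd)
    ev[[i]] <- data.frame(
      patient_id = i,
      event_type = c(rep("dose", k), "aptt", rep("aptt", length(aptt_times))),
      time_h = c(times, -1, aptt_times),
      value = c(amounts, cont$initial_aptt[i], mech_aptt[i] + noise)
    )
  }
  events <- do.call(rbind, ev)

  structure(list(patients = patients, events = events, config = config,
                 calibration = cal, n_therapeutic_meas = length(aptt_times)),
            class = "hepadose_cohort")
}

#' @export
print.hepadose_cohort <- function(x, ...) {
  cat(sprintf("synthetic heparin cohort: %d patients, dialect '%s', seed %d\n",
              nrow(x$patients), x$config$dialect, x$config$seed))
  invisible(x)
}

#' Generative outcome probabilities under a counterfactual dose
#'
#' Returns the exact probability, under the generator's hidden mechanism, that
#' a patient's therapeutic aPTT (the mean of the noisy 8-24 h measurements)
#' falls in each outcome band if the total dose were `candidate_dose`. The
#' mean of `k` measurements with noise SD `s` is Gaussian around the mechanism
#' line with SD `s / sqrt(k)`; band probabilities are the corresponding normal
#' tail areas. This is the test oracle for the recommendation engine.
#'
#' @param record one row of the cohort `patients` table (must carry the hidden
#'   `true_intercept` / `true_slope` columns).
#' @param candidate_dose counterfactual total dose (native dose unit).
#' @param cohort the `hepadose_cohort` the record came from (supplies noise SD,
#'   measurement count and label scheme).
#' @return Named numeric vector of 3 probabilities summing to 1.
#' @export
oracle_probabilities <- function(record, candidate_dose, cohort) {
  stopifnot(inherits(cohort, "hepadose_cohort"))
  if (is.null(record$true_intercept) || is.null(record$true_slope) ||
      is.na(record$true_intercept) || is.na(record$true_slope)) {
    stop("record does not carry the hidden mechanism parameters")
  }
  scheme <- label_scheme(cohort$config$dialect)
  mu <- record$true_intercept + record$true_slope * candidate_dose
  se <- cohort$config$noise_sd / sqrt(cohort$n_therapeutic_meas)
  p_sub <- stats::pnorm(scheme$sub_upper, mu, se)
  p_norm <- stats::pnorm(scheme$normal_upper, mu, se) - p_sub
  p_sup <- 1 - p_sub - p_norm
  stats::setNames(c(p_sub, p_norm, p_sup), therapeutic_classes())
}

#' Write / read a cohort as delimited tables
#'
#' `write_cohort()` emits `patients.csv` (one row per patient, static features
#' plus the hidden `true_*` oracle columns), `events.csv` (long event table)
#' and `config.json` into `dir`; `read_cohort()` reconstructs the cohort.
#'
#' @param cohort a `hepadose_cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns a
#'   `hepadose_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hepadose_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"), row.names = FALSE)
  utils::write.csv(cohort$events, file.path(dir, "events.csv"), row.names = FALSE)
  cfg <- cohort$config
  cfg$params <- NULL
  jsonlite::write_json(c(cfg, list(n_therapeutic_meas = cohort$n_therapeutic_meas)),
                       file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- generator_config(cfg$n_patients, cfg$dialect, cfg$seed, cfg$noise_sd,
                             cfg$dose_coefficient, cfg$class_mix,
                             cfg$missing_sofa_rate, cfg$outlier_rate)
  patients <- utils::read.csv(file.path(dir, "patients.csv"), stringsAsFactors = FALSE)
  # an all-NA character column reads back as logical
  patients$true_outlier_feature <- as.character(patients$true_outlier_feature)
  events <- utils::read.csv(file.path(dir, "events.csv"), stringsAsFactors = FALSE)
  structure(list(patients = patients, events = events, config = config,
                 calibration = calibrate_targets(config),
                 n_therapeutic_meas = cfg$n_therapeutic_meas),
            class = "hepadose_cohort")
}
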