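# Fixture builders, all generated in code at test time.

# Minimal hand-built event-level cohort for inclusion/labelling tests.
# `patients` needs patient_id + age; `events` is the long event table.
make_mini_cohort <- function(patients, events, dialect = "mimic", noise_sd = 5) {
  cfg <- generator_config(max(1, nrow(patients)), dialect, seed = 1,
                          noise_sd = noise_sd)
  structure(list(patients = patients, events = events, config = cfg,
                 n_therapeutic_meas = 17),
            class = "hepadose_cohort")
}

std_events <- function(id, dose_times = 0, dose_values = 5000,
                       aptt_times = c(-1, 8:24), aptt_values = NULL) {
  if (is.null(aptt_values)) aptt_values <- rep(70, length(aptt_times))
  data.frame(
    patient_id = id,
    event_type = c(rep("dose", length(dose_times)), rep("aptt", length(aptt_times))),
    time_h = c(dose_times, aptt_times),
    value = c(dose_values, aptt_values)
  )
}

# Preprocessing fixture with uniform feature draws: the clean rows can never
# exceed the 3-sigma bounds (a uniform variate is at most ~1.73 SDs from its
# mean), so implanted x10 inflations are the only removable outliers.
make_uniform_fixture <- function(n = 100, n_outliers = 3, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    patient_id = seq_len(n),
    weight = runif(n, 60, 100),
    initial_aptt = runif(n, 25, 55),
    creatinine = runif(n, 0.8, 2.2),
    liver_enzyme = runif(n, 0.9, 2.5),
    total_dose = runif(n, 4000, 16000)
  )
  implanted <- sample(n, n_outliers)
  df$weight[implanted] <- df$weight[implanted] * 10
  list(rows = df, implanted = sort(implanted))
}

# Small linearly separable 3-class dataset shaped like a hepadose_dataset.
# Features are kept strictly positive so f1 can stand in for a dose column.
make_toy_dataset <- function(n_per_class = 100, seed = 1, sep = 3) {
  set.seed(seed)
  centers <- matrix(c(2, 2, 2 + sep, 2, 2, 2 + sep), ncol = 2, byrow = TRUE)
  rows <- do.call(rbind, lapply(1:3, function(c) {
    data.frame(f1 = pmax(0.01, rnorm(n_per_class, centers[c, 1], 0.4)),
               f2 = pmax(0.01, rnorm(n_per_class, centers[c, 2], 0.4)),
               label = therapeutic_classes()[c])
  }))
  rows$label <- factor(rows$label, levels = therapeutic_classes())
  structure(list(
    rows = rows,
    schema = list(dialect = "mimic", features = c("f1", "f2"),
                  continuous = c("f1", "f2"), groups = list(),
                  vocab = list(), dose = "f1"),
    report = list()
  ), class = "hepadose_dataset")
}

# Shared standard synthetic cohort/dataset for the heavier acceptance checks:
# built once per test run and memoised in the testthat environment.
standard_dataset <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 3600, seed = 42) {
    key <- paste0("d", n, "_", seed)
    if (is.null(cache[[key]])) {
      coh <- generate_cohort(generator_config(n, "mimic", seed = seed))
      cache[[key]] <- list(cohort = coh, dataset = preprocess_cohort(coh))
    }
    cache[[key]]
  }
})
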