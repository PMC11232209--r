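#' AWGS 2019 sarcopenia screening
#'
#' Applies the Asian Working Group for Sarcopenia 2019 cut-offs to a
#' subject table. Low muscle mass: ASMI < 7.0 kg/m2 (men) / < 5.7 kg/m2
#' (women); low strength: grip < 28 kg (men) / < 18 kg (women); low
#' performance: gait speed < 1.0 m/s. All comparisons are strict, so
#' boundary values are not low. Sarcopenia is low mass plus low strength
#' and/or low performance; all three flags give severe sarcopenia;
#' strength or performance deficits without low mass are labelled
#' `possible_low_function` and are not sarcopenia.
#'
#' @param subjects Tibble with columns `id`, `sex` ("male"/"female"),
#'   `asmi` (kg/m2), `grip` (kg, best of trials) and `pace` (m/s, mean
#'   walking speed). Derive `grip`/`pace` with [derive_outcome_metrics()]
#'   if you have raw trials.
#' @return The input with `low_mass`, `low_strength`, `low_performance`
#'   and `category` (none / possible_low_function / sarcopenia /
#'   severe_sarcopenia) columns appended.
#' @export
#' @examples
#' screen_awgs(tibble::tibble(id = 1, sex = "male", asmi = 6.5,
#'                            grip = 25, pace = 0.9))
screen_awgs <- function(subjects) {
  subjects <- as_tibble(subjects)
  need <- c("sex", "asmi", "grip", "pace")
  miss <- setdiff(need, names(subjects))
  na_cols <- if (length(miss) == 0) {
    need[colSums(is.na(subjects[need])) > 0]
  } else character()
  if (length(miss) > 0 || length(na_cols) > 0) {
    stop_rehab(paste0("incomplete record(s); missing: ",
                      paste(unique(c(miss, na_cols)), collapse = ", ")),
               "rehabpose_incomplete_record_error")
  }
  if (!all(subjects$sex %in% c("male", "female"))) {
    stop_rehab("sex must be 'male' or 'female'", "rehabpose_parameter_error")
  }
  subjects |>
    mutate(
      low_mass = .data$asmi < ifelse(.data$sex == "male", 7.0, 5.7),
      low_strength = .data$grip < ifelse(.data$sex == "male", 28, 18),
      low_performance = .data$pace < 1.0,
      category = awgs_category(.data$low_mass, .data$low_strength, .data$low_performance)
    )
}

# pure function of the three flags; the full truth table is asserted in tests
awgs_category <- function(low_mass, low_strength, low_performance) {
  dplyr::case_when(
    low_mass & low_strength & low_performance ~ "severe_sarcopenia",
    low_mass & (low_strength | low_performance) ~ "sarcopenia",
    !low_mass & (low_strength | low_performance) ~ "possible_low_function",
    .default = "none"
  )
}

#' Derive the outcome battery from raw trial measurements
#'
#' Scoring rules of the assessment battery: grip strength is the best of
#' the repeated dynamometer trials; walking pace is the mean of per-trial
#' speeds (distance / time), reported to two decimal places; BMI is
#' weight / height^2. Timed-up-and-go and the SF-36 aggregate pass through
#' unchanged.
#'
#' @param record A list or one-row tibble with `height` (m), `weight` (kg),
#'   `grip_trials` (numeric vector, kg), `walk_trials` (tibble with
#'   `distance` m and `time` s), and optionally `tugt` (s) and `sf36`.
#' @return A one-row tibble: `grip`, `pace`, `bmi`, `tugt`, `sf36`.
#' @export
derive_outcome_metrics <- function(record) {
  grip_trials <- record$grip_trials
  if (is.list(grip_trials) && !is.data.frame(grip_trials)) grip_trials <- grip_trials[[1]]
  walk <- record$walk_trials
  if (is.list(walk) && !is.data.frame(walk)) walk <- walk[[1]]
  if (length(grip_trials) < 1 || is.null(walk) || nrow(walk) < 2) {
    stop_rehab("need >= 1 grip trial and >= 2 walk trials", "rehabpose_incomplete_record_error")
  }
  if (any(walk$time <= 0)) {
    stop_rehab("walk trial with non-positive time", "rehabpose_measurement_error")
  }
  check_number(record$height, "height", lo = 0, strict_lo = TRUE)
  check_number(record$weight, "weight", lo = 0, strict_lo = TRUE)
  pace <- round2(mean(walk$distance / walk$time), 2)
  tibble(
    grip = max(grip_trials),
    pace = pace,
    bmi = round2(record$weight / record$height^2, 2),
    tugt = record$tugt %||% NA_real_,
    sf36 = record$sf36 %||% NA_real_
  )
}

# round half up (commercial rounding), as measurement protocols expect,
# rather than R's round-half-even
round2 <- function(x, digits) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Trial eligibility check
#'
#' Eligible subjects are aged 60--75 (inclusive), screen as sarcopenia or
#' severe sarcopenia under AWGS 2019, and trip none of the configured
#' exclusion flags. Every failed criterion is reported.
#'
#' @param subjects Screened subject tibble ([screen_awgs()] output with an
#'   `age` column; optional logical exclusion columns).
#' @param exclusion_flags Names of logical columns that exclude when TRUE
#'   (e.g. musculoskeletal medication, neurological disorder, prior Taichi
#'   practice).
#' @return Input with `eligible` (logical) and `reasons` (character;
#'   semicolon-separated failed criteria, empty when eligible).
#' @export
check_eligibility <- function(subjects, exclusion_flags = character()) {
  subjects <- as_tibble(subjects)
  stopifnot(all(c("age", "category") %in% names(subjects)))
  miss <- setdiff(exclusion_flags, names(subjects))
  if (length(miss) > 0) {
    stop_rehab(paste0("unknown exclusion flag column(s): ", paste(miss, collapse = ", ")),
               "rehabpose_config_error")
  }
  reasons <- pmap(subjects, function(...) {
    row <- list(...)
    r <- character()
    if (row$age < 60 || row$age > 75) r <- c(r, "age")
    if (!row$category %in% c("sarcopenia", "severe_sarcopenia")) r <- c(r, "AWGS criteria")
    for (fl in exclusion_flags) if (isTRUE(row[[fl]])) r <- c(r, fl)
    r
  })
  subjects |>
    mutate(eligible = map_lgl(reasons, ~ length(.x) == 0),
           reasons = map_chr(reasons, paste, collapse = "; "))
}

#' Sex-stratified randomization
#'
#' Within each sex stratum, draws a seeded uniform random number per
#' subject, sorts the stratum by these numbers and deals subjects to the
#' `k` groups round-robin, so within-stratum group sizes differ by at most
#' one and the allocation is reproducible from the seed.
#'
#' @param subjects Tibble with `id` and `sex`.
#' @param k Number of groups (>= 2).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param group_labels Optional length-`k` labels (default "group_1", ...).
#' @return Input with a `group` column appended.
#' @export
randomize_stratified <- function(subjects, k = 3, seed, group_labels = NULL) {
  check_number(k, "k", lo = 2)
  if (missing(seed)) stop_rehab("a seed is required", "rehabpose_parameter_error")
  subjects <- as_tibble(subjects)
  labels <- group_labels %||% paste0("group_", seq_len(k))
  stopifnot(length(labels) == k)
  rng <- local({ set.seed(seed); stats::runif(nrow(subjects)) })
  small <- subjects |> count(.data$sex) |> filter(.data$n < k)
  if (nrow(small) > 0) {
    warn(sprintf("stratum '%s' has fewer subjects than groups", small$sex[1]))
  }
  subjects |>
    mutate(.rand = rng) |>
    group_by(.data$sex) |>
    arrange(.data$.rand, .by_group = TRUE) |>
    mutate(group = labels[(row_number() - 1L) %% k + 1L]) |>
    ungroup() |>
    arrange(match(.data$id, subjects$id)) |>
    select(-".rand")
}

#' Build the intervention session schedule
#'
#' The 12-week programme has three sessions per week of 40 minutes each
#' (10-minute warm-up, 5-minute cool-down), in two stages: a basic
#' movement-learning stage over weeks 1--4 and an intensive practice stage
#' over weeks 5--12.
#'
#' @param weeks Number of weeks (default 12).
#' @param per_week Sessions per week (default 3).
#' @param session_minutes,warmup,cooldown Durations in minutes.
#' @param stage1_weeks Last week of stage 1 (default 4).
#' @return Tibble of `weeks * per_week` sessions with `week`,
#'   `index_in_week`, `session`, `stage`, `duration`, `warmup`, `cooldown`.
#' @export
build_schedule <- function(weeks = 12, per_week = 3, session_minutes = 40,
                           warmup = 10, cooldown = 5, stage1_weeks = 4) {
  for (nm in c("weeks", "per_week", "session_minutes", "warmup", "cooldown")) {
    check_number(get(nm), nm, lo = 0, strict_lo = nm %in% c("weeks", "per_week", "session_minutes"))
  }
  tidyr::expand_grid(week = seq_len(weeks), index_in_week = seq_len(per_week)) |>
    mutate(session = row_number(),
           stage = ifelse(.data$week <= stage1_weeks, 1L, 2L),
           duration = session_minutes, warmup = warmup, cooldown = cooldown)
}

#' Read a subject table from CSV
#'
#' One row per subject; columns as expected by [screen_awgs()] and
#' [check_eligibility()].
#'
#' @param path CSV file.
#' @return A tibble.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop_rehab(sprintf("no such file: %s", path), "rehabpose_io_error")
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
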