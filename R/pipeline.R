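#' Map stimulus side to intact/missing hand per subject
#'
#' Recodes left/right stimulus sides into the hand frame used throughout the
#' analysis: for one-handed subjects the side of the absent hand maps to
#' "missing"; for two-handed controls the non-dominant side maps to "missing"
#' and the dominant side to "intact". The same recoding is applied to the
#' response when a `response` column is present.
#'
#' @param trials Tibble of trial records with `subject_id`, `stimulus_side`
#'   (`"left"`/`"right"`) and optionally `response`
#'   (`"left"`/`"right"`/`"none"`).
#' @param subjects Tibble with one row per subject: `subject_id`, `group`,
#'   and `dominant_side` (controls) or `missing_side` (one-handed groups).
#' @return `trials` with added `stimulus_hand` and (when applicable)
#'   `response_hand` columns in `{"intact", "missing"}`.
#' @export
map_hands <- function(trials, subjects) {
  stopifnot(all(c("subject_id", "stimulus_side") %in% names(trials)))
  stopifnot(all(c("subject_id", "group") %in% names(subjects)))
  if (!"dominant_side" %in% names(subjects)) subjects$dominant_side <- NA_character_
  if (!"missing_side" %in% names(subjects)) subjects$missing_side <- NA_character_

  missing_side <- ifelse(
    subjects$group == "controls",
    other_side(subjects$dominant_side),
    subjects$missing_side
  )
  bad <- subjects$subject_id[is.na(missing_side)]
  if (length(bad))
    stop("missing handedness metadata for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  side_map <- stats::setNames(missing_side, subjects$subject_id)

  unknown <- setdiff(unique(trials$subject_id), names(side_map))
  if (length(unknown))
    stop("missing handedness metadata for subject(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  ms <- unname(side_map[as.character(trials$subject_id)])
  trials$stimulus_hand <- ifelse(trials$stimulus_side == ms, "missing", "intact")
  if ("response" %in% names(trials)) {
    trials$response_hand <- dplyr::case_when(
      trials$response == "none" ~ NA_character_,
      trials$response == ms ~ "missing",
      TRUE ~ "intact"
    )
  }
  trials
}

other_side <- function(x) {
  ifelse(x == "left", "right", ifelse(x == "right", "left", NA_character_))
}

#' Filter invalid trials and report exclusion rates
#'
#' Drops trials flagged as noisy recordings and trials without a response,
#' and reports per-subject rates. Subjects whose no-response rate reaches
#' `max_no_response` (default 0.27, the rate at which a participant is
#' considered unusable) are flagged for exclusion but not removed; removal is
#' the caller's decision.
#'
#' @param trials Tibble with `subject_id`, `response` and `noisy_recording`.
#' @param max_no_response No-response rate at or above which a subject is
#'   flagged.
#' @return A list: `trials` (valid trials only) and `report`, a per-subject
#'   tibble with `n_trials`, `noisy_rate`, `no_response_rate` and `flagged`.
#' @export
filter_trials <- function(trials, max_no_response = 0.27) {
  stopifnot(all(c("subject_id", "response", "noisy_recording") %in% names(trials)))
  report <- trials |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      noisy_rate = mean(.data$noisy_recording),
      no_response_rate = mean(.data$response == "none"),
      .groups = "drop"
    ) |>
    dplyr::mutate(flagged = .data$no_response_rate >= max_no_response)
  valid <- dplyr::filter(trials, !.data$noisy_recording, .data$response != "none")
  list(trials = valid, report = report)
}

#' Log-transform RTs and trim outliers per subject and condition
#'
#' Restricts to correct trials (only those enter the RT analysis), applies a
#' natural-log transform, and removes trials whose log RT deviates more than
#' `sd_limit` standard deviations from the subject's mean, separately for
#' each condition (by default stimulus hand crossed with difficulty). The
#' trim is a single pass: means and SDs are not recomputed after removal.
#' Cells with fewer than 3 trials are left untrimmed with a warning.
#'
#' @param trials Tibble with `subject_id`, `rt`, `correct` and the condition
#'   columns.
#' @param condition Character vector of condition column names.
#' @param sd_limit Trim limit in SD units (default 3).
#' @return A list: `trials` (correct trials that survived the trim, with a
#'   `log_rt` column) and `report` (per subject: trials entering, trials
#'   trimmed).
#' @export
log_trim_rt <- function(trials, condition = c("stimulus_hand", "difficulty"),
                        sd_limit = 3) {
  stopifnot(all(c("subject_id", "rt", "correct") %in% names(trials)))
  missing_cond <- setdiff(condition, names(trials))
  if (length(missing_cond))
    stop("condition column(s) not found: ",
         paste(missing_cond, collapse = ", "), call. = FALSE)

  dat <- trials |>
    dplyr::filter(.data$correct) |>
    dplyr::mutate(log_rt = log(.data$rt))

  dat <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("subject_id", condition)))) |>
    dplyr::mutate(
      .n_cell = dplyr::n(),
      .dev = abs(.data$log_rt - mean(.data$log_rt)),
      .sd = sd(.data$log_rt)
    ) |>
    dplyr::ungroup()

  if (any(dat$.n_cell < 3))
    warning("condition cell(s) with fewer than 3 trials left untrimmed",
            call. = FALSE)

  keep <- dat$.n_cell < 3 | is.na(dat$.sd) | dat$.sd == 0 |
    dat$.dev <= sd_limit * dat$.sd

  report <- dat |>
    dplyr::mutate(.trimmed = !keep) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_correct = dplyr::n(), n_trimmed = sum(.data$.trimmed),
                     .groups = "drop")

  list(
    trials = dat[keep, setdiff(names(dat), c(".n_cell", ".dev", ".sd"))],
    report = report
  )
}

#' Assign easy/hard difficulty from an independent reference group
#'
#' Computes a per-image central RT (the median of correct-trial RTs across
#' all reference subjects) and splits the images at the median of those
#' per-image values: images at or below the median are "easy", the rest
#' "hard". Ties at the median therefore fall on the easy side; with 48
#' distinct per-image values this yields a 24/24 split.
#'
#' @param reference_trials Tibble of reference-group trials with `image_id`,
#'   `rt` and `correct` (and `response` if no-response trials are present).
#' @param image_ids Images that must be covered; defaults to those present.
#' @return A tibble (`image_id`, `ref_rt`, `difficulty`) ordered by
#'   `image_id`.
#' @export
assign_difficulty <- function(reference_trials, image_ids = NULL) {
  stopifnot(all(c("image_id", "rt", "correct") %in% names(reference_trials)))
  dat <- dplyr::filter(reference_trials, .data$correct, !is.na(.data$rt))
  if (is.null(image_ids)) image_ids <- sort(unique(reference_trials$image_id))
  per_image <- dat |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(ref_rt = median(.data$rt), .groups = "drop")
  absent <- setdiff(image_ids, per_image$image_id)
  if (length(absent))
    stop("no reference trials for image(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  per_image <- per_image[match(image_ids, per_image$image_id), ]
  cut <- median(per_image$ref_rt)
  per_image$difficulty <- ifelse(per_image$ref_rt <= cut, "easy", "hard")
  per_image
}

#' Signal-detection indices per subject
#'
#' Treats "the intact hand was shown" as the signal: a hit is responding
#' "intact" to an intact-hand image and a false alarm is responding "intact"
#' to a missing-hand image. Returns d' = z(H) - z(F) and criterion
#' c = -(z(H) + z(F)) / 2, so a positive c indicates a tendency to
#' over-report "missing hand". Extreme rates are corrected by the 1/(2N)
#' rule: 0 becomes 1/(2N) and 1 becomes 1 - 1/(2N), with N the number of
#' signal (or noise) trials.
#'
#' @param trials Valid trials of one subject, with `stimulus_hand` and
#'   `response_hand` in `{"intact", "missing"}`.
#' @return A one-row tibble: `hit_rate`, `false_alarm_rate`, `d_prime`,
#'   `criterion_c`, `n_signal`, `n_noise`.
#' @examples
#' sdt_from_rates(0.69, 0.31, 100, 100) # d' ~ 0.99, c ~ 0
#' @export
sdt_indices <- function(trials) {
  stopifnot(all(c("stimulus_hand", "response_hand") %in% names(trials)))
  sig <- trials$stimulus_hand == "intact"
  n_signal <- sum(sig)
  n_noise <- sum(!sig)
  if (n_signal == 0 || n_noise == 0)
    stop("need at least one signal (intact) and one noise (missing) trial",
         call. = FALSE)
  h <- mean(trials$response_hand[sig] == "intact")
  f <- mean(trials$response_hand[!sig] == "intact")
  sdt_from_rates(h, f, n_signal, n_noise)
}

#' @rdname sdt_indices
#' @param hit_rate,false_alarm_rate Raw rates in \[0, 1\].
#' @param n_signal,n_noise Trial counts behind each rate (used by the 1/(2N)
#'   extreme-rate correction).
#' @export
sdt_from_rates <- function(hit_rate, false_alarm_rate, n_signal, n_noise) {
  clamp <- function(p, n) pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  h <- clamp(hit_rate, n_signal)
  f <- clamp(false_alarm_rate, n_noise)
  tibble::tibble(
    hit_rate = h,
    false_alarm_rate = f,
    d_prime = qnorm(h) - qnorm(f),
    criterion_c = -(qnorm(h) + qnorm(f)) / 2,
    n_signal = n_signal,
    n_noise = n_noise
  )
}

#' Phantom motor control score
#'
#' The motor task asks for five finger-thumb opposition cycles; its score is
#' the average time per cycle. Supply either the five per-cycle durations or
#' the total time for all five.
#'
#' @param cycles Numeric vector of 5 cycle durations in seconds.
#' @param total Total duration of the five cycles in seconds (used when only
#'   the total was recorded).
#' @return Mean cycle time in seconds.
#' @examples
#' motor_task_score(total = 90.3) # 18.06
#' @export
motor_task_score <- function(cycles = NULL, total = NULL) {
  if (is.null(cycles) == is.null(total))
    stop("supply exactly one of `cycles` or `total`", call. = FALSE)
  if (!is.null(cycles)) {
    if (length(cycles) != 5 || anyNA(cycles))
      stop("`cycles` must be 5 non-missing durations", call. = FALSE)
    mean(cycles)
  } else {
    if (length(total) != 1 || is.na(total))
      stop("`total` must be a single non-missing duration", call. = FALSE)
    total / 5
  }
}

#' Compound prosthesis-usage score
#'
#' Standardises the activity-log rating and the wear-time rating within the
#' cohort (z-transform) and sums them per subject.
#'
#' @param pal_rating Numeric vector of prosthesis activity-log ratings.
#' @param wear_time_rating Numeric vector of wear-time ratings (same
#'   subjects, same order).
#' @return Numeric vector of compound scores (cohort mean 0).
#' @export
prosthesis_score <- function(pal_rating, wear_time_rating) {
  stopifnot(length(pal_rating) == length(wear_time_rating))
  if (anyNA(pal_rating) || anyNA(wear_time_rating))
    stop("ratings must not contain missing values", call. = FALSE)
  if (sd(pal_rating) == 0 || sd(wear_time_rating) == 0)
    stop("zero variance in a rating; compound score undefined", call. = FALSE)
  as.numeric(scale(pal_rating)) + as.numeric(scale(wear_time_rating))
}

#' Subject-level summaries and outlier flags
#'
#' Runs the full chain on a mapped trial table: validity filtering, accuracy
#' per condition, log-RT trimming, mean log RT of surviving correct trials,
#' and a per-condition subject outlier flag (deviation of more than
#' `sd_limit` SDs from the group mean, a reporting flag rather than an
#' automatic exclusion).
#'
#' @param trials Trial table after [map_hands()], with a `difficulty` column.
#' @param max_no_response Passed to [filter_trials()].
#' @param sd_limit Trim / outlier limit in SD units.
#' @return A list: `summary` (subject x hand x difficulty accuracy, mean log
#'   RT, counts, trims), `sdt` (per-subject [sdt_indices()]), `exclusions`
#'   (the [filter_trials()] report) and `outliers` (subject x condition
#'   flags).
#' @export
summarize_subjects <- function(trials, max_no_response = 0.27, sd_limit = 3) {
  stopifnot(all(c("subject_id", "group", "stimulus_hand", "difficulty",
                  "response_hand", "rt", "noisy_recording", "response")
                %in% names(trials)))
  flt <- filter_trials(trials, max_no_response = max_no_response)
  valid <- flt$trials |>
    dplyr::mutate(correct = .data$response_hand == .data$stimulus_hand)

  acc <- valid |>
    dplyr::group_by(.data$subject_id, .data$group, .data$stimulus_hand,
                    .data$difficulty) |>
    dplyr::summarise(n_valid = dplyr::n(), accuracy = mean(.data$correct),
                     .groups = "drop")

  trim <- log_trim_rt(valid, condition = c("stimulus_hand", "difficulty"),
                      sd_limit = sd_limit)
  rts <- trim$trials |>
    dplyr::group_by(.data$subject_id, .data$stimulus_hand, .data$difficulty) |>
    dplyr::summarise(n_rt = dplyr::n(), mean_log_rt = mean(.data$log_rt),
                     .groups = "drop")
  summary <- acc |>
    dplyr::left_join(rts, by = c("subject_id", "stimulus_hand", "difficulty")) |>
    dplyr::left_join(trim$report, by = "subject_id") |>
    dplyr::arrange(.data$subject_id, .data$stimulus_hand, .data$difficulty)

  sdt <- valid |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::group_modify(~ sdt_indices(.x)) |>
    dplyr::ungroup()

  outliers <- summary |>
    dplyr::group_by(.data$group, .data$stimulus_hand, .data$difficulty) |>
    dplyr::mutate(
      acc_outlier = abs(.data$accuracy - mean(.data$accuracy)) >
        sd_limit * sd(.data$accuracy),
      rt_outlier = abs(.data$mean_log_rt - mean(.data$mean_log_rt)) >
        sd_limit * sd(.data$mean_log_rt)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("subject_id", "group", "stimulus_hand",
                                  "difficulty", "acc_outlier", "rt_outlier")))

  list(summary = summary, sdt = sdt, exclusions = flt$report,
       outliers = outliers)
}
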