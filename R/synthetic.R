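#' Specification of a synthetic behavioural cohort
#'
#' Defines the study conditions emulated by [generate_cohort()]: three groups
#' (21 two-handed controls, 16 amputees, 17 congenital one-handers), two
#' blocks of 48 hand images (24 postures, each mirrored into a left and a
#' right version), an easy/hard posture split with an RT inflation for hard
#' postures, noisy-recording and no-response contamination, and amputee
#' covariates (phantom motor control times coupled to mean laterality RT at a
#' target rank correlation, age at amputation, prosthesis-usage ratings).
#'
#' Trials are generated from the racing-simulator model itself: controls and
#' amputees use the two-simulator architecture, congenital one-handers the
#' single-simulator architecture with the lower threshold. Amputees
#' additionally carry a subject-level RT slowdown multiplier coupled to their
#' phantom motor time through a Gaussian copula, so that the configured
#' Spearman correlation between the two is achieved in expectation.
#'
#' @param n_controls,n_amputees,n_congenital Group sizes (0 to omit a group,
#'   otherwise at least 2).
#' @param n_blocks Experimental blocks; each presents every image once.
#' @param n_image_pairs Mirrored posture pairs (each contributes a left and a
#'   right image).
#' @param hard_pairs Indices of pairs whose postures are hard.
#' @param hard_inflation Multiplicative RT inflation for hard postures.
#' @param params Base [simulator_params()] shared by all architectures
#'   (controls boundary separation taken from here; see [architecture()] for
#'   why the published half-separation 0.17 appears as 0.34 here).
#' @param congenital_threshold Boundary separation of the single congenital
#'   simulator (published half-separation 0.138, i.e. 0.276).
#' @param noisy_rate Probability a trial is flagged as a noisy recording.
#' @param no_response_mean,no_response_max Mean and per-subject maximum of
#'   the no-response rate; subject rates are drawn from a scaled Beta with
#'   this mean on `[0, no_response_max]`.
#' @param subject_sdlog SD (log scale) of the subject RT multiplier.
#' @param trial_sdlog SD (log scale) of multiplicative trial RT noise.
#' @param phantom_target_rho Target Spearman correlation between amputees'
#'   phantom motor time and their mean laterality RT, in (-1, 1).
#' @param phantom_meanlog,phantom_sdlog Log-normal parameters of the phantom
#'   motor time (seconds; defaults span the observed 9-230 s range).
#' @param amputation_age_range Uniform range of age at amputation (years).
#' @param p_left_dominant Probability a control is left-hand dominant.
#' @param p_right_missing Probability a one-hander's missing side is right.
#' @param max_rt Display limit in seconds; generated RTs beyond it become
#'   no-response trials.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_controls = 21, n_amputees = 16, n_congenital = 17,
                        n_blocks = 2, n_image_pairs = 24,
                        hard_pairs = 13:24, hard_inflation = 1.25,
                        params = simulator_params(threshold = 0.34),
                        congenital_threshold = 0.276,
                        noisy_rate = 0.028,
                        no_response_mean = 0.02, no_response_max = 0.104,
                        subject_sdlog = 0.2, trial_sdlog = 0.1,
                        phantom_target_rho = 0.7,
                        phantom_meanlog = log(20), phantom_sdlog = 0.7,
                        amputation_age_range = c(17, 45),
                        p_left_dominant = 1 / 3, p_right_missing = 0.25,
                        max_rt = 5) {
  spec <- structure(as.list(environment()), class = "cohort_spec")
  for (g in c("n_controls", "n_amputees", "n_congenital")) {
    if (spec[[g]] != 0 && spec[[g]] < 2)
      stop("`", g, "` must be 0 or at least 2", call. = FALSE)
  }
  for (r in c("noisy_rate", "no_response_mean", "no_response_max")) {
    if (spec[[r]] < 0 || spec[[r]] > 1)
      stop("`", r, "` must lie in [0, 1]", call. = FALSE)
  }
  if (spec$no_response_mean >= spec$no_response_max)
    stop("`no_response_mean` must be below `no_response_max`", call. = FALSE)
  if (abs(spec$phantom_target_rho) >= 1)
    stop("`phantom_target_rho` must lie in (-1, 1)", call. = FALSE)
  validate_simulator_params(spec$params)
  spec
}

#' Generate a synthetic cohort
#'
#' Draws a full trial-level cohort from a [cohort_spec()]: per-subject
#' handedness metadata and covariates, then per-trial responses and RTs from
#' the group's racing-simulator architecture, with hard-posture inflation,
#' subject and trial RT noise, display-limit censoring, and injected
#' noisy-recording and no-response contamination.
#'
#' @param spec A `cohort_spec`.
#' @param seed Master seed; with the same seed and spec the cohort is
#'   reproduced exactly. `NULL` uses the ambient RNG state.
#' @return A list with `trials` (one row per trial: `subject_id`, `group`,
#'   `block`, `image_id`, `stimulus_side`, `response`, `rt`,
#'   `noisy_recording`), `subjects` (metadata and covariates) and `truth`
#'   (the spec, seed, difficulty map and hidden per-subject parameters).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_controls = 2, n_amputees = 2,
#'                                       n_congenital = 2), seed = 1)
#' dplyr::count(cohort$trials, group)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(seed)) generate_cohort_impl(spec, NULL)
  else withr::with_seed(seed, generate_cohort_impl(spec, seed))
}

generate_cohort_impl <- function(spec, seed) {
  sides <- c("left", "right")
  pair_ids <- seq_len(spec$n_image_pairs)
  image_grid <- expand.grid(pair = pair_ids, side = sides,
                            stringsAsFactors = FALSE)
  image_grid$image_id <- sprintf("p%02d_%s", image_grid$pair, image_grid$side)
  difficulty_map <- tibble::tibble(
    image_id = image_grid$image_id,
    pair = image_grid$pair,
    difficulty = ifelse(image_grid$pair %in% spec$hard_pairs, "hard", "easy")
  ) |> dplyr::arrange(.data$image_id)

  groups <- rep(c("controls", "amputees", "congenital"),
                c(spec$n_controls, spec$n_amputees, spec$n_congenital))
  prefix <- c(controls = "C", amputees = "A", congenital = "G")
  ids <- stats::ave(seq_along(groups), groups, FUN = seq_along)
  subject_id <- sprintf("%s%02d", prefix[groups], ids)
  n_sub <- length(groups)

  is_control <- groups == "controls"
  dominant_side <- ifelse(
    is_control, ifelse(runif(n_sub) < spec$p_left_dominant, "left", "right"),
    NA_character_)
  missing_side <- ifelse(
    !is_control, ifelse(runif(n_sub) < spec$p_right_missing, "right", "left"),
    NA_character_)

  # subject RT multiplier; amputees are coupled to phantom motor time through
  # a Gaussian copula so rank correlation with mean laterality RT hits target
  z1 <- rnorm(n_sub)
  multiplier <- exp(spec$subject_sdlog * z1)
  phantom <- rep(NA_real_, n_sub)
  amp <- groups == "amputees"
  if (any(amp)) {
    r_pearson <- 2 * sin(pi * spec$phantom_target_rho / 6)
    z2 <- r_pearson * z1[amp] + sqrt(1 - r_pearson^2) * rnorm(sum(amp))
    phantom[amp] <- exp(spec$phantom_meanlog + spec$phantom_sdlog * z2)
  }

  age <- round(runif(n_sub, 25, 60))
  age_at_amputation <- ifelse(
    amp, pmin(round(runif(n_sub, spec$amputation_age_range[1],
                          spec$amputation_age_range[2])), age - 1),
    NA_real_)
  one_handed <- !is_control
  pal_rating <- ifelse(one_handed, round(rnorm(n_sub, 50, 15), 1), NA_real_)
  wear_time_rating <- ifelse(one_handed, round(rnorm(n_sub, 5, 2), 1), NA_real_)
  b_shape <- spec$no_response_max / spec$no_response_mean - 1
  no_response_rate <- spec$no_response_max * stats::rbeta(n_sub, 1, b_shape)

  subjects <- tibble::tibble(
    subject_id, group = groups, dominant_side, missing_side, age,
    age_at_amputation, phantom_motor_rt = phantom, pal_rating,
    wear_time_rating
  )

  arch_two <- architecture("controls", spec$params)
  arch_one <- architecture("congenital", spec$params,
                           threshold = spec$congenital_threshold)

  trial_list <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    miss <- if (is_control[i]) other_side(dominant_side[i]) else missing_side[i]
    tr <- expand.grid(block = seq_len(spec$n_blocks), pair = pair_ids,
                      side = sides, stringsAsFactors = FALSE)
    tr <- tr[order(tr$block, runif(nrow(tr))), ] # random order within block
    tr$image_id <- sprintf("p%02d_%s", tr$pair, tr$side)
    tr$stimulus_hand <- ifelse(tr$side == miss, "missing", "intact")
    tr$hard <- tr$pair %in% spec$hard_pairs
    n_tr <- nrow(tr)

    arch <- if (groups[i] == "congenital") arch_one else arch_two
    out <- tr
    out$response_hand <- NA_character_
    out$rt_model <- NA_real_
    for (h in c("intact", "missing")) {
      idx <- which(tr$stimulus_hand == h)
      sim <- run_trials(arch, h, n = length(idx))
      out$response_hand[idx] <- sim$response_hand
      out$rt_model[idx] <- sim$rt
    }

    rt_obs <- out$rt_model * multiplier[i] *
      ifelse(out$hard, spec$hard_inflation, 1) *
      exp(rnorm(n_tr, 0, spec$trial_sdlog))
    no_resp <- rt_obs > spec$max_rt | runif(n_tr) < no_response_rate[i]
    response <- ifelse(
      no_resp, "none",
      ifelse(out$response_hand == "missing", miss, other_side(miss)))

    trial_list[[i]] <- tibble::tibble(
      subject_id = subject_id[i],
      group = groups[i],
      block = out$block,
      image_id = out$image_id,
      stimulus_side = out$side,
      response = response,
      rt = ifelse(no_resp, NA_real_, rt_obs),
      noisy_recording = runif(n_tr) < spec$noisy_rate
    )
  }

  list(
    trials = dplyr::bind_rows(trial_list),
    subjects = subjects,
    truth = list(
      spec = spec, seed = seed, difficulty_map = difficulty_map,
      subject_truth = tibble::tibble(subject_id,
                                     rt_multiplier = multiplier,
                                     no_response_rate)
    )
  )
}

#' A small fixed worked example
#'
#' A deterministic 3-subject, 12-trial-per-subject table whose accuracy,
#' trimming, exclusion and signal-detection outcomes can be computed by hand,
#' for exact regression tests:
#'
#' * `S1` (right-dominant control): 12 valid trials, 10 correct, hit rate 5/6
#'   and false-alarm rate 1/6.
#' * `S2` (left-missing amputee): 12 correct trials; 11 RTs of 0.8 s and one
#'   of 8 s, so per-subject log-RT trimming removes exactly that trial.
#' * `S3` (right-missing congenital): 4 of 12 trials without a response
#'   (33 percent, above the 27 percent exclusion threshold) and one noisy
#'   trial.
#'
#' @return A list with `trials` and `subjects` tibbles.
#' @export
worked_fixture <- function() {
  side6 <- rep(c("left", "right"), each = 6)
  img <- sprintf("i%02d_%s", rep(1:6, 2), side6)
  difficulty <- rep(rep(c("easy", "hard"), 3), 2) # pairs 1,3,5 easy; 2,4,6 hard

  # S1: right-dominant control; left images = missing, right = intact.
  # Responds "right" (intact) on 5/6 right images (H = 5/6) and on 1/6 left
  # images (F = 1/6): 10 of 12 correct.
  s1_resp <- c("left", "left", "left", "left", "left", "right",
               "right", "right", "right", "right", "right", "left")
  s1 <- tibble::tibble(
    subject_id = "S1", group = "controls", block = 1L, image_id = img,
    stimulus_side = side6, difficulty,
    response = s1_resp,
    rt = c(0.82, 0.74, 0.91, 1.05, 0.68, 1.32,
           0.71, 0.66, 0.88, 0.95, 1.10, 1.21),
    noisy_recording = FALSE
  )

  # S2: left-missing amputee, all 12 correct; one extreme RT outlier (8 s).
  s2 <- tibble::tibble(
    subject_id = "S2", group = "amputees", block = 1L, image_id = img,
    stimulus_side = side6, difficulty,
    response = side6,
    rt = c(rep(0.8, 5), 8, rep(0.8, 6)),
    noisy_recording = FALSE
  )

  # S3: right-missing congenital; 4 no-response trials, 1 noisy trial.
  s3_resp <- c("left", "left", "none", "left", "none", "right",
               "right", "none", "right", "none", "left", "right")
  s3 <- tibble::tibble(
    subject_id = "S3", group = "congenital", block = 1L, image_id = img,
    stimulus_side = side6, difficulty,
    response = s3_resp,
    rt = ifelse(s3_resp == "none", NA_real_,
                c(0.9, 1.1, NA, 1.3, NA, 1.0, 1.2, NA, 0.95, NA, 1.4, 1.15)),
    noisy_recording = c(rep(FALSE, 11), TRUE)
  )

  subjects <- tibble::tibble(
    subject_id = c("S1", "S2", "S3"),
    group = c("controls", "amputees", "congenital"),
    dominant_side = c("right", NA, NA),
    missing_side = c(NA, "left", "right")
  )

  list(trials = dplyr::bind_rows(s1, s2, s3), subjects = subjects)
}
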