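small_spec <- function(...) {
  cohort_spec(n_controls = 4, n_amputees = 4, n_congenital = 4, ...)
}

test_that("a cohort regenerates byte-identically from its master seed", {
  a <- generate_cohort(small_spec(), seed = 5)
  b <- generate_cohort(a$truth$spec, seed = a$truth$seed)
  expect_identical(a$trials, b$trials)
  expect_identical(a$subjects, b$subjects)
})

test_that("cohort structure matches the study design", {
  ch <- generate_cohort(small_spec(), seed = 6)
  expect_equal(nrow(ch$trials), 12 * 2 * 48)
  expect_equal(dplyr::n_distinct(ch$trials$image_id), 48)
  # every image shown once per block per subject
  per <- dplyr::count(ch$trials, subject_id, block, image_id)
  expect_true(all(per$n == 1))
  # mirrored pairs share a difficulty class
  dm <- ch$truth$difficulty_map
  expect_true(all(tapply(dm$difficulty, dm$pair,
                         function(d) length(unique(d)) == 1)))
  # half of each subject's trials map to each hand
  mapped <- map_hands(ch$trials, ch$subjects)
  counts <- dplyr::count(mapped, subject_id, stimulus_hand)
  expect_true(all(counts$n == 48))
  # amputees carry phantom and amputation-age covariates, others do not
  amp <- ch$subjects$group == "amputees"
  expect_false(anyNA(ch$subjects$phantom_motor_rt[amp]))
  expect_true(all(is.na(ch$subjects$phantom_motor_rt[!amp])))
  expect_true(all(ch$subjects$age_at_amputation[amp] < ch$subjects$age[amp]))
})

test_that("contamination rates recover their configured values", {
  rates <- vapply(1:10, function(s) {
    ch <- generate_cohort(small_spec(), seed = 100 + s)
    c(mean(ch$trials$noisy_recording), mean(ch$trials$response == "none"))
  }, numeric(2))
  expect_lt(abs(mean(rates[1, ]) - 0.028), 0.005)
  # injected no-response mean 0.02, plus rare display-limit censoring
  expect_gt(mean(rates[2, ]), 0.005)
  expect_lt(mean(rates[2, ]), 0.06)
  # per-subject realised rates stay near the configured [0, 0.104] band
  ch <- generate_cohort(cohort_spec(), seed = 200)
  per <- filter_trials(ch$trials)$report
  expect_true(all(per$no_response_rate <= 0.104 + 3 * sqrt(0.104 * 0.896 / 96)))
})

test_that("an unbiased noise-free cohort judges both hands equally well", {
  spec <- cohort_spec(
    n_controls = 10, n_amputees = 0, n_congenital = 0,
    params = simulator_params(threshold = 0.34, start_bias = 0),
    noisy_rate = 0, no_response_mean = 1e-6, no_response_max = 1e-3,
    subject_sdlog = 0, trial_sdlog = 0, hard_inflation = 1
  )
  ch <- generate_cohort(spec, seed = 7)
  mapped <- map_hands(ch$trials, ch$subjects)
  acc <- mapped |>
    dplyr::filter(response != "none") |>
    dplyr::group_by(stimulus_hand) |>
    dplyr::summarise(acc = mean(response_hand == stimulus_hand), n = dplyr::n())
  se <- sqrt(sum(acc$acc * (1 - acc$acc) / acc$n))
  expect_lt(abs(diff(acc$acc)), 4 * se)
})

test_that("the phantom copula couples motor control to laterality RT", {
  rho <- vapply(1:20, function(s) {
    ch <- generate_cohort(cohort_spec(n_controls = 0, n_congenital = 0),
                          seed = 300 + s)
    mapped <- map_hands(ch$trials, ch$subjects)
    mrt <- mapped |>
      dplyr::filter(!noisy_recording, response != "none",
                    response_hand == stimulus_hand) |>
      dplyr::group_by(subject_id) |>
      dplyr::summarise(m = mean(rt))
    j <- dplyr::inner_join(mrt, ch$subjects, by = "subject_id")
    cor(j$m, j$phantom_motor_rt, method = "spearman")
  }, numeric(1))
  # population target 0.7; compare to the expected sample Spearman at n = 16
  expect_lt(abs(mean(rho) - expected_sample_spearman(0.7, 16)),
            3 * sd(rho) / sqrt(length(rho)) + 0.03)
  expect_error(cohort_spec(phantom_target_rho = 1), "phantom_target_rho")
})

test_that("the generating threshold is recovered from a low-noise cohort", {
  spec <- cohort_spec(
    n_controls = 0, n_amputees = 0, n_congenital = 17,
    noisy_rate = 0, no_response_mean = 1e-6, no_response_max = 1e-3,
    subject_sdlog = 0, trial_sdlog = 0, hard_inflation = 1
  )
  ch <- generate_cohort(spec, seed = 8)
  mapped <- map_hands(ch$trials, ch$subjects)
  tgt <- mapped |>
    dplyr::filter(response != "none") |>
    dplyr::mutate(correct = response_hand == stimulus_hand) |>
    dplyr::group_by(stimulus_hand) |>
    dplyr::summarise(accuracy = mean(correct),
                     mean_rt_correct = mean(rt[correct]), .groups = "drop")
  fit <- fit_parameters(tgt, list(threshold = c(0.2, 0.276, 0.35)),
                        group = "congenital", n_per_hand = 2000, seed = 8)
  expect_equal(fit$best$threshold, 0.276)
})

test_that("the worked fixture reproduces its hand-computed outcomes", {
  fx <- worked_fixture()
  expect_identical(fx$trials, worked_fixture()$trials)

  mapped <- map_hands(fx$trials, fx$subjects)
  valid <- filter_trials(mapped)$trials
  s1 <- valid[valid$subject_id == "S1", ]
  expect_equal(mean(s1$response_hand == s1$stimulus_hand), 10 / 12)

  sdt1 <- sdt_indices(s1)
  expect_equal(sdt1$d_prime, qnorm(5 / 6) - qnorm(1 / 6), tolerance = 1e-10)
  expect_equal(sdt1$criterion_c, -(qnorm(5 / 6) + qnorm(1 / 6)) / 2,
               tolerance = 1e-10)

  # S2's single 8 s response is the only trial trimmed
  s2 <- valid[valid$subject_id == "S2", ]
  s2$correct <- s2$response_hand == s2$stimulus_hand
  trim <- log_trim_rt(s2, condition = character(0))
  expect_equal(trim$report$n_trimmed, 1)
  expect_false(8 %in% trim$trials$rt)

  expect_true(filter_trials(mapped)$report$flagged[3])
})
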