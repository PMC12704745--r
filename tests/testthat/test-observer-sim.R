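test_that("simulation is deterministic given the seed and leaves RNG state alone", {
  dsg <- design_spec(asynchrony_levels_ms = c(18L, 52L),
                     trials_per_condition = 30L, n_subjects = 3L)
  obs <- sdt_observer(dprime = c(0.5, 1.2), dprime_sd = 0.1, logm_sd = 0.2)
  a <- simulate_sdt_dataset(dsg, obs, seed = 11)
  b <- simulate_sdt_dataset(dsg, obs, seed = 11)
  c <- simulate_sdt_dataset(dsg, obs, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, c))

  set.seed(99); x1 <- rnorm(3)
  set.seed(99); invisible(simulate_sdt_dataset(dsg, obs, seed = 5)); x2 <- rnorm(3)
  expect_identical(x1, x2)
})

test_that("output follows the standard trial schema", {
  tr <- sim_sdt_quick(1, 50, seed = 2)
  expect_named(tr, c("subject", "experiment", "asynchrony_ms", "n_touches",
                     "sync_side", "response_side", "pas",
                     "rt_decision_s", "rt_postdecision_s", "censored"))
  expect_true(all(tr$pas %in% 1:3))
  expect_true(all(tr$sync_side %in% c("left", "right")))
  expect_true(all(tr$rt_decision_s >= 0))
  expect_no_error(validate_trials(tr))
})

test_that("a chance observer responds at chance", {
  tr <- sim_sdt_quick(0, 4000, seed = 3)
  acc <- mean(tr$sync_side == tr$response_side)
  expect_lt(abs(acc - 0.5), 0.03)
})

test_that("fitted d' increases with generative d'", {
  dsg <- design_spec(asynchrony_levels_ms = c(18L, 52L, 150L),
                     trials_per_condition = 2000L, n_subjects = 1L)
  tr <- simulate_sdt_dataset(dsg, sdt_observer(dprime = c(0.2, 0.8, 1.5)),
                             seed = 7)
  fit <- fit_sdt(tr)
  fit <- fit[order(fit$asynchrony_ms), ]
  expect_true(all(diff(fit$dprime) > 0))
  expect_lt(max(abs(fit$dprime - c(0.2, 0.8, 1.5))), 0.15)
})

test_that("full lapsing abolishes discrimination regardless of d'", {
  tr <- sim_sdt_quick(3, 4000, seed = 4, lapse_rate = 1)
  acc <- mean(tr$sync_side == tr$response_side)
  expect_lt(abs(acc - 0.5), 0.03)
})

test_that("inclusion_filter applies the ownership questionnaire rule", {
  # clear illusion: ownership mean 2, control mean 0.5
  expect_true(inclusion_filter(c(2, 2, 2, rep(0.5, 6))))
  # ownership mean must exceed 1: exactly 1 fails
  expect_false(inclusion_filter(c(1, 1, 1, rep(-1, 6))))
  # difference must exceed 1: exactly 1 fails
  expect_false(inclusion_filter(c(2, 2, 2, rep(1, 6))))
  # data-frame input, one row per participant
  q <- tibble::as_tibble(as.list(setNames(rep(2, 9), paste0("Q", 1:9))))
  q <- dplyr::bind_rows(q, dplyr::mutate(q, Q4 = 0, Q5 = 0, Q6 = 0,
                                         Q7 = 0, Q8 = 0, Q9 = 0))
  expect_identical(inclusion_filter(q), c(FALSE, TRUE))
  # malformed input
  expect_error(inclusion_filter(1:5), class = "metaown_validation_error")
  expect_error(inclusion_filter(tibble::tibble(Q1 = 1)),
               class = "metaown_validation_error")
  expect_error(inclusion_filter(c(NA, rep(1, 8))),
               class = "metaown_validation_error")
})

test_that("invalid configurations are rejected with config errors", {
  expect_error(design_spec(asynchrony_levels_ms = c(52, 18)),
               class = "metaown_config_error")
  expect_error(design_spec(asynchrony_levels_ms = -5),
               class = "metaown_config_error")
  expect_error(design_spec(trials_per_condition = 0),
               class = "metaown_config_error")
  expect_error(sdt_observer(dprime = -1), class = "metaown_config_error")
  expect_error(sdt_observer(dprime = 1, mratio = 0),
               class = "metaown_config_error")
  expect_error(sdt_observer(dprime = 1, type2_criteria = c(0.5, -1)),
               class = "metaown_config_error")
  expect_error(sdt_observer(dprime = 1, lapse_rate = 1.5),
               class = "metaown_config_error")
  expect_error(ddm_observer(v = 1, a = -1), class = "metaown_config_error")
  expect_error(ddm_observer(v = 1, w = 1.2), class = "metaown_config_error")
  expect_error(ddm_observer(v = 1, confidence_cutpoints = c(1, 0)),
               class = "metaown_config_error")
  dsg <- design_spec(asynchrony_levels_ms = c(18L, 52L))
  expect_error(simulate_sdt_dataset(dsg, sdt_observer(dprime = c(1, 1, 1)),
                                    seed = 1),
               class = "metaown_config_error")
  expect_error(sim_sdt_quick(1, 10, seed = NA),
               class = "metaown_config_error")
})

test_that("diffusion simulation is deterministic and respects censoring", {
  obs <- ddm_observer(v = c(0.8, 1.5), a = 1.6, t0 = 0.3)
  a <- simulate_ddm_trials(obs, 200, seed = 21,
                           asynchrony_levels_ms = c(18L, 150L))
  b <- simulate_ddm_trials(obs, 200, seed = 21,
                           asynchrony_levels_ms = c(18L, 150L))
  expect_identical(a, b)
  expect_true(all(a$rt_decision_s > obs$t0))
  # a tight stimulation limit forces censoring flags
  cen <- simulate_ddm_trials(ddm_observer(v = 0.01, a = 4), 200, seed = 22,
                             asynchrony_levels_ms = 52L,
                             max_stim_duration_s = 0.05)
  expect_true(any(cen$censored))
  expect_true(all(cen$rt_decision_s[cen$censored] >= 0.05))
})
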