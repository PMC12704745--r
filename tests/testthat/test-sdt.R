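test_that("dprime_2afc matches the quantile formula on a known table", {
  cnt <- counts_from_cells(84, 16, 16, 84)
  res <- dprime_2afc(cnt)
  expect_equal(res$dprime, (qnorm(0.84) - qnorm(0.16)) / sqrt(2),
               tolerance = 1e-10)
  expect_equal(res$criterion_c, 0, tolerance = 1e-10)
  expect_false(res$correction_applied)
  # yes/no convention drops the 1/sqrt(2)
  expect_equal(dprime_2afc(cnt, scale = "yesno")$dprime,
               qnorm(0.84) - qnorm(0.16), tolerance = 1e-10)
})

test_that("dprime_2afc agrees with a brute-force recount on random trials", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 200
    tr <- tibble::tibble(
      subject = 1L, experiment = "t", asynchrony_ms = 52L, n_touches = 6L,
      sync_side = sample(c("left", "right"), n, TRUE),
      response_side = sample(c("left", "right"), n, TRUE, prob = c(0.4, 0.6)),
      pas = sample(1:3, n, TRUE),
      rt_decision_s = 1, rt_postdecision_s = 1, censored = FALSE)
    res <- dprime_2afc(tabulate_counts(tr))
    # oracle: recount by hand
    h_n <- sum(tr$sync_side == "right" & tr$response_side == "right")
    m_n <- sum(tr$sync_side == "right" & tr$response_side == "left")
    f_n <- sum(tr$sync_side == "left" & tr$response_side == "right")
    c_n <- sum(tr$sync_side == "left" & tr$response_side == "left")
    h <- h_n / (h_n + m_n); f <- f_n / (f_n + c_n)
    if (h %in% c(0, 1) || f %in% c(0, 1)) {
      h <- (h_n + 0.5) / (h_n + m_n + 1); f <- (f_n + 0.5) / (f_n + c_n + 1)
    }
    expect_equal(res$dprime, (qnorm(h) - qnorm(f)) / sqrt(2), tolerance = 1e-12)
    expect_equal(res$criterion_c, -(qnorm(h) + qnorm(f)) / 2, tolerance = 1e-12)
  }
})

test_that("relabelling the sides preserves d' and flips the criterion", {
  tr <- sim_sdt_quick(1, 400, seed = 33, criterion_c = 0.3)
  flip <- function(x) ifelse(x == "left", "right", "left")
  tr2 <- dplyr::mutate(tr, sync_side = flip(sync_side),
                       response_side = flip(response_side))
  a <- dprime_2afc(tabulate_counts(tr))
  b <- dprime_2afc(tabulate_counts(tr2))
  expect_equal(b$dprime, a$dprime, tolerance = 1e-12)
  expect_equal(b$criterion_c, -a$criterion_c, tolerance = 1e-12)
})

test_that("d' is monotone in the hit rate and antitone in the false-alarm rate", {
  base <- dprime_2afc(counts_from_cells(60, 40, 30, 70))$dprime
  expect_gt(dprime_2afc(counts_from_cells(70, 30, 30, 70))$dprime, base)
  expect_lt(dprime_2afc(counts_from_cells(60, 40, 40, 60))$dprime, base)
})

test_that("extreme rates trigger the log-linear correction", {
  res <- dprime_2afc(counts_from_cells(50, 0, 10, 40))
  expect_true(res$correction_applied)
  expect_true(is.finite(res$dprime))
  expect_equal(res$p_hit, 50.5 / 51, tolerance = 1e-12)
})

test_that("degenerate tables and malformed trials are rejected", {
  tr <- trials_from_array(array(c(0L, 0L, 0L, 0L, 10L, 0L, 10L, 0L,
                                  0L, 0L, 0L, 0L),
                                dim = c(2, 2, 3),
                                dimnames = list(stimulus = c("left", "right"),
                                                response = c("left", "right"),
                                                rating = 1:3)))
  # only left-synchronous trials present
  tr <- tr[tr$sync_side == "left", ]
  expect_error(dprime_2afc(tabulate_counts(tr)),
               class = "metaown_estimation_error")

  bad <- sim_sdt_quick(1, 20, seed = 1)
  bad$pas[7] <- 4L
  expect_error(validate_trials(bad), regexp = "row 7",
               class = "metaown_validation_error")
  bad2 <- sim_sdt_quick(1, 20, seed = 1)
  bad2$response_side[3] <- "up"
  expect_error(validate_trials(bad2), regexp = "row 3",
               class = "metaown_validation_error")
  bad3 <- sim_sdt_quick(1, 20, seed = 1)
  bad3$rt_decision_s[5] <- -1
  expect_error(validate_trials(bad3), class = "metaown_validation_error")
})

test_that("fit_sdt returns one row per subject x condition", {
  dsg <- design_spec(asynchrony_levels_ms = c(18L, 52L),
                     trials_per_condition = 40L, n_subjects = 4L)
  tr <- simulate_sdt_dataset(dsg, sdt_observer(dprime = c(0.5, 1)), seed = 9)
  fit <- fit_sdt(tr)
  expect_equal(nrow(fit), 8)
  expect_setequal(unique(fit$subject), 1:4)
  expect_setequal(unique(fit$asynchrony_ms), c(18L, 52L))
})

test_that("censored trials are excluded from counts", {
  tr <- sim_sdt_quick(1, 100, seed = 44)
  tr$censored[1:10] <- TRUE
  expect_equal(tabulate_counts(tr)$n_trials, 90)
})
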