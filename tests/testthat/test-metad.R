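test_that("conditional rating probabilities sum to one per stimulus", {
  p <- metaown:::metad_probs(1.3, 0.2, c(-0.3, -0.9), c(0.7, 1.4))
  for (s in 1:2) {
    expect_equal(sum(p[s, "left", ]) + sum(p[s, "right", ]), 2,
                 tolerance = 1e-9) # each response side is itself conditional
    expect_equal(sum(p[s, "left", ]), 1, tolerance = 1e-9)
    expect_equal(sum(p[s, "right", ]), 1, tolerance = 1e-9)
  }
  expect_true(all(p >= 0))
})

test_that("metad_loglik rejects mis-ordered criteria", {
  cnt <- tabulate_counts(sim_sdt_quick(1, 200, seed = 5))
  expect_identical(metad_loglik(cnt, 1, c(0.5, 0.2), c(0.5, 1)), -Inf)
  expect_true(is.finite(metad_loglik(cnt, 1, c(-0.4, -0.9), c(0.4, 0.9))))
})

test_that("an ideal rater recovers M-ratio near 1", {
  cnt <- tabulate_counts(sim_sdt_quick(1.4, 8000, seed = 6, mratio = 1))
  fit <- fit_metad(cnt)
  expect_true(fit$converged)
  expect_lt(abs(fit$mratio - 1), 0.1)
  # reported meta-d' uses the same convention as d'
  expect_equal(fit$meta_dprime / fit$dprime, fit$mratio, tolerance = 1e-9)
})

test_that("shuffling ratings across trials destroys metacognitive sensitivity", {
  tr <- sim_sdt_quick(1.4, 8000, seed = 8, mratio = 1)
  set.seed(81)
  tr$pas <- sample(tr$pas) # pairing with accuracy destroyed
  fit <- fit_metad(tabulate_counts(tr))
  expect_lt(abs(fit$meta_dprime), 0.15)
})

test_that("fit_metad matches the profile-likelihood grid oracle", {
  set.seed(61)
  for (i in 1:3) {
    tr <- sim_sdt_quick(runif(1, 0.5, 1.5), 400, seed = 600 + i,
                        mratio = runif(1, 0.5, 1.2),
                        criterion_c = runif(1, -0.2, 0.2))
    cnt <- tabulate_counts(tr)
    fit <- fit_metad(cnt)
    oracle <- metad_grid_oracle(cnt)
    expect_lt(abs(fit$log_likelihood - oracle$ll), 1e-3)
    expect_lt(abs(fit$meta_dprime * sqrt(2) - oracle$md), 0.02)
  }
})

test_that("the reported optimum dominates perturbed parameter sets", {
  cnt <- tabulate_counts(sim_sdt_quick(1.2, 500, seed = 62))
  fit <- fit_metad(cnt)
  md <- fit$meta_dprime * sqrt(2)
  ll_at <- function(md) {
    metad_loglik(cnt, md,
                 t2_lower = c(fit$t2_low_inner, fit$t2_low_outer),
                 t2_upper = c(fit$t2_high_inner, fit$t2_high_outer))
  }
  # consistency: the reported likelihood is reproduced by metad_loglik
  expect_equal(ll_at(md), fit$log_likelihood, tolerance = 1e-6)
  # optimality along the meta-d' axis (criteria near-optimal at the optimum)
  expect_gte(fit$log_likelihood + 1e-6, ll_at(md + 0.2))
  expect_gte(fit$log_likelihood + 1e-6, ll_at(md - 0.2))
})

test_that("fit_metad validates its inputs", {
  cnt <- tabulate_counts(sim_sdt_quick(1, 100, seed = 63))
  expect_error(fit_metad(cnt, n_ratings = 4),
               class = "metaown_validation_error")
})

test_that("fit_metad_by returns one row per subject x condition", {
  dsg <- design_spec(asynchrony_levels_ms = c(18L, 150L),
                     trials_per_condition = 120L, n_subjects = 3L)
  tr <- simulate_sdt_dataset(dsg, sdt_observer(dprime = c(0.6, 1.2)), seed = 64)
  fit <- fit_metad_by(tr)
  expect_equal(nrow(fit), 6)
  expect_true(all(c("dprime", "meta_dprime", "mratio") %in% names(fit)))
  expect_true(all(is.finite(fit$mratio)))
})
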