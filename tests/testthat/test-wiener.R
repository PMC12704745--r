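test_that("the density vanishes at or before the nondecision time", {
  d <- wiener_fpt_density(c(0, 0.1, 0.3, 0.30001), "upper",
                          v = 1, a = 1.5, w = 0.5, t0 = 0.3)
  expect_identical(d[1:3], c(0, 0, 0))
  expect_gte(d[4], 0)
})

test_that("boundary densities obey the reflection symmetry", {
  t <- seq(0.05, 3, by = 0.05)
  up <- wiener_fpt_density(t, "upper", v = 0.8, a = 1.4, w = 0.35)
  lo <- wiener_fpt_density(t, "lower", v = -0.8, a = 1.4, w = 0.65)
  expect_equal(up, lo, tolerance = 1e-10)
})

test_that("zero drift and central start point give symmetric halves", {
  t <- seq(0.01, 5, by = 0.01)
  up <- wiener_fpt_density(t, "upper", v = 0, a = 1.5, w = 0.5)
  lo <- wiener_fpt_density(t, "lower", v = 0, a = 1.5, w = 0.5)
  expect_equal(up, lo, tolerance = 1e-12)
  p_up <- integrate(function(t) wiener_fpt_density(t, "upper", 0, 1.5, 0.5),
                    0, Inf, rel.tol = 1e-9)$value
  expect_equal(p_up, 0.5, tolerance = 1e-5)
})

test_that("each boundary integrates to the analytic choice probability", {
  cases <- list(c(v = 1.2, a = 1.5, w = 0.5), c(v = 0.4, a = 2.2, w = 0.3),
                c(v = -0.9, a = 1.1, w = 0.6))
  for (cs in cases) {
    p_up <- integrate(function(t) {
      wiener_fpt_density(t, "upper", cs["v"], cs["a"], cs["w"])
    }, 0, Inf, rel.tol = 1e-9, subdivisions = 500L)$value
    p_lo <- integrate(function(t) {
      wiener_fpt_density(t, "lower", cs["v"], cs["a"], cs["w"])
    }, 0, Inf, rel.tol = 1e-9, subdivisions = 500L)$value
    oracle <- upper_prob_oracle(cs["v"], cs["a"], cs["w"])
    expect_equal(p_up, unname(oracle), tolerance = 1e-4)
    expect_equal(unname(choice_probability(cs["v"], cs["a"], cs["w"])),
                 unname(oracle), tolerance = 1e-10)
    expect_equal(p_up + p_lo, 1, tolerance = 1e-4)
  }
})

test_that("choice_probability limits behave", {
  expect_equal(choice_probability(0, 1.5, 0.35), 0.35)
  expect_gt(choice_probability(8, 1.5, 0.5), 0.999)
  expect_lt(choice_probability(-8, 1.5, 0.5), 0.001)
  expect_equal(choice_probability(-1.1, 1.4, 0.45),
               1 - choice_probability(1.1, 1.4, 0.55), tolerance = 1e-12)
  expect_error(choice_probability(1, -1, 0.5), class = "metaown_config_error")
  expect_error(wiener_fpt_density(1, "upper", 1, 1.5, w = 1.5),
               class = "metaown_config_error")
})

test_that("the density matches a Euler-simulated first-passage histogram", {
  # modest simulation; boundaries are widened by the standard half-order
  # continuity correction for discrete-time crossing detection
  v <- 1.5; a <- 1.2; w <- 0.5; dt <- 1e-4; n <- 50000
  set.seed(91)
  sim <- metaown:::.euler_ddm_cpp(rep(v, n), a, w, dt, 10)
  eps <- 0.5826 * sqrt(dt)
  a_eff <- a + 2 * eps; w_eff <- (w * a + eps) / a_eff
  up <- sim[sim[, 2] == 1 & sim[, 3] == 0, 1]
  breaks <- c(seq(0, 1.2, by = 0.1), Inf)
  emp <- as.vector(table(cut(up, breaks))) / n
  theo <- vapply(seq_len(length(breaks) - 1), function(i) {
    integrate(function(t) wiener_fpt_density(t, "upper", v, a_eff, w_eff),
              breaks[i], min(breaks[i + 1], 60),
              rel.tol = 1e-8)$value
  }, numeric(1))
  se <- sqrt(pmax(theo * (1 - theo), 1e-8) / n)
  expect_true(all(abs(emp - theo) < 5 * se + 5e-4))
})
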