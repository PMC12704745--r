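# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("a single integer `seed` is required.", class = "metaown_config_error")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

# truncated standard-normal-with-mean sample: X ~ N(mu, 1) | X > lo (or X < hi)
rtruncnorm_above <- function(n, mu, lo) {
  p <- pnorm(lo - mu)
  qnorm(p + runif(n) * (1 - p)) + mu
}
rtruncnorm_below <- function(n, mu, hi) {
  p <- pnorm(hi - mu)
  qnorm(runif(n) * p) + mu
}

#' Simulate a 2AFC body-ownership experiment with PAS ratings
#'
#' Generates trial-level data from the equal-variance SDT observer described
#' in [sdt_observer()]. On each trial one hand is tapped synchronously
#' (`sync_side`); type-1 evidence `x ~ N(+/- D/2, 1)` with internal separation
#' `D = sqrt(2) * dprime` (so that the fitted 2AFC d' recovers `dprime`) is
#' compared with the criterion `C` to give the response. A second Gaussian
#' evidence sample with separation `mratio * D`, drawn on the response side of
#' the proportionally scaled criterion, is cut into PAS 1-3. Lapse trials
#' (probability `lapse_rate`) give a uniform random response and a rating from
#' stimulus-independent noise.
#'
#' @param design a [design_spec()].
#' @param params an [sdt_observer()]; `dprime` of length 1 or one per design
#'   condition.
#' @param seed integer; the simulation is deterministic given the seed.
#' @param experiment label written into the `experiment` column.
#' @return tibble with one row per trial and columns `subject`, `experiment`,
#'   `asynchrony_ms`, `n_touches`, `sync_side`, `response_side`, `pas`,
#'   `rt_decision_s`, `rt_postdecision_s`, `censored`.
#' @export
simulate_sdt_dataset <- function(design, params, seed, experiment = "exp1") {
  stopifnot(inherits(design, "design_spec"), inherits(params, "sdt_observer"))
  conds <- design_conditions(design)
  k <- nrow(conds)
  dp <- params$dprime
  if (length(dp) == 1) dp <- rep(dp, k)
  if (length(dp) != k) {
    abort(paste0("`dprime` has ", length(dp), " values but the design has ",
                 k, " conditions."), class = "metaown_config_error")
  }
  with_seed(seed, {
    subjects <- purrr::map(seq_len(design$n_subjects), function(s) {
      # symmetric subject variation; truncating at zero would bias a
      # chance-level observer's mean sensitivity upward
      dps <- dp + rnorm(k, 0, params$dprime_sd)
      m_s <- params$mratio * exp(rnorm(1, 0, params$logm_sd))
      trials <- conds[rep(seq_len(k), each = design$trials_per_condition), ]
      n <- nrow(trials)
      D <- sqrt(2) * dps[rep(seq_len(k), each = design$trials_per_condition)]
      d_stim <- ifelse(runif(n) < 0.5, 1, -1)           # +1: right hand synchronous
      x <- rnorm(n, d_stim * D / 2, 1)
      resp_right <- x > params$criterion_c
      # lapses: uniform response
      lapse <- runif(n) < params$lapse_rate
      resp_right[lapse] <- runif(sum(lapse)) < 0.5
      # metacognitive layer
      md1 <- m_s * D
      c1m <- m_s * params$criterion_c
      mu2 <- d_stim * md1 / 2
      x2 <- numeric(n)
      iR <- which(resp_right & !lapse); iL <- which(!resp_right & !lapse)
      x2[iR] <- rtruncnorm_above(length(iR), mu2[iR], c1m)
      x2[iL] <- rtruncnorm_below(length(iL), mu2[iL], c1m)
      x2[lapse] <- rnorm(sum(lapse), c1m, 1)            # stimulus-independent
      o <- params$type2_criteria
      pas <- ifelse(resp_right,
                    1L + (x2 > c1m + o[1]) + (x2 > c1m + o[1] + o[2]),
                    1L + (x2 < c1m - o[1]) + (x2 < c1m - o[1] - o[2]))
      trials |>
        mutate(subject = s,
               experiment = experiment,
               sync_side = ifelse(d_stim > 0, "right", "left"),
               response_side = ifelse(resp_right, "right", "left"),
               pas = as.integer(pas),
               rt_decision_s = pmin(3, exp(rnorm(n, log(1.1), 0.3))),
               rt_postdecision_s = pmin(3, exp(rnorm(n, log(0.8), 0.3))),
               censored = FALSE)
    })
    bind_rows(subjects) |>
      select("subject", "experiment", "asynchrony_ms", "n_touches",
             "sync_side", "response_side", "pas",
             "rt_decision_s", "rt_postdecision_s", "censored")
  })
}
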