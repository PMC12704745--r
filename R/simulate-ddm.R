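#' Simulate speeded 2AFC trials from a diffusion observer
#'
#' Decision stage: a Wiener process with diffusion scale 1, boundaries 0 and
#' `a`, start `w * a`, and drift signed by the synchronously tapped side, is
#' integrated by Euler-Maruyama steps of `dt` (1 ms by default) until
#' absorption; the upper boundary maps to a "right" response. Paths not
#' absorbed by `max_stim_duration_s` are emitted with `censored = TRUE`.
#' Post-decision stage: evidence keeps accumulating for the trial's
#' post-decision interval with drift `v_post` (still signed by the stimulus);
#' its terminal state, expressed in the frame of the chosen response — so that
#' confirming evidence is positive — is cut by `confidence_cutpoints` into
#' PAS 1-3.
#'
#' @param params a [ddm_observer()]; `v` (and `v_post`) of length 1 or one per
#'   asynchrony level.
#' @param n_trials total number of trials, allocated equally across
#'   asynchrony levels.
#' @param seed integer seed; the simulation is deterministic given the seed.
#' @param asynchrony_levels_ms condition labels matched to `v`.
#' @param max_stim_duration_s censoring limit for the decision stage (s).
#' @param dt Euler step (s).
#' @param subject,experiment labels written into the output.
#' @return trial tibble in the standard schema (see [simulate_sdt_dataset()]).
#' @export
simulate_ddm_trials <- function(params, n_trials, seed,
                                asynchrony_levels_ms = NULL,
                                max_stim_duration_s = 30,
                                dt = 0.001,
                                subject = 1L, experiment = "exp3") {
  stopifnot(inherits(params, "ddm_observer"))
  if (n_trials < 1) abort("`n_trials` must be positive.",
                          class = "metaown_config_error")
  if (max_stim_duration_s <= 0) abort("`max_stim_duration_s` must be positive.",
                                      class = "metaown_config_error")
  k <- length(params$v)
  asyn <- asynchrony_levels_ms %||% c(18L, 31L, 52L, 88L, 150L)[seq_len(k)]
  if (length(asyn) != k) {
    abort("`asynchrony_levels_ms` must match the length of `v`.",
          class = "metaown_config_error")
  }
  v_post <- params$v_post
  if (length(v_post) == 1) v_post <- rep(v_post, k)
  if (length(v_post) != k) {
    abort("`v_post` must have length 1 or match `v`.",
          class = "metaown_config_error")
  }
  with_seed(seed, {
    cond <- rep(seq_len(k), length.out = n_trials)
    d_stim <- ifelse(runif(n_trials) < 0.5, 1, -1)   # +1: right synchronous
    drift <- d_stim * params$v[cond]
    sim <- .euler_ddm_cpp(drift, params$a, params$w, dt, max_stim_duration_s)
    rt <- params$t0 + sim[, 1]
    resp_right <- sim[, 2] == 1
    censored <- sim[, 3] == 1
    # postdecisional accumulation: terminal state is exactly Gaussian
    t_post <- pmin(3, params$postdecision_duration * exp(rnorm(n_trials, 0, 0.1)))
    e_post <- d_stim * v_post[cond] * t_post + sqrt(t_post) * rnorm(n_trials)
    # choice-frame evidence: positive when it supports the chosen side
    y <- ifelse(resp_right, e_post, -e_post)
    cc <- params$confidence_cutpoints
    pas <- 1L + (y > cc[1]) + (y > cc[2])
    tibble(subject = subject,
           experiment = experiment,
           asynchrony_ms = asyn[cond],
           n_touches = NA_integer_,
           sync_side = ifelse(d_stim > 0, "right", "left"),
           response_side = ifelse(resp_right, "right", "left"),
           pas = as.integer(pas),
           rt_decision_s = rt,
           rt_postdecision_s = t_post,
           censored = censored)
  })
}

#' Simulate a speeded experiment for several diffusion observers
#'
#' Convenience wrapper around [simulate_ddm_trials()]: one observer per
#' subject, with drift jittered between subjects by `v_sd`.
#'
#' @inheritParams simulate_ddm_trials
#' @param design a [design_spec()] with `speeded = TRUE`.
#' @return trial tibble covering all subjects.
#' @export
simulate_ddm_experiment <- function(design, params, seed, experiment = "exp3") {
  stopifnot(inherits(design, "design_spec"), inherits(params, "ddm_observer"))
  k <- length(design$asynchrony_levels_ms)
  v <- params$v
  if (length(v) == 1) v <- rep(v, k)
  if (length(v) != k) {
    abort("`v` must have one drift per design asynchrony level.",
          class = "metaown_config_error")
  }
  n_per_subj <- design$trials_per_condition * k
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max, design$n_subjects)
    purrr::map(seq_len(design$n_subjects), function(s) {
      p_s <- params
      p_s$v <- v + rnorm(k, 0, params$v_sd)
      simulate_ddm_trials(p_s, n_per_subj, seed = seeds[s],
                          asynchrony_levels_ms = design$asynchrony_levels_ms,
                          max_stim_duration_s = design$max_stim_duration_s,
                          subject = s, experiment = experiment)
    }) |> bind_rows()
  })
}
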