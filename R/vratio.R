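# v-ratio: postdecisional evidence accumulation for awareness -----------------
#
# Joint likelihood of (choice, decision RT) under the Wiener model and of the
# PAS rating under a postdecisional accumulator: after the decision, evidence
# keeps accumulating for the observed post-decision interval with drift v_post
# signed by the stimulus. In the frame of the chosen response the terminal
# state is N(+v_post * t_post, t_post) on correct trials and
# N(-v_post * t_post, t_post) on errors; two fitted cut-points map it to
# PAS 1-3. v-ratio = v_post / v is the dynamic analogue of M-ratio.

vratio_nll <- function(par, dat, k) {
  v <- par[seq_len(k)]
  a <- exp(par[k + 1]); w <- stats::plogis(par[k + 2]); t0 <- exp(par[k + 3])
  v_post <- par[k + 4]
  c1 <- par[k + 5]; c2 <- c1 + exp(par[k + 6])
  nll1 <- .wiener_nll_cpp(dat$rt, dat$upper, dat$sgn * v[dat$cond], a, w, t0)
  if (!is.finite(nll1)) return(Inf)
  mu <- ifelse(dat$correct, 1, -1) * v_post * dat$t_post
  sdv <- sqrt(dat$t_post)
  p1 <- pnorm(c1, mu, sdv)
  p2 <- pnorm(c2, mu, sdv) - p1
  p3 <- pnorm(c2, mu, sdv, lower.tail = FALSE)
  pk <- cbind(p1, p2, p3)[cbind(seq_along(mu), dat$pas)]
  nll1 - sum(log(pmax(pk, 1e-300)))
}

#' Fit the postdecisional drift rate and v-ratio
#'
#' Jointly fits the decision-stage diffusion (per-condition drift `v`,
#' boundary, start point, nondecision time) and a postdecisional accumulator
#' whose terminal state at the observed post-decision response time,
#' thresholded by two fitted cut-points, generates the PAS rating. Returns the
#' postdecisional drift `v_post` and `vratio = v_post / mean(v)`; drifts are
#' signed toward the chosen boundary, so the v-ratio is positive whenever the
#' ratings carry information about accuracy. Post-decision intervals are
#' capped at the 3 s PAS window.
#'
#' @param trials one subject's trial tibble with decision and post-decision
#'   response times and PAS ratings.
#' @param drift `"pooled"` (one drift; default) or `"by_condition"`.
#' @param min_trials minimum number of uncensored trials.
#' @return one-row tibble: `v` (mean decision drift), `v_post`, `vratio`, `a`,
#'   `w`, `t0`, confidence cut-points, `log_likelihood`, `converged`, plus
#'   per-condition drift columns in `"by_condition"` mode.
#' @export
fit_vratio <- function(trials, drift = c("pooled", "by_condition"),
                       min_trials = 50) {
  drift <- match.arg(drift)
  validate_trials(trials, required = c("sync_side", "response_side", "pas",
                                       "rt_decision_s", "rt_postdecision_s"))
  dat <- ddm_prepare(trials, min_trials)
  sub <- if ("censored" %in% names(trials)) trials[!trials$censored, ] else trials
  dat$pas <- sub$pas
  dat$t_post <- pmax(pmin(sub$rt_postdecision_s, 3), 1e-3)
  dat$correct <- (dat$upper == 1) == (dat$sgn > 0)
  if (length(unique(dat$pas)) < 2) {
    abort("PAS is constant across trials; the postdecisional drift is not identifiable.",
          class = "metaown_estimation_error")
  }
  if (drift == "pooled") { dat$cond <- rep(1L, length(dat$cond)); dat$k <- 1L }
  k <- dat$k
  acc <- dat$correct
  v0 <- max(0.2, 2 * qnorm(min(max(mean(acc), 0.51), 0.98)))
  t0_0 <- 0.9 * min(dat$rt)
  starts <- list(c(rep(v0, k), log(1.5), 0, log(t0_0), v0, 0, log(1)),
                 c(rep(v0, k), log(1.5), 0, log(t0_0), 0, 0, log(1)),
                 c(rep(0.5 * v0, k), log(2), 0, log(0.5 * t0_0), 0.5 * v0, -0.5, log(0.8)))
  lower <- c(rep(-8, k), log(0.2), stats::qlogis(0.02), log(1e-3), -8, -6, -4)
  upper <- c(rep(8, k), log(6), stats::qlogis(0.98), log(min(dat$rt) * 0.999), 8, 6, 3)
  fits <- purrr::compact(purrr::map(starts, function(s0) {
    tryCatch(optim(s0, vratio_nll, dat = dat, k = k, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = list(maxit = 500)),
             error = function(e) NULL)
  }))
  if (!length(fits)) abort("v-ratio optimisation failed.",
                           class = "metaown_estimation_error")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  par <- best$par
  v <- par[seq_len(k)]
  out <- tibble(v = mean(v),
                v_post = par[k + 4],
                vratio = par[k + 4] / mean(v),
                a = exp(par[k + 1]), w = stats::plogis(par[k + 2]),
                t0 = exp(par[k + 3]),
                cut_1 = par[k + 5], cut_2 = par[k + 5] + exp(par[k + 6]),
                n_trials = length(dat$rt),
                log_likelihood = -best$value,
                converged = best$convergence == 0)
  if (drift == "by_condition") {
    vt <- setNames(as.list(v), sprintf("v_%sms", dat$conds))
    out <- bind_cols(out, as_tibble(vt))
  }
  out
}

#' v-ratio per subject
#'
#' @inheritParams fit_vratio
#' @param trials multi-subject trial tibble.
#' @return tibble with one row per subject.
#' @export
fit_vratio_by <- function(trials, drift = "pooled", min_trials = 50) {
  subjects <- sort(unique(trials$subject))
  purrr::map(subjects, function(s) {
    bind_cols(tibble(subject = s),
              fit_vratio(trials[trials$subject == s, ], drift = drift,
                         min_trials = min_trials))
  }) |> bind_rows()
}
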