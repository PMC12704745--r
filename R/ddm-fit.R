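# Diffusion-model fitting -----------------------------------------------------
#
# Stimulus-coded: the upper boundary is a "right" response; trial drift is
# sign(stimulus) * v[condition]. Parameters are optimised / sampled on
# unconstrained scales: v free, log(a), qlogis(w), log(t0).

ddm_prepare <- function(trials, min_trials = 1) {
  validate_trials(trials,
                  required = c("sync_side", "response_side", "rt_decision_s"))
  if ("censored" %in% names(trials)) trials <- trials[!trials$censored, ]
  if (nrow(trials) < min_trials) {
    abort(sprintf("need at least %d uncensored trials, got %d.",
                  min_trials, nrow(trials)),
          class = "metaown_validation_error")
  }
  if (sd(trials$rt_decision_s) == 0) {
    abort("response times have zero variance; diffusion parameters are not identifiable.",
          class = "metaown_estimation_error")
  }
  if (length(unique(trials$response_side)) < 2) {
    abort("both choice outcomes must be represented.",
          class = "metaown_estimation_error")
  }
  conds <- sort(unique(trials$asynchrony_ms))
  list(rt = trials$rt_decision_s,
       upper = as.integer(trials$response_side == "right"),
       sgn = ifelse(trials$sync_side == "right", 1, -1),
       cond = match(trials$asynchrony_ms, conds),
       conds = conds, k = length(conds))
}

ddm_nll <- function(par, dat) {
  k <- dat$k
  v <- par[seq_len(k)]
  a <- exp(par[k + 1]); w <- stats::plogis(par[k + 2]); t0 <- exp(par[k + 3])
  .wiener_nll_cpp(dat$rt, dat$upper, dat$sgn * v[dat$cond], a, w, t0)
}

#' Single-subject diffusion fit by maximum likelihood
#'
#' Fits per-condition drift rates, boundary separation, relative start point
#' and nondecision time to one subject's speeded 2AFC data against the Wiener
#' first-passage-time likelihood (diffusion scale fixed at 1). Censored trials
#' are excluded.
#'
#' @param trials one subject's trial tibble.
#' @param min_trials minimum number of uncensored trials required.
#' @return object of class `ddm_fit`: `$v` (named by asynchrony), `$a`, `$w`,
#'   `$t0`, `$loglik`, `$n_trials`, `$converged`. Use [tidy()] for a tibble.
#' @export
fit_ddm_mle <- function(trials, min_trials = 10) {
  dat <- ddm_prepare(trials, min_trials)
  k <- dat$k
  acc <- (dat$upper == 1) == (dat$sgn > 0)
  v0 <- max(0.2, 2 * qnorm(min(max(mean(acc), 0.51), 0.98)))
  t0_0 <- 0.9 * min(dat$rt)
  starts <- list(c(rep(v0, k), log(1.5), 0, log(t0_0)),
                 c(rep(0.5 * v0, k), log(2.2), 0, log(0.5 * t0_0)))
  lower <- c(rep(-8, k), log(0.2), stats::qlogis(0.02), log(1e-3))
  upper <- c(rep(8, k), log(6), stats::qlogis(0.98), log(min(dat$rt) * 0.999))
  fits <- purrr::compact(purrr::map(starts, function(s0) {
    tryCatch(optim(s0, ddm_nll, dat = dat, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = list(maxit = 400)),
             error = function(e) NULL)
  }))
  if (!length(fits)) abort("diffusion optimisation failed.",
                           class = "metaown_estimation_error")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  par <- best$par
  structure(
    list(v = setNames(par[seq_len(k)], paste0(dat$conds, "ms")),
         conditions = dat$conds,
         a = exp(par[k + 1]), w = stats::plogis(par[k + 2]),
         t0 = exp(par[k + 3]),
         loglik = -best$value, n_trials = length(dat$rt),
         converged = best$convergence == 0, par_transformed = par),
    class = "ddm_fit"
  )
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("<ddm_fit> ", x$n_trials, " trials; a = ", round(x$a, 3), ", w = ",
      round(x$w, 3), ", t0 = ", round(x$t0, 3), "\n  v: ",
      paste(names(x$v), round(x$v, 3), sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Hierarchical Bayesian diffusion model
#'
#' Group-level diffusion fit for a speeded experiment: subject-level
#' parameters (per-condition drift, log boundary, logit start point, log
#' nondecision time) are drawn from independent group normals. Sampling is
#' Metropolis-within-Gibbs — joint adaptive random-walk updates of each
#' subject's parameter block against the Wiener likelihood, conjugate Gibbs
#' updates of group means and variances — with chains initialised from jittered
#' single-subject maximum-likelihood fits. Group-location draws are returned
#' on natural scales (`v[...]` per condition, `a`, `w`, `t0`); convergence is
#' asserted at split-Rhat below `rhat_limit` (1.02), otherwise a warning is
#' attached and `$converged_ok` is `FALSE`.
#'
#' @param trials multi-subject trial tibble.
#' @param chains number of chains (>= 2).
#' @param iterations post-burn-in iterations per chain.
#' @param burn_in adaptation iterations discarded from each chain.
#' @param seed integer seed.
#' @param min_trials minimum uncensored trials per subject (default 100).
#' @param rhat_limit convergence threshold on group parameters.
#' @return a `posterior_samples` object; `$subject_summary` holds posterior
#'   means of subject-level parameters, `$conditions` the asynchrony levels.
#' @export
fit_hddm <- function(trials, chains = 3, iterations = 2000, burn_in = 500,
                     seed = 1, min_trials = 100, rhat_limit = 1.02) {
  if (chains < 2) {
    abort("at least two chains are required for convergence diagnostics.",
          class = "metaown_config_error")
  }
  subjects <- sort(unique(trials$subject))
  S <- length(subjects)
  dats <- purrr::map(subjects, function(s) {
    ddm_prepare(trials[trials$subject == s, ], min_trials)
  })
  conds <- dats[[1]]$conds
  if (!all(vapply(dats, function(d) identical(d$conds, conds), logical(1)))) {
    abort("all subjects must share the same condition set.",
          class = "metaown_validation_error")
  }
  k <- length(conds)
  P <- k + 3 # v_1..v_k, log a, logit w, log t0
  par_names <- c(sprintf("v[%sms]", conds), "a", "w", "t0")

  mle <- purrr::map(dats, function(d) {
    # lightweight ML start per subject
    fit_ddm_mle_raw(d)
  })
  eta0 <- do.call(rbind, purrr::map(mle, "par")) # S x P

  prop_sd <- c(rep(0.12, k), 0.04, 0.10, 0.05)
  m0 <- colMeans(eta0); s0sq <- 100
  a0 <- 2; b0 <- 0.2 # inverse-gamma prior on group variances

  run_chain <- function(chain_id) {
    eta <- eta0 + matrix(rnorm(S * P, 0, 0.03), S, P)
    M <- colMeans(eta)
    V <- pmax(apply(eta, 2, var), 0.01)
    scale_s <- rep(0.6, S)
    acc_ct <- rep(0, S); acc_win <- 0
    ll <- vapply(seq_len(S), function(s) -ddm_nll(eta[s, ], dats[[s]]), numeric(1))
    n_tot <- burn_in + iterations
    keep <- matrix(NA_real_, iterations, P)
    subj_sum <- matrix(0, S, P)
    for (it in seq_len(n_tot)) {
      for (s in seq_len(S)) {
        prop <- eta[s, ] + scale_s[s] * prop_sd * rnorm(P)
        ll_prop <- -ddm_nll(prop, dats[[s]])
        if (is.finite(ll_prop)) {
          lp_old <- ll[s] + sum(dnorm(eta[s, ], M, sqrt(V), log = TRUE))
          lp_new <- ll_prop + sum(dnorm(prop, M, sqrt(V), log = TRUE))
          if (log(runif(1)) < lp_new - lp_old) {
            eta[s, ] <- prop; ll[s] <- ll_prop; acc_ct[s] <- acc_ct[s] + 1
          }
        }
      }
      acc_win <- acc_win + 1
      if (it <= burn_in && acc_win == 25) {
        rate <- acc_ct / acc_win
        scale_s <- scale_s * exp(0.8 * (rate - 0.25))
        scale_s <- pmin(pmax(scale_s, 0.05), 5)
        acc_ct[] <- 0; acc_win <- 0
      }
      # conjugate group updates
      for (p in seq_len(P)) {
        V[p] <- 1 / rgamma(1, a0 + S / 2,
                           b0 + sum((eta[, p] - M[p])^2) / 2)
        post_var <- 1 / (S / V[p] + 1 / s0sq)
        post_mean <- post_var * (sum(eta[, p]) / V[p] + m0[p] / s0sq)
        M[p] <- rnorm(1, post_mean, sqrt(post_var))
      }
      if (it > burn_in) {
        j <- it - burn_in
        keep[j, ] <- c(M[seq_len(k)], exp(M[k + 1]),
                       stats::plogis(M[k + 2]), exp(M[k + 3]))
        subj_sum <- subj_sum + eta
      }
    }
    list(draws = keep, subj_mean = subj_sum / iterations)
  }

  res <- with_seed(seed, purrr::map(seq_len(chains), run_chain))
  draws <- array(NA_real_, dim = c(chains, iterations, P),
                 dimnames = list(chain = seq_len(chains),
                                 iteration = seq_len(iterations),
                                 parameter = par_names))
  for (ch in seq_len(chains)) draws[ch, , ] <- res[[ch]]$draws
  subj_mean <- Reduce(`+`, purrr::map(res, "subj_mean")) / chains
  subject_summary <- tibble(subject = rep(subjects, each = P),
                            parameter = rep(par_names, S),
                            value = as.vector(t(cbind(
                              subj_mean[, seq_len(k), drop = FALSE],
                              exp(subj_mean[, k + 1]),
                              stats::plogis(subj_mean[, k + 2]),
                              exp(subj_mean[, k + 3])))))
  ps <- new_posterior_samples(draws, burn_in = burn_in,
                              extra = list(conditions = conds,
                                           subject_summary = subject_summary))
  ps$converged_ok <- max(ps$rhat) < rhat_limit
  if (!ps$converged_ok) {
    warn(paste0("group-level split-Rhat exceeds ", rhat_limit, " (max ",
                format(max(ps$rhat), digits = 4),
                "); posterior summaries are flagged."))
  }
  ps
}

# internal: ML fit on a prepared data list, returning the transformed vector
fit_ddm_mle_raw <- function(dat) {
  k <- dat$k
  acc <- (dat$upper == 1) == (dat$sgn > 0)
  v0 <- max(0.2, 2 * qnorm(min(max(mean(acc), 0.51), 0.98)))
  s0 <- c(rep(v0, k), log(1.5), 0, log(0.9 * min(dat$rt)))
  lower <- c(rep(-8, k), log(0.2), stats::qlogis(0.02), log(1e-3))
  upper <- c(rep(8, k), log(6), stats::qlogis(0.98), log(min(dat$rt) * 0.999))
  fit <- optim(s0, ddm_nll, dat = dat, method = "L-BFGS-B",
               lower = lower, upper = upper, control = list(maxit = 300))
  list(par = fit$par, value = fit$value)
}
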