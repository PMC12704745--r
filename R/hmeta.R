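# Hierarchical Bayesian group M-ratio ----------------------------------------
#
# One joint model: for every condition c, subject-level log M-ratio is drawn
# from a group normal with mean mu[c] and SD sigma[c]; subject meta-d' is
# exp(logM) * d1 with the subject's type-1 d' and relative criterion fixed at
# their (log-linear corrected) point estimates. Rating counts per stimulus
# class are multinomial with cell probabilities = fixed type-1 response
# probability x meta-level conditional rating probability. Pairwise condition
# contrasts are computed from the joint posterior of mu (log units).

hmeta_model_string <- "
model {
  for (c in 1:C) {
    mu[c] ~ dnorm(0, 1)
    sigma[c] ~ dnorm(0, 1) T(0.001, )
    tau[c] <- pow(sigma[c], -2)
  }
  for (s in 1:S) {
    for (c in 1:C) {
      logM[s, c] ~ dnorm(mu[c], tau[c]) T(-5, 2.3)
      md[s, c] <- exp(logM[s, c]) * d1[s, c]
      c1m[s, c] <- cprime[s, c] * md[s, c]
      dU1[s, c] ~ dnorm(0, 0.25) T(0.01, )
      dU2[s, c] ~ dnorm(0, 0.25) T(0.01, )
      dL1[s, c] ~ dnorm(0, 0.25) T(0.01, )
      dL2[s, c] ~ dnorm(0, 0.25) T(0.01, )
      cU1[s, c] <- c1m[s, c] + dU1[s, c]
      cU2[s, c] <- cU1[s, c] + dU2[s, c]
      cL1[s, c] <- c1m[s, c] - dL1[s, c]
      cL2[s, c] <- cL1[s, c] - dL2[s, c]
      for (g in 1:2) { # stimulus class: 1 = left synchronous, 2 = right
        mu_s[s, c, g] <- (2 * g - 3) * md[s, c] / 2
        denR[s, c, g] <- max(1 - phi(c1m[s, c] - mu_s[s, c, g]), 1e-10)
        denL[s, c, g] <- max(phi(c1m[s, c] - mu_s[s, c, g]), 1e-10)
        # cells 1..3: respond left, rating 1..3; cells 4..6: respond right
        p[s, c, g, 1] <- t1[s, c, g, 1] *
          max(phi(c1m[s, c] - mu_s[s, c, g]) - phi(cL1[s, c] - mu_s[s, c, g]), 1e-12) / denL[s, c, g]
        p[s, c, g, 2] <- t1[s, c, g, 1] *
          max(phi(cL1[s, c] - mu_s[s, c, g]) - phi(cL2[s, c] - mu_s[s, c, g]), 1e-12) / denL[s, c, g]
        p[s, c, g, 3] <- t1[s, c, g, 1] *
          max(phi(cL2[s, c] - mu_s[s, c, g]), 1e-12) / denL[s, c, g]
        p[s, c, g, 4] <- t1[s, c, g, 2] *
          max(phi(cU1[s, c] - mu_s[s, c, g]) - phi(c1m[s, c] - mu_s[s, c, g]), 1e-12) / denR[s, c, g]
        p[s, c, g, 5] <- t1[s, c, g, 2] *
          max(phi(cU2[s, c] - mu_s[s, c, g]) - phi(cU1[s, c] - mu_s[s, c, g]), 1e-12) / denR[s, c, g]
        p[s, c, g, 6] <- t1[s, c, g, 2] *
          max(1 - phi(cU2[s, c] - mu_s[s, c, g]), 1e-12) / denR[s, c, g]
        for (j in 1:6) { pn[s, c, g, j] <- p[s, c, g, j] / sum(p[s, c, g, 1:6]) }
        counts[s, c, g, 1:6] ~ dmulti(pn[s, c, g, 1:6], ntot[s, c, g])
      }
    }
  }
}
"

#' Hierarchical Bayesian group M-ratio per condition
#'
#' Fits the joint hierarchical model described above with JAGS, with three
#' 10,000-iteration chains and 1,000 burn-in by default. Group-level posterior
#' distributions of log M-ratio (one node per condition) are returned with
#' split-Rhat and effective-sample-size diagnostics; if any group-level Rhat
#' exceeds 1.05 a convergence warning is attached and credibility calls from
#' [compare_conditions()] are suppressed.
#'
#' @param trials trial tibble (standard schema), or a precomputed list as
#'   produced internally (advanced use).
#' @param condition_col column defining conditions (default `asynchrony_ms`).
#' @param chains number of MCMC chains (>= 2).
#' @param iterations post-burn-in iterations per chain.
#' @param burn_in adaptation + burn-in iterations.
#' @param seed integer seed for the JAGS RNGs.
#' @param quiet suppress JAGS progress output.
#' @return a `posterior_samples` object with parameters `mu[...]` (group log
#'   M-ratio) and `sigma[...]` per condition; condition labels in
#'   `$conditions`.
#' @export
fit_hmeta_group <- function(trials, condition_col = "asynchrony_ms",
                            chains = 3, iterations = 10000, burn_in = 1000,
                            seed = 1, quiet = TRUE) {
  if (chains < 2) {
    abort("at least two chains are required for convergence diagnostics.",
          class = "metaown_config_error")
  }
  validate_trials(trials)
  subjects <- sort(unique(trials$subject))
  conds <- sort(unique(trials[[condition_col]]))
  S <- length(subjects); C <- length(conds)
  if (S < 5) abort("at least 5 subjects are required.",
                   class = "metaown_validation_error")
  counts <- array(0L, dim = c(S, C, 2, 6))
  ntot <- array(0L, dim = c(S, C, 2))
  d1 <- matrix(NA_real_, S, C); cprime <- matrix(NA_real_, S, C)
  t1 <- array(NA_real_, dim = c(S, C, 2, 2)) # type-1 P(resp | stim), fixed
  for (si in seq_len(S)) {
    for (ci in seq_len(C)) {
      sel <- list(subject = subjects[si])
      sel[[condition_col]] <- conds[ci]
      cnt <- tryCatch(tabulate_counts(trials, condition = sel),
                      error = function(e) NULL)
      if (is.null(cnt)) {
        abort(sprintf("subject %s has no trials in condition %s.",
                      subjects[si], conds[ci]),
              class = "metaown_validation_error")
      }
      ref <- metad_reference(cnt)
      d1[si, ci] <- max(ref$d1, 0.05)  # meta-d' scale needs positive d'
      cprime[si, ci] <- ref$cprime
      nsr <- counts_by_stimulus(cnt)   # [stim, resp, rating]
      for (g in 1:2) {
        stim <- c("left", "right")[g]
        cells <- c(nsr[stim, "left", 1:3], nsr[stim, "right", 1:3])
        counts[si, ci, g, ] <- cells
        ntot[si, ci, g] <- sum(cells)
        mu1 <- (2 * g - 3) * d1[si, ci] / 2
        c1 <- cprime[si, ci] * d1[si, ci]
        pr_right <- pnorm(c1 - mu1, lower.tail = FALSE)
        pr_right <- min(max(pr_right, 1e-6), 1 - 1e-6)
        t1[si, ci, g, ] <- c(1 - pr_right, pr_right)
      }
    }
  }
  if (any(ntot == 0)) {
    abort("every subject x condition needs trials from both stimulus classes.",
          class = "metaown_validation_error")
  }
  data <- list(S = S, C = C, counts = counts, ntot = ntot,
               d1 = d1, cprime = cprime, t1 = t1)
  inits <- lapply(seq_len(chains), function(ch) {
    list(mu = rep(0, C), sigma = rep(0.5, C),
         logM = matrix(0, S, C),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.integer(seed) + 1000L * ch) %% .Machine$integer.max)
  })
  jm <- rjags::jags.model(textConnection(hmeta_model_string), data = data,
                          inits = inits, n.chains = chains,
                          n.adapt = max(100, burn_in %/% 2), quiet = quiet)
  update(jm, n.iter = burn_in, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("mu", "sigma"), n.iter = iterations,
                              progress.bar = "none")
  draws <- coda_to_array(samp)
  ps <- new_posterior_samples(draws, burn_in = burn_in,
                              extra = list(conditions = conds,
                                           condition_col = condition_col))
  grp <- grep("^mu\\[", ps$params)
  ps$suppress_credibility <- FALSE
  if (any(ps$rhat[grp] > 1.05)) {
    warn(paste0("group-level Rhat exceeds 1.05 (max ",
                format(max(ps$rhat[grp]), digits = 4),
                "); credibility calls are suppressed."))
    ps$suppress_credibility <- TRUE
  }
  ps
}

coda_to_array <- function(samp) {
  m <- length(samp)
  it <- nrow(samp[[1]]); p <- ncol(samp[[1]])
  draws <- array(NA_real_, dim = c(m, it, p),
                 dimnames = list(chain = seq_len(m), iteration = seq_len(it),
                                 parameter = colnames(samp[[1]])))
  for (ch in seq_len(m)) draws[ch, , ] <- as.matrix(samp[[ch]])
  draws
}

mu_draws <- function(post, cond) {
  i <- match(cond, post$conditions)
  if (is.na(i)) {
    abort(paste0("condition `", cond, "` not found in the posterior."),
          class = "metaown_validation_error")
  }
  nm <- if (length(post$conditions) == 1) "mu" else sprintf("mu[%d]", i)
  j <- match(nm, post$params)
  as.vector(post$draws[, , j])
}

#' Compare two conditions' group M-ratio posteriors
#'
#' Elementwise difference of the group log M-ratio draws for a pair of
#' conditions, summarised by the posterior mean and the 95% highest-density
#' interval; the difference is credible when the interval excludes zero.
#'
#' @param post a `posterior_samples` from [fit_hmeta_group()].
#' @param pair two condition labels (difference = first minus second).
#' @param prob HDI mass (default 0.95).
#' @return one-row tibble: `cond_a`, `cond_b`, `posterior_mean_diff`,
#'   `hdi_lower`, `hdi_upper`, `credible`.
#' @export
compare_conditions <- function(post, pair, prob = 0.95) {
  stopifnot(inherits(post, "posterior_samples"), length(pair) == 2)
  d <- mu_draws(post, pair[1]) - mu_draws(post, pair[2])
  h <- hdi(d, prob)
  credible <- h[1] > 0 || h[2] < 0
  if (isTRUE(post$suppress_credibility)) credible <- NA
  tibble(cond_a = pair[1], cond_b = pair[2],
         posterior_mean_diff = mean(d),
         hdi_lower = unname(h[1]), hdi_upper = unname(h[2]),
         credible = credible)
}

#' All pairwise condition comparisons
#'
#' @inheritParams compare_conditions
#' @return tibble with one row per unordered condition pair.
#' @export
compare_all_conditions <- function(post, prob = 0.95) {
  cn <- post$conditions
  pairs <- utils::combn(seq_along(cn), 2)
  purrr::map(seq_len(ncol(pairs)), function(j) {
    compare_conditions(post, cn[pairs[, j]], prob)
  }) |> bind_rows()
}
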