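# Shared helpers and independent oracles used across the test files.

# Build a trial tibble realising a given [stimulus, response, rating] count
# array (dimnames stimulus/response in {left, right}, rating 1..3), so count
# tables with exact cell contents can be constructed through the public API.
trials_from_array <- function(nsr) {
  rows <- list()
  for (s in c("left", "right")) {
    for (r in c("left", "right")) {
      for (k in 1:3) {
        n <- nsr[s, r, as.character(k)]
        if (n > 0) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            subject = 1L, experiment = "test",
            asynchrony_ms = 52L, n_touches = 6L,
            sync_side = s, response_side = r, pas = k,
            rt_decision_s = 1, rt_postdecision_s = 0.8, censored = FALSE)
          rows[[length(rows)]] <- rows[[length(rows)]][rep(1, n), ]
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

counts_from_array <- function(nsr) tabulate_counts(trials_from_array(nsr))

# Count table with given type-1 cells and arbitrary (uninformative) ratings.
counts_from_cells <- function(n_hit, n_miss, n_fa, n_cr) {
  nsr <- array(0L, dim = c(2, 2, 3),
               dimnames = list(stimulus = c("left", "right"),
                               response = c("left", "right"),
                               rating = 1:3))
  nsr["right", "right", 1] <- n_hit
  nsr["right", "left", 1] <- n_miss
  nsr["left", "right", 1] <- n_fa
  nsr["left", "left", 1] <- n_cr
  counts_from_array(nsr)
}

# Independent meta-d' rating log-likelihood, written directly from the
# equal-variance rating SDT equations (a separate code path from the
# package's metad_probs / metad_loglik).
metad_oracle_ll <- function(npad, cprime, md, lg) {
  c1m <- cprime * md
  cU1 <- c1m + exp(lg[1]); cU2 <- cU1 + exp(lg[2])
  cL1 <- c1m - exp(lg[3]); cL2 <- cL1 - exp(lg[4])
  ll <- 0
  for (s in 1:2) {
    mu <- c(-md / 2, md / 2)[s]
    den_l <- max(pnorm(c1m - mu), 1e-300)
    den_r <- max(1 - pnorm(c1m - mu), 1e-300)
    pl <- c(pnorm(c1m - mu) - pnorm(cL1 - mu),
            pnorm(cL1 - mu) - pnorm(cL2 - mu),
            pnorm(cL2 - mu)) / den_l
    pr <- c(pnorm(cU1 - mu) - pnorm(c1m - mu),
            pnorm(cU2 - mu) - pnorm(cU1 - mu),
            1 - pnorm(cU2 - mu)) / den_r
    ll <- ll + sum(npad[s, 1, ] * log(pmax(pl, 1e-300))) +
      sum(npad[s, 2, ] * log(pmax(pr, 1e-300)))
  }
  ll
}

# Profile log-likelihood at a fixed meta-d': maximise the oracle likelihood
# over the four rating criteria by Nelder-Mead from two starts, restarting
# once from the better optimum.
metad_profile_ll <- function(npad, cprime, md) {
  obj <- function(lg) -metad_oracle_ll(npad, cprime, md, lg)
  best <- NULL
  for (s0 in list(rep(log(0.5), 4), rep(log(1.2), 4))) {
    o <- stats::optim(s0, obj, method = "Nelder-Mead",
                      control = list(maxit = 600, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 600, reltol = 1e-12))
  -best$value
}

# Brute-force scan of the meta-d' profile likelihood: coarse grid, fine grid
# around the coarse argmax, then a local golden-section polish. Returns the
# maximising meta-d' (yes/no units) and the profile log-likelihood there.
metad_grid_oracle <- function(cnt, coarse = seq(-0.5, 3.5, by = 0.1)) {
  ref <- metaown:::metad_reference(cnt)
  npad <- metaown:::counts_by_stimulus(cnt) + 1 / 6
  pll <- function(m) metad_profile_ll(npad, ref$cprime, m)
  ll <- vapply(coarse, pll, numeric(1))
  m0 <- coarse[which.max(ll)]
  fine <- seq(m0 - 0.12, m0 + 0.12, by = 0.01)
  llf <- vapply(fine, pll, numeric(1))
  m1 <- fine[which.max(llf)]
  pol <- stats::optimize(pll, interval = c(m1 - 0.015, m1 + 0.015),
                         maximum = TRUE, tol = 1e-7)
  list(md = pol$maximum, ll = pol$objective)
}

# JZS Bayes factor by quadrature in g-space (Rouder et al. 2009, eq. 1),
# an independent route from the package's effect-size-space integration.
jzs_gspace_oracle <- function(t, n, r) {
  nu <- n - 1
  f <- function(g) {
    (1 + n * g * r^2)^(-0.5) *
      (1 + t^2 / ((1 + n * g * r^2) * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g))
  }
  stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value /
    (1 + t^2 / nu)^(-(nu + 1) / 2)
}

# Analytic probability of absorption at the upper boundary of a Wiener
# diffusion (scale 1), written directly from the exponential martingale.
upper_prob_oracle <- function(v, a, w) {
  if (abs(v) < 1e-12) return(w)
  (1 - exp(-2 * v * a * w)) / (1 - exp(-2 * v * a))
}

# A quick single-condition SDT dataset.
sim_sdt_quick <- function(dprime, n_trials, seed, mratio = 0.8,
                          criterion_c = 0, lapse_rate = 0) {
  dsg <- design_spec(asynchrony_levels_ms = 52L,
                     trials_per_condition = n_trials, n_subjects = 1L)
  simulate_sdt_dataset(dsg, sdt_observer(dprime = dprime, mratio = mratio,
                                         criterion_c = criterion_c,
                                         lapse_rate = lapse_rate),
                       seed = seed)
}
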