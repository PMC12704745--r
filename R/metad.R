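# Meta-d' model -------------------------------------------------------------
#
# Equal-variance SDT at the metacognitive level: stimulus distributions
# N(-md/2, 1) and N(+md/2, 1) on a latent awareness axis, the type-1 criterion
# pinned at its observed *relative* position c' = c1/d1 (so c1_meta = c' * md),
# and two rating criteria per response side placed outward from c1_meta.
# Rating probabilities are conditional on the response; maximising their
# multinomial likelihood over (md, criteria) yields meta-d', the type-1
# sensitivity an SDT-ideal rater would need to produce the observed
# confidence-accuracy relationship.

# conditional rating probabilities p[stimulus, response, rating]
metad_probs <- function(meta_d, c1m, t2_lower, t2_upper, n_ratings = 3) {
  mu <- c(left = -meta_d / 2, right = meta_d / 2)
  p <- array(NA_real_, dim = c(2, 2, n_ratings),
             dimnames = list(stimulus = c("left", "right"),
                             response = c("left", "right"),
                             rating = seq_len(n_ratings)))
  # criteria from most extreme "left" to most extreme "right"
  cuts_l <- c(-Inf, rev(t2_lower), c1m)   # response left: ratings n..1 inward
  cuts_r <- c(c1m, t2_upper, Inf)         # response right: ratings 1..n outward
  for (s in 1:2) {
    Fl <- pnorm(cuts_l, mu[s])
    Fr <- pnorm(cuts_r, mu[s])
    denom_l <- Fl[n_ratings + 1]          # P(respond left | stimulus)
    denom_r <- 1 - Fr[1]
    pl <- diff(Fl)                        # left response, rating n..1
    pr <- diff(Fr)                        # right response, rating 1..n
    p[s, "left", ] <- rev(pl) / max(denom_l, 1e-300)
    p[s, "right", ] <- pr / max(denom_r, 1e-300)
  }
  p
}

#' Meta-d' model log-likelihood
#'
#' Multinomial log-likelihood of the rating counts conditional on stimulus and
#' response under the meta-d' model, with the type-1 criterion pinned at the
#' observed relative criterion. Exposed so the optimum returned by
#' [fit_metad()] can be verified by direct search.
#'
#' @param counts a `count_table`.
#' @param meta_d candidate meta-d' (internal yes/no units, see [fit_metad()]).
#' @param t2_lower two rating criteria below the scaled type-1 criterion, in
#'   decreasing order of rating (distance): `c(cut_1|2, cut_2|3)` going down.
#' @param t2_upper two rating criteria above it, increasing.
#' @param pad add 1/(2 * n_ratings) to every type-2 cell (default `TRUE`).
#' @return log-likelihood in nats.
#' @export
metad_loglik <- function(counts, meta_d, t2_lower, t2_upper, pad = TRUE) {
  ref <- metad_reference(counts)
  n <- counts_by_stimulus(counts)
  n <- n + if (pad) 1 / (2 * counts$n_ratings) else 0
  c1m <- ref$cprime * meta_d
  if (!(t2_lower[1] < c1m && t2_lower[2] < t2_lower[1] &&
        t2_upper[1] > c1m && t2_upper[2] > t2_upper[1])) {
    return(-Inf)
  }
  p <- metad_probs(meta_d, c1m, t2_lower, t2_upper, counts$n_ratings)
  sum(n * log(pmax(p, 1e-300)))
}

# type-1 anchors for the meta fit (yes/no units, log-linear corrected)
metad_reference <- function(counts) {
  t1 <- dprime_2afc(counts, scale = "yesno")
  d1 <- t1$dprime
  c1 <- t1$criterion_c
  cprime <- if (abs(d1) > 1e-2) c1 / d1 else c1 # degenerate d1: unit scale
  list(d1 = d1, c1 = c1, cprime = cprime)
}

#' Fit meta-d' by maximum likelihood
#'
#' Estimates metacognitive sensitivity from a [tabulate_counts()] table by
#' maximising the response-conditional multinomial likelihood of the PAS
#' ratings under the meta-d' model (see [metad_loglik()]). A single meta-d' is
#' shared across response sides; the two rating criteria per side are free.
#' Zero cells are handled by adding 1/(2 * n_ratings) to every type-2 cell.
#' Optimisation is bounded quasi-Newton (L-BFGS-B) from five deterministic
#' starts; ties are broken by likelihood, then by smaller |meta-d'|.
#'
#' Meta-d' is fitted on the internal evidence axis and reported in the same
#' convention as [dprime_2afc()] (`scale = "2afc"` divides by sqrt(2)), so
#' `meta_dprime` is directly comparable with `dprime` and
#' `mratio = meta-d'/d'` is convention-free. Because the ratio is undefined
#' at chance-level type-1 performance, its denominator is anchored at
#' |d'| = 0.05 (internal units) — the same anchor used by
#' [fit_hmeta_group()] — whenever the observed |d'| falls below that value.
#'
#' @param counts a `count_table`.
#' @param n_ratings number of rating levels (3 for the PAS).
#' @param pad pad zero cells (default `TRUE`).
#' @param scale reporting convention, as in [dprime_2afc()].
#' @return one-row tibble: `meta_dprime`, `mratio`, `dprime`, `type1_c_prime`,
#'   type-2 criteria, `log_likelihood`, `converged`.
#' @export
fit_metad <- function(counts, n_ratings = 3, pad = TRUE,
                      scale = c("2afc", "yesno")) {
  scale <- match.arg(scale)
  stopifnot(inherits(counts, "count_table"))
  if (n_ratings != counts$n_ratings) {
    abort("`n_ratings` does not match the count table.",
          class = "metaown_validation_error")
  }
  n <- counts_by_stimulus(counts)
  by_correct <- c(sum(n["left", "left", ], n["right", "right", ]),
                  sum(n["left", "right", ], n["right", "left", ]))
  if (!pad && any(by_correct == 0)) {
    abort("no trials in one correctness class and padding disabled.",
          class = "metaown_estimation_error")
  }
  ref <- metad_reference(counts)
  npad <- n + if (pad) 1 / (2 * n_ratings) else 0

  nll <- function(par) {
    md <- par[1]
    c1m <- ref$cprime * md
    t2u <- c(c1m + exp(par[2]), c1m + exp(par[2]) + exp(par[3]))
    t2l <- c(c1m - exp(par[4]), c1m - exp(par[4]) - exp(par[5]))
    p <- metad_probs(md, c1m, t2l, t2u, n_ratings)
    -sum(npad * log(pmax(p, 1e-300)))
  }

  d1 <- ref$d1
  starts <- list(
    c(d1, log(0.5), log(0.5), log(0.5), log(0.5)),
    c(0.5 * d1, log(0.3), log(0.3), log(0.3), log(0.3)),
    c(1.5 * d1, log(0.8), log(0.8), log(0.8), log(0.8)),
    c(0.1, log(0.5), log(0.5), log(0.5), log(0.5)),
    c(max(0.25 * d1, 0.05), log(1), log(0.2), log(1), log(0.2))
  )
  lower <- c(-10, rep(-6, 4)); upper <- c(10, rep(2.5, 4))
  fits <- purrr::map(starts, function(s0) {
    s0[1] <- min(max(s0[1], lower[1] + 0.01), upper[1] - 0.01)
    tryCatch(
      optim(s0, nll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
  })
  fits <- purrr::compact(fits)
  if (!length(fits)) {
    abort("meta-d' optimisation failed from all starts.",
          class = "metaown_estimation_error")
  }
  vals <- vapply(fits, function(f) f$value, numeric(1))
  best_val <- min(vals)
  cand <- fits[vals <= best_val + 1e-6]
  best <- cand[[which.min(vapply(cand, function(f) abs(f$par[1]), numeric(1)))]]
  md <- best$par[1]
  c1m <- ref$cprime * md
  t2u <- c(c1m + exp(best$par[2]), c1m + exp(best$par[2]) + exp(best$par[3]))
  t2l <- c(c1m - exp(best$par[4]), c1m - exp(best$par[4]) - exp(best$par[5]))
  s <- if (scale == "2afc") 1 / sqrt(2) else 1
  # keep the ratio defined at near-zero type-1 sensitivity by anchoring the
  # denominator at 0.05 (the same anchor the hierarchical group model uses)
  d1_anchor <- if (abs(d1) < 0.05) 0.05 * ifelse(d1 < 0, -1, 1) else d1
  tibble(meta_dprime = s * md,
         dprime = s * d1,
         mratio = md / d1_anchor,
         type1_c_prime = ref$cprime,
         t2_low_outer = t2l[2], t2_low_inner = t2l[1],
         t2_high_inner = t2u[1], t2_high_outer = t2u[2],
         log_likelihood = -best$value,
         converged = best$convergence == 0)
}

#' Meta-d' and M-ratio per subject and condition
#'
#' Runs [fit_sdt()] and [fit_metad()] on every subject x condition cell and
#' joins the results into one tidy table.
#'
#' @param trials trial tibble (standard schema).
#' @param ... passed to [fit_metad()].
#' @return tibble with one row per subject x condition, appending
#'   `meta_dprime` and `mratio` to the SDT columns.
#' @export
fit_metad_by <- function(trials, ...) {
  validate_trials(trials)
  cells <- condition_cells(trials)
  purrr::map(seq_len(nrow(cells)), function(i) {
    sel <- as.list(cells[i, ])
    cnt <- tabulate_counts(trials, condition = sel)
    t1 <- dprime_2afc(cnt)
    t2 <- fit_metad(cnt, ...)
    bind_cols(as_tibble(sel),
              t1[c("dprime", "criterion_c", "n_trials", "correction_applied")],
              t2[c("meta_dprime", "mratio", "type1_c_prime",
                   "log_likelihood", "converged")])
  }) |> bind_rows()
}
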