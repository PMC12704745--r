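#' 2AFC sensitivity and criterion
#'
#' Computes body-ownership sensitivity and bias from a [tabulate_counts()]
#' table using the 2AFC convention
#' \deqn{d' = \frac{1}{\sqrt{2}}\left[Z(P_{Hit}) - Z(P_{FA})\right], \qquad
#'       C = -\frac{1}{2}\left[Z(P_{Hit}) + Z(P_{FA})\right],}
#' where Z is the standard-normal quantile. A d' of zero is chance
#' discrimination; positive C denotes a bias away from reporting the signal
#' (right) side, i.e., a left bias. When any raw rate is 0 or 1 the log-linear
#' correction (0.5 added to each type-1 cell) is applied first and flagged.
#'
#' @param counts a `count_table`.
#' @param scale `"2afc"` (default, the 1/sqrt(2) convention) or `"yesno"`
#'   (unscaled).
#' @return one-row tibble: `dprime`, `criterion_c`, `p_hit`, `p_fa`,
#'   `n_trials`, `correction_applied`.
#' @export
dprime_2afc <- function(counts, scale = c("2afc", "yesno")) {
  scale <- match.arg(scale)
  stopifnot(inherits(counts, "count_table"))
  n_sig <- counts$n_hit + counts$n_miss
  n_noise <- counts$n_fa + counts$n_cr
  if (n_sig == 0 || n_noise == 0) {
    abort("both stimulus classes need at least one trial.",
          class = "metaown_estimation_error")
  }
  h <- counts$n_hit / n_sig
  f <- counts$n_fa / n_noise
  corrected <- h %in% c(0, 1) || f %in% c(0, 1)
  if (corrected) { # log-linear rule
    h <- (counts$n_hit + 0.5) / (n_sig + 1)
    f <- (counts$n_fa + 0.5) / (n_noise + 1)
  }
  s <- if (scale == "2afc") 1 / sqrt(2) else 1
  tibble(dprime = s * (qnorm(h) - qnorm(f)),
         criterion_c = -0.5 * (qnorm(h) + qnorm(f)),
         p_hit = h, p_fa = f,
         n_trials = counts$n_trials,
         correction_applied = corrected)
}

#' Per-subject, per-condition SDT results
#'
#' Tabulates and scores every subject x condition cell of a trial table.
#'
#' @param trials trial tibble (standard schema).
#' @param scale passed to [dprime_2afc()].
#' @return tibble with one row per subject x condition.
#' @export
fit_sdt <- function(trials, scale = "2afc") {
  validate_trials(trials)
  cells <- condition_cells(trials)
  purrr::pmap(cells, function(...) {
    sel <- list(...)
    res <- dprime_2afc(tabulate_counts(trials, condition = sel), scale = scale)
    bind_cols(as_tibble(sel), res)
  }) |> bind_rows()
}

condition_cells <- function(trials) {
  cols <- intersect(c("subject", "asynchrony_ms", "n_touches"), names(trials))
  cols <- cols[vapply(cols, function(cl) !all(is.na(trials[[cl]])), logical(1))]
  dplyr::distinct(trials[cols]) |> arrange(across(dplyr::everything()))
}
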