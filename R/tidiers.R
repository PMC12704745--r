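# broom-style tidiers -----------------------------------------------------------

#' Tidy a posterior sample object
#'
#' One row per parameter: posterior mean, SD, median, 95% HDI, split-Rhat and
#' effective sample size.
#'
#' @param x a `posterior_samples`.
#' @param prob HDI mass.
#' @param ... unused.
#' @return tibble.
#' @export
tidy.posterior_samples <- function(x, prob = 0.95, ...) {
  purrr::map(seq_along(x$params), function(j) {
    v <- as.vector(x$draws[, , j])
    h <- hdi(v, prob)
    tibble(parameter = x$params[j], mean = mean(v), sd = sd(v),
           median = median(v), hdi_lower = unname(h[1]),
           hdi_upper = unname(h[2]),
           rhat = unname(x$rhat[j]), ess = unname(x$ess[j]))
  }) |> bind_rows()
}

#' @export
glance.posterior_samples <- function(x, ...) {
  d <- dim(x$draws)
  tibble(chains = d[1], iterations = d[2], parameters = d[3],
         burn_in = x$burn_in, max_rhat = max(x$rhat), min_ess = min(x$ess),
         converged_ok = x$converged_ok %||% (max(x$rhat) < 1.05))
}

#' Tidy a single-subject diffusion fit
#'
#' @param x a `ddm_fit`.
#' @param ... unused.
#' @return tibble with one row per parameter.
#' @export
tidy.ddm_fit <- function(x, ...) {
  tibble(parameter = c(sprintf("v[%s]", names(x$v)), "a", "w", "t0"),
         estimate = c(unname(x$v), x$a, x$w, x$t0))
}

#' @export
glance.ddm_fit <- function(x, ...) {
  tibble(log_likelihood = x$loglik, n_trials = x$n_trials,
         converged = x$converged)
}

# re-export the broom generics so tidy()/glance() work without attaching broom
#' @importFrom broom tidy
#' @export
broom::tidy

#' @importFrom broom glance
#' @export
broom::glance
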