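# Diagnostic plots ---------------------------------------------------------------

#' Sensitivity by condition
#'
#' Group mean with standard-error bars over subjects, per asynchrony (and
#' touches when present), for any per-subject measure column of a tidy result
#' table ([fit_sdt()], [fit_metad_by()], [fit_vratio_by()]).
#'
#' @param data tidy per-subject result table.
#' @param measure column to summarise (default `dprime`).
#' @return a ggplot.
#' @export
plot_by_condition <- function(data, measure = "dprime") {
  stopifnot(measure %in% names(data))
  has_touch <- "n_touches" %in% names(data) && !all(is.na(data$n_touches)) &&
    length(unique(data$n_touches)) > 1
  group_cols <- c("asynchrony_ms", if (has_touch) "n_touches")
  summ <- data |>
    group_by(across(dplyr::all_of(group_cols))) |>
    summarise(mean = mean(.data[[measure]]),
              se = sd(.data[[measure]]) / sqrt(n()), .groups = "drop")
  p <- ggplot(summ, aes(x = factor(.data$asynchrony_ms), y = .data$mean)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_errorbar(aes(ymin = .data$mean - .data$se,
                      ymax = .data$mean + .data$se), width = 0.15) +
    geom_point(size = 2) +
    labs(x = "visuotactile asynchrony (ms)", y = measure) +
    theme_minimal()
  if (has_touch) p <- p + facet_wrap(~ n_touches, labeller = "label_both")
  p
}

#' @describeIn plot_by_condition posterior densities of the group parameters.
#' @param object a `posterior_samples`.
#' @param pattern regular expression selecting parameters (default group
#'   log M-ratio / drift nodes).
#' @param ... unused.
#' @export
autoplot.posterior_samples <- function(object, pattern = "^(mu|v)\\[", ...) {
  td <- tidy_draws(object)
  keep <- grep(pattern, names(td), value = TRUE)
  if (!length(keep)) keep <- setdiff(names(td), c("chain", "iteration"))
  long <- pivot_longer(td[c("chain", keep)], -"chain",
                       names_to = "parameter", values_to = "value")
  ggplot(long, aes(x = .data$value)) +
    geom_density(fill = "grey80") +
    facet_wrap(~ parameter, scales = "free") +
    labs(x = "posterior draw", y = "density") +
    theme_minimal()
}

#' Pairwise HDI comparison plot
#'
#' Posterior mean differences in group log M-ratio with 95% HDIs for every
#' condition pair; intervals crossing zero indicate no credible difference.
#'
#' @param comparisons output of [compare_all_conditions()].
#' @return a ggplot.
#' @export
plot_comparisons <- function(comparisons) {
  comparisons <- mutate(comparisons,
                        pair = paste(.data$cond_a, "-", .data$cond_b))
  ggplot(comparisons, aes(x = .data$posterior_mean_diff, y = .data$pair)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    geom_errorbar(aes(xmin = .data$hdi_lower, xmax = .data$hdi_upper),
                  width = 0.2, orientation = "y") +
    geom_point(size = 2) +
    labs(x = "difference in group log M-ratio (95% HDI)", y = NULL) +
    theme_minimal()
}
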