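# Group-level statistics -------------------------------------------------------

as_subject_condition_matrix <- function(values, value = "value",
                                        subject = "subject",
                                        condition = "condition") {
  if (is.matrix(values)) {
    if (anyNA(values)) abort("missing cells in the subject x condition matrix.",
                             class = "metaown_validation_error")
    return(values)
  }
  for (cl in c(value, subject, condition)) {
    if (!cl %in% names(values)) {
      abort(paste0("long data need column `", cl, "`."),
            class = "metaown_validation_error")
    }
  }
  wide <- pivot_wider(values[c(subject, condition, value)],
                      names_from = dplyr::all_of(condition),
                      values_from = dplyr::all_of(value))
  m <- as.matrix(wide[-1])
  rownames(m) <- as.character(wide[[1]])
  if (anyNA(m)) abort("missing cells in the subject x condition matrix.",
                      class = "metaown_validation_error")
  m
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Computes the within-subject F test from sums of squares, partial eta
#' squared, and the Greenhouse-Geisser epsilon from the condition covariance
#' matrix; degrees of freedom and the p value are epsilon-corrected whenever
#' epsilon < 1.
#'
#' @param values subject x condition matrix, or a long data frame with
#'   `subject`, `condition`, `value` columns.
#' @param value,subject,condition column names for long input.
#' @return one-row tibble: `F`, `df_num`, `df_den`, `p`, `eta_p_sq`,
#'   `gg_epsilon`, `corrected`, plus uncorrected dfs.
#' @export
rm_anova_gg <- function(values, value = "value", subject = "subject",
                        condition = "condition") {
  Y <- as_subject_condition_matrix(values, value = value, subject = subject,
                                   condition = condition)
  n <- nrow(Y); k <- ncol(Y)
  if (k < 2) abort("need at least 2 conditions.", class = "metaown_validation_error")
  if (n < 3) abort("need at least 3 subjects.", class = "metaown_validation_error")
  grand <- mean(Y)
  mj <- colMeans(Y); mi <- rowMeans(Y)
  ss_cond <- n * sum((mj - grand)^2)
  ss_subj <- k * sum((mi - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  ms_err <- ss_err / df2
  F <- if (ms_err <= 0) 0 else (ss_cond / df1) / ms_err
  # Greenhouse-Geisser epsilon from the double-centred covariance matrix
  S <- stats::cov(Y)
  M <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  trM <- sum(diag(M))
  eps <- if (sum(M^2) <= 0) 1 else trM^2 / ((k - 1) * sum(M^2))
  eps <- min(max(eps, 1 / (k - 1)), 1)
  corrected <- eps < 1 - 1e-12
  dfn <- df1 * if (corrected) eps else 1
  dfd <- df2 * if (corrected) eps else 1
  p <- if (F <= 0) 1 else pf(F, dfn, dfd, lower.tail = FALSE)
  tibble(F = F, df_num = dfn, df_den = dfd, p = p,
         eta_p_sq = if (ss_cond + ss_err > 0) ss_cond / (ss_cond + ss_err) else 0,
         gg_epsilon = eps, corrected = corrected,
         df_num_raw = df1, df_den_raw = df2)
}

#' Mixed repeated-measures ANOVA (one between, one within factor)
#'
#' Two-factor extension of [rm_anova_gg()] with a between-subject factor, used
#' for cross-experiment comparisons. Within-subject effects carry the
#' Greenhouse-Geisser correction from the pooled within-group covariance.
#'
#' @param values long data frame with `subject`, `condition`, `group`, `value`.
#' @return tibble with one row per effect (`group`, `condition`,
#'   `group:condition`).
#' @export
rm_anova_mixed <- function(values) {
  for (cl in c("subject", "condition", "group", "value")) {
    if (!cl %in% names(values)) {
      abort(paste0("long data need column `", cl, "`."),
            class = "metaown_validation_error")
    }
  }
  values <- mutate(values, subject = paste(.data$group, .data$subject, sep = ":"))
  subj <- factor(values$subject); grp <- factor(values$group)
  cond <- factor(values$condition); y <- values$value
  n_s <- nlevels(subj); k <- nlevels(cond); G <- nlevels(grp)
  if (any(table(subj, cond) != 1)) {
    abort("each subject needs exactly one value per condition.",
          class = "metaown_validation_error")
  }
  grand <- mean(y)
  m_subj <- tapply(y, subj, mean)
  m_grp <- tapply(y, grp, mean)
  m_cond <- tapply(y, cond, mean)
  m_gc <- tapply(y, list(grp, cond), mean)
  grp_of_subj <- tapply(as.character(grp), subj, `[`, 1)
  n_per_grp <- table(grp_of_subj)

  ss_grp <- k * sum(n_per_grp * (m_grp[names(n_per_grp)] - grand)^2)
  ss_subj_w <- k * sum((m_subj - m_grp[grp_of_subj])^2)
  ss_cond <- n_s * sum((m_cond - grand)^2)
  dev_int <- m_gc - matrix(m_grp[rownames(m_gc)], G, k) -
    matrix(m_cond, G, k, byrow = TRUE) + grand
  ss_int <- sum(sweep(dev_int^2, 1, as.numeric(n_per_grp[rownames(m_gc)]), `*`))
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_grp - ss_subj_w - ss_cond - ss_int

  df_grp <- G - 1; df_sw <- n_s - G
  df_cond <- k - 1; df_int <- (G - 1) * (k - 1); df_err <- (n_s - G) * (k - 1)

  # pooled within-group covariance for epsilon
  Y <- as_subject_condition_matrix(values)
  Sp <- Reduce(`+`, lapply(levels(grp), function(g) {
    rows <- rownames(Y) %in% names(grp_of_subj)[grp_of_subj == g]
    (sum(rows) - 1) * stats::cov(Y[rows, , drop = FALSE])
  })) / (n_s - G)
  M <- sweep(sweep(Sp, 1, rowMeans(Sp)), 2, colMeans(Sp)) + mean(Sp)
  eps <- if (sum(M^2) <= 0) 1 else sum(diag(M))^2 / ((k - 1) * sum(M^2))
  eps <- min(max(eps, 1 / (k - 1)), 1)

  eff <- function(name, ss, df1, ss_e, df2, e = 1) {
    F <- if (ss_e <= 0) 0 else (ss / df1) / (ss_e / df2)
    tibble(effect = name, F = F, df_num = df1 * e, df_den = df2 * e,
           p = if (F <= 0) 1 else pf(F, df1 * e, df2 * e, lower.tail = FALSE),
           eta_p_sq = if (ss + ss_e > 0) ss / (ss + ss_e) else 0,
           gg_epsilon = e, corrected = e < 1 - 1e-12)
  }
  bind_rows(eff("group", ss_grp, df_grp, ss_subj_w, df_sw),
            eff("condition", ss_cond, df_cond, ss_err, df_err, eps),
            eff("group:condition", ss_int, df_int, ss_err, df_err, eps))
}

#' JZS Bayes-factor one-sample t test
#'
#' Default Bayesian t test with a Cauchy prior of width `rscale` on the
#' standardised effect size (0.707 by default). The Bayes factor is computed
#' by numerical integration of the noncentral-t likelihood over the prior;
#' the directional version (`bf_plus0`) integrates over the positive
#' half-Cauchy.
#'
#' @param values numeric vector (differences or single sample against zero).
#' @param direction `"two_sided"` or `"positive"` for the reported `bf`.
#' @param rscale Cauchy prior width.
#' @param robustness if `TRUE`, attach a robustness sweep over `rscale_grid`.
#' @param rscale_grid widths for the robustness sweep.
#' @return one-row tibble: `t`, `n`, `cohens_d`, `bf10`, `bf_plus0`, `bf`
#'   (the requested direction), `rscale`; optional `robustness` list column.
#' @export
bayes_t_one_sample <- function(values, direction = c("two_sided", "positive"),
                               rscale = 0.707, robustness = FALSE,
                               rscale_grid = seq(0.2, 1.5, by = 0.1)) {
  direction <- match.arg(direction)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) abort("need at least 2 observations.",
                   class = "metaown_validation_error")
  s <- sd(values)
  if (s == 0) abort("zero variance; the t statistic is undefined.",
                    class = "metaown_estimation_error")
  t <- mean(values) / (s / sqrt(n))
  bf10 <- jzs_bf(t, n, rscale, one_sided = FALSE)
  bfp <- jzs_bf(t, n, rscale, one_sided = TRUE)
  out <- tibble(t = t, n = n, cohens_d = mean(values) / s,
                bf10 = bf10, bf_plus0 = bfp,
                bf = if (direction == "positive") bfp else bf10,
                rscale = rscale, direction = direction)
  if (robustness) {
    out$robustness <- list(tibble(
      rscale = rscale_grid,
      bf = vapply(rscale_grid, function(r) {
        jzs_bf(t, n, r, one_sided = direction == "positive")
      }, numeric(1))))
  }
  out
}

# JZS Bayes factor from (t, n): likelihood-ratio of the marginal under a
# Cauchy(0, rscale) effect-size prior vs the point null, integrated in
# effect-size space.
jzs_bf <- function(t, n, rscale, one_sided = FALSE) {
  nu <- n - 1
  f <- function(d) dt(t, nu, ncp = d * sqrt(n)) * dcauchy(d, 0, rscale)
  # one half-line integral can be negligibly small relative to the other;
  # relax the tolerance there rather than fail on roundoff
  quad <- function(lo, hi) {
    r <- suppressWarnings(integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = 0,
                                    stop.on.error = FALSE))
    if (r$message != "OK") {
      r <- suppressWarnings(integrate(f, lo, hi, rel.tol = 1e-8,
                                      stop.on.error = FALSE))
    }
    r$value
  }
  num <- if (one_sided) 2 * quad(0, Inf) else quad(-Inf, 0) + quad(0, Inf)
  num / dt(t, nu)
}

#' Sequential Bayes-factor analysis
#'
#' Bayes factor as a function of accumulating subjects (in subject order);
#' a presentation-level wrapper around [bayes_t_one_sample()].
#'
#' @inheritParams bayes_t_one_sample
#' @return tibble with `n` and `bf` per accumulation step.
#' @export
bayes_t_sequential <- function(values, direction = "two_sided", rscale = 0.707) {
  purrr::map(2:length(values), function(i) {
    b <- bayes_t_one_sample(values[seq_len(i)], direction, rscale)
    tibble(n = i, bf = b$bf)
  }) |> bind_rows()
}

#' Bayesian one-way repeated-measures ANOVA (BF01)
#'
#' Bayes factor of the null (subject effects only) against the condition-effect
#' model under Zellner-Siow g-priors: scale r = 0.5 on fixed (condition)
#' effects and r = 1 on random (subject) effects, with marginal likelihoods by
#' seeded Monte-Carlo integration over the g parameters.
#'
#' @param values subject x condition matrix or long data frame (as in
#'   [rm_anova_gg()]).
#' @param r_fixed,r_random prior scales.
#' @param mc_samples Monte-Carlo draws for the g integrals.
#' @param seed integer seed.
#' @return BF01 (support for the null) as a single positive number.
#' @export
bf_oneway_rm <- function(values, r_fixed = 0.5, r_random = 1,
                         mc_samples = 8000, seed = 1) {
  Y <- as_subject_condition_matrix(values)
  n <- nrow(Y); k <- ncol(Y)
  if (k < 2) abort("need at least 2 conditions.",
                   class = "metaown_validation_error")
  y <- as.vector(Y) # stacked by condition
  N <- length(y)
  subj <- factor(rep(seq_len(n), times = k))
  cond <- factor(rep(seq_len(k), each = n))
  Xs <- stats::model.matrix(~ subj - 1)
  # orthonormal sum-to-zero projection for the fixed effect
  Ck <- diag(k) - 1 / k
  Q <- eigen(Ck, symmetric = TRUE)$vectors[, seq_len(k - 1), drop = FALSE]
  Xf <- stats::model.matrix(~ cond - 1) %*% Q
  yc <- y - mean(y)
  center <- function(X) sweep(X, 2, colMeans(X))
  Xs <- center(Xs); Xf <- center(Xf)

  log_marg <- function(X, ginv_diag) {
    A <- crossprod(X) + diag(ginv_diag, ncol(X))
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    b <- crossprod(X, yc)
    quad <- sum(backsolve(ch, b, transpose = TRUE)^2)
    resid <- sum(yc^2) - quad
    if (resid <= 0) return(-Inf)
    0.5 * sum(log(ginv_diag)) - sum(log(diag(ch))) - (N - 1) / 2 * log(resid)
  }
  with_seed(seed, {
    g_r <- 1 / rgamma(mc_samples, 0.5, rate = r_random^2 / 2)
    g_f <- 1 / rgamma(mc_samples, 0.5, rate = r_fixed^2 / 2)
    lm_null <- vapply(seq_len(mc_samples), function(i) {
      log_marg(Xs, rep(1 / g_r[i], n))
    }, numeric(1))
    X_full <- cbind(Xs, Xf)
    lm_full <- vapply(seq_len(mc_samples), function(i) {
      log_marg(X_full, c(rep(1 / g_r[i], n), rep(1 / g_f[i], k - 1)))
    }, numeric(1))
    lse <- function(x) { m <- max(x); m + log(mean(exp(x - m))) }
    exp(lse(lm_null) - lse(lm_full))
  })
}

#' Normality screening and Kruskal-Wallis test
#'
#' Kolmogorov-Smirnov normality statistic per group (against a normal with the
#' group's mean and SD) and the Kruskal-Wallis rank test across groups, the
#' standard treatment for non-normal response-time data.
#'
#' @param data long data frame with `value` and `group` columns (names
#'   configurable).
#' @param value,group column names.
#' @return list with `normality` (per-group KS tibble) and `kruskal` (one-row
#'   tibble with `H`, `df`, `p`).
#' @export
nonparametric_tests <- function(data, value = "value", group = "group") {
  for (cl in c(value, group)) {
    if (!cl %in% names(data)) {
      abort(paste0("need column `", cl, "`."), class = "metaown_validation_error")
    }
  }
  v <- data[[value]]; g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("need at least 2 groups.",
                            class = "metaown_validation_error")
  if (any(table(g) < 2)) abort("every group needs at least 2 values.",
                               class = "metaown_validation_error")
  normality <- purrr::map(levels(g), function(lv) {
    x <- v[g == lv]
    ks <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
    tibble(group = lv, n = length(x), ks_statistic = unname(ks$statistic),
           ks_p = ks$p.value)
  }) |> bind_rows()
  kw <- kruskal.test(v, g)
  list(normality = normality,
       kruskal = tibble(H = unname(kw$statistic),
                        df = unname(kw$parameter), p = kw$p.value))
}
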