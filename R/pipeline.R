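# Pipeline: simulate -> fit -> compare -> report -------------------------------

trial_col_types <- readr::cols(
  subject = readr::col_integer(),
  experiment = readr::col_character(),
  asynchrony_ms = readr::col_integer(),
  n_touches = readr::col_integer(),
  sync_side = readr::col_character(),
  response_side = readr::col_character(),
  pas = readr::col_integer(),
  rt_decision_s = readr::col_double(),
  rt_postdecision_s = readr::col_double(),
  censored = readr::col_logical()
)

#' Read a trial table
#'
#' Reads the canonical tab-separated trial format and validates the schema:
#' the header must contain exactly the documented columns, sides must be
#' left/right, PAS in 1-3 and response times nonnegative; violations are
#' reported with row and column.
#'
#' @param path file path.
#' @return validated trial tibble.
#' @export
read_trials <- function(path) {
  hdr <- names(readr::spec_tsv(path)$cols)
  unknown <- setdiff(hdr, trial_schema)
  if (length(unknown)) {
    abort(paste0("unknown column(s) in trial file: ",
                 paste(unknown, collapse = ", ")),
          class = "metaown_validation_error")
  }
  missing <- setdiff(trial_schema, hdr)
  if (length(missing)) {
    abort(paste0("trial file is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "metaown_validation_error")
  }
  trials <- readr::read_tsv(path, col_types = trial_col_types, progress = FALSE)
  probs <- readr::problems(trials)
  if (nrow(probs)) {
    abort(sprintf("malformed value at row %d, column %s of %s.",
                  probs$row[1], probs$col[1], path),
          class = "metaown_validation_error")
  }
  validate_trials(trials)
  trials
}

#' Write a trial table
#'
#' @param trials trial tibble.
#' @param path destination (tab-separated text).
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_tsv(trials[trial_schema], path, progress = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles an experiment template, its design and observer parameters, sampler
#' settings and the mandatory seed. Templates: `exp1` (five asynchronies),
#' `exp2` (asynchrony x number of touches), `exp3` (speeded, diffusion +
#' v-ratio), `control1` (rotated hands: chance-level d', type-1 analysis
#' only), `control2` (visuotactile simultaneity with reduced awareness
#' efficiency).
#'
#' @param template experiment template name.
#' @param seed integer seed (mandatory).
#' @param n_subjects optional override of the template's sample size.
#' @param design named list of [design_spec()] overrides.
#' @param observer named list of observer-parameter overrides.
#' @param sampler named list: `chains`, `iterations`, `burn_in` for the MCMC
#'   stages (defaults 3 / 2000 / 500; set 10000 / 1000 for a full run).
#' @return object of class `run_config`.
#' @export
run_config <- function(template = c("exp1", "exp2", "exp3", "control1", "control2"),
                       seed, n_subjects = NULL,
                       design = list(), observer = list(), sampler = list()) {
  template <- match.arg(template)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` is mandatory and must be a single integer.",
          class = "metaown_validation_error")
  }
  tpl <- pipeline_template(template)
  tpl$design <- utils::modifyList(tpl$design, design)
  tpl$observer <- utils::modifyList(tpl$observer, observer)
  smp <- utils::modifyList(list(chains = 3, iterations = 2000, burn_in = 500),
                           sampler)
  if (!is.null(n_subjects)) tpl$design$n_subjects <- n_subjects
  cfg <- list(template = template, seed = as.integer(seed),
              design = tpl$design, observer = tpl$observer, sampler = smp,
              stages = tpl$stages, kind = tpl$kind)
  cfg$hash <- rlang::hash(cfg[c("template", "seed", "design", "observer",
                                "sampler")])
  structure(cfg, class = "run_config")
}

pipeline_template <- function(template) {
  switch(
    template,
    exp1 = list(
      kind = "sdt",
      design = list(asynchrony_levels_ms = c(18L, 31L, 52L, 88L, 150L),
                    touches_levels = 6L, trials_per_condition = 60L,
                    n_subjects = 32L),
      observer = list(dprime = c(0.1, 0.4, 0.7, 1.0, 1.2), criterion_c = 0,
                      mratio = 0.8, lapse_rate = 0.01,
                      dprime_sd = 0.15, logm_sd = 0.25),
      stages = c("simulate", "sdt", "metad", "hmeta", "stats")),
    exp2 = list(
      kind = "sdt",
      design = list(asynchrony_levels_ms = c(18L, 52L, 88L, 150L),
                    touches_levels = c(3L, 6L, 9L), trials_per_condition = 25L,
                    n_subjects = 44L),
      observer = list(dprime = as.vector(outer(c(0.1, 0.6, 0.9, 1.1),
                                               c(0.8, 1.0, 1.2))),
                      criterion_c = 0, mratio = 0.8, lapse_rate = 0.01,
                      dprime_sd = 0.15, logm_sd = 0.25),
      stages = c("simulate", "sdt", "metad", "hmeta", "stats")),
    exp3 = list(
      kind = "ddm",
      design = list(asynchrony_levels_ms = c(18L, 31L, 52L, 88L, 150L),
                    touches_levels = 6L, trials_per_condition = 96L,
                    n_subjects = 20L, speeded = TRUE,
                    max_stim_duration_s = 30),
      observer = list(v = c(0.5, 0.8, 1.1, 1.4, 1.7), a = 1.8, w = 0.5,
                      t0 = 0.35, postdecision_duration = 0.8,
                      confidence_cutpoints = c(0, 0.8), v_sd = 0.1),
      stages = c("simulate", "ddm", "vratio", "rt_stats")),
    control1 = list(
      kind = "sdt",
      design = list(asynchrony_levels_ms = c(18L, 31L, 52L, 88L, 150L),
                    touches_levels = 6L, trials_per_condition = 60L,
                    n_subjects = 32L),
      observer = list(dprime = 0, criterion_c = 0, mratio = 0.8,
                      lapse_rate = 0.01, dprime_sd = 0.1, logm_sd = 0.25),
      stages = c("simulate", "sdt", "stats")),
    control2 = list(
      kind = "sdt",
      design = list(asynchrony_levels_ms = c(18L, 31L, 52L, 88L, 150L),
                    touches_levels = 6L, trials_per_condition = 60L,
                    n_subjects = 32L),
      observer = list(dprime = c(0.5, 0.8, 1.0, 1.3, 1.5), criterion_c = 0,
                      mratio = 0.5, lapse_rate = 0.01,
                      dprime_sd = 0.15, logm_sd = 0.25),
      stages = c("simulate", "sdt", "metad", "hmeta", "stats"))
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages appropriate to the configuration's template —
#' simulate, type-1 SDT, meta-d'/M-ratio, hierarchical group M-ratio with
#' pairwise HDI comparisons, group statistics, and for the speeded template
#' the hierarchical diffusion fit, v-ratio, and response-time tests — and
#' returns all tidy result tables. Every table carries the configuration hash
#' and seed as attributes; re-running with an identical configuration
#' reproduces non-MCMC outputs bit-identically.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, tables are written with
#'   [write_tables()] (also on stage failure, for the stages completed).
#' @param quiet suppress progress messages.
#' @return a `report_bundle`: list of tibbles plus `config` and `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  bundle <- list(config = config)
  log <- tibble(stage = character(), seconds = numeric(), seed = integer())
  say <- function(...) if (!quiet) message(...)
  run_stage <- function(name, seed_offset, fun) {
    t0 <- Sys.time()
    stage_seed <- (config$seed + seed_offset) %% .Machine$integer.max
    res <- tryCatch(fun(stage_seed), error = function(e) {
      if (!is.null(out_dir)) {
        bundle$log <<- log
        try(write_tables(structure(bundle, class = "report_bundle"), out_dir),
            silent = TRUE)
      }
      abort(paste0("pipeline stage `", name, "` failed: ",
                   conditionMessage(e)),
            class = "metaown_stage_error")
    })
    log <<- bind_rows(log, tibble(stage = name,
                                  seconds = as.numeric(difftime(Sys.time(), t0,
                                                                units = "secs")),
                                  seed = as.integer(stage_seed)))
    say("stage ", name, " done")
    res
  }
  dsg <- do.call(design_spec, config$design)
  smp <- config$sampler

  if ("simulate" %in% config$stages) {
    bundle$trials <- run_stage("simulate", 1L, function(s) {
      if (config$kind == "ddm") {
        simulate_ddm_experiment(dsg, do.call(ddm_observer, config$observer),
                                seed = s, experiment = config$template)
      } else {
        simulate_sdt_dataset(dsg, do.call(sdt_observer, config$observer),
                             seed = s, experiment = config$template)
      }
    })
  }
  if ("sdt" %in% config$stages) {
    bundle$sdt <- run_stage("sdt", 2L, function(s) fit_sdt(bundle$trials))
  }
  if ("metad" %in% config$stages) {
    bundle$metad <- run_stage("metad", 3L, function(s) fit_metad_by(bundle$trials))
  }
  if ("hmeta" %in% config$stages) {
    post <- run_stage("hmeta", 4L, function(s) {
      fit_hmeta_group(bundle$trials, chains = smp$chains,
                      iterations = smp$iterations, burn_in = smp$burn_in,
                      seed = s)
    })
    bundle$hmeta_posterior <- post
    bundle$hmeta <- tidy(post)
    bundle$hmeta_comparisons <- compare_all_conditions(post)
  }
  if ("ddm" %in% config$stages) {
    post <- run_stage("ddm", 5L, function(s) {
      fit_hddm(bundle$trials, chains = smp$chains,
               iterations = smp$iterations, burn_in = smp$burn_in, seed = s)
    })
    bundle$ddm_posterior <- post
    bundle$ddm <- tidy(post)
  }
  if ("vratio" %in% config$stages) {
    bundle$vratio <- run_stage("vratio", 6L, function(s) {
      fit_vratio_by(bundle$trials)
    })
  }
  if ("stats" %in% config$stages) {
    bundle$stats <- run_stage("stats", 7L, function(s) {
      sdt_long <- mutate(bundle$sdt,
                         condition = condition_label(
                           .data$asynchrony_ms, .data$n_touches,
                           multi_touch = length(dsg$touches_levels) > 1))
      anova_d <- rm_anova_gg(sdt_long, value = "dprime",
                             subject = "subject", condition = "condition")
      bf_d <- sdt_long |>
        group_by(.data$condition) |>
        dplyr::reframe(bayes_t_one_sample(.data$dprime, direction = "positive"))
      out <- bind_rows(
        mutate(anova_d, measure = "dprime", test = "rm_anova_gg",
               condition = NA_character_, bf = NA_real_),
        mutate(bf_d, measure = "dprime", test = "bayes_t_positive",
               F = NA_real_, p = NA_real_)
      )
      if (!is.null(bundle$metad)) {
        m_long <- mutate(bundle$metad,
                         condition = condition_label(
                           .data$asynchrony_ms, .data$n_touches,
                           multi_touch = length(dsg$touches_levels) > 1))
        anova_m <- rm_anova_gg(m_long, value = "mratio",
                               subject = "subject", condition = "condition")
        bf01 <- bf_oneway_rm(
          as_subject_condition_matrix(m_long, value = "mratio",
                                      subject = "subject",
                                      condition = "condition"),
          seed = s)
        out <- bind_rows(
          out,
          mutate(anova_m, measure = "mratio", test = "rm_anova_gg",
                 condition = NA_character_, bf = NA_real_),
          tibble(measure = "mratio", test = "bf01_oneway_rm", bf = bf01))
      }
      out
    })
  }
  if ("rt_stats" %in% config$stages) {
    bundle$rt_stats <- run_stage("rt_stats", 8L, function(s) {
      trials <- bundle$trials[!bundle$trials$censored, ]
      np <- nonparametric_tests(trials, value = "rt_decision_s",
                                group = "asynchrony_ms")
      bind_rows(mutate(np$normality, test = "ks_normality"),
                mutate(np$kruskal, test = "kruskal_wallis"))
    })
  }
  bundle$log <- log
  # stamp tables with provenance
  for (nm in names(bundle)) {
    if (is.data.frame(bundle[[nm]])) {
      attr(bundle[[nm]], "config_hash") <- config$hash
      attr(bundle[[nm]], "seed") <- config$seed
    }
  }
  res <- structure(bundle, class = "report_bundle")
  if (!is.null(out_dir)) write_tables(res, out_dir)
  res
}

#' Write a report bundle to disk
#'
#' Writes every result table as tab-separated text, posterior draws in a
#' columnar chain/iteration/parameter format, the stage log, and a manifest
#' with the configuration hash, seed and package version.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tables <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle)) {
    x <- bundle[[nm]]
    if (is.data.frame(x)) {
      readr::write_tsv(x, file.path(dir, paste0(nm, ".tsv")), progress = FALSE)
    } else if (inherits(x, "posterior_samples")) {
      readr::write_tsv(tidy_draws(x), file.path(dir, paste0(nm, "_draws.tsv")),
                       progress = FALSE)
    }
  }
  cfg <- bundle$config
  manifest <- c(paste0("template: ", cfg$template),
                paste0("seed: ", cfg$seed),
                paste0("config_hash: ", cfg$hash),
                paste0("package_version: ",
                       as.character(utils::packageVersion("metaown"))),
                paste0("written: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Posterior draws as a tidy table
#'
#' @param post a `posterior_samples`.
#' @return tibble with `chain`, `iteration`, one column per parameter.
#' @export
tidy_draws <- function(post) {
  d <- post$draws
  dm <- dim(d)
  out <- tibble(chain = rep(seq_len(dm[1]), dm[2]),
                iteration = rep(seq_len(dm[2]), each = dm[1]))
  for (j in seq_len(dm[3])) out[[post$params[j]]] <- as.vector(d[, , j])
  out
}
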