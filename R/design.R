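#' Experimental design specification
#'
#' Describes a two-rubber-hands 2AFC ownership experiment: the set of
#' visuotactile asynchronies between the seen and felt taps, the number of
#' touches used to induce the illusion, trials per condition, and whether
#' responses are speeded (self-terminated stimulation with an upper limit on
#' stimulation time).
#'
#' Default values give the classic unspeeded design: five asynchronies
#' (18, 31, 52, 88, 150 ms), six touches over 12 s, 60 trials per asynchrony
#' (300 trials in total). A touch-number manipulation adds `touches_levels`;
#' a speeded design uses `speeded = TRUE` with `max_stim_duration_s` capping
#' stimulation (30 s), and 480 trials over eight 60-trial blocks is obtained
#' with 96 trials per asynchrony.
#'
#' @param asynchrony_levels_ms strictly increasing positive integers (ms).
#' @param touches_levels positive integers; number of taps per trial.
#' @param trials_per_condition trials in each asynchrony x touches cell.
#' @param n_subjects number of simulated observers.
#' @param speeded logical; speeded response mode.
#' @param max_stim_duration_s cap on stimulation time in speeded mode (s).
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(asynchrony_levels_ms = c(18L, 31L, 52L, 88L, 150L),
                        touches_levels = 6L,
                        trials_per_condition = 60L,
                        n_subjects = 32L,
                        speeded = FALSE,
                        max_stim_duration_s = 30) {
  if (length(asynchrony_levels_ms) < 1 || any(asynchrony_levels_ms <= 0) ||
      is.unsorted(asynchrony_levels_ms, strictly = TRUE)) {
    abort("`asynchrony_levels_ms` must be strictly increasing positive values.",
          class = "metaown_config_error")
  }
  if (any(touches_levels <= 0)) {
    abort("`touches_levels` must be positive.", class = "metaown_config_error")
  }
  if (trials_per_condition < 1 || n_subjects < 1) {
    abort("`trials_per_condition` and `n_subjects` must be positive.",
          class = "metaown_config_error")
  }
  if (max_stim_duration_s <= 0) {
    abort("`max_stim_duration_s` must be positive.",
          class = "metaown_config_error")
  }
  structure(
    list(asynchrony_levels_ms = as.integer(asynchrony_levels_ms),
         touches_levels = as.integer(touches_levels),
         trials_per_condition = as.integer(trials_per_condition),
         n_subjects = as.integer(n_subjects),
         speeded = isTRUE(speeded),
         max_stim_duration_s = max_stim_duration_s),
    class = "design_spec"
  )
}

#' Condition table of a design
#'
#' @param design a [design_spec()].
#' @return tibble with `asynchrony_ms`, `n_touches` and a `condition` label.
#' @export
design_conditions <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  crossing(n_touches = design$touches_levels,
           asynchrony_ms = design$asynchrony_levels_ms) |>
    mutate(condition = condition_label(.data$asynchrony_ms, .data$n_touches,
                                       multi_touch = length(design$touches_levels) > 1)) |>
    select("condition", "asynchrony_ms", "n_touches")
}

condition_label <- function(asynchrony_ms, n_touches, multi_touch = FALSE) {
  if (multi_touch) sprintf("%dms_%dt", asynchrony_ms, n_touches)
  else sprintf("%dms", asynchrony_ms)
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec> ", length(x$asynchrony_levels_ms), " asynchronies (",
      paste(x$asynchrony_levels_ms, collapse = ", "), " ms) x ",
      length(x$touches_levels), " touch levels (",
      paste(x$touches_levels, collapse = ", "), "), ",
      x$trials_per_condition, " trials/condition, ",
      x$n_subjects, " subjects",
      if (x$speeded) paste0(", speeded (max ", x$max_stim_duration_s, " s)"),
      "\n", sep = "")
  invisible(x)
}

#' Signal-detection observer parameters
#'
#' Generative parameters of a synthetic 2AFC observer with a metacognitive
#' layer. Type-1 evidence is an equal-variance Gaussian whose separation is
#' calibrated so that the fitted 2AFC d' (with the 1/sqrt(2) convention)
#' recovers `dprime`. Awareness (PAS) ratings come from a second Gaussian
#' evidence sample with sensitivity `mratio * dprime`, drawn congruent with
#' the side of the type-1 response relative to the scaled decision criterion —
#' the exact generative counterpart of the meta-d' model, so the fitted
#' M-ratio recovers `mratio` for any positive value.
#'
#' @param dprime type-1 sensitivity per condition (recycled to the number of
#'   design conditions), in 2AFC d' units.
#' @param criterion_c decision criterion C (positive = left bias).
#' @param mratio target metacognitive efficiency meta-d'/d' (> 0).
#' @param type2_criteria two positive increments placing the PAS 1/2 and 2/3
#'   cut-points outward from the decision criterion on the meta-evidence axis.
#' @param lapse_rate probability of a lapse trial: a uniform random response
#'   with a stimulus-independent rating.
#' @param dprime_sd,logm_sd between-subject SDs of d' and log M-ratio.
#' @return an object of class `sdt_observer`.
#' @export
sdt_observer <- function(dprime, criterion_c = 0, mratio = 0.8,
                         type2_criteria = c(0.5, 0.6), lapse_rate = 0,
                         dprime_sd = 0, logm_sd = 0) {
  if (any(dprime < 0)) abort("`dprime` must be nonnegative.",
                             class = "metaown_config_error")
  if (mratio <= 0) abort("`mratio` must be positive.",
                         class = "metaown_config_error")
  if (length(type2_criteria) != 2 || any(type2_criteria <= 0)) {
    abort("`type2_criteria` must be two positive increments.",
          class = "metaown_config_error")
  }
  if (lapse_rate < 0 || lapse_rate > 1) {
    abort("`lapse_rate` must lie in [0, 1].", class = "metaown_config_error")
  }
  structure(
    list(dprime = dprime, criterion_c = criterion_c, mratio = mratio,
         type2_criteria = type2_criteria, lapse_rate = lapse_rate,
         dprime_sd = dprime_sd, logm_sd = logm_sd),
    class = "sdt_observer"
  )
}

#' Drift-diffusion observer parameters
#'
#' Generative parameters of a speeded 2AFC observer: a Wiener diffusion with
#' diffusion scale fixed at s = 1, absorbing boundaries 0 and `a`, start point
#' `w * a`, and per-condition drift `v` signed toward the correct boundary.
#' After the decision, evidence continues to accumulate for the trial's
#' post-decision interval with drift `v_post` (still signed by the stimulus);
#' the terminal state, expressed in the frame of the chosen response, is cut
#' by `confidence_cutpoints` into PAS 1-3.
#'
#' @param v drift rate per condition (evidence units / s).
#' @param a boundary separation (> 0).
#' @param w relative start point in (0, 1).
#' @param t0 nondecision time in seconds (>= 0).
#' @param v_post postdecisional drift rate.
#' @param postdecision_duration mean duration of postdecisional accumulation (s).
#' @param confidence_cutpoints two ordered reals cutting the postdecisional
#'   accumulator into PAS 1/2/3.
#' @param v_sd between-subject SD of drift.
#' @return an object of class `ddm_observer`.
#' @export
ddm_observer <- function(v, a = 1.8, w = 0.5, t0 = 0.3,
                         v_post = NULL, postdecision_duration = 0.8,
                         confidence_cutpoints = c(0, 0.8), v_sd = 0) {
  if (a <= 0) abort("boundary `a` must be positive.",
                    class = "metaown_config_error")
  if (w <= 0 || w >= 1) abort("`w` must lie in (0, 1).",
                              class = "metaown_config_error")
  if (t0 < 0) abort("`t0` must be nonnegative.", class = "metaown_config_error")
  if (postdecision_duration <= 0) {
    abort("`postdecision_duration` must be positive.",
          class = "metaown_config_error")
  }
  if (length(confidence_cutpoints) != 2 ||
      diff(confidence_cutpoints) <= 0) {
    abort("`confidence_cutpoints` must be two ordered values.",
          class = "metaown_config_error")
  }
  structure(
    list(v = v, a = a, w = w, t0 = t0,
         v_post = v_post %||% v, postdecision_duration = postdecision_duration,
         confidence_cutpoints = confidence_cutpoints, v_sd = v_sd),
    class = "ddm_observer"
  )
}

#' Rubber-hand illusion inclusion test
#'
#' Applies the standard questionnaire criterion for experiencing the illusion:
#' the mean of the three ownership statements (Q1-Q3) must exceed 1, and must
#' exceed the mean of the six control statements (Q4-Q9) by more than 1.
#'
#' @param q data frame with columns `Q1`..`Q9` (one row per participant), or a
#'   numeric vector of nine scores.
#' @return logical vector, `TRUE` for participants who pass.
#' @export
inclusion_filter <- function(q) {
  if (is.numeric(q) && is.null(dim(q))) {
    if (length(q) != 9) {
      abort("expected nine questionnaire items (Q1-Q9).",
            class = "metaown_validation_error")
    }
    q <- as_tibble(as.list(setNames(q, paste0("Q", 1:9))))
  }
  items <- paste0("Q", 1:9)
  missing <- setdiff(items, names(q))
  if (length(missing)) {
    abort(paste0("missing questionnaire items: ", paste(missing, collapse = ", ")),
          class = "metaown_validation_error")
  }
  qm <- as.matrix(q[items])
  if (anyNA(qm)) abort("questionnaire items contain missing values.",
                       class = "metaown_validation_error")
  own <- rowMeans(qm[, 1:3, drop = FALSE])
  ctl <- rowMeans(qm[, 4:9, drop = FALSE])
  unname(own > 1 & (own - ctl) > 1)
}
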