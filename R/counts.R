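trial_schema <- c("subject", "experiment", "asynchrony_ms", "n_touches",
                  "sync_side", "response_side", "pas",
                  "rt_decision_s", "rt_postdecision_s", "censored")

#' Validate a trial table
#'
#' Checks the standard trial schema: sides in \{left, right\}, PAS in 1-3,
#' nonnegative response times. Returns the table invisibly; aborts with a
#' row-level message otherwise.
#'
#' @param trials trial tibble.
#' @param required columns that must be present.
#' @return `trials`, invisibly.
#' @export
validate_trials <- function(trials, required = c("sync_side", "response_side", "pas")) {
  missing <- setdiff(required, names(trials))
  if (length(missing)) {
    abort(paste0("trial table is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "metaown_validation_error")
  }
  check_levels <- function(col, levels) {
    if (!col %in% names(trials)) return()
    bad <- which(!trials[[col]] %in% levels)
    if (length(bad)) {
      abort(sprintf("column `%s` has invalid value `%s` at row %d.",
                    col, as.character(trials[[col]][bad[1]]), bad[1]),
            class = "metaown_validation_error")
    }
  }
  check_levels("sync_side", c("left", "right"))
  check_levels("response_side", c("left", "right"))
  check_levels("pas", 1:3)
  for (col in c("rt_decision_s", "rt_postdecision_s")) {
    if (col %in% names(trials)) {
      bad <- which(!is.na(trials[[col]]) & trials[[col]] < 0)
      if (length(bad)) {
        abort(sprintf("column `%s` is negative at row %d.", col, bad[1]),
              class = "metaown_validation_error")
      }
    }
  }
  invisible(trials)
}

#' Tabulate type-1 and type-2 response counts
#'
#' Builds the count table that the SDT and meta-d' fits consume. With the
#' right hand coded as the "signal" side: a hit is responding "right" when the
#' right hand was synchronously tapped, a false alarm is responding "right"
#' when the left hand was (i.e., the right hand was the asynchronous one).
#' Type-2 counts are ratings cross-classified by response side and
#' correctness.
#'
#' @param trials trial tibble (standard schema).
#' @param condition optional named list selecting rows, e.g.
#'   `list(asynchrony_ms = 52)`; matched against equality on columns.
#' @return an object of class `count_table` with fields `n_hit`, `n_miss`,
#'   `n_fa`, `n_cr` and `type2`, a `response x correctness x rating` array.
#' @export
tabulate_counts <- function(trials, condition = NULL) {
  validate_trials(trials)
  if (!is.null(condition)) {
    for (nm in names(condition)) {
      if (!nm %in% names(trials)) {
        abort(paste0("selector column `", nm, "` not in trial table."),
              class = "metaown_validation_error")
      }
      trials <- trials[trials[[nm]] %in% condition[[nm]], , drop = FALSE]
    }
  }
  if ("censored" %in% names(trials)) trials <- trials[!trials$censored, , drop = FALSE]
  if (nrow(trials) == 0) {
    abort("no trials match the condition selector.",
          class = "metaown_validation_error")
  }
  sig <- trials$sync_side == "right"
  rr <- trials$response_side == "right"
  correct <- sig == rr
  type2 <- array(0L, dim = c(2, 2, 3),
                 dimnames = list(response = c("left", "right"),
                                 correctness = c("incorrect", "correct"),
                                 rating = 1:3))
  tab <- table(factor(trials$response_side, c("left", "right")),
               factor(ifelse(correct, "correct", "incorrect"),
                      c("incorrect", "correct")),
               factor(trials$pas, 1:3))
  type2[] <- as.integer(tab)
  structure(
    list(n_hit = sum(sig & rr), n_miss = sum(sig & !rr),
         n_fa = sum(!sig & rr), n_cr = sum(!sig & !rr),
         type2 = type2, n_ratings = 3L, n_trials = nrow(trials)),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> ", x$n_trials, " trials: hit ", x$n_hit, ", miss ",
      x$n_miss, ", fa ", x$n_fa, ", cr ", x$n_cr, "\n", sep = "")
  print(x$type2)
  invisible(x)
}

# counts indexed by (stimulus, response, rating); stimulus "right" means the
# right hand was the synchronous one
counts_by_stimulus <- function(counts) {
  t2 <- counts$type2
  out <- array(0L, dim = c(2, 2, counts$n_ratings),
               dimnames = list(stimulus = c("left", "right"),
                               response = c("left", "right"),
                               rating = seq_len(counts$n_ratings)))
  # response right & correct -> stimulus right; right & incorrect -> left, etc.
  out["right", "right", ] <- t2["right", "correct", ]
  out["left", "right", ] <- t2["right", "incorrect", ]
  out["left", "left", ] <- t2["left", "correct", ]
  out["right", "left", ] <- t2["left", "incorrect", ]
  out
}
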