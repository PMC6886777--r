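#' Tidy an FLR curve
#'
#' @param x A `phosphosim_flr` curve.
#' @param ... Ignored.
#' @return A plain tibble of the curve rows plus the score field name.
#' @method tidy phosphosim_flr
#' @export
tidy.phosphosim_flr <- function(x, ...) {
  out <- as_tibble(x)
  out$score_field <- attr(x, "score_field") %||% NA_character_
  out
}

#' One-row summary of an FLR curve
#'
#' @param x A `phosphosim_flr` curve.
#' @param target FLR level for the cutoff summary, default 0.01.
#' @param ... Ignored.
#' @return A one-row tibble: totals, sequence errors, cutoff and correct
#'   count at `target`.
#' @method glance phosphosim_flr
#' @export
glance.phosphosim_flr <- function(x, target = 0.01, ...) {
  cut <- cutoff_at_flr(x, target)
  n <- nrow(x)
  tibble(
    n_scored = if (n) x$n_correct[[n]] + x$n_false[[n]] else 0L,
    n_sequence_errors = attr(x, "n_sequence_errors") %||% NA_integer_,
    flr_target = target,
    cutoff = cut$cutoff,
    n_correct_at_cutoff = cut$n_correct
  )
}

#' Tidy a condition-sweep result
#'
#' @param x A `phosphosim_sweep` tibble.
#' @param ... Ignored.
#' @return The sweep rows as a plain tibble.
#' @method tidy phosphosim_sweep
#' @export
tidy.phosphosim_sweep <- function(x, ...) as_tibble(x)

#' One-row summary of a condition sweep
#'
#' @param x A `phosphosim_sweep` tibble.
#' @param ... Ignored.
#' @return A one-row tibble naming the best (condition, scoring) pair and
#'   its correct count and cutoff.
#' @method glance phosphosim_sweep
#' @export
glance.phosphosim_sweep <- function(x, ...) {
  best <- x[which.max(x$n_correct), ]
  tibble(
    n_conditions = length(unique(x$condition)),
    n_scorings = length(unique(x$scoring)),
    best_condition = best$condition,
    best_scoring = best$scoring,
    best_n_correct = best$n_correct,
    best_cutoff = best$cutoff
  )
}
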