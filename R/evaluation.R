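# half-up rounding to match printed two-decimal accuracy tables
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Rank snapshots by best FEB
#'
#' Ascending numeric order: the most negative (best-binding) FEB first. Ties
#' are broken by snapshot id so the ranking is deterministic.
#'
#' @param feb Named numeric vector (`snapshot_id -> best FEB`) or a data frame
#'   with columns `snapshot_id` and `best_feb`.
#' @return Character vector of snapshot ids, best first.
#' @examples
#' rank_by_feb(c(a = -9, b = -7, c = -8)) # "a" "c" "b"
#' @export
rank_by_feb <- function(feb) {
  if (is.data.frame(feb)) {
    stopifnot(all(c("snapshot_id", "best_feb") %in% names(feb)))
    feb <- setNames(feb$best_feb, feb$snapshot_id)
  }
  if (anyNA(feb) || any(!is.finite(feb))) {
    abort("All FEB values must be finite to rank.")
  }
  names(feb)[order(feb, names(feb))]
}

#' The best-p% snapshot set
#'
#' The `floor(level * M)` snapshots with the lowest FEB under a ranking; the
#' reference set for selection accuracy.
#'
#' @param ranked Character vector from [rank_by_feb()].
#' @param level Fraction in (0, 1].
#' @param n_total Model size `M`; defaults to `length(ranked)`.
#' @return Character vector of the set's member ids (in rank order).
#' @examples
#' length(best_set(as.character(1:3100), 0.10)) # 310
#' @export
best_set <- function(ranked, level, n_total = length(ranked)) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level > 1) {
    abort("`level` must be a single fraction in (0, 1].")
  }
  head(ranked, floor(level * n_total))
}

#' Selection accuracy against a best-FEB set
#'
#' The percentage of a reference best-p% set recovered by a selection:
#' `100 * |selected intersect best| / |best|`, rounded half-up to two
#' decimals (the precision of the published accuracy tables).
#'
#' @param selected Character vector of selected (docked) snapshot ids.
#' @param best Character vector, the reference best set.
#' @return A single numeric percentage in \[0, 100\].
#' @examples
#' selection_accuracy(as.character(1:305), as.character(1:310)) # 98.39
#' @export
selection_accuracy <- function(selected, best) {
  if (!length(best)) abort("The reference best set is empty.")
  round_half_up(100 * length(intersect(selected, best)) / length(best), 2)
}

#' Summarise a terminated campaign against ground truth
#'
#' Ranks the ground-truth FEBs, forms the best-10/20/30% sets, and reports how
#' much of each the campaign's docked set retained, together with the
#' docked/discarded bookkeeping. Only undocked members of discarded subgroups
#' count as discarded; their already-docked members stay in the docked tally.
#'
#' @param state A terminated `rffr_state` (every subgroup `F` or `D`).
#' @param ground_truth Named numeric vector of true best FEBs.
#' @param levels Best-set levels to evaluate.
#' @return A list of class `rffr_summary`: `n_snapshots`, `n_docked`,
#'   `n_discarded`, `n_batches`, and an `accuracy` tibble (`level`,
#'   `best_size`, `n_selected`, `accuracy`).
#' @export
summarize_campaign <- function(state, ground_truth,
                               levels = c(0.10, 0.20, 0.30)) {
  stopifnot(inherits(state, "rffr_state"))
  if (!all(state$subgroups$status %in% c("F", "D"))) {
    abort("Campaign has not terminated: subgroups remain active.")
  }
  docked_ids <- state$snapshots$snapshot_id[state$snapshots$docked]
  ranked <- rank_by_feb(ground_truth)
  m <- length(ranked)
  acc <- purrr::map(levels, function(lv) {
    bs <- best_set(ranked, lv, m)
    tibble(
      level = lv,
      best_size = length(bs),
      n_selected = length(intersect(docked_ids, bs)),
      accuracy = selection_accuracy(docked_ids, bs)
    )
  }) |> bind_rows()
  structure(
    list(
      n_snapshots = nrow(state$snapshots),
      n_docked = length(docked_ids),
      n_discarded = sum(state$snapshots$discarded & !state$snapshots$docked),
      n_batches = state$batch_index,
      accuracy = acc
    ),
    class = "rffr_summary"
  )
}

#' @export
print.rffr_summary <- function(x, ...) {
  cat(sprintf(
    "<rffr campaign summary> %d snapshots: %d docked, %d discarded, %d batches\n",
    x$n_snapshots, x$n_docked, x$n_discarded, x$n_batches
  ))
  cat("Retention of the ground-truth best-FEB sets:\n")
  for (i in seq_len(nrow(x$accuracy))) {
    cat(sprintf(
      "  best %2.0f%%: %4d of %4d selected, accuracy %6.2f%%\n",
      100 * x$accuracy$level[i], x$accuracy$n_selected[i],
      x$accuracy$best_size[i], x$accuracy$accuracy[i]
    ))
  }
  invisible(x)
}

#' @method tidy rffr_summary
#' @export
tidy.rffr_summary <- function(x, ...) {
  x$accuracy
}

#' @method glance rffr_summary
#' @export
glance.rffr_summary <- function(x, ...) {
  tibble(
    n_snapshots = x$n_snapshots,
    n_docked = x$n_docked,
    n_discarded = x$n_discarded,
    n_batches = x$n_batches,
    min_accuracy = min(x$accuracy$accuracy)
  )
}

#' @method autoplot rffr_summary
#' @export
autoplot.rffr_summary <- function(object, ...) {
  ggplot2::ggplot(
    object$accuracy,
    ggplot2::aes(x = factor(100 * .data$level), y = .data$accuracy)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::labs(
      x = "best-FEB set level (%)",
      y = "retention of the best set (%)",
      title = sprintf(
        "Reduced model quality: %d of %d snapshots docked",
        object$n_docked, object$n_snapshots
      )
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 100))
}
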