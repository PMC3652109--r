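#' Divide clusters of snapshots into subgroups
#'
#' Each cluster is split, in its input order, into contiguous chunks of at
#' most `subgroup_size` snapshots. Subgroups are the unit of adaptive control:
#' they start active (`A`) at priority 2 and are later promoted, demoted,
#' finalized, or discarded as their docking results accumulate. Subgroup ids
#' follow the `G{cluster}L{chunk}` convention.
#'
#' @param clustering Tibble from [read_clustering()] (columns `snapshot_id`,
#'   `cluster_id`).
#' @param subgroup_size Maximum members per subgroup.
#' @return The clustering tibble with a `subgroup_id` column added.
#' @examples
#' cl <- tibble::tibble(snapshot_id = paste0("s", 1:10), cluster_id = "c1")
#' table(form_subgroups(cl, subgroup_size = 4)$subgroup_id)
#' @export
form_subgroups <- function(clustering, subgroup_size = 155L) {
  subgroup_size <- as.integer(subgroup_size)
  if (is.na(subgroup_size) || subgroup_size < 1L) {
    abort("`subgroup_size` must be a positive integer.")
  }
  if (nrow(clustering) == 0L) abort("Cannot form subgroups from an empty clustering.")
  cluster_index <- match(clustering$cluster_id, unique(clustering$cluster_id))
  clustering |>
    mutate(.cluster_index = cluster_index) |>
    group_by(.data$cluster_id) |>
    mutate(
      .chunk = (row_number() - 1L) %/% subgroup_size + 1L,
      subgroup_id = sprintf("G%dL%d", .data$.cluster_index, .data$.chunk)
    ) |>
    ungroup() |>
    select(-".cluster_index", -".chunk")
}

#' Should the adaptive analysis run?
#'
#' Analysis starts once the docked fraction reaches the configured start
#' percentage and keeps running after every batch from then on. A start
#' percentage of 1 disables the analysis entirely: the whole model is docked
#' and nothing is ever discarded.
#'
#' @param progress Fraction of the model docked, in \[0, 1\].
#' @param start_pct Configured start percentage, in (0, 1].
#' @return `TRUE` when the analysis should run.
#' @examples
#' should_analyze(0.30, 0.30) # TRUE: the threshold is inclusive
#' should_analyze(1.00, 1.00) # FALSE: analysis disabled
#' @export
should_analyze <- function(progress, start_pct) {
  stopifnot(progress >= 0, progress <= 1, start_pct > 0, start_pct <= 1)
  start_pct < 1 && progress >= start_pct
}

#' Score every subgroup from partial docking results
#'
#' A subgroup's score is the mean best FEB (kcal/mol) over its docked members;
#' it is undefined (`NA`) until at least `m_min` members have docked, so that
#' one early lucky or unlucky docking cannot decide a subgroup's fate.
#'
#' @param state An `rffr_state`.
#' @param m_min Minimum docked members before a score is defined.
#' @return Tibble with `subgroup_id`, `n_docked`, `n_members`, `score`.
#' @export
subgroup_scores <- function(state, m_min = 3L) {
  state$snapshots |>
    group_by(.data$subgroup_id) |>
    summarise(
      n_docked = sum(.data$docked),
      n_members = n(),
      score = ifelse(
        sum(.data$docked) >= m_min,
        mean(.data$best_feb[.data$docked]),
        NA_real_
      ),
      .groups = "drop"
    ) |>
    arrange(.data$subgroup_id)
}

#' Evaluate subgroups against the pooled FEB distribution
#'
#' The core adaptive rule. Let `G` be the empirical distribution of every
#' docked best-FEB value so far (linear-interpolation quantiles on the sorted
#' list). Each active subgroup with a defined score `s` is banded:
#' `s <= quantile(G, q1)` earns priority 1, `s <= quantile(G, q2)` priority 2,
#' otherwise priority 3; additionally `s > quantile(G, qd)` marks the subgroup
#' discarded (`D`) — unless every member has already docked, in which case the
#' subgroup is finalized (`F`) regardless of score. Only actual changes are
#' returned, ordered by subgroup id.
#'
#' @param state An `rffr_state` with at least one docking result.
#' @param criteria A [criteria_params()] object.
#' @return A tibble of changes: `subgroup_id`, `old_priority`, `new_priority`,
#'   `old_status`, `new_status`, `reason`.
#' @export
evaluate_subgroups <- function(state, criteria) {
  stopifnot(inherits(state, "rffr_state"), inherits(criteria, "rffr_criteria"))
  pooled <- state$snapshots$best_feb[state$snapshots$docked]
  if (!length(pooled)) {
    abort("Cannot evaluate subgroups before any docking result exists.")
  }
  cuts <- quantile(pooled, c(criteria$q1, criteria$q2, criteria$qd),
    names = FALSE, type = 7
  )
  scores <- subgroup_scores(state, m_min = criteria$m_min) |>
    select("subgroup_id", "n_docked", "score")
  info <- state$subgroups |>
    left_join(scores, by = "subgroup_id") |>
    filter(.data$status == "A") |>
    arrange(.data$subgroup_id)

  changes <- purrr::map(seq_len(nrow(info)), function(i) {
    row <- info[i, ]
    if (row$n_docked == row$n_members) {
      return(tibble(
        subgroup_id = row$subgroup_id,
        old_priority = row$priority, new_priority = row$priority,
        old_status = row$status, new_status = "F",
        reason = "all members docked"
      ))
    }
    if (is.na(row$score)) return(NULL)
    s <- row$score
    new_priority <- if (s <= cuts[1]) 1L else if (s <= cuts[2]) 2L else 3L
    new_status <- if (s > cuts[3]) "D" else row$status
    reason <- if (new_status == "D") {
      sprintf("score %.4f above discard quantile %.4f", s, cuts[3])
    } else {
      sprintf("score %.4f in priority-%d band", s, new_priority)
    }
    if (new_priority == row$priority && new_status == row$status) return(NULL)
    tibble(
      subgroup_id = row$subgroup_id,
      old_priority = row$priority, new_priority = new_priority,
      old_status = row$status, new_status = new_status,
      reason = reason
    )
  })
  out <- bind_rows(changes)
  if (nrow(out) == 0L) {
    out <- tibble(
      subgroup_id = character(),
      old_priority = integer(), new_priority = integer(),
      old_status = character(), new_status = character(),
      reason = character()
    )
  }
  out
}

#' Apply subgroup changes to the campaign state
#'
#' Updates priorities and statuses, records one provenance event and queues
#' one update-file record per changed field, and on a discard removes the
#' subgroup's undocked members from the pending pool (already-docked members
#' keep their results). A priority change is the transient "P" condition: it
#' is visible in provenance while the subgroup keeps operating as active.
#'
#' @param state An `rffr_state`.
#' @param changes Tibble from [evaluate_subgroups()].
#' @return The updated state.
#' @export
apply_changes <- function(state, changes) {
  stopifnot(inherits(state, "rffr_state"))
  unknown <- setdiff(changes$subgroup_id, state$subgroups$subgroup_id)
  if (length(unknown)) {
    abort(paste0("Change references unknown subgroup(s): ",
                 paste(unknown, collapse = ", ")))
  }
  for (i in seq_len(nrow(changes))) {
    ch <- changes[i, ]
    idx <- match(ch$subgroup_id, state$subgroups$subgroup_id)
    if (ch$new_priority != ch$old_priority) {
      state$subgroups$priority[idx] <- ch$new_priority
      state$updates <- c(state$updates, list(list(
        subgroup_id = ch$subgroup_id, priority = ch$new_priority, status = NULL
      )))
      state <- log_event(state, "change", list(
        subgroup = ch$subgroup_id, field = "priority",
        old = ch$old_priority, new = ch$new_priority,
        transient_status = "P", reason = ch$reason
      ))
    }
    if (ch$new_status != ch$old_status) {
      state$subgroups$status[idx] <- ch$new_status
      state$updates <- c(state$updates, list(list(
        subgroup_id = ch$subgroup_id, priority = NULL, status = ch$new_status
      )))
      state <- log_event(state, "change", list(
        subgroup = ch$subgroup_id, field = "status",
        old = ch$old_status, new = ch$new_status, reason = ch$reason
      ))
      if (ch$new_status == "D") {
        drop <- !state$snapshots$docked &
          state$snapshots$subgroup_id == ch$subgroup_id
        state$snapshots$discarded[drop] <- TRUE
      }
    }
  }
  state
}

# append an event to the in-memory provenance list
log_event <- function(state, kind, payload) {
  state$provenance <- c(state$provenance, list(list(
    ordinal = state$next_ordinal, kind = kind, payload = payload
  )))
  state$next_ordinal <- state$next_ordinal + 1L
  state
}
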