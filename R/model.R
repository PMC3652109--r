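#' Experiment configuration
#'
#' Bundles every tunable of an adaptive ensemble-docking campaign: when the
#' adaptive analysis starts, how large the balanced task queues are, and the
#' quantile-band criteria used to promote, demote, or discard subgroups.
#'
#' @param experiment_id Integer identifier, unique per docking experiment.
#' @param start_pct Fraction of the model that must be docked before adaptive
#'   analysis starts, in (0, 1]. At `1` the analysis never runs and every
#'   snapshot is docked.
#' @param n_nodes Number of nodes (`N`); with `tasks_per_node` it fixes the
#'   queue length `Q = N * T`.
#' @param tasks_per_node Parallel tasks per node (`T`).
#' @param criteria A [criteria_params()] object, or `NULL` for defaults.
#' @param seed Integer seed driving every stochastic component.
#' @param subgroup_size Maximum snapshots per subgroup when clusters are split.
#' @param weight_scheme How subgroup priority maps to an apportionment weight:
#'   `"inverse"` (weight `4 - priority`, so priority 1 receives the largest
#'   share) or `"raw"` (weight equal to the priority value).
#'
#' @return A list of class `rffr_config`.
#' @examples
#' experiment_config(start_pct = 0.3, seed = 1)
#' @export
experiment_config <- function(experiment_id = 1L,
                              start_pct = 0.30,
                              n_nodes = 5L,
                              tasks_per_node = 32L,
                              criteria = NULL,
                              seed = 1L,
                              subgroup_size = 155L,
                              weight_scheme = c("inverse", "raw")) {
  weight_scheme <- match.arg(weight_scheme)
  if (!is.numeric(start_pct) || length(start_pct) != 1L ||
      start_pct <= 0 || start_pct > 1) {
    abort("`start_pct` must be a single value in (0, 1].")
  }
  n_nodes <- as.integer(n_nodes)
  tasks_per_node <- as.integer(tasks_per_node)
  if (is.na(n_nodes) || n_nodes < 1L) abort("`n_nodes` must be a positive integer.")
  if (is.na(tasks_per_node) || tasks_per_node < 1L) {
    abort("`tasks_per_node` must be a positive integer.")
  }
  subgroup_size <- as.integer(subgroup_size)
  if (is.na(subgroup_size) || subgroup_size < 1L) {
    abort("`subgroup_size` must be a positive integer.")
  }
  if (is.null(criteria)) {
    criteria <- criteria_params(m_min = max(3L, ceiling(0.1 * subgroup_size)))
  }
  stopifnot(inherits(criteria, "rffr_criteria"))
  structure(
    list(
      experiment_id = as.integer(experiment_id),
      start_pct = start_pct,
      n_nodes = n_nodes,
      tasks_per_node = tasks_per_node,
      criteria = criteria,
      seed = as.integer(seed),
      subgroup_size = subgroup_size,
      weight_scheme = weight_scheme
    ),
    class = "rffr_config"
  )
}

#' Quantile-band criteria for subgroup evaluation
#'
#' Subgroup scores (mean best FEB of docked members, kcal/mol) are compared to
#' quantiles of the pooled docked-FEB distribution: scores at or below the
#' `q1` quantile earn priority 1, scores between `q1` and `q2` priority 2,
#' scores above `q2` priority 3, and scores above the `qd` quantile are
#' discarded. A subgroup is only scored once at least `m_min` of its members
#' have docked.
#'
#' @param q1,q2 Promotion/demotion quantiles, `0 < q1 < q2 <= qd < 1`.
#' @param qd Discard quantile.
#' @param m_min Minimum docked members before a subgroup is scored.
#' @return A list of class `rffr_criteria`.
#' @examples
#' criteria_params(q1 = 1 / 3, q2 = 2 / 3, qd = 0.75, m_min = 5)
#' @export
criteria_params <- function(q1 = 1 / 3, q2 = 2 / 3, qd = 0.75, m_min = 3L) {
  if (!(q1 > 0 && q1 < q2 && q2 <= qd && qd < 1)) {
    abort("Criteria quantiles must satisfy 0 < q1 < q2 <= qd < 1.")
  }
  m_min <- as.integer(m_min)
  if (is.na(m_min) || m_min < 1L) abort("`m_min` must be a positive integer.")
  structure(
    list(q1 = q1, q2 = q2, qd = qd, m_min = m_min),
    class = "rffr_criteria"
  )
}

subgroup_statuses <- c("A", "F", "D", "P")

#' Read an experiment configuration from YAML or JSON
#'
#' Loads a configuration file whose keys mirror the arguments of
#' [experiment_config()] (`experiment_id`, `start_pct`, `n_nodes`,
#' `tasks_per_node`, `subgroup_size`, `seed`, `weight_scheme`, and an
#' optional `criteria` block with `q1`, `q2`, `qd`, `m_min`). Missing keys
#' fall back to the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `rffr_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    abort("Config file must be .yaml, .yml, or .json.")
  }
  known <- c(
    "experiment_id", "start_pct", "n_nodes", "tasks_per_node",
    "subgroup_size", "seed", "weight_scheme"
  )
  unknown <- setdiff(names(raw), c(known, "criteria"))
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  args <- raw[intersect(names(raw), known)]
  if (!is.null(raw$criteria)) {
    args$criteria <- do.call(criteria_params, raw$criteria)
  }
  do.call(experiment_config, args)
}

#' Initialise campaign state from formed subgroups
#'
#' @param subgroups Tibble from [form_subgroups()] with columns `snapshot_id`,
#'   `cluster_id`, `subgroup_id`.
#' @param experiment_id Integer experiment identifier.
#' @return A list of class `rffr_state` holding a per-snapshot tibble
#'   (`snapshots`), a per-subgroup tibble (`subgroups`), the batch counter, and
#'   an in-memory provenance event list.
#' @examples
#' cl <- tibble::tibble(snapshot_id = paste0("s", 1:6),
#'                      cluster_id = rep(c("c1", "c2"), each = 3))
#' st <- new_campaign_state(form_subgroups(cl, subgroup_size = 2))
#' progress(st)
#' @export
new_campaign_state <- function(subgroups, experiment_id = 1L) {
  required <- c("snapshot_id", "cluster_id", "subgroup_id")
  if (!all(required %in% names(subgroups))) {
    abort("`subgroups` needs columns snapshot_id, cluster_id, subgroup_id.")
  }
  snapshots <- tibble(
    snapshot_id = as.character(subgroups$snapshot_id),
    cluster_id = as.character(subgroups$cluster_id),
    subgroup_id = as.character(subgroups$subgroup_id),
    docked = FALSE,
    best_feb = NA_real_,
    discarded = FALSE,
    batch = NA_integer_
  )
  if (anyDuplicated(snapshots$snapshot_id)) {
    abort("Snapshot ids must be unique across the model.")
  }
  sub_tbl <- snapshots |>
    group_by(.data$subgroup_id, .data$cluster_id) |>
    summarise(n_members = n(), .groups = "drop") |>
    mutate(status = "A", priority = 2L) |>
    arrange(.data$subgroup_id)
  structure(
    list(
      experiment_id = as.integer(experiment_id),
      snapshots = snapshots,
      subgroups = sub_tbl,
      batch_index = 0L,
      provenance = list(),
      next_ordinal = 1L,
      updates = list()
    ),
    class = "rffr_state"
  )
}

#' Fraction of the model docked so far
#'
#' @param state An `rffr_state`.
#' @return `n_docked / n_snapshots`, in \[0, 1\].
#' @export
progress <- function(state) {
  stopifnot(inherits(state, "rffr_state"))
  m <- nrow(state$snapshots)
  if (m == 0L) abort("Campaign state holds an empty model.")
  sum(state$snapshots$docked) / m
}

#' Check campaign-state invariants
#'
#' Reports (never raises) violations of the structural invariants: subgroups
#' partition clusters, a snapshot is docked or pending or excluded by discard,
#' a finalized (`F`) subgroup has every member docked, and counts are
#' conserved.
#'
#' @param state An `rffr_state`.
#' @return A character vector of violation messages; empty when valid.
#' @export
validate_state <- function(state) {
  stopifnot(inherits(state, "rffr_state"))
  out <- character()
  snaps <- state$snapshots
  subs <- state$subgroups

  dup <- snaps$snapshot_id[duplicated(snaps$snapshot_id)]
  if (length(dup)) {
    out <- c(out, paste0(
      "partition: snapshot(s) in more than one subgroup: ",
      paste(unique(dup), collapse = ", ")
    ))
  }
  # subgroups must not straddle clusters
  straddle <- snaps |>
    distinct(.data$subgroup_id, .data$cluster_id) |>
    group_by(.data$subgroup_id) |>
    summarise(k = n(), .groups = "drop") |>
    filter(.data$k > 1L)
  if (nrow(straddle)) {
    out <- c(out, paste0(
      "partition: subgroup(s) span multiple clusters: ",
      paste(straddle$subgroup_id, collapse = ", ")
    ))
  }
  if (!setequal(unique(snaps$subgroup_id), subs$subgroup_id)) {
    out <- c(out, "partition: snapshot table and subgroup table disagree on subgroup ids")
  }
  if (!all(subs$status %in% subgroup_statuses)) {
    out <- c(out, "status: unknown subgroup status letter")
  }
  if (!all(subs$priority %in% 1:3)) {
    out <- c(out, "priority: subgroup priority outside 1..3")
  }
  # F implies all members docked
  by_sub <- snaps |>
    group_by(.data$subgroup_id) |>
    summarise(all_docked = all(.data$docked), .groups = "drop")
  fin <- subs$subgroup_id[subs$status == "F"]
  bad_f <- setdiff(fin, by_sub$subgroup_id[by_sub$all_docked])
  if (length(bad_f)) {
    out <- c(out, paste0(
      "status: finalized subgroup(s) with undocked members: ",
      paste(bad_f, collapse = ", ")
    ))
  }
  if (any(snaps$docked & snaps$discarded)) {
    out <- c(out, "conservation: snapshot both docked and discarded")
  }
  if (any(snaps$docked & is.na(snaps$best_feb))) {
    out <- c(out, "results: docked snapshot without a best FEB")
  }
  if (any(!snaps$docked & !is.na(snaps$best_feb))) {
    out <- c(out, "results: undocked snapshot carrying a best FEB")
  }
  # discarded snapshots must sit in D subgroups
  disc_subs <- subs$subgroup_id[subs$status == "D"]
  if (any(snaps$discarded & !snaps$subgroup_id %in% disc_subs)) {
    out <- c(out, "conservation: discarded snapshot outside a discarded subgroup")
  }
  n_total <- nrow(snaps)
  n_acc <- sum(snaps$docked) + sum(!snaps$docked & !snaps$discarded) +
    sum(snaps$discarded & !snaps$docked)
  if (n_acc != n_total) {
    out <- c(out, "conservation: docked + pending + discarded does not cover the model")
  }
  out
}

#' @export
print.rffr_state <- function(x, ...) {
  cat(sprintf(
    "<rffr campaign state> experiment %d: %d snapshots, %d subgroups, batch %d\n",
    x$experiment_id, nrow(x$snapshots), nrow(x$subgroups), x$batch_index
  ))
  cat(sprintf(
    "  docked %d | pending %d | discarded (undocked) %d\n",
    sum(x$snapshots$docked),
    sum(!x$snapshots$docked & !x$snapshots$discarded),
    sum(x$snapshots$discarded & !x$snapshots$docked)
  ))
  invisible(x)
}

# ids still available for dispatch: undocked, undiscarded, in an active subgroup
available_snapshots <- function(state) {
  active <- state$subgroups$subgroup_id[state$subgroups$status == "A"]
  state$snapshots |>
    filter(!.data$docked, !.data$discarded, .data$subgroup_id %in% active)
}
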