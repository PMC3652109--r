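#' Run an adaptive ensemble-docking campaign
#'
#' The end-to-end loop: clusters are split into subgroups, docking tasks are
#' apportioned into priority-balanced queues of `Q = N * T` and dispatched to
#' a simulated worker pool, and — once the configured fraction of the model
#' has been docked — every batch is followed by an adaptive analysis that
#' promotes, demotes, finalizes, or discards subgroups from the pooled FEB
#' distribution. The campaign terminates when every subgroup is finalized or
#' discarded; the docked set is the reduced receptor model.
#'
#' @param clustering Tibble from [read_clustering()] (or a path to one).
#' @param config An [experiment_config()].
#' @param backend A docking backend ([synthetic_backend()] or [dlg_backend()]).
#' @param out_dir Optional directory; when given, the control file, update
#'   files, provenance log, and results table are written there.
#' @param ground_truth Optional named numeric vector of true best FEBs; when
#'   given the report includes a [summarize_campaign()] quality summary.
#' @return A list of class `rffr_campaign`: `config`, final `state`, `results`
#'   tibble (`snapshot_id`, `best_feb`, `n_runs`, `source`, `batch`),
#'   `summary` (or `NULL`), and `files` (paths written, or `NULL`).
#' @examples
#' m <- generate_model(n_snapshots = 60, n_clusters = 3, seed = 1)
#' be <- synthetic_backend(m$ground_truth, seed = 1)
#' cfg <- experiment_config(start_pct = 1, n_nodes = 2, tasks_per_node = 5,
#'                          subgroup_size = 10, seed = 1)
#' run_campaign(m$clustering, cfg, be)$state
#' @export
run_campaign <- function(clustering, config = experiment_config(),
                         backend, out_dir = NULL, ground_truth = NULL) {
  stopifnot(inherits(config, "rffr_config"), inherits(backend, "rffr_backend"))
  if (is.character(clustering)) clustering <- read_clustering(clustering)
  subgroups <- form_subgroups(clustering, config$subgroup_size)
  state <- new_campaign_state(subgroups, config$experiment_id)
  Q <- queue_length(config$n_nodes, config$tasks_per_node)
  n_workers <- Q
  results <- list()

  repeat {
    state <- finalize_docked(state)
    if (all(state$subgroups$status %in% c("F", "D"))) break

    active <- state$subgroups |> filter(.data$status == "A")
    avail <- available_snapshots(state) |>
      group_by(.data$subgroup_id) |>
      summarise(available = n(), .groups = "drop")
    sg_avail <- active |>
      left_join(avail, by = "subgroup_id") |>
      mutate(available = ifelse(is.na(.data$available), 0L, .data$available))
    alloc <- apportion(Q, sg_avail, config$weight_scheme)
    if (nrow(alloc) == 0L) break # nothing left to dispatch

    q <- build_queue(state, alloc)
    state <- q$state
    disp <- simulate_dispatch(q$tasks, n_workers, backend)
    if (any(disp$results$failed)) {
      abort(paste0(
        "Docking backend failed in batch ", q$batch_index, " for snapshot(s): ",
        paste(disp$results$snapshot_id[disp$results$failed], collapse = ", ")
      ))
    }
    state <- log_event(state, "dispatch", list(
      batch = q$batch_index, tasks = as.list(q$tasks),
      worker_tally = as.list(disp$worker_tally), makespan = disp$makespan
    ))
    idx <- match(disp$results$snapshot_id, state$snapshots$snapshot_id)
    state$snapshots$docked[idx] <- TRUE
    state$snapshots$best_feb[idx] <- disp$results$best_feb
    state$snapshots$batch[idx] <- q$batch_index
    state <- log_event(state, "result", list(
      batch = q$batch_index, n_results = nrow(disp$results),
      batch_best_feb = min(disp$results$best_feb)
    ))
    results[[q$batch_index]] <- disp$results |>
      select("snapshot_id", "best_feb", "n_runs", "source") |>
      mutate(batch = q$batch_index)

    state <- finalize_docked(state)
    if (should_analyze(progress(state), config$start_pct)) {
      changes <- evaluate_subgroups(state, config$criteria)
      state <- log_event(state, "analysis", list(
        batch = state$batch_index,
        progress = progress(state),
        n_changes = nrow(changes)
      ))
      state <- apply_changes(state, changes)
    }
  }

  results <- bind_rows(results)
  summary <- if (!is.null(ground_truth)) {
    summarize_campaign(state, ground_truth)
  }
  files <- if (!is.null(out_dir)) {
    write_campaign_outputs(state, config, results, summary, out_dir)
  }
  structure(
    list(
      config = config, state = state, results = results,
      summary = summary, files = files
    ),
    class = "rffr_campaign"
  )
}

# mark every fully docked active subgroup finalized, with provenance
finalize_docked <- function(state) {
  by_sub <- state$snapshots |>
    group_by(.data$subgroup_id) |>
    summarise(all_docked = all(.data$docked), .groups = "drop")
  done <- by_sub$subgroup_id[by_sub$all_docked]
  to_fin <- state$subgroups$subgroup_id[
    state$subgroups$status == "A" & state$subgroups$subgroup_id %in% done
  ]
  for (sid in sort(to_fin)) {
    state$subgroups$status[state$subgroups$subgroup_id == sid] <- "F"
    state <- log_event(state, "change", list(
      subgroup = sid, field = "status", old = "A", new = "F",
      reason = "all members docked"
    ))
  }
  state
}

write_campaign_outputs <- function(state, config, results, summary, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  control_path <- file.path(out_dir, "control.xml")
  write_control_file(
    state$experiment_id,
    state$subgroups |> select("subgroup_id", "status", "priority"),
    state$snapshots |> select("snapshot_id", "subgroup_id", "docked"),
    path = control_path
  )
  update_dir <- file.path(out_dir, "updates")
  dir.create(update_dir, showWarnings = FALSE)
  update_paths <- character(length(state$updates))
  for (i in seq_along(state$updates)) {
    up <- state$updates[[i]]
    update_paths[i] <- file.path(update_dir, sprintf("update_%04d.xml", i))
    write_update_file(up$subgroup_id,
      priority = up$priority, status = up$status,
      path = update_paths[i]
    )
  }
  prov_path <- file.path(out_dir, "provenance.jsonl")
  write_provenance(state$provenance, prov_path)
  results_path <- file.path(out_dir, "results.csv")
  readr::write_csv(results, results_path, progress = FALSE)
  summary_path <- NULL
  if (!is.null(summary)) {
    summary_path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(
      list(
        n_snapshots = summary$n_snapshots, n_docked = summary$n_docked,
        n_discarded = summary$n_discarded, n_batches = summary$n_batches,
        accuracy = summary$accuracy
      ),
      summary_path,
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    txt_path <- file.path(out_dir, "summary.txt")
    sink(txt_path)
    print(summary)
    sink()
  }
  list(
    control = control_path, updates = update_paths,
    provenance = prov_path, results = results_path, summary = summary_path
  )
}

#' @export
print.rffr_campaign <- function(x, ...) {
  cat(sprintf(
    "<rffr campaign> experiment %d: %d/%d snapshots docked in %d batches, %d discarded\n",
    x$config$experiment_id, sum(x$state$snapshots$docked),
    nrow(x$state$snapshots), x$state$batch_index,
    sum(x$state$snapshots$discarded & !x$state$snapshots$docked)
  ))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' @method tidy rffr_campaign
#' @export
tidy.rffr_campaign <- function(x, ...) {
  per_sub <- x$state$snapshots |>
    group_by(.data$subgroup_id) |>
    summarise(
      n_docked = sum(.data$docked),
      n_discarded = sum(.data$discarded & !.data$docked),
      mean_feb = ifelse(any(.data$docked),
        mean(.data$best_feb[.data$docked]), NA_real_
      ),
      .groups = "drop"
    )
  x$state$subgroups |>
    left_join(per_sub, by = "subgroup_id") |>
    arrange(.data$subgroup_id)
}

#' @method glance rffr_campaign
#' @export
glance.rffr_campaign <- function(x, ...) {
  tibble(
    experiment_id = x$config$experiment_id,
    start_pct = x$config$start_pct,
    n_snapshots = nrow(x$state$snapshots),
    n_docked = sum(x$state$snapshots$docked),
    n_discarded = sum(x$state$snapshots$discarded & !x$state$snapshots$docked),
    n_batches = x$state$batch_index,
    n_updates = length(x$state$updates)
  )
}

#' @method autoplot rffr_campaign
#' @export
autoplot.rffr_campaign <- function(object, ...) {
  per_batch <- object$results |>
    group_by(.data$batch) |>
    summarise(n_docked = n(), .groups = "drop") |>
    mutate(cumulative = cumsum(.data$n_docked))
  ggplot2::ggplot(per_batch, ggplot2::aes(x = .data$batch, y = .data$cumulative)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(
      yintercept = nrow(object$state$snapshots),
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::labs(
      x = "batch", y = "snapshots docked (cumulative)",
      title = sprintf(
        "Campaign progress: %d docked, %d discarded",
        sum(object$state$snapshots$docked),
        sum(object$state$snapshots$discarded & !object$state$snapshots$docked)
      )
    )
}
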