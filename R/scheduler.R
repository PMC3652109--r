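#' Balanced-queue length
#'
#' The dispatcher fills one queue of `Q = N * T` docking tasks per batch,
#' where `N` is the number of nodes and `T` the parallel tasks per node.
#'
#' @param n_nodes Number of nodes (`N`).
#' @param tasks_per_node Tasks per node (`T`).
#' @return Integer queue length `Q`.
#' @examples
#' queue_length(5, 32) # 160
#' @export
queue_length <- function(n_nodes, tasks_per_node) {
  n_nodes <- as.integer(n_nodes)
  tasks_per_node <- as.integer(tasks_per_node)
  if (is.na(n_nodes) || n_nodes < 1L || is.na(tasks_per_node) || tasks_per_node < 1L) {
    abort("`n_nodes` and `tasks_per_node` must be positive integers.")
  }
  n_nodes * tasks_per_node
}

priority_weight <- function(priority, weight_scheme = c("inverse", "raw")) {
  weight_scheme <- match.arg(weight_scheme)
  switch(weight_scheme,
    inverse = 4L - as.integer(priority),
    raw = as.integer(priority)
  )
}

#' Apportion queue slots across active subgroups
#'
#' Splits the queue of `Q` slots across the active subgroups in proportion to
#' their priority weights, using largest-remainder (Hamilton) rounding so the
#' integer shares sum exactly to `min(Q, total available)`. A subgroup never
#' receives more slots than it has available snapshots; any surplus is
#' redistributed among the remaining subgroups, still in proportion to weight.
#' Ties in fractional remainder go to the higher weight, then the
#' lexicographically smaller subgroup id.
#'
#' @param Q Queue length.
#' @param subgroups Tibble with columns `subgroup_id`, `priority`, `available`
#'   (undocked, undiscarded member count).
#' @param weight_scheme `"inverse"` (default; priority 1 gets the largest
#'   share) or `"raw"` (share proportional to the raw priority value).
#' @return Tibble `subgroup_id`, `priority`, `weight`, `n_tasks`; rows with
#'   zero availability are dropped. Empty tibble when nothing is available.
#' @examples
#' sg <- tibble::tibble(subgroup_id = c("G1L1", "G2L1"),
#'                      priority = c(2L, 3L), available = c(100L, 100L))
#' apportion(6, sg) # weights 2 and 1: shares 4 and 2
#' @export
apportion <- function(Q, subgroups, weight_scheme = c("inverse", "raw")) {
  weight_scheme <- match.arg(weight_scheme)
  stopifnot(all(c("subgroup_id", "priority", "available") %in% names(subgroups)))
  Q <- as.integer(Q)
  if (is.na(Q) || Q < 1L) abort("`Q` must be a positive integer.")
  sg <- subgroups |>
    filter(.data$available > 0L) |>
    mutate(weight = priority_weight(.data$priority, weight_scheme)) |>
    arrange(.data$subgroup_id)
  if (nrow(sg) == 0L) {
    return(tibble(
      subgroup_id = character(), priority = integer(),
      weight = integer(), n_tasks = integer()
    ))
  }
  total <- min(Q, sum(sg$available))
  shares <- setNames(rep(0L, nrow(sg)), sg$subgroup_id)
  open <- rep(TRUE, nrow(sg))
  remaining <- total
  # cap-and-redistribute: subgroups whose proportional quota exceeds their
  # availability are filled and removed, then quotas are recomputed
  repeat {
    if (remaining == 0L || !any(open)) break
    quota <- remaining * sg$weight[open] / sum(sg$weight[open])
    over <- quota > sg$available[open]
    if (!any(over)) break
    idx <- which(open)[over]
    shares[idx] <- sg$available[idx]
    remaining <- remaining - sum(sg$available[idx])
    open[idx] <- FALSE
  }
  if (remaining > 0L && any(open)) {
    idx <- which(open)
    quota <- remaining * sg$weight[idx] / sum(sg$weight[idx])
    base <- floor(quota)
    frac <- quota - base
    extra <- remaining - sum(base)
    ord <- order(-frac, -sg$weight[idx], sg$subgroup_id[idx])
    bump <- rep(0L, length(idx))
    if (extra > 0L) bump[ord[seq_len(extra)]] <- 1L
    shares[idx] <- as.integer(base + bump)
  }
  sg |>
    mutate(n_tasks = as.integer(shares[.data$subgroup_id])) |>
    filter(.data$n_tasks > 0L) |>
    select("subgroup_id", "priority", "weight", "n_tasks")
}

#' Build a balanced queue of docking tasks
#'
#' Materialises an allocation into an ordered task list: priority-1 subgroups
#' first, then 2, then 3 (ties between subgroups broken by id); within a
#' subgroup, snapshots keep their input order. The build and its allocation
#' are logged to provenance.
#'
#' @param state An `rffr_state`.
#' @param allocation Tibble from [apportion()].
#' @return A list of class `rffr_queue` with `batch_index`, `tasks`
#'   (snapshot-id vector), `allocation`, and the updated `state`.
#' @export
build_queue <- function(state, allocation) {
  stopifnot(inherits(state, "rffr_state"))
  status <- state$subgroups$status[
    match(allocation$subgroup_id, state$subgroups$subgroup_id)
  ]
  if (any(is.na(status) | status != "A")) {
    abort("Allocation references a subgroup that is not active.")
  }
  avail <- available_snapshots(state)
  alloc <- allocation |> arrange(.data$priority, .data$subgroup_id)
  tasks <- purrr::map(seq_len(nrow(alloc)), function(i) {
    members <- avail$snapshot_id[avail$subgroup_id == alloc$subgroup_id[i]]
    if (length(members) < alloc$n_tasks[i]) {
      abort("Allocation exceeds a subgroup's available snapshots.")
    }
    head(members, alloc$n_tasks[i])
  })
  tasks <- unlist(tasks, use.names = FALSE)
  if (is.null(tasks)) tasks <- character()
  batch <- state$batch_index + 1L
  state$batch_index <- batch
  state <- log_event(state, "queue_built", list(
    batch = batch,
    allocation = setNames(as.list(alloc$n_tasks), alloc$subgroup_id),
    n_tasks = length(tasks)
  ))
  structure(
    list(batch_index = batch, tasks = tasks, allocation = alloc, state = state),
    class = "rffr_queue"
  )
}

#' Simulate master-slave dispatch of a queue
#'
#' A deterministic discrete-event simulation of the worker pool: `W = N * T`
#' workers pull the next task as soon as they fall idle (the master also runs
#' tasks, so no worker slot is reserved for coordination). Task durations come
#' from the backend; the synthetic backend uses a constant one tick, under
#' which per-worker loads balance within one task.
#'
#' @param tasks Character vector of snapshot ids (a queue's task list).
#' @param n_workers Worker count `W`.
#' @param backend A docking backend, e.g. [synthetic_backend()].
#' @return A list of class `rffr_dispatch`: `results` tibble (one row per
#'   task: `snapshot_id`, `best_feb`, `n_runs`, `source`, `worker`, `start`,
#'   `finish`, `failed`), `worker_tally` integer vector, `makespan`.
#' @export
simulate_dispatch <- function(tasks, n_workers, backend) {
  stopifnot(inherits(backend, "rffr_backend"))
  if (!length(tasks)) abort("Cannot dispatch an empty queue.")
  n_workers <- as.integer(n_workers)
  if (is.na(n_workers) || n_workers < 1L) abort("`n_workers` must be >= 1.")
  free_at <- rep(0, n_workers)
  n <- length(tasks)
  worker <- integer(n)
  t_start <- numeric(n)
  t_finish <- numeric(n)
  feb <- rep(NA_real_, n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    w <- which.min(free_at) # earliest-idle worker, lowest index on ties
    dur <- backend$duration(tasks[i])
    worker[i] <- w
    t_start[i] <- free_at[w]
    t_finish[i] <- free_at[w] + dur
    free_at[w] <- t_finish[i]
    res <- tryCatch(backend$dock(tasks[i]), error = function(e) e)
    if (inherits(res, "error")) {
      failed[i] <- TRUE
    } else {
      feb[i] <- res
    }
  }
  results <- tibble(
    snapshot_id = tasks,
    best_feb = feb,
    n_runs = backend$n_runs,
    source = backend$source,
    worker = worker,
    start = t_start,
    finish = t_finish,
    failed = failed
  )
  tally <- tabulate(worker, nbins = n_workers)
  structure(
    list(results = results, worker_tally = tally, makespan = max(t_finish)),
    class = "rffr_dispatch"
  )
}
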