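# Shared fixture builders. Everything is generated in code; nothing binary.

# a small campaign state over explicit clusters, e.g. list(c1 = 4, c2 = 2)
make_state <- function(cluster_sizes, subgroup_size = 100L, experiment_id = 1L) {
  clustering <- tibble::tibble(
    snapshot_id = sprintf("s%03d", seq_len(sum(cluster_sizes))),
    cluster_id = rep(names(cluster_sizes), times = cluster_sizes)
  )
  new_campaign_state(
    form_subgroups(clustering, subgroup_size),
    experiment_id = experiment_id
  )
}

# manually record docking results, bypassing the dispatcher
dock_manually <- function(state, ids, febs) {
  idx <- match(ids, state$snapshots$snapshot_id)
  stopifnot(!anyNA(idx))
  state$snapshots$docked[idx] <- TRUE
  state$snapshots$best_feb[idx] <- febs
  state
}

# AutoDock 4.2-style docking log with one energy line per run, written
# independently of the parser under test
write_dlg_lines <- function(energies, extra_noise_lines = TRUE) {
  header <- c(
    "       __________________________________________________________",
    "               AutoDock",
    "       __________________________________________________________",
    "DPF> ga_run 25",
    sprintf("Total number of runs: %d", length(energies))
  )
  runs <- unlist(lapply(seq_along(energies), function(i) {
    c(
      sprintf("Run:   %d / %d", i, length(energies)),
      "DOCKED: MODEL",
      sprintf(
        "DOCKED: USER    Estimated Free Energy of Binding    =   %.2f kcal/mol  [=(1)+(2)+(3)-(4)]",
        energies[i]
      ),
      if (extra_noise_lines) {
        sprintf("DOCKED: USER    Final Intermolecular Energy     =   %.2f kcal/mol", energies[i] - 0.5)
      },
      "DOCKED: ENDMDL"
    )
  }))
  c(header, runs)
}

# random, valid control-file content for round-trip property tests
random_control_instance <- function() {
  n_sub <- sample(0:5, 1)
  subgroups <- tibble::tibble(
    subgroup_id = if (n_sub) sprintf("G%dL%d", sample(1:9, n_sub, TRUE), seq_len(n_sub)) else character(),
    status = sample(c("A", "F", "D", "P"), n_sub, replace = TRUE),
    priority = sample(1:3, n_sub, replace = TRUE)
  )
  snap_counts <- if (n_sub) sample(0:6, n_sub, replace = TRUE) else integer()
  snapshots <- tibble::tibble(
    snapshot_id = if (sum(snap_counts)) sprintf("s%04d", seq_len(sum(snap_counts))) else character(),
    subgroup_id = rep(subgroups$subgroup_id, times = snap_counts),
    docked = sample(c(TRUE, FALSE), sum(snap_counts), replace = TRUE)
  )
  list(
    experiment_id = sample(1:9999, 1),
    subgroups = subgroups,
    snapshots = snapshots
  )
}

# brute-force apportionment oracle: all compositions of `total` over k parts,
# minimal L1 deviation from the exact proportional quotas
compositions_k <- function(total, k) {
  if (k == 1L) return(matrix(total, ncol = 1))
  grid <- do.call(expand.grid, rep(list(0:total), k))
  as.matrix(grid[rowSums(grid) == total, , drop = FALSE])
}

oracle_min_deviation <- function(Q, weights) {
  quota <- Q * weights / sum(weights)
  comps <- compositions_k(Q, length(weights))
  dev <- rowSums(abs(sweep(comps, 2, quota)))
  min(dev)
}
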