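#' Generate a synthetic clustered receptor ensemble
#'
#' Emulates the input to an adaptive ensemble-docking campaign: `M` snapshots
#' split as evenly as possible into `k` clusters whose members share a class
#' of binding energies. Snapshot `i` of cluster `c` draws its ground-truth
#' best FEB from `Normal(mean_c, sd)`. Clusters with well-separated means
#' (`>= 4 sd` apart) mimic a high-quality clustering in which cluster
#' membership is strongly informative about docking outcome; shrinking the
#' separation degrades the clustering quality.
#'
#' @param n_snapshots Total snapshots `M`.
#' @param n_clusters Cluster count `k`.
#' @param cluster_means Mean FEB (kcal/mol) per cluster; default
#'   `base_mean + separation * (0:(k-1))`, ascending, so cluster 1 is the most
#'   promising.
#' @param cluster_sd Within-cluster FEB standard deviation (kcal/mol).
#' @param separation Gap between adjacent cluster means (kcal/mol) when
#'   `cluster_means` is not given; the default `4 * cluster_sd`.
#' @param base_mean Mean FEB of the best cluster (kcal/mol).
#' @param seed Integer seed; the same seed reproduces the model exactly.
#' @return A list of class `rffr_model`: `clustering` tibble (`snapshot_id`,
#'   `cluster_id`, `similarity_label`) and `ground_truth`, a named numeric
#'   vector of true best FEBs.
#' @examples
#' m <- generate_model(n_snapshots = 30, n_clusters = 3, seed = 1)
#' table(m$clustering$cluster_id)
#' @export
generate_model <- function(n_snapshots = 3100L,
                           n_clusters = 5L,
                           cluster_means = NULL,
                           cluster_sd = 0.5,
                           separation = 4 * cluster_sd,
                           base_mean = -11,
                           seed = 1L) {
  n_snapshots <- as.integer(n_snapshots)
  n_clusters <- as.integer(n_clusters)
  if (is.na(n_snapshots) || is.na(n_clusters) ||
      n_clusters < 1L || n_snapshots < n_clusters) {
    abort("Need `n_snapshots >= n_clusters >= 1`.")
  }
  if (!is.numeric(cluster_sd) || cluster_sd <= 0) {
    abort("`cluster_sd` must be positive.")
  }
  if (is.null(cluster_means)) {
    cluster_means <- base_mean + separation * (seq_len(n_clusters) - 1L)
  }
  if (length(cluster_means) != n_clusters) {
    abort("`cluster_means` must have one value per cluster.")
  }
  # even split: first (M mod k) clusters get one extra member
  sizes <- rep(n_snapshots %/% n_clusters, n_clusters)
  extra <- n_snapshots %% n_clusters
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  cluster_of <- rep(seq_len(n_clusters), times = sizes)
  width <- nchar(as.character(n_snapshots))
  ids <- sprintf(paste0("s%0", width, "d"), seq_len(n_snapshots))
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  truth <- rnorm(n_snapshots, mean = cluster_means[cluster_of], sd = cluster_sd)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  clustering <- tibble(
    snapshot_id = ids,
    cluster_id = paste0("c", cluster_of),
    similarity_label = "synthetic"
  )
  structure(
    list(
      clustering = clustering,
      ground_truth = setNames(truth, ids),
      spec = list(
        n_snapshots = n_snapshots, n_clusters = n_clusters,
        cluster_means = cluster_means, cluster_sd = cluster_sd, seed = seed
      )
    ),
    class = "rffr_model"
  )
}

#' Synthetic docking backend
#'
#' Stands in for a docking engine: each snapshot's reported best FEB is its
#' ground-truth value plus seeded Gaussian noise emulating run-to-run search
#' variability. Results are memoised at construction, so docking the same
#' snapshot twice (or rerunning with the same seed) returns the identical
#' value.
#'
#' @param ground_truth Named numeric vector of true best FEBs (kcal/mol), as
#'   produced by [generate_model()].
#' @param seed Integer seed for the noise draws.
#' @param sigma_noise Standard deviation (kcal/mol) of the docking noise;
#'   `0` reproduces the ground truth exactly.
#' @param n_runs Number of independent search runs recorded per docking.
#' @param duration Task duration in scheduler ticks (constant), or a function
#'   of the snapshot id.
#' @return A list of class `rffr_backend` with elements `dock(snapshot_id)`,
#'   `duration(snapshot_id)`, `n_runs`, `source`.
#' @examples
#' m <- generate_model(n_snapshots = 10, n_clusters = 2, seed = 1)
#' be <- synthetic_backend(m$ground_truth, seed = 1, sigma_noise = 0)
#' be$dock("s01") == unname(m$ground_truth["s01"])
#' @export
synthetic_backend <- function(ground_truth, seed = 1L, sigma_noise = 0.2,
                              n_runs = 25L, duration = 1) {
  stopifnot(is.numeric(ground_truth), !is.null(names(ground_truth)))
  if (sigma_noise < 0) abort("`sigma_noise` must be non-negative.")
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  noise <- if (sigma_noise > 0) {
    rnorm(length(ground_truth), 0, sigma_noise)
  } else {
    rep(0, length(ground_truth))
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  observed <- ground_truth + noise
  dur_fun <- if (is.function(duration)) duration else function(id) duration
  structure(
    list(
      dock = function(snapshot_id) {
        if (!snapshot_id %in% names(observed)) {
          abort(paste0("Unknown snapshot id: ", snapshot_id))
        }
        unname(observed[[snapshot_id]])
      },
      duration = dur_fun,
      n_runs = as.integer(n_runs),
      source = "synthetic"
    ),
    class = "rffr_backend"
  )
}

#' Docking backend over AutoDock DLG files
#'
#' Adapts a directory of AutoDock 4.2 docking logs (one `<snapshot_id>.dlg`
#' per snapshot) to the backend interface: `dock()` returns the best FEB
#' parsed from the log via [parse_dlg_best_feb()].
#'
#' @param dir Directory containing `.dlg` files named by snapshot id.
#' @param n_runs Runs per docking recorded in the results.
#' @param duration Task duration in scheduler ticks.
#' @return An `rffr_backend`.
#' @export
dlg_backend <- function(dir, n_runs = 25L, duration = 1) {
  if (!dir.exists(dir)) abort(paste0("No such directory: ", dir))
  dur_fun <- if (is.function(duration)) duration else function(id) duration
  structure(
    list(
      dock = function(snapshot_id) {
        path <- file.path(dir, paste0(snapshot_id, ".dlg"))
        if (!file.exists(path)) {
          abort(paste0("No DLG file for snapshot: ", snapshot_id))
        }
        parse_dlg_best_feb(path)
      },
      duration = dur_fun,
      n_runs = as.integer(n_runs),
      source = "dlg"
    ),
    class = "rffr_backend"
  )
}
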