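test_that("queue length is the node-task product", {
  expect_equal(queue_length(5, 32), 160)
  expect_equal(queue_length(1, 1), 1)
  expect_equal(queue_length(8, 32), 256)
  expect_error(queue_length(0, 32), "positive")
  expect_error(queue_length(5, -1), "positive")
})

test_that("apportionment follows priority weights with largest-remainder rounding", {
  sg <- function(priorities, avail = 10000L) {
    tibble::tibble(
      subgroup_id = sprintf("G%dL1", seq_along(priorities)),
      priority = as.integer(priorities),
      available = as.integer(avail)
    )
  }
  # weights 2 and 1 (priorities 2 and 3): exact thirds of 6
  expect_equal(apportion(6, sg(c(2, 3)))$n_tasks, c(4, 2))
  # equal weights split evenly
  expect_equal(apportion(160, sg(c(3, 3)))$n_tasks, c(80, 80))
  # weights 3, 2, 1: exact quotas 80, 53.33, 26.67 -> 80, 53, 27
  expect_equal(apportion(160, sg(c(1, 2, 3)))$n_tasks, c(80, 53, 27))
  # raw-priority variant: priority values used directly as weights
  expect_equal(
    apportion(6, sg(c(2, 1)), weight_scheme = "raw")$n_tasks, c(4, 2)
  )
})

test_that("apportionment attains the brute-force minimal deviation exhaustively", {
  # every priority assignment over 1..4 subgroups, every Q up to 20, ample
  # availability: the integer shares must sum to Q and deviate from the exact
  # proportional quotas no more than the best composition found by brute force
  for (k in 1:4) {
    prios <- as.matrix(do.call(expand.grid, rep(list(1:3), k)))
    for (Q in c(1:20)) {
      comps <- compositions_k(Q, k)
      for (r in seq_len(nrow(prios))) {
        weights <- 4 - prios[r, ]
        got <- apportion(Q, tibble::tibble(
          subgroup_id = sprintf("G%dL1", 1:k),
          priority = as.integer(prios[r, ]),
          available = 1000L
        ))
        shares <- integer(k)
        shares[match(got$subgroup_id, sprintf("G%dL1", 1:k))] <- got$n_tasks
        expect_equal(sum(shares), Q)
        quota <- Q * weights / sum(weights)
        dev <- sum(abs(shares - quota))
        best <- min(rowSums(abs(sweep(comps, 2, quota))))
        expect_lt(dev - best, 1e-9)
      }
    }
  }
})

test_that("apportionment caps shares at availability and redistributes", {
  set.seed(11)
  for (i in 1:200) {
    k <- sample(1:5, 1)
    Q <- sample(1:60, 1)
    sg <- tibble::tibble(
      subgroup_id = sprintf("G%dL1", 1:k),
      priority = sample(1:3, k, replace = TRUE),
      available = sample(0:30, k, replace = TRUE)
    )
    got <- apportion(Q, sg)
    total_avail <- sum(sg$available)
    if (total_avail == 0) {
      expect_equal(nrow(got), 0)
      next
    }
    expect_equal(sum(got$n_tasks), min(Q, total_avail))
    merged <- dplyr::left_join(got, sg, by = c("subgroup_id", "priority"))
    expect_true(all(merged$n_tasks <= merged$available))
  }
})

test_that("shares weakly increase with weight when availability is ample", {
  set.seed(12)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    Q <- sample(5:100, 1)
    sg <- tibble::tibble(
      subgroup_id = sprintf("G%dL1", 1:k),
      priority = sample(1:3, k, replace = TRUE),
      available = 10000L
    )
    got <- apportion(Q, sg)
    # grouped by weight, mean share non-decreasing with weight
    by_w <- tapply(got$n_tasks, got$weight, mean)
    expect_true(all(diff(by_w) >= 0))
  }
})

test_that("queues list higher-priority subgroups first, in input snapshot order", {
  st <- make_state(c(c1 = 3, c2 = 3), subgroup_size = 3)
  st$subgroups$priority <- c(1L, 3L)
  alloc <- apportion(3, tibble::tibble(
    subgroup_id = c("G1L1", "G2L1"), priority = c(1L, 3L),
    available = c(3L, 3L)
  ))
  q <- build_queue(st, alloc)
  # weight 3 vs 1: G1L1 gets 2 of 3 slots and leads the queue
  expect_equal(q$tasks, c("s001", "s002", "s004"))

  # two equal-priority subgroups: ordered by subgroup id
  st2 <- make_state(c(c1 = 2, c2 = 2), subgroup_size = 2)
  alloc2 <- tibble::tibble(
    subgroup_id = c("G2L1", "G1L1"), priority = c(2L, 2L),
    weight = c(2L, 2L), n_tasks = c(1L, 1L)
  )
  q2 <- build_queue(st2, alloc2)
  expect_equal(q2$tasks, c("s001", "s003"))

  # empty allocation -> empty queue
  q3 <- build_queue(st2, alloc2[0, ])
  expect_equal(q3$tasks, character(0))

  # allocation naming a non-active subgroup is rejected
  st3 <- st2
  st3$subgroups$status[1] <- "D"
  expect_error(build_queue(st3, alloc2), "not active")
})

test_that("the dispatcher executes every task exactly once with balanced loads", {
  m <- generate_model(n_snapshots = 200, n_clusters = 2, seed = 3)
  be <- synthetic_backend(m$ground_truth, seed = 3)
  ids <- names(m$ground_truth)

  d1 <- simulate_dispatch(ids[1:4], 2, be)
  expect_equal(d1$worker_tally, c(2, 2))

  d2 <- simulate_dispatch(ids[1], 8, be)
  expect_equal(nrow(d2$results), 1)
  expect_equal(sum(d2$worker_tally == 0), 7)

  d3 <- simulate_dispatch(ids[1:160], 40, be)
  expect_equal(d3$makespan, 4) # 160 constant-duration tasks on 40 workers
  expect_equal(diff(range(d3$worker_tally)), 0)
  expect_equal(sort(d3$results$snapshot_id), sort(ids[1:160]))
  expect_false(any(duplicated(d3$results$snapshot_id)))

  # constant durations always balance within one task
  for (n in c(7, 33, 101)) {
    d <- simulate_dispatch(ids[1:n], 10, be)
    expect_lte(diff(range(d$worker_tally)), 1)
    expect_equal(nrow(d$results), n)
  }
  expect_error(simulate_dispatch(character(0), 4, be), "empty queue")
})

test_that("a failing backend marks tasks failed instead of dropping them", {
  m <- generate_model(n_snapshots = 10, n_clusters = 1, seed = 4)
  be <- synthetic_backend(m$ground_truth, seed = 4)
  broken <- structure(
    list(
      dock = function(id) if (id == "s03") stop("engine crashed") else be$dock(id),
      duration = function(id) 1,
      n_runs = 25L,
      source = "synthetic"
    ),
    class = "rffr_backend"
  )
  d <- simulate_dispatch(names(m$ground_truth)[1:5], 2, broken)
  expect_equal(nrow(d$results), 5) # nothing silently dropped
  expect_equal(d$results$snapshot_id[d$results$failed], "s03")
  expect_true(is.na(d$results$best_feb[d$results$failed]))
})
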