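test_that("clusters are split into contiguous subgroups in input order", {
  cl10 <- tibble::tibble(snapshot_id = sprintf("s%02d", 1:10), cluster_id = "c1")
  sg <- form_subgroups(cl10, subgroup_size = 4)
  expect_equal(as.vector(table(sg$subgroup_id)), c(4, 4, 2))
  expect_equal(unique(sg$subgroup_id), c("G1L1", "G1L2", "G1L3"))
  # contiguity: the first four snapshots form the first subgroup
  expect_equal(sg$subgroup_id[1:4], rep("G1L1", 4))

  cl4 <- tibble::tibble(snapshot_id = paste0("s", 1:4), cluster_id = "c1")
  expect_equal(unique(form_subgroups(cl4, 10)$subgroup_id), "G1L1")

  cl_big <- tibble::tibble(
    snapshot_id = sprintf("s%04d", 1:3100),
    cluster_id = paste0("c", rep(1:5, each = 620))
  )
  sg_big <- form_subgroups(cl_big, 155)
  expect_equal(length(unique(sg_big$subgroup_id)), 20)
  expect_true(all(table(sg_big$subgroup_id) == 155))
  expect_equal(nrow(sg_big), 3100)

  expect_error(form_subgroups(cl10[0, ], 4), "empty")
})

test_that("analysis triggers at the start percentage and never at 100%", {
  expect_false(should_analyze(0.29, 0.30))
  expect_true(should_analyze(0.30, 0.30)) # inclusive boundary
  expect_true(should_analyze(0.75, 0.30))
  expect_false(should_analyze(1.0, 1.0)) # analysis disabled at 100%
  expect_false(should_analyze(0.99, 1.0))
})

test_that("subgroup scores are mean docked FEB, undefined below m_min", {
  st <- make_state(c(c1 = 2, c2 = 3), subgroup_size = 5)
  st <- dock_manually(st, c("s001", "s002"), c(-9.1, -8.9))
  sc <- subgroup_scores(st, m_min = 2)
  expect_equal(sc$score[sc$subgroup_id == "G1L1"], -9.0)
  expect_true(is.na(sc$score[sc$subgroup_id == "G2L1"])) # 0 docked

  st2 <- dock_manually(st, "s003", -7.5)
  sc2 <- subgroup_scores(st2, m_min = 2)
  expect_true(is.na(sc2$score[sc2$subgroup_id == "G2L1"])) # 1 docked < m_min

  st3 <- dock_manually(st, c("s003", "s004", "s005"), c(-7, -6, -5))
  sc3 <- subgroup_scores(st3, m_min = 3)
  expect_equal(sc3$score[sc3$subgroup_id == "G2L1"], -6.0)
})

test_that("evaluation matches the hand-computed two-subgroup instance", {
  # subgroup A: 2 members, both docked, good energies; subgroup B: 4 members,
  # 1 docked, poor energy. Pooled docked FEBs: {-9.1, -8.9, -4.1}. With
  # linear-interpolation quantiles, the 0.75 quantile is -6.5, the 2/3
  # quantile -7.3, so B scores above both: priority 3 and discard. A is
  # fully docked: finalized regardless of score.
  st <- make_state(c(c1 = 2, c2 = 4), subgroup_size = 5)
  st <- dock_manually(st, c("s001", "s002", "s003"), c(-9.1, -8.9, -4.1))
  crit <- criteria_params(m_min = 1)
  expect_equal(
    unname(stats::quantile(c(-9.1, -8.9, -4.1), 0.75, type = 7)), -6.5
  )
  ch <- evaluate_subgroups(st, crit)
  a <- ch[ch$subgroup_id == "G1L1", ]
  b <- ch[ch$subgroup_id == "G2L1", ]
  expect_equal(a$new_status, "F")
  expect_equal(b$new_priority, 3L)
  expect_equal(b$new_status, "D")
  # deterministic ordering by subgroup id
  expect_equal(ch$subgroup_id, sort(ch$subgroup_id))
})

test_that("identical scores are treated symmetrically across subgroups", {
  st <- make_state(c(c1 = 4, c2 = 4), subgroup_size = 4)
  st <- dock_manually(st, c("s001", "s002", "s005", "s006"), rep(-7, 4))
  ch <- evaluate_subgroups(st, criteria_params(m_min = 2))
  # both subgroups sit at the same score: same band for both (ties resolve
  # to the better band via <=), and neither is discarded
  expect_true(all(ch$new_status != "D"))
  expect_equal(length(unique(ch$new_priority)), 1L)
})

test_that("a fully docked subgroup finalizes even with the worst score", {
  st <- make_state(c(c1 = 2, c2 = 4), subgroup_size = 5)
  # G1L1 fully docked with *terrible* energies; G2L1 partially docked, good
  st <- dock_manually(st, c("s001", "s002"), c(-1.0, -1.2))
  st <- dock_manually(st, c("s003", "s004", "s005"), c(-9, -9.1, -8.8))
  ch <- evaluate_subgroups(st, criteria_params(m_min = 2))
  g1 <- ch[ch$subgroup_id == "G1L1", ]
  expect_equal(g1$new_status, "F")
  expect_false("D" %in% g1$new_status)
})

test_that("evaluation requires at least one docking result", {
  st <- make_state(c(c1 = 4), subgroup_size = 2)
  expect_error(evaluate_subgroups(st, criteria_params()), "before any docking")
})

test_that("applying changes updates state, pending pool, and update records", {
  st <- make_state(c(c1 = 4, c2 = 4), subgroup_size = 4)
  st <- dock_manually(st, "s005", -5)
  changes <- tibble::tibble(
    subgroup_id = c("G1L1", "G2L1"),
    old_priority = c(2L, 2L), new_priority = c(1L, 2L),
    old_status = c("A", "A"), new_status = c("A", "D"),
    reason = c("promote", "discard")
  )
  st2 <- apply_changes(st, changes)
  expect_equal(st2$subgroups$priority[st2$subgroups$subgroup_id == "G1L1"], 1L)
  expect_equal(st2$subgroups$status[st2$subgroups$subgroup_id == "G2L1"], "D")
  # 3 undocked members of the discarded subgroup leave the pending pool
  expect_equal(sum(st2$snapshots$discarded), 3)
  expect_equal(sum(!st2$snapshots$docked & !st2$snapshots$discarded), 4)
  # one update record per changed field
  expect_equal(length(st2$updates), 2)
  expect_identical(validate_state(st2), character(0))

  # unknown subgroup rejected; empty change list is the identity
  expect_error(
    apply_changes(st, dplyr::mutate(changes, subgroup_id = c("G9L9", "G2L1"))),
    "G9L9"
  )
  st3 <- apply_changes(st, changes[0, ])
  expect_identical(st3$snapshots, st$snapshots)
  expect_identical(st3$subgroups, st$subgroups)
})

test_that("evaluation is idempotent on unchanged results", {
  st <- make_state(c(c1 = 4, c2 = 4, c3 = 4), subgroup_size = 4)
  st <- dock_manually(
    st, c("s001", "s002", "s005", "s006", "s009", "s010"),
    c(-9, -8.8, -7, -7.2, -3, -3.1)
  )
  crit <- criteria_params(m_min = 2)
  ch1 <- evaluate_subgroups(st, crit)
  st2 <- apply_changes(st, ch1)
  ch2 <- evaluate_subgroups(st2, crit)
  expect_equal(nrow(ch2), 0)
})

test_that("discarding is monotone in the discard quantile", {
  set.seed(7)
  st <- make_state(c(c1 = 6, c2 = 6, c3 = 6), subgroup_size = 3)
  ids <- st$snapshots$snapshot_id
  docked <- ids[c(1:2, 4:5, 7:8, 10:11, 13:14, 16:17)]
  st <- dock_manually(st, docked, rnorm(12, mean = rep(c(-9, -6, -3), each = 4)))
  n_discarded <- sapply(c(0.70, 0.75, 0.85, 0.90), function(qd) {
    ch <- evaluate_subgroups(st, criteria_params(qd = qd, m_min = 2))
    sum(ch$new_status == "D")
  })
  expect_true(all(diff(n_discarded) <= 0)) # lower qd never discards fewer
})

test_that("an earlier analysis start discards more snapshots on average", {
  discarded_at <- function(start_pct) {
    sapply(1:10, function(s) {
      m <- generate_model(n_snapshots = 400, n_clusters = 4, seed = s)
      be <- synthetic_backend(m$ground_truth, seed = s + 500)
      cfg <- experiment_config(
        start_pct = start_pct, n_nodes = 2, tasks_per_node = 16,
        subgroup_size = 25, seed = s
      )
      rep <- run_campaign(m$clustering, cfg, be)
      sum(rep$state$snapshots$discarded & !rep$state$snapshots$docked)
    })
  }
  expect_gte(mean(discarded_at(0.30)), mean(discarded_at(0.70)))
})
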