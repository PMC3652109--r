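---
title: "Adaptive snapshot selection for ensemble docking: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive snapshot selection for ensemble docking: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rffr)
```

## The problem

Ensemble docking treats a flexible protein receptor as a set of
conformations ("snapshots") sampled from a molecular dynamics trajectory and
docks the ligand against each one, scoring every pose by its estimated free
energy of binding (FEB, kcal/mol; more negative is better). The ensemble
view is physically faithful but computationally brutal: the cost of a
virtual screen scales with the ensemble size. The observation this package
operationalises is that snapshots arrive pre-clustered by structural
similarity, and cluster membership is informative about docking outcome —
so a campaign can *watch its own partial results* and stop paying for
regions of the ensemble that are demonstrably unpromising. The surviving,
docked subset is the reduced receptor model.

## The adaptive procedure

Clusters are split, in input order, into contiguous **subgroups** of at most
`subgroup_size` snapshots (default 155, giving 20 subgroups on a
3,100-snapshot, 5-cluster model). Subgroups start active (`A`) at priority
2 of a 1–3 scale. Each batch, the scheduler apportions a queue of
`Q = N × T` tasks over active subgroups in proportion to priority weight,
dispatches it to a simulated worker pool, and records results. Once the
docked fraction reaches `start_pct`, every batch is followed by an
evaluation:

* A subgroup's **score** is the mean best FEB of its docked members. The
  mean (not the minimum) is used because a subgroup is credited for the
  general quality of its conformations, not one lucky pose; the score is
  undefined until `m_min` members have docked so a handful of early results
  cannot seal a subgroup's fate.
* Scores are banded against quantiles of the **pooled** docked-FEB
  distribution (all results so far, including those from subgroups already
  discarded — keeping the reference distribution stable as the pool
  narrows): at or below the `q1` quantile → priority 1, at or below `q2` →
  priority 2, above → priority 3; above the `qd` quantile → discarded.
* A subgroup whose members are all docked is **finalized** (`F`) whatever
  its score: there is no work left to save, and its results stay in the
  pool.
* Discarding removes only the *undocked* members from the campaign;
  already-docked members keep their results and remain part of the docked
  tally.

The campaign terminates when every subgroup is finalized or discarded.
Termination is guaranteed: every batch either docks at least one snapshot
or, when nothing is available, the remaining active subgroups are by
construction fully docked and finalize.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `start_pct` | 0.30 | docked fraction that triggers the first analysis; 1.0 disables analysis entirely (the exhaustive reference campaign). The boundary is inclusive: exactly 30% triggers. |
| `n_nodes`, `tasks_per_node` | 5, 32 | fix the queue length `Q = N·T = 160` and the worker-pool width |
| `subgroup_size` | 155 | snapshots per subgroup; smaller subgroups react faster but score noisier |
| `q1`, `q2` | 1/3, 2/3 | promotion/demotion quantiles of the pooled FEB distribution |
| `qd` | 0.75 | discard quantile |
| `m_min` | `max(3, ⌈0.1·subgroup_size⌉)` | docked members required before a subgroup is scored |
| `sigma_noise` | 0.2 kcal/mol | run-to-run docking noise in the synthetic backend |

## Queue apportionment

The queue length is the node–task product, and slots are split across active
subgroups proportionally to priority. Because priority 1 denotes the *most*
promising subgroup, using the raw priority value as the weight would hand
the largest share to the least promising work; the package therefore maps
priority *p* to weight *w* = 4 − *p* by default, which honours the stated
intent that higher-priority subgroups are served first and most. The raw
proportional variant remains available via `weight_scheme = "raw"` for
experimentation.

Fractional quotas are rounded by the largest-remainder (Hamilton) method —
the shares sum exactly to `min(Q, available)` and minimise total deviation
from the exact quotas — with ties broken by higher weight, then subgroup id.
A subgroup never receives more slots than it has undocked, undiscarded
members; surplus is redistributed among the remaining subgroups, still in
proportion to weight. Within a queue, tasks are ordered priority 1 first,
then 2, then 3, subgroup id breaking ties, and input snapshot order within a
subgroup.

The dispatcher is a deterministic discrete-event simulation of the
`N·T`-worker master–slave pool (the master also executes tasks, so no slot
is reserved for coordination). Idle workers pull the next task; ties go to
the lowest worker index. With the constant one-tick durations of the
synthetic backend, per-worker loads provably balance within one task. The
simulation models the scheduling contract — who runs what, when, exactly
once — not message transport or network behaviour.

## What the synthetic generator emulates — and what it does not

`generate_model()` produces `M` snapshots split evenly over `k` clusters;
snapshot FEBs are drawn from per-cluster normal distributions. Defaults are
chosen once to mirror a realistic, high-quality clustering of a
3,100-snapshot campaign: 5 clusters, within-cluster spread
σ = 0.5 kcal/mol, adjacent cluster means separated by 4σ = 2 kcal/mol, best
cluster centred at −11 kcal/mol (the range AutoDock-style scoring functions
report for good binders). The synthetic backend returns the true FEB plus
`Normal(0, 0.2)` kcal/mol noise, emulating the run-to-run variability of a
stochastic search, and records 25 runs per docking, the usual protocol for
Lamarckian-GA docking. Both generator and backend are fully determined by
their seeds, and docking results are memoised, so a rerun reproduces the
campaign — including its provenance log — byte for byte.

Two idealisations matter when reading test results. First, normality:
real FEB distributions are skewed and heavy-tailed, and real clusterings
are imperfect, with clusters that straddle energy classes. With
well-separated synthetic clusters the adaptive campaign typically retains
100% of the best-FEB sets; on real data, retention in the mid-90s is the
realistic expectation, and a low-quality clustering removes the signal the
method relies on altogether — passing tests demonstrate the machinery, not
a guarantee about arbitrary ensembles. Second, constant task durations:
real docking times vary per snapshot, which spreads worker loads; the
backend accepts a per-snapshot duration function when that matters.

## Numerical choices and degenerate inputs

* Quantiles are linear-interpolation order statistics
  (`stats::quantile(type = 7)`) on the sorted docked-FEB list, for
  determinism and continuity in small pools.
* Accuracy is rounded half-up to two decimals, the precision of the
  published tables this metric follows; `best_set` sizes use the floor rule
  (`⌊level·M⌋`: 310/620/930 at 10/20/30% of 3,100).
* Ties everywhere — FEB ranking, apportionment remainders, queue order —
  fall back to lexicographic snapshot/subgroup id, so no run depends on
  hash or insertion order.
* Score ties at a band boundary resolve to the better band (`≤`), so
  identical subgroups are treated identically.
* Degenerate inputs are rejected loudly: empty models, empty queues,
  duplicate snapshot ids (named in the error), unknown status letters,
  update records carrying two changes, non-increasing provenance ordinals.
  A backend failure marks the task failed and aborts the batch with the
  offending snapshot ids; nothing is dropped silently.

## Design decisions worth recording

* **Status `P`.** The status vocabulary includes "priority changed", but
  scheduling semantics only ever distinguish active/finalized/discarded. A
  priority change is therefore recorded as a provenance event (with a
  `transient_status = "P"` marker) while the subgroup keeps operating as
  active — the alternative, a fourth operational state, would complicate
  every invariant for no behavioural difference.
* **Evaluation cadence.** Re-evaluation happens after every completed
  batch, not after every individual result. Batch-level cadence makes the
  analysis order-independent within a batch and matches the flow of results
  between dispatch and analysis.
* **Quantile-band criteria.** The promote/demote/discard rule is stated
  here as an explicit, testable criterion (good FEB → high priority; poor →
  demote, then discard) with all four knobs configurable; the literature
  this pattern follows leaves the concrete criterion open.
* **Updates between batches only.** Priority/status updates are applied at
  batch boundaries; a queue already dispatched runs to completion. This
  keeps the dispatch contract simple and every batch auditable.
* **One process, same artifacts.** The original web-server/middleware split
  (two processes exchanging control and update files over the network) is
  collapsed into one process that still produces the identical file
  contracts — control XML, per-change update XML, provenance log — so the
  observable behaviour is preserved without transport plumbing.
* **Provenance ordinals.** Events are ordered by an integer ordinal rather
  than wall-clock timestamps, making logs reproducible and diffable.

## Problem sizes used in the test suite

Unit and property tests run on models of 100–1,000 snapshots with
proportionally smaller queues, which exercise every code path in seconds.
The end-to-end acceptance checks use the full 3,100-snapshot, 5-cluster,
`Q = 160` configuration — the scale the defaults were designed around — with
ten seeds for the stochastic retention property; a single full campaign
completes in about a second.

## Known limitations

* Snapshots are opaque identifiers with attached energies: no coordinates,
  poses, or RMSD-based pose quality — the selection logic, not structural
  post-analysis, is the scope.
* The DLG parser extracts only the best estimated FEB per log; it does not
  read cluster histograms or per-run poses.
* The discard rule compares subgroup means against pooled quantiles; a
  heterogeneous subgroup containing a few excellent snapshots inside a poor
  cluster can lose them. That risk is inherent to the subgroup-level
  pattern and shrinks with subgroup size.
* `evaluate` assumes the pooled FEB distribution is informative; during a
  pathological early phase (all results from one cluster) the bands are
  narrow and `m_min` is the only guard. Raising `start_pct` is the remedy
  when clusters are suspected to be poorly separated.
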