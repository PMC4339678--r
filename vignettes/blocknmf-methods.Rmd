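---
title: "Divergence-based NMF with blockwise and data-parallel execution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence-based NMF with blockwise and data-parallel execution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blocknmf)
```

## The model

Non-negative matrix factorization approximates a non-negative data matrix
$V \in \mathbb{R}^{n \times m}$ (genes in rows, samples in columns) by a
product $W H$ with $W \in \mathbb{R}^{n \times k}$,
$H \in \mathbb{R}^{k \times m}$, all entries non-negative and
$k \ll n, m$. The factors are fit by alternating the multiplicative
update rules

$$H_{pj} \leftarrow H_{pj}
  \frac{\sum_i W_{ip} V_{ij} / (WH)_{ij}}{\sum_r W_{rp}}, \qquad
  W_{ip} \leftarrow W_{ip}
  \frac{\sum_j V_{ij} H_{pj} / (WH)_{ij}}{\sum_t H_{pt}},$$

which never increase the generalized Kullback–Leibler divergence
$D(V \,\|\, WH) = \sum_{ij} \big( V_{ij} \log \tfrac{V_{ij}}{(WH)_{ij}}
- V_{ij} + (WH)_{ij} \big)$ and keep non-negative factors non-negative.
The model assumes the data are non-negative intensity-like values; it is
scale-dependent (no internal normalization is applied), and for $k > 1$
the optimum is not unique — factors are identifiable at best up to
permutation and diagonal rescaling, which is why results are reported
through the assignment view rather than raw coefficients.

Each column of $W$ is a *metagene*; sample $j$ is assigned to
$\arg\max_p H_{pj}$ and gene $i$ to $\arg\max_p W_{ip}$, ties broken
toward the lowest factor index so the assignment is deterministic and
independent of evaluation order. The two assignments together give a
biclustering of genes and samples.

## Stopping rule

Convergence is declared from the *stability of the sample assignment*,
not from the objective: every `test_period` ($j$) iterations the
assignment vector is compared elementwise with the previous test's; a run
of `stability` ($t$) consecutive unchanged comparisons stops the fit, and
otherwise `max_iters` ($i$) caps it. The comparison is exact label
equality, not permutation-invariant matching: within one run the factors
persist across tests, so a drift of labels is a real change in the
solution and must reset the counter. An alternative reading — comparing
relative changes in $H$ itself — was considered and rejected as the rule,
because the assignment vector is the quantity the downstream
classification consumes.

Defaults are `j = 10`, `t = 40`, `i = 2000`, the tool's canonical
invocation; with these values the earliest possible stop is iteration
410 (41 identical consecutive tests). The divergence can additionally be
recorded per iteration (`track_objective = TRUE`) at the cost of one
extra $n \times m$ product per iteration; it is off by default and the
final divergence is always reported.

## Parameters and numerical choices

* **Rank `k`** (count, $2 \le k \le \min(n,m)$ on the command line): the
  number of metagenes. The library accepts $k = 1$, which is analytically
  convenient (the fit has a closed-form flavor and a provably monotone,
  bounded objective) but rarely useful in analysis.
* **`epsilon`** (default $2^{-52}$, double-precision machine epsilon) is
  added inside both quotient denominators, $V/(WH + \varepsilon)$ and the
  factor-sum denominators. The update rules are silent about zeros; the
  guard preserves exact fixed points to machine precision while making
  all-zero columns or rows harmless instead of producing NaN.
* **Initialization** is i.i.d. uniform on the open unit interval,
  strictly positive — a zero entry would be absorbed forever by the
  multiplicative form. The draw is seeded (Mersenne–Twister) and the
  caller's RNG state is saved and restored, so identical
  `(n, m, k, seed)` give bit-identical starting factors anywhere,
  including on every worker of a distributed run, which removes the need
  for an initial broadcast.
* **Update order** is H first, then W, within each iteration: the H pass
  reduces and accumulates the row sums of the updated $H$, which are
  exactly the denominator the W rule needs, so the W pass starts with its
  denominator ready. The W pass symmetrically accumulates the column sums
  of $W$ for the next iteration's H pass.
* **Precision**: in-memory arithmetic is always IEEE double. The
  `"single"` option selects 4-byte elements for binary file I/O and for
  the block-planning footprint; it exists because expression matrices are
  commonly exchanged as 32-bit binary dumps, not for speed.

## Out-of-core execution

Both update rules are separable — the H rule column by column given full
$W$, the W rule row by row given full $H$ — so only $V$ needs streaming:
$W$ and $H$ (small, since $k$ is small) stay resident while $V$ passes
through in column blocks of width $b_m$ and row blocks of height $b_n$.

The footprint model for a column block of width $b$, in elements, is
$nk + km + nb + nb + kb + k$: resident $W$ and $H$, the $V$ block, the
$(WH)$ block, the $k \times b$ intermediate, and the $k$-length
accumulator; the row-block model swaps $n$ and $m$. `plan_blocks()`
chooses the largest $b$ whose footprint fits `budget_bytes` (closed form,
tested against a linear scan), errors below the minimum feasible budget
reporting that minimum, and degenerates to a single block — bit-identical
to the in-memory path — when the budget covers the whole matrix. Blocks
are contiguous equal-width ranges with a short tail; no padding, which is
a device-alignment concern with no CPU counterpart.

Blocked and unblocked passes differ only in floating-point summation
order (the accumulated $k$-vectors versus whole-matrix sums), observed
and asserted at relative $10^{-10}$ per update and $10^{-8}$ after 100
iterations in the test suite. $V$ blocks are served through a small
reader contract with two providers — in-memory slicing and seek-and-read
over the binary file format — and the file provider tracks the largest
block it ever materialized so tests can verify the out-of-core claim.
Each pass recomputes the per-block product $(WH)$ from the full resident
factors rather than caching partial products; at $k \ll n, m$ the product
is cheap and the cache would double the block footprint. No prefetching
or compute/transfer overlap is attempted: concurrency would add
nondeterminism without exercising more of the method.

## Data-parallel execution

The distributed mode partitions the columns of $V$ (for the H pass) and
its rows (for the W pass) among $P$ workers in balanced contiguous
ranges, sizes differing by at most one; $W$ and $H$ are fully replicated.
After each update rule a collective step restores coherence: an
all-gather of the updated slices and an all-reduce (elementwise sum) of
the partial $k$-vectors — exactly two collectives per iteration, counted
in the report. The reduction is performed in fixed ascending rank order,
so distributed runs are deterministic; with $P = 1$ the run is
bit-identical to the serial fit. The collectives are defined as a
contract and executed by an in-process backend: message passing is
infrastructure, not method, and the in-process backend exercises the same
synchronization structure while remaining fully testable on one machine.
Convergence is evaluated from the replicated $H$, so all workers stop at
the same iteration with the same factors.

## The synthetic generator

`make_planted()` emulates the low-rank structure the method targets: each
sample is owned by one factor (round-robin, so every factor owns at least
one sample); the owning coefficient in $H_{\mathrm{true}}$ exceeds every
off-block coefficient in its column by exactly the `separation` ratio
(default 10) on top of a per-sample uniform scale in $[0.5, 1.5]$;
$W_{\mathrm{true}}$ is uniform on $[0.1, 1]$; optional noise is additive
half-normal with scale `noise_level` times the mean signal, which keeps
$V$ non-negative without rejection or clipping. Row labels `gene0001…`
and column labels `sample01…` exercise the labeled text I/O path.

What it does *not* emulate: real microarray or count distributions
(heavy tails, heteroscedastic noise, batch effects), correlated gene
modules of unequal size, or samples of mixed membership. Passing the
recovery tests therefore shows the algorithm and its execution modes are
correct on well-separated low-rank data — it does not certify biological
classification performance on real cohorts.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run at desk scale, chosen so
the full suite completes in well under a minute of compute while still
forcing the interesting regimes: scalar-loop oracle comparisons on 100
random instances up to $10 \times 10$, $k \le 4$; 440-iteration
monotonicity traces on twenty $100 \times 40$ problems; blockwise and
2–4-worker agreement on $200 \times 120$, $k = 5$, with budgets forcing
at least four blocks per direction; label recovery on twenty seeds of
$500 \times 40$, $k = 3$, separation 10, zero noise; and the acceptance
script's main run on a $5000 \times 38$ planted matrix at rank 4 — the
shape of a classic leukemia expression panel — with 5% noise.

## Known limitations

* Only the KL-divergence objective and the plain multiplicative updates
  are implemented — no Frobenius variant, no sparseness or smoothness
  penalties, no relaxed/accelerated update schedules.
* Dense matrices only; no missing values, and no compressed or HDF5
  inputs.
* Model selection (choosing $k$ by consensus clustering across restarts)
  is out of scope; the deterministic seeding makes such a loop easy to
  script over the CLI, but no cophenetic statistic is computed.
* The binary format's two dialects (raw, and 8-byte dimension header) are
  this package's declared convention for row-major little-endian dumps;
  legacy files from other tools should be checked against it before use.
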