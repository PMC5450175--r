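---
title: "Methods: Markov state models of adjacency dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Markov state models of adjacency dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphmsm)
```

## The model

`graphmsm` describes a biomolecule's dynamics as a Markov chain over
*contact patterns*. The chain's states are not geometric clusters but
labeled adjacency matrices: for an ordered tuple of $k$ residues, the strict
upper triangle of the induced subgraph's adjacency matrix, read row by row
as a binary number with the first pair as the most significant bit, is the
tuple's *adjacency id*. A $k$-tuple therefore has
$|\mathcal{A}_k| = 2^{k(k-1)/2}$ possible states (8 for $k=3$, 64 for
$k=4$, 1{,}024 for $k=5$), and a state transition means a concrete
structural event — a contact forming or breaking inside that neighbourhood.

```{r}
# the canonical worked example: ordered (a,b,c,d), edges a-c, a-d, b-d, c-d
adjacency_id(rbind(c(1, 3), c(1, 4), c(2, 4), c(3, 4)), 1:4)  # 011011 -> 27
```

The input is a *dynamic graph*: a fixed vertex set with per-snapshot edge
sets $E_1,\dots,E_\tau$, stored as the initial snapshot plus batches
$E^+_t = E_t\setminus E_{t-1}$, $E^-_t = E_{t-1}\setminus E_t$. From an MD
trajectory this graph arises by keeping one atom per residue (C3$'$ for
RNA) and connecting residues closer than a cut-off $d$. Updating an id
under an edge event $\{a,b\}$ costs a single $\pm 2^{e(a,b,V')}$ when both
endpoints lie in the tuple and nothing otherwise, which is what makes the
streamed whole-molecule computation cheap: one pass over the batches
maintains the ids of *all* tuples simultaneously, and an event only touches
the tuples containing both endpoints.

Counting consecutive id pairs (self-transitions included) gives the local
transition matrix $T(V')$ of each ordered tuple. All tuples containing a
vertex $a$ form its transition tensor $C_a(V)$; their counts are pooled row
by row and normalized into the global row-stochastic matrix $T_g(a)$. The
stationary distribution $\pi$ ($\pi T_g = \pi$) and its Shannon entropy
$H = -\sum_i \pi_i \log_2 \pi_i$ (bits) summarize how many contact
patterns vertex $a$'s neighbourhoods actually inhabit at equilibrium;
$\Delta H = H_{\mathrm{ref}} - H_{\mathrm{other}}$ compares two runs, e.g.
ligand-free versus ligand-bound, with positive values meaning entropy loss
in the second run. RMSF (computed about the per-atom mean position, no
superposition) is carried along as the conventional baseline.

### The pooling rule

The published weighting of slices into a global matrix can be read in more
than one way (the summation index of the per-slice totals is used
inconsistently in its source). We resolve it as: *weight each slice's
row-conditional transition probabilities by that slice's share of all
observed transitions leaving the state*. That choice is algebraically
identical to summing raw counts across slices and row-normalizing once, and
it is the only reading that guarantees a row-stochastic result — which the
downstream spectral step requires. Slices that visit a state often
dominate that state's global row; slices that never leave a state
contribute exactly their self-transition mass.

## Parameters that matter

* **`d` (Å)** — contact cut-off. For C3' RNA graphs 10–15 Å is the
  physically sensible window (covers Watson–Crick pairing, Hoogsteen and
  stacking distances); 13 Å is the default used in the examples. Stationary
  distributions are known to be robust within this window; very large `d`
  freezes the graph into a single dense state. Exact equality
  $\lVert r_i - r_j\rVert = d$ counts as *no* contact — the published
  definition leaves the boundary case open, and fixing it (a measure-zero
  event) is required for bit-for-bit reproducibility.
* **`k`** — tuple size, 2–10 for id bookkeeping (ids fit 64-bit doubles
  exactly: at most 45 bits), but the full per-vertex computation is limited
  to $k\le 5$ because the state space grows as $2^{k(k-1)/2}$. $k=3$ is a
  good screening default; $k=4$ adds stacking-scale patterns at 64 states.
* **`pseudocount`** — adds $P_k = 1/|\mathcal{A}_k|$ to every cell of every
  local matrix before pooling. On by default: it makes every chain
  irreducible, so $\pi$ is unique, at a bias that vanishes as
  $\tau \to \infty$ (a property the test-suite checks explicitly). The
  placement per local matrix (rather than once on $T_g$) is a design
  choice; its source prescribes the value but not the placement.
* **`min_contact_prob`** — tuples with no vertex pair of contact
  probability above this threshold are skipped. The default 0 reproduces
  the strict "$P > 0$" rule: such tuples sit in one state forever and carry
  no transition information, so filtering changes nothing for vertices
  whose surviving tuple sets coincide (also tested bit-for-bit) while
  cutting the tuple count severalfold.

## What the synthetic generators emulate

`generate_random_dynamic_graph(n, e, b, tau, seed)` realizes exactly the
requested vertex count, edge count and per-step batch size (half removals,
half additions, so $|E|$ is conserved for even `b`), the substrate for the
stream/oracle equivalence tests at arbitrary scale.

`generate_synthetic_trajectory()` emulates a folded 65-nucleotide RNA at
C3' resolution: a self-avoiding random walk with 6 Å steps (the typical
consecutive C3'–C3' distance) and 9 Å excluded volume between
non-consecutive beads, confined to a 24 Å sphere. Those numbers were chosen
once, from the geometry of the target system: they reproduce the contact
statistics of a real 65-mer at $d = 13$ Å (about 180–240 edges, mean degree
around 7). Frames add an AR(1) displacement per bead (stationary SD 1.5 Å
per coordinate, frame-to-frame correlation 0.9), so pairs near the cut-off
oscillate across it and the derived graphs change by a few dozen edges per
snapshot — the same order as cut-off graphs from real MD sampled every few
hundred ps.

What the generator does **not** emulate: secondary-structure topology
(helices, loops), cooperative transitions between distinct folds,
anisotropic fluctuations, or ligand chemistry. Passing tests therefore
demonstrate the correctness of the bookkeeping and the estimators on
realistic graph statistics — not that any particular biological conclusion
transfers; for that, feed real trajectories.

## Numerical choices

* **Stationary distributions.** Up to 64 states: dense left
  eigendecomposition, dominant eigenvector, sign-normalized. Above 64
  states: power iteration on the lazy chain $(I+T)/2$, which has the same
  fixed point but is aperiodic, run to an iterate change below $10^{-12}$
  (at most $10^5$ iterations). Components below $10^{-12}$ are clipped to
  zero and the vector renormalized. Reducible chains (possible with
  pseudo-counts off, e.g. a static graph) produce a warning and a
  deterministic representative (first eigenvector in the sort order). An
  independent linear-solve oracle cross-checks both paths in the tests.
* **Degenerate rows.** A state with no outgoing observations (only
  possible with pseudo-counts off) gets a uniform row, keeping $T_g$
  stochastic.
* **Exactness of pooling.** All counts are integers plus dyadic
  pseudo-counts ($1/2^{K}$), so pooled sums are exact in doubles and the
  streamed one-pass result is bit-identical to the naive per-tuple replay —
  asserted with `expect_identical` in the tests, not just to tolerance.
* **Indexing.** Vertices are 1-based inside R (the natural R convention);
  the on-disk stream dialect uses 0-based integer labels, mapped at the
  boundary. Adjacency ids are 0-based everywhere and index matrix rows
  offset by one.
* **Ties and order.** Edges are stored canonically as $(\min,\max)$ and
  sorted; tuple slices are ordered lexicographically; all outputs are
  byte-stable across repeated runs.

## Design decisions that were genuinely open

* **Per-vertex tuple grouping.** The number of ordered $k$-tuples
  containing a fixed vertex is $k\,(|V|-1)!/(|V|-k)!$; each ordered tuple
  contributes its matrix to all $k$ member vertices, and matrices are
  conceptually computed once (the streamed pass pools per-vertex counts in
  the combination's canonical order and then sums over the $k!$
  position-permutations of the bit layout, which is mathematically the
  same thing at a fraction of the bookkeeping).
* **Generator split.** The random-graph benchmarks fix only the average
  batch size; the 50/50 add/remove split that keeps $|E|$ constant is our
  choice, matching the constant per-graph edge counts those benchmarks
  report.
* **Markov-recovery test chain.** The 4-state chain used to validate
  estimation at $\tau = 10^4$ was specified as well-mixing (self-transition
  probabilities near 0.55): the stationary vector of a slowly mixing chain
  cannot be pinned to ±0.02 by $10^4$ samples, so a fast-mixing chain is
  the only regime in which that tolerance is a meaningful test of
  correctness rather than of luck.

## Problem sizes used by the test-suite

Unit and property tests run on graphs of 5–20 vertices and up to 300
snapshots, with brute-force oracles at $n \le 8$. The end-to-end check uses
the full study geometry — 65 residues, 1{,}000 frames, $d = 13$ Å, $k = 3$,
contact-filtered (roughly 260{,}000 ordered tuples) — and completes in well
under a minute. $k = 4$ on the same graph means 16.2 million ordered tuples
and is substantially heavier; $k = 5$ full models are exercised only at toy
sizes, while its 991{,}186{,}560-tuple enumeration is checked as arithmetic
only.

## Known limitations

* States are *labeled* adjacency matrices, not isomorphism classes: two
  tuples with mirror-image contact patterns occupy different states. That
  is intentional (the per-vertex pooling needs position information) but
  means $H$ values at different $k$ are not directly comparable.
* No trajectory superposition before RMSF; pre-align externally if global
  rotation/translation should be removed.
* The dynamic graph has a fixed vertex set; residues cannot appear or
  disappear mid-run.
* Entropy measures the diversity of *visited contact states*, not
  Cartesian amplitude: a stiffer molecule with many persistent contacts
  can hold more adjacency entropy than a floppy one that collapses into
  the disconnected state. Interpret $\Delta H$ alongside $\Delta$RMSF, not
  as a substitute.
* Lag-time selection, implied timescales, coarse-graining of the chain and
  transition-path analysis are out of scope.
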