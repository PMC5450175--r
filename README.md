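# graphmsm

Markov state models of adjacency dynamics in molecular contact graphs.

`graphmsm` quantifies the coarse-grained conformational dynamics of a
biomolecule — it was built with RNA in mind, where one C3' bead per
nucleotide captures most of the architecture — directly in the space of
*contact patterns*, instead of the usual RMSD-plus-clustering route to
Markov state models. It is aimed at people analysing MD trajectories of
structured RNAs (riboswitches, aptamers) who want per-nucleotide flexibility
profiles and entropy changes upon ligand binding.

## The model

A trajectory of T frames is reduced to one representative atom per residue
and thresholded with a Euclidean cut-off *d* (10–15 Å for C3' graphs): frame
*t* becomes an undirected graph *G_t = (V, E_t)* with an edge wherever two
residues are within *d*. The sequence is stored as an initial snapshot plus
*batches* of edge additions `E⁺_t = E_t \ E_{t−1}` and removals
`E⁻_t = E_{t−1} \ E_t`, with batch size `δ_t = |E⁺_t| + |E⁻_t|` and
`δ_avg = Σ_t δ_t / τ`.

For an **ordered** tuple *V′* of *k* vertices, the strict upper triangle of
the induced subgraph's adjacency matrix, read row by row as a binary number
(most significant bit first), gives the **adjacency id**
`id(V′) ∈ [0, 2^(k(k−1)/2))` — the Markov state of that tuple. Ids are
maintained incrementally: an edge {a,b} with both endpoints in *V′* changes
the id by ±2^e(a,b,V′), where *e* is the bit position of that pair, so a
whole run costs one pass over the edge stream for *all* tuples at once.

Consecutive ids give the local transition count matrix *T(V′)* (plus an
optional minimal pseudo-count `P_k = 1/|A_k|` per cell). All tuples
containing a vertex *a* form its transition tensor *C_a(V)*; pooling their
counts row-wise and normalizing yields the **global transition matrix**
*T_g(a)* — equivalently, each slice's row-conditional probabilities weighted
by its share of transitions leaving the state. Its stationary distribution π
(dominant left eigenvector) gives the **conformational entropy**
`H = −Σ π_i log₂ π_i` in bits, and two runs are compared by
`ΔH = H_ref − H_other` alongside the conventional
`ΔRMSF = RMSF_ref − RMSF_other`.

Because the tuples whose vertices never meet stay in one state forever, the
computation can be restricted to tuples with at least one pair of non-zero
contact probability — typically an order-of-magnitude reduction with no
information loss.

## Worked example

Two synthetic 65-residue runs with the same fold: a free one and a stiffer
"bound" one (per-bead fluctuation 1.5 Å vs 0.8 Å).

```r
library(graphmsm)

traj_free  <- generate_synthetic_trajectory(n_residues = 65, n_frames = 500, seed = 1)
traj_bound <- generate_synthetic_trajectory(n_residues = 65, n_frames = 500, seed = 1,
                                            fluctuation = 0.8)

g_free <- trajectory_to_dynamic_graph(traj_free, d = 13)
g_free
#> dynamic graph: 65 vertices, 500 snapshots, |E_1| = 177, delta_avg = 28.8

P <- contact_probability(traj_free, d = 13)
run_free <- run_full_computation(g_free, k = 3, contact_prob = P)
run_free
#> global-model run: k = 3, 65 vertices, 142,788 ordered tuples (contact-filtered), tau = 500

run_free$models[["R10"]]
#> global model: vertex R10, 8 states (k = 3), 6834 slices, H = 1.8228 bits
round(run_free$models[["R10"]]$pi, 4)
#> [1] 0.5797 0.1295 0.1295 0.0080 0.1295 0.0080 0.0080 0.0077

g_bound <- trajectory_to_dynamic_graph(traj_bound, d = 13)
run_bound <- run_full_computation(g_bound, k = 3,
                                  contact_prob = contact_probability(traj_bound, d = 13))
cmp <- compare_runs(run_free, run_bound, ref_traj = traj_free, other_traj = traj_bound)
head(cmp[, c("vertex", "H_ref", "H_other", "delta_H", "delta_rmsf")], 5)
#>   vertex H_ref H_other delta_H delta_rmsf
#> 1     R1  1.68    2.14  -0.454       1.12
#> 2     R2  1.73    2.00  -0.263       1.11
#> 3     R3  1.95    2.14  -0.193       1.09
#> 4     R4  2.15    2.36  -0.211       1.16
#> 5     R5  1.86    2.14  -0.286       1.09
```

Reading the output: residue R10's three-vertex neighbourhoods spend ~58% of
their pooled stationary weight in the contact-free state and the rest in a
handful of bonded states, worth 1.82 bits of conformational entropy. The
ΔRMSF column shows the stiffer run fluctuating ~1.1 Å less, as constructed.
The ΔH column is negative here — the stiffer run holds *more* adjacency
entropy — because its contacts persist instead of collapsing into the
disconnected state; H measures the diversity of contact patterns a residue
visits, not Cartesian amplitude, which is exactly why it complements RMSF
rather than duplicating it. In a run-versus-itself comparison both columns
are identically zero.

The same pipeline is scriptable from a shell via `exec/graphmsm`
(`gen-graph`, `graph-from-traj`, `rmsf`, `ids`, `transitions`, `full`,
`compare`); see `exec/graphmsm` without arguments for usage.

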