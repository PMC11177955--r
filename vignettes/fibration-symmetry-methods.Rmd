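---
title: "Methods: fibration symmetry, cluster synchronization, and structural inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fibration symmetry, cluster synchronization, and structural inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrasym)
```

# The scientific problem

A structural brain network (a connectome of white-matter tracts between
regions of interest, ROIs) constrains which patterns of synchronized activity
the brain can sustain. fibrasym implements a symmetry account of that
structure–function link for the dorsal-stream language network of eleven
ROIs: supplementary motor area (SMA), premotor area (PreMA), Broca's area
(BA), angular gyrus (AG), Wernicke's area (WA) and supramarginal gyrus (SMG),
the last five bilaterally.

Two notions of graph symmetry are involved.

* **Automorphisms** are node permutations preserving adjacency globally
  (`PA = AP` for the permutation and adjacency matrices); their orbits form
  the orbital partition. This is the "physics" symmetry: rigid and global.
* **Fibration symmetry** is local: two nodes are equivalent when their
  *input trees* — the rooted trees of all reversed walks into them — are
  isomorphic. The equivalence classes are the *fibers*, which coincide with
  the classes of the coarsest *balanced coloring* (equitable partition):
  a coloring where same-coloured nodes receive the same number of in-arcs
  from each colour. Nodes in one fiber synchronize under any dynamics
  admissible for the graph.

Every orbit lies inside a fiber, so the number of fibers never exceeds the
number of orbits; equality signals maximal symmetry, and departures measure
symmetry breaking as the brain moves from its anatomical baseline into rest
or a language task.

# Pipeline overview

1. **Synchrony** (`instantaneous_phase()`, `plv_matrix()`,
   `surrogate_significance()`, `group_average()`): ROI time series are
   demeaned, their analytic signal computed by FFT, and the phase-locking
   value (PLV) — the modulus of the time-averaged phasor of the phase
   difference — taken for every ROI pair; per-subject matrices are averaged
   per condition.
2. **Cluster synchronization** (`detect_cs()`): percolation on the
   group-average PLV matrix yields a hierarchy of synchronized cliques.
3. **Coloring** (`cs_to_coloring()`): the cliques become a target coloring.
4. **Structural inference** (`infer_structural_network()`): an exact integer
   edge-edit program finds the fewest arc removals making the target the
   balanced coloring of the edited baseline connectome; a verification loop
   certifies it is the *minimal* balanced coloring.
5. **Symmetry report** (`run_symmetry_report()`): fibers, orbits,
   automorphism group and counts for each network.

`run_full_pipeline()` chains all stages; the same steps are exposed by the
thin command-line wrapper in `inst/cli/fibrasym.R`.

```{r pipeline}
res <- run_full_pipeline(list(conditions = list(
  rest     = build_printed_plv_fixture("rest"),
  phonemic = build_printed_plv_fixture("phonemic"),
  verb     = build_printed_plv_fixture("verb"))))
res$summary
```

The baseline has five fibers equal to five orbits; the resting-state network
keeps only local symmetry (four fibers, eleven singleton orbits); the task
network splits Broca's area (`{SMA, BA_L}` and `{BA_R, WA_L, WA_R}`),
restoring five fibers while the group symmetry stays fully broken.

# The clique condition and the percolation procedure

A candidate cluster-synchronization (CS) clique of N nodes is accepted when
the sum of its pairwise PLVs is at least `N(N-1)/2` times the PLV of every
link from a member to a non-member — equivalently, its mean internal PLV
(the *Cluster PLV*) must reach the strongest boundary link. Boundary values
are always read from the full matrix: judging boundaries only on the
partially percolated graph would trivially accept early cliques.

`detect_cs()` adds entries in decreasing weight order (equal weights as one
batch), tests each *newly formed maximal clique* once, and maintains a pool
of frozen, pairwise-disjoint cliques. Three rules resolve the cases the
condition alone leaves open:

* **Growth.** An accepted clique may later be absorbed by an accepted strict
  superset. Without growth, real-valued data would freeze a genuinely
  synchronized triangle at its strongest pair forever.
* **No partial theft.** A candidate that overlaps a frozen clique without
  containing it is rejected; frozen clusters never lose members.
* **Coverage stop.** Percolation stops once the pool covers every node —
  beyond that point no further clique can form among unfrozen nodes, and
  running to exhaustion would eventually glue unrelated clusters through the
  weakest entries of the matrix. A clique spanning *all* nodes has an empty
  boundary set, which leaves the condition undefined; such cliques are not
  acceptable.

These semantics are verified in the test suite against an independent
exhaustive oracle that enumerates every node subset, keeps those that are
maximal cliques of the graph thresholded at their weakest internal link and
satisfy the condition, and replays them in formation order under the same
rules.

Ties in Cluster PLV are ranked by size (larger first) and then by the
smallest member label; the resting-state fixture's two 0.689 pairs land AG
before BA under this rule.

# The edge-edit integer program

Given a baseline digraph `G = (V, E)` and a target coloring, the program has
binary removal variables for each arc, binary addition variables for each
non-edge (fixed to zero in removals-only mode, which is the falsifiable
one-to-many structure–function hypothesis: *can* the functional coloring be
sustained by a sub-network of the anatomical baseline?), and binary
imbalance indicators `s_pq^R` for cross-colour node pairs. Constraints:
balance equalities for every same-colour pair and source colour; in-degree
at least one per node; and big-M (M = n) indicator constraints forcing, for
every pair of different colours, at least one colour whose retained in-count
distinguishes them — a necessary condition for the target to be *minimal*.
The objective is `alpha * removals + beta * additions` (defaults 1 and 1).

**Exact solving.** The balance equalities force every member of a target
class T to retain (plus gain) the same in-count `k[T, S]` from each source
class S. Edit costs separate per node once these counts are fixed, the
in-degree constraint becomes `rowSums(k) >= 1`, and the indicator system is
satisfiable exactly when the rows of `k` are pairwise distinct. Solving over
these integer profiles is therefore *equivalent* to the arc-level program.
`solve_edit_program()` enumerates profile assignments in increasing cost by
best-first search, materializes arc-level solutions deterministically
(per node and source class, the retained sources are taken in canonical node
order), and among equal-cost optima returns the one whose removal vector is
lexicographically smallest over the canonical arc order. This tie-break is a
design choice: downstream symmetry reports need a deterministic network.
`write_lp()` exports the full arc-level program in LP format for external
solvers.

Because the indicator constraints are necessary but not sufficient,
`verify_and_repair_minimality()` recomputes the coarsest balanced coloring
of the edited graph; if it is coarser than the target (the classic failure:
two colour classes with identical profiles and no cross edges), the edit set
is excluded by a no-good cut and the program re-solved, up to a configurable
cap. Both fixture inferences verify on the first solution.

# The synthetic-data generator

The generator stands in for the study's unavailable raw recordings and
emulates its acquisition: 11 ROIs, 160 volumes at TR = 2.5 s, 20 subjects
per condition, band-limited dynamics in 0.01–0.1 Hz. Per colour class a
latent analytic signal is drawn with random in-band Fourier coefficients;
member i's signal is `Re(z(t) * exp(1i*(eps_i(t) + o_i)))` plus Gaussian
noise (`noise_sd`, default 0.05), with `eps_i` i.i.d. von Mises jitter of
concentration kappa and `o_i` a fixed offset. Keeping the latent amplitude
makes the FFT analytic signal recover the planted phase exactly, so
`kappa = Inf, noise_sd = 0` gives within-cluster PLV exactly 1.

For finite kappa, the phase difference of two members is the difference of
two independent von Mises draws, so the expected within-pair PLV is the
*squared* mean resultant length `(I1(kappa)/I0(kappa))^2`; the plain ratio
`I1/I0` applies member-to-latent. Tests check the generator against a
direct Monte-Carlo simulation of the von Mises resultant at the matched
number of retained samples. The default `kappa = 10` puts within-cluster
PLVs near 0.9 and cross-cluster pairs near the finite-length noise floor,
comfortably separated — group-averaged over 20 subjects, the planted
coloring is recovered in at least 95 of 100 seeded runs at `kappa = 8`.

What the generator does **not** emulate: hemodynamic response convolution,
scanner drift and physiological noise, head motion, spatial correlation
between ROIs, or task-evoked mean shifts. Passing tests therefore establish
the pipeline's correctness on phase-locked band-limited signals, not its
robustness to fMRI artefacts.

Surrogates for the significance test are random circular shifts plus
coin-flip time reversal per ROI — a transformation group that preserves each
row's spectrum and marginal distribution while destroying cross-ROI phase
alignment; with the `(1 + count)/(B + 1)` convention the resulting
randomization test controls the family-wise error exactly at level alpha
via the maximum-PLV null distribution. The generalized-Pareto tail option
(`tail = "gpd"`) smooths small p-values by a probability-weighted-moments
fit to the top exceedances; it is off by default.

# The baseline connectome fixture

The packaged edge list realizes the anatomically described tracts — FAT
(SMA–BA), SMA–premotor connections, arcuate fasciculus / dorsal pathway II
(BA–WA), dorsal pathway I (PreMA–WA), SLF attachments of BA and PreMA to
both inferior parietal regions (SMG, AG), local parietal–temporal links
(AG–WA, AG–SMG), and callosal homotopic edges for BA and AG — as 22
undirected tracts expanded to 44 arcs. The transcription was selected, from
all mirror-symmetric subsets of those candidate tracts, as one reproducing
*every* reported symmetry fact simultaneously: five fibers equal to five
orbits with the published memberships, the mirror permutation and the
WA/SMG swap as automorphisms, a feasible removals-only resting-state edit
whose result has four fibers and only the identity automorphism, and a task
edit with five fibers and trivial group. Notably, consistency *excludes*
callosal WA–WA and SMG–SMG edges: with them the resting-state optimum is
unique and mirror-symmetric, contradicting the published trivial
automorphism group; without them the baseline group has order exactly 8
(generated by the two within-hemisphere WA/SMG swaps and the mirror).
`baseline_connectome()` re-validates the fixture against the published
partitions at every load and refuses to return a corrupted graph.

# Numerical choices and degenerate inputs

* Analytic-signal edge transients: the first and last 5% of samples are
  excluded from every PLV average (configurable `trim`).
* PLV matrices are symmetrized and clipped to `[0, 1]` to machine tolerance;
  constant (zero-variance) rows raise an error naming the ROI.
* Refinement assigns class names in canonical order (size descending, then
  smallest label), making colorings deterministic and comparable.
* Automorphism enumeration backtracks with candidates restricted to the same
  fiber and equal in/out degrees (orbits refine fibers, so this is lossless);
  it is capped at 16 nodes. Generator subsets are reported for groups of
  order at most 1024 — beyond that, listing generators has no value for
  these analyses.
* Input trees are truncated at depth `n - 1`, which suffices to decide fiber
  equivalence on an n-node graph; subtree objects and canonical forms are
  memoized, since depth-10 trees on the baseline would otherwise hold about
  a million nodes.
* Degenerate edit programs: an empty class-profile set (a node that can
  receive from no colour) is reported as infeasible, which in removals-only
  mode becomes the explicit `hypothesis_falsified` status rather than an
  error.
* Kuramoto integration uses fixed-step classical Runge-Kutta (`dt = 0.05`);
  within-fiber trajectory spread below 1e-8 over a horizon of 20 time units
  is the flow-invariance criterion.

# Problem sizes used in the test suite

Property tests run on 200 random digraphs of up to 8 nodes (arc density
0.3–0.6, a range where automorphism groups stay informative), 50 four-node
edit-program instances checked against an exhaustive removal-subset oracle,
100 random synchronization matrices of up to 6 nodes checked against the
exhaustive clique oracle, 100 seeded generator runs for planted-coloring
recovery, and 200 noise replicates (199 surrogates each) for the
family-wise error of the significance test; the error-rate assertion is a
one-sided binomial consistency check at the 1% level, the statistically
well-posed reading of "type-I at most alpha" for a Monte-Carlo estimate.

# Known limitations

* Exact enumeration limits automorphism analysis to small networks (the
  intended mesoscopic regime); no nauty/bliss-style canonical labelling is
  attempted.
* The edit program's profile search is exponential in the number of colour
  classes in the worst case; it is instantaneous for the study-sized
  problems this package targets.
* Quasi-fibrations (approximate symmetries) and weighted tracts are out of
  scope; all structural edges are binary.
* The percolation semantics are one documented interpretation of the clique
  condition's open details (boundary set, ties, growth, stopping); the
  printed hierarchies constrain but do not uniquely determine them.
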