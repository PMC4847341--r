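---
title: "Dynamic probabilistic protein networks and core-attachment complex detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic probabilistic protein networks and core-attachment complex detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dppnet)
```

## The problem

Static PPI networks aggregate interactions that never co-occur in time:
a protein's partners at one cell-cycle phase are mixed with its partners
at another.  Complex detection on such a network conflates transient
assemblies.  `dppnet` addresses this by attaching *temporal activity*
information, derived from a time-course expression experiment, to a
static interactome, and by detecting complexes only among proteins that
are simultaneously active.

## The activity model

### Per-gene thresholds

For a gene with values $G_1..G_n$ over $n$ time points, with mean
$\alpha$ and sample SD $\sigma$ (divisor $n-1$), the three activity
thresholds are

$$Ge\_thresh_k = \alpha + k\,\sigma\left(1 - \frac{1}{1+\sigma^2}\right),
  \quad k = 1,2,3.$$

The damping factor $1 - 1/(1+\sigma^2)$ encodes a bias–noise tradeoff:
for a quiet gene ($\sigma^2$ small) the threshold collapses towards the
mean, so weakly fluctuating but consistently expressed genes are not
excluded; for a noisy gene it approaches the plain $k$-sigma rule.
Note the term assumes a particular expression scale — $\sigma \approx 1$
is the crossover — and the package applies it to whatever scale the
input matrix carries.  Users working with log-ratios near zero variance
should be aware the thresholds will hug the mean.

### Tiered active probability

A value at or above the 3-/2-/1-sigma threshold maps to active
probability 0.99 / 0.95 / 0.68; below the 1-sigma threshold the protein
is inactive (0).  The constants are the normal-interval masses 0.9973,
0.9545, 0.6827 truncated to two decimals; the acceptance suite verifies
this correspondence against `pnorm`.  Boundary behaviour is "value
$\ge$ threshold", exactly as the tier definition states.

Two degenerate cases are handled literally and logged rather than
special-cased:

* **Zero-variance genes**: all thresholds equal the mean, so every time
  point gets level 0.99.  Such genes carry no temporal information; a
  warning names them.
* **Duplicate gene rows** in the input are averaged element-wise (a
  deterministic, order-independent resolution) with a warning.

### Cycle collapsing

Inputs recorded over several replicate cycles (the emulated data has 3
metabolic cycles × 12 intervals) are reduced to one profile of 12 time
points by per-position arithmetic mean across cycles.  The mean is the
standard choice for replicate reduction and suppresses per-cycle noise
by $\sqrt{3}$; `collapse_cycles` also offers `first` (first cycle only)
and `none` for sensitivity analysis.

## The DPPN

The DPPN is one attributed graph, not 12 snapshot graphs: each vertex
carries its active-time set with per-time probability levels, each edge
carries the intersection of its endpoints' active sets, and edges whose
intersection is empty are removed.  Vertices without expression data
are dropped (no probability can be assigned to them and edge
intersections would be undefined) and the removal counts are logged so
dataset reduction is auditable.  Snapshot views are implicit in the
per-time-point weights.

Neighbourhoods and the average degree in the topology score

$$\mathrm{Topology}(e_{ij}) =
  \frac{|N_i \cap N_j| + 1}
       {\max\{\overline{d}, |N_i|\} + \max\{\overline{d}, |N_j|\}}$$

are computed on the *pruned* DPPN, not the raw static network: the
score is defined as a property of the dynamic graph, and using stale
static degrees would let edges deleted by pruning still penalise their
endpoints.  This choice is a package decision, recorded here, since
either reading is defensible.

The time-indexed edge weight multiplies the topology score by both
endpoints' probability levels at that time, so the same interaction can
be strong at one time point and absent at another.

## Complex detection

### Phase 1 — cores

All maximal cliques with $\ge 3$ members (Bron–Kerbosch via `igraph`)
that share at least one common active time point are scored by

$$\mathrm{Clique\_score} = \left(\max_{k \in A_c} \prod_{v \in C} P_k(v)\right)
  \cdot \sum_{e \in E_c} \mathrm{Topology}(e),$$

and assigned the time point achieving the max (earliest on ties).
Selection is greedy in score order with overlap resolution in the style
of maximal-clique merging used by CMC: after promoting the top clique
$A$, any remaining candidate $B$ with $|A \cap B|/|B| \ge 0.5$ is
deleted; a partially overlapping $B$ is pruned of $A$'s members, kept
if at least `min_clique_size` members remain (a pruned clique is still
a clique), and re-scored over its remaining edges.  The 0.5 ratio is
exposed as `overlap_thresh` because the original prune rule is not
fully specified; ties in score are broken by larger member count, then
lexicographic member order, making the whole pipeline deterministic.

Complexes of low density or size 2 cannot arise from cliques, so edges
not contained in any selected clique-core whose *maximum* weight over
their active-time set strictly exceeds `core_thresh` (default 0.09)
become 2-member edge-cores at the argmax time (earliest on ties).  The
maximum over time is the most permissive reading consistent with a
time-indexed weight; both threshold comparisons are strict ("larger
than"), matching the algorithm's description.

### Phase 2 — attachments

For each core, every DPPN neighbour active at the core's time $T_c$
with attachment score

$$\mathrm{Attach} = \frac{1}{|C|}\sum_{v_i \in C}
  \mathrm{Weight}(e_{T_c}(v_i, v_k))$$

strictly above `extend_thresh` (default 0.05) is added.  Attachment is
a single pass against the frozen core — the score is defined against
the core, not a partially grown complex — and one protein may attach to
several cores, so overlapping predictions are possible (biologically
expected).  Edge-cores also undergo attachment: they are cores.
Identical final member sets are deduplicated keeping the higher-scoring
core.  Both defaults (0.09, 0.05) are the values reported optimal in
published sweeps on yeast interactomes; `sweep_thresholds` reproduces
that protocol on any input.

## Evaluation

Matching uses neighborhood affinity
$NA(P,B) = |P \cap B|^2/(|P||B|) > 0.2$, many-to-many.  Precision and
recall count matched predicted / benchmark complexes; Sn and PPV are
computed from the full protein-overlap matrix $T_{ij}$ with
$\mathrm{PPV}$'s denominator the total overlap mass (the standard
definition), and PPV is defined as 0
when there is no overlap at all.  Benchmark complexes are *not*
filtered to proteins present in the input network; absolute recall is
therefore conservative, which matters when comparing against numbers
computed with filtered benchmarks.

## The synthetic world

The generator emits the statistical structure the method consumes, not
a biophysical simulation:

* **Network**: planted complexes occupy disjoint protein blocks and are
  realised as cliques (optionally density-thinned); all other pairs get
  independent background edges (`background_edge_prob`, default 0.01 —
  sparse, like the ~2·10³ proteins / ~10⁴ interactions regime of the
  emulated interactomes).
* **Expression**: per gene, baseline $\mu_g \sim U(5, 10)$ (arbitrary
  units) plus $N(0, \sigma)$ noise per time point ($\sigma = 1$).
  Background genes additionally carry a random-phase sinusoid of
  amplitude $1\sigma$, giving realistic incidental activity at their
  wave peaks.  Planted members receive an `amplitude`·$\sigma$ pulse
  (default 4) at their complex's time point *in every cycle*; after
  3-cycle averaging the pulse clears the member's own 3-sigma threshold
  with margin while the remaining points stay mostly inactive (the
  planted-member 0.99 guarantee is verified post-hoc in the tests).
  Amplitude 4 was chosen once as "unambiguous signal": amplitude 3 sits
  exactly at the threshold boundary and makes recovery a coin flip.
* **Benchmark** = the planted complexes; ground truth is also written
  as JSON.

What a green test establishes: the pipeline recovers coordinated,
clique-shaped, strongly pulsed complexes and assigns their time point.
What it does not: performance on real data, where signal is weaker,
complexes are not cliques, expression and protein abundance decouple,
and the benchmark contains complexes invisible to the interactome.

### The shuffling control

`shuffle_expression` permutes each gene's values across time columns
independently, preserving per-gene means, SDs and thresholds (verified
in tests) while destroying temporal alignment.  The acceptance control
applies it to the *12-point collapsed* profiles — the profile the
activity layer actually consumes, which is the permutation unit of the
standard randomisation control.  Shuffling the 36 raw columns instead splits
each 3-cycle pulse into up to three scattered active times; co-active
*fragments* of a planted complex then persist, and because a fragment
$F \subset B$ matches whenever $|F| > |B|/5$ under the $NA > 0.2$
rule, small synthetic worlds can show *higher* F after raw-column
shuffling.  This is a property of the affinity threshold, not of the
method, and is worth knowing when designing controls.

## Numerical and degenerate-input choices

* All greedy and output orderings have total, deterministic tie-breaks
  (score, then size, then lexicographic member key); identical inputs
  give byte-identical outputs.
* Thresholds `core_thresh`/`extend_thresh` are compared strictly, as
  worded; boundary rows of published sweep tables cannot disambiguate
  strict vs non-strict.
* Earliest time point wins ties in clique probability and edge-core
  argmax.
* Empty DPPNs, empty activity tables and empty prediction lists are
  legal and produce empty (or zero-metric, with warning) results rather
  than errors; empty *benchmark* sets are an error.
* An isolated vertex that is active stays in the DPPN (it can still be
  counted in the active-protein distribution); it can never join a
  complex.

## Known limitations

* Non-integer sigma multipliers are not implemented; only $k = 1,2,3$
  tiers exist.
* mRNA level is used as a proxy for protein activity; no
  transcript-to-protein modelling.
* Confidence-weighted input PPIs are not supported (interactions are
  treated as unweighted).
* The comparison methods from the literature (ClusterONE, COACH, CMC,
  MCL, …) are out of scope; the evaluation module scores any externally
  produced prediction lists instead.
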