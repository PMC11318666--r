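---
title: "Reconstructing chromosome 3D structures with co-clustering-weighted error-vector resultants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing chromosome 3D structures with co-clustering-weighted error-vector resultants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chromosome conformation capture assays (Hi-C and relatives) measure, for
every pair of fixed-size genomic intervals ("bins"), a contact frequency
$F_{ij} \ge 0$: how often the two loci were caught in physical proximity
across a cell population.  Restraint-based structure modelling turns this
matrix into a 3D model — one point per bin — whose pairwise distances are
as compatible as possible with the observed frequencies.  `evrc`
implements such a reconstruction for single chromosomes and for whole
genomes assembled from intra- and inter-chromosome matrices, together
with a simulation test bed and evaluation metrics.

## From frequencies to target distances

The closer two loci, the more often they touch.  We adopt the standard
power-law conversion

$$D_{ij} = \begin{cases} F_{ij}^{-\alpha}, & F_{ij} > 0\\
\infty, & \text{otherwise,}\end{cases}$$

computed by `freq_to_dist()`.  $D_{ij} = \infty$ means "no usable
constraint", and such pairs are skipped everywhere downstream.  The
exponent $\alpha$ defaults to 0.5, a common choice for real Hi-C counts;
for the simulation test bed, whose frequencies are exact reciprocal
distances, $\alpha = 1$ makes the conversion self-inverse and should
always be used.  Bins with no finite distance at all (e.g. unmappable
regions) are removed by `drop_isolated_bins()` and re-emitted as `NaN`
rows on output so genome coordinates stay aligned.

## Co-clustering weights

Not every constraint deserves equal pull.  Two bins that sit in the same
densely self-interacting neighbourhood — the same topologically
associating domain, say — should influence each other's placement more
than two bins whose neighbourhoods barely interact.  We quantify this
with a pairwise extension of the clustering coefficient.  The contact
graph (`build_graph()`) has an edge wherever $D_{ij}$ is finite.  For a
node $i$ with neighbour set $N_i$, the classical clustering coefficient
is $CC_i = 2e_i / (k_i(k_i-1))$ with $k_i = |N_i|$ and $e_i$ the number
of edges among the neighbours.  For a pair, let $U_{ij} = N_i \cup N_j$
with $k_{ij} = |U_{ij}|$ and let $e_{ij}$ count every graph edge whose
two endpoints both lie in $U_{ij}$; then

$$coCC_{ij} = \frac{2\,e_{ij}}{k_{ij}(k_{ij}-1)} \in [0, 1],$$

defined as 0 when $k_{ij} \le 1$ (no clustering evidence).  Note the
conventions, which matter in corner cases: $U_{ij}$ is the literal union
of the two neighbour sets, so when $i$ and $j$ are adjacent each belongs
to the other's set and the edge $(i,j)$ itself is counted; and $e_{ij}$
counts *all* edges internal to the union, not only edges between shared
neighbours.  As a worked example, a pair whose union has 7 nodes and 10
internal edges gets $10/21 \approx 0.476$; with only 6 internal edges,
$6/21 \approx 0.286$.  `cocc_matrix()` computes all pairs once, up front
— the weights depend only on the data, never on coordinates — using a
bitset edge-counting kernel in C++ (`O(n^2)$ pairs, each counted over
packed adjacency rows), which the test suite checks against a literal
edge-list recount.

Pairs with $D_{ij} = \infty$ still have a well-defined weight (they may
share neighbours) but contribute nothing to the optimization, because
only finite-distance pairs enter the sums below.

## The error-vector resultant iteration

Each bin $j$ has current coordinates $P_j$, initialised uniformly at
random in a cube whose side is the mean finite target distance
(`init_scale = 1`); the search thus starts at the data's natural scale.
For a constrained pair, the error vector

$$E_{ij} = \frac{P_i - P_j}{\lVert P_i - P_j\rVert}\,
\bigl(\lVert P_i - P_j\rVert - D_{ij}\bigr)$$

points from $P_j$ toward $P_i$ when the pair is too far apart and away
when too close; its magnitude is the constraint violation.  The weighted
resultant of a bin is

$$E_j = \sum_{i \ne j,\; D_{ij} < \infty}
\frac{coCC_{ij}}{(N-1)^{\beta}}\, E_{ij},$$

with $N$ the number of kept bins, and the global objective is
$F = \sum_j \lVert E_j \rVert$ with convergence monitored through
$\Delta F = |F_t - F_{t-1}|$.  For multi-chromosome input the sum runs
genome-wide, so $N$ is the global bin count.

**The coordinate update is the damped resultant** $P_j \leftarrow P_j +
E_j/(N-1)$, all bins moved synchronously from the pre-step coordinates.
The damping is essential, not cosmetic: the resultant aggregates up to
$N-1$ error vectors, so adding it raw makes the effective step size grow
linearly with the number of constraints and the iteration diverges for
any realistic $N$ (a two-line experiment with a few hundred bins
confirms this).  Dividing by $N-1$ turns the move into the
$coCC$-weighted *mean* of the bin's error vectors — the same fixed
points, but a contraction.  At $N = 2$ the damping factor is 1 and the
update exhibits the well-known synchronous overshoot (two bins swap
through each other); this is harmless at realistic sizes and accepted
for the sake of order-independence and bit-reproducibility, which a
sequential per-bin sweep would not give.  The convergence factor
$\beta$ (default 0.1) damps further: larger values shrink the weights
and slow convergence.

### Stopping, stalls, and divergence

The run stops when $\Delta F <$ `tol` (default $10^{-6}$) or after
`max_iter` (default 20000) iterations.  Two numerical refinements:

* **Stall guard.**  On instances with entangled intermediate states
  (e.g. a closed spiral threading itself), $F$ can decrease through a
  long, nearly flat plateau where single-iteration $\Delta F$ dips below
  the tolerance while the structure is still visibly wrong.  The
  convergence check therefore requires $\Delta F <$ `tol` on 10
  *consecutive* iterations.  At a genuine optimum $\Delta F$ stays below
  tolerance, so the run merely stops a few iterations later; transient
  dips no longer cause premature stops.
* **Divergence detector.**  A run whose objective rises for 100
  consecutive iterations *and* exceeds 10 times its starting value (or
  produces non-finite values) aborts with an error suggesting a larger
  $\beta$.  The two-sided condition avoids false alarms during
  legitimate slow barrier crossings, where $F$ can creep upward for long
  stretches at a low level.

Flat (planar) structures deserve a note: an out-of-plane ripple changes
pairwise distances only at second order, so its restoring force vanishes
with its amplitude and the last fraction of a percent of RMSD decays
algebraically rather than geometrically.  The default tolerance resolves
this mode to a few tenths of a percent of the structure diameter; the
distance correlation is essentially unaffected either way.

Coincident points (distance below $10^{-12}$) have no defined error
direction and receive a seeded-random unit direction scaled by the
target distance.  All randomness — initialisation and this jitter guard
— is driven by the single `seed` in `evrc_config()`, and identical
inputs with identical seeds reproduce traces bit for bit.

Optional Gaussian smoothing (`smooth_structure()`) filters each
coordinate along the bin order with a truncated, renormalised kernel,
independently per chain.  It exists purely for visualization; the
default `"auto"` applies none, and all evaluation metrics use unsmoothed
coordinates.

## The simulation test bed

`generate_model()` provides six closed-form curves of increasing
difficulty: circle, open spiral, circular (torus-wound, closed) spiral,
replication fork, double helix, and double spherical helix — the last
three split across two chains to emulate multi-chromosome systems with
both intra- and inter-chain contacts.  Contact frequencies are the
reciprocal pairwise distances (`contacts_from_structure()`), so a
reconstruction at $\alpha = 1$ faces an exactly solvable problem.  The
default size is 500 points per structure (250 per chain for the
double-chain models).  The curve parameterizations are the package's
own canonical choices (unit circle; helix radius 1, four turns, height
4; torus radii 3 and 1 with 16 windings; fork trunk with strand offset
0.05 and quadratic divergence; anti-phase double helix; unit-sphere
spirals with trimmed poles so the chains never touch), fixed once and
documented in `?model_spec`.  Since the contacts are *derived from the
generated geometry itself*, any smooth realization preserves the logic
of the round-trip tests.

Noise emulates experimental uncertainty multiplicatively on distances,
*before* conversion to frequencies: each finite $D_{ij}$ is multiplied
by $(1 + r\,s)$, $r \sim U[-1, 1]$ drawn once per unordered pair (so
matrices stay symmetric), noise level $s \in [0, 1]$.  A clamp at
$10^{-9}$ times the original distance guards the $s = 1$, $r \to -1$
corner.  What this generator does *not* emulate: polymer physics,
resolution-dependent count statistics (Poisson sampling, coverage
biases), normalization artefacts, or structural heterogeneity across
cells.  Passing the simulation suite therefore demonstrates the
optimizer's correctness and noise robustness on geometrically faithful
inputs, not performance on any particular experimental dataset.

## Evaluation

* `superpose()`/`rmsd()` — least-squares (SVD/Kabsch) superposition.
  Reflection is allowed by default because contact data cannot determine
  chirality; uniform scale fitting is off by default because the power
  law fixes the absolute scale, but can be enabled when comparing
  against methods with arbitrary output scale.
* `distance_pcc()` — Pearson correlation of the two structures' full
  pairwise-distance vectors; invariant under rigid motion, reflection,
  and uniform scaling.
* `recovered_scc()` — Spearman correlation between input frequencies
  and frequencies back-computed from the model
  ($F' = d^{-1/\alpha}$), over pairs with positive input frequency
  (zero-frequency pairs have no recoverable rank).  Ties get average
  ranks; on highly symmetric test curves, exactly tied distances can
  flip order by one ulp between two algebraically equivalent
  expressions, so "perfect" agreement means 1 up to that tie jitter.

## Test problem sizes

The packaged tests reconstruct all six structures at 100 points
(noiseless, five seeds each, asserting post-superposition RMSD below 1%
of the structure diameter and distance-PCC above 0.999) and at the full
500 points under noise $s = 0.1$ and $s = 1.0$ (asserting minimum
distance-PCC above 0.99 and 0.96 respectively).  The scaled 100-point
noise run is also checked; at $s = 1.0$ its bound is relaxed to 0.91,
since with a quarter of the bins there are ~16 times fewer pairs over
which the distance noise averages out.  These sizes are the package's
chosen test conditions; the acceptance script
(`scripts/acceptance.R`) re-runs the 500-point noise sweep from scratch
with three seeds per noise level.

## Known limitations

* The optimizer is a plain damped resultant iteration: no momentum,
  annealing, or line search.  Entangled topologies (closed curves) can
  take several thousand iterations to unthread.
* The frequency-distance relation is a single global power law; no
  per-distance calibration or balancing (ICE/KR) is performed, and
  inputs are expected to be already binned and, if desired, normalized.
* Structures are point chains; no excluded volume or chromatin
  persistence length is modelled.
* The co-clustering weights are computed once from the input graph; a
  graph that is almost complete (as with noiseless simulated data)
  yields nearly uniform weights, in which case the weighting is
  effectively neutral.
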