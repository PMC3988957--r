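---
title: "Methods: motif statistics and null models for multiplex interneuron networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif statistics and null models for multiplex interneuron networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlinet)
```

## Data model and conventions

A recording data set (`mli_data`) bundles a cell table and a pair table.
Cells carry sagittal-plane coordinates (x, y, μm), a transverse coordinate
(z, μm — depth across parallel sagittal planes of the slice) and optionally
a normalized molecular-layer position `ml_pos` (0 at the Purkinje cell
layer, 1 at the pia). Every unordered pair within a simultaneous recording
set of n cells is tested in both directions, so the validator enforces
exactly `choose(n, 2)` pair rows per set; distances Δxy (Euclidean, in the
sagittal plane) and Δz (absolute) are recomputed from coordinates and
cross-checked against stored values at 10⁻⁶ μm.

An electrical connection is an undirected edge, present when the coupling
coefficient is at least 1% (the detection threshold; configurable via
`cc_threshold`). A chemical connection is a directed edge; a bidirectional
pair is simply two directed edges, never a separate edge type. Booleans are
stored as 0/1 in CSV; GraphML export writes one arc per electrical edge
flagged `type = "electrical"` and interprets it symmetrically on re-import.

## Triad classification

Triads are encoded as bit codes over fixed slots — three unordered pairs
(undirected) or six ordered pairs (directed) — and canonicalized by
minimizing the code over the six node permutations. This yields 4
undirected and 16 directed isomorphism classes, indexed by (edge count,
canonical code). The published pattern numbering for directed triads is not
strictly ordered by edge count and is only partially recoverable from named
examples, so the package never relies on bare indices: reports always carry
the class name (e.g. `feedforward`, `three_loop`, `regulating_mutual`) and
the canonical code. Unnamed classes received descriptive names in the same
spirit (`converging_mutual`, `mutual_loop`, `five_edge`, ...).

A directed class is *transitive* when every directed 2-path A→B→C (A ≠ C)
is closed by A→C, *not applicable* when the class contains no such 2-path
(too few edges: the empty triad, single edge, mutual pair, and the two
star configurations), and *intransitive* otherwise. Over the 16 classes
this gives 4 transitive, 7 intransitive and 5 not-applicable classes,
verified in the tests by brute force over all 64 labeled digraphs.

Quadruplet sets are decomposed into their four triads for all triplet-level
statistics; pairs contribute nothing. A triplet's transverse dispersion is
the mean of its three pairwise Δz values, computed over all three pairs
(not only connected ones) because fully unconnected triplets still enter
the anticlustering analysis.

## Clustering and anticlustering

The clustering coefficient of a recorded subnetwork (3 or 4 cells) is its
global transitivity: closed 2-paths divided by 2-paths, undefined when no
2-path exists. For triplets this is 1 exactly on triangles, 0 exactly on
2-edge paths, and undefined otherwise, which matches the worked cases the
analysis relies on. For quadruplets, global transitivity and per-node
averaging can differ; global transitivity is the package's definition
throughout (per-node averaging offers no advantage for 3–4 node induced
subgraphs and breaks the triplet identities). The anticlustering
coefficient is the same quantity on the complement graph over the same
nodes. Chemical triads are collapsed to their undirected support first,
treating uni- and bidirectional connections identically. Group means are
taken over the subnetworks where the coefficient is defined, with the
counts of measurable subnetworks reported; they deliberately do not
estimate a whole-network clustering coefficient — they exist to be compared
with the same statistic computed on null-model samples over the same
geometry.

Under independent wiring at rate p, the mean triplet clustering coefficient
has the closed form p/(3−2p) (= P(triangle)/(P(triangle)+P(2-edge))) and
the mean anticlustering coefficient (1−p)/(1+2p); the test suite checks the
Monte Carlo machinery against both at 10⁵ triplets.

Coefficient-versus-dispersion relationships are unweighted OLS fits of the
per-triplet coefficient against its Δz dispersion (binning is for display
only), with intercept/slope uncertainties from a nonparametric bootstrap
over triplets, and comparisons against model fits by Monte Carlo rank.

## Null models and testing

Three generative nulls are available through `fit_null_model()`:

* **uniform** — every electrical edge Bernoulli(p_E), every directed
  chemical edge Bernoulli(p_C), independent. The rates default to the
  estimates p_E = n_E/n_pairs and p_C = n_C/(2 n_pairs) from the fitted
  data but can be supplied explicitly (e.g. a simulation's known generating
  rates, or published values); refitting to structured data absorbs part of
  the structure into the rates and is conservative.
* **nonuniform_distance** — per-pair probabilities follow the measured
  distance dependence. Binned profiles (default 20 μm bins in Δxy up to
  180 μm, 10 μm bins in Δz up to 50 μm, matching the tested range; per-bin
  SDs by bootstrap over pairs) are combined as a separable product
  p(Δxy)·p(Δz), rescaled so the model reproduces the observed global
  connection count on the recorded geometry — the 2-D combination rule is
  not identified by one-axis marginals, and this normalization is the
  weakest assumption that preserves the marginal rates. Empty bins are
  interpolated from neighboring bins; out-of-range distances are clamped to
  the nearest bin.
* **nonuniform_distance_ml** — additionally reweights chemical edge
  direction by a two-bin table P(downward | connected) estimated from the
  data, capturing a preference for connections projecting down the
  molecular layer. This is an explicit simplification: the exact published
  form of the position-dependent model is not available, and only this
  direction-bias variant is in scope.

Monte Carlo significance uses the add-one rank rule
p = (1 + #{null ≥ observed})/(1 + n) (two-sided doubles the smaller tail),
so the default n = 9,999 samples give a one-sided floor of 10⁻⁴. Bonferroni
correction is min(1, m·p) with m allowed to exceed the number of reported
tests. Motif ratio tests decompose each sampled wiring into triplets
identically to the data, report observed/predicted frequency ratios per
class, and include the grouped transitive/intransitive comparison, which is
the primary detector of transitivity structure: at realistic effect sizes
single rare classes (e.g. feedforward alone against a 16-class Bonferroni
family) carry much less power than the grouped test.

## Common neighbors and synchrony

For each pair (A, B) in a set of ≥ 3 cells, a third recorded cell N is an
electrical common neighbor when N–A and N–B are both electrical, a chemical
common neighbor when N has a chemical connection (either direction) with
both, and a chain neighbor when the connections run strictly X→N→Y with
{X, Y} = {A, B} (a convergent A→N←B does not qualify). A mixed neighbor has
exactly one electrical link to one member and one chemical link to the
other; pairs that also have a pure electrical or pure chemical common
neighbor are excluded from the mixed category so that the cross-network
effect is isolated. Outcome probabilities are three non-exclusive
indicators — no connection, electrical present, chemical present — so dual
pairs increment both rates; comparisons use 2×2 chi-squared tests without
continuity correction (category versus rest) and Monte Carlo sampling of a
fitted null on the category pairs' geometry.

IPSC synchrony is the peak of the chance-normalized cross-correlogram
(bin = 1 ms, bins centered on zero lag): counts of event-time differences
divided by rate_a·rate_b·duration·bin, so 1 means independence. The peak is
searched within ±5 ms of zero lag (shared MLI input produces
millisecond-scale synchrony; the window is configurable), and a
jitter-surrogate option is provided as a robustness check on the
normalization. Because the peak is a maximum over ~11 bins, its null
distribution for independent trains sits above 1 (extreme-value bias); the
calibration tests therefore compare measured peaks against the exact
max-of-Poisson-counts oracle rather than assuming the peak itself
concentrates at 1 — only the full correlogram averages to 1. Group
contrasts of synchrony indices (e.g. chemically connected versus
unconnected pairs) use Welch t-tests.

Event detection from raw current traces is out of scope; the module
consumes event times. Trace-level helpers cover the coupling coefficient,
spike-triggered averaging with pre-spike baseline subtraction, the
gabazine decomposition of dual connections (chemical = control −
gabazine, pointwise), and the Nernst potential (temperature default 32 °C,
the recording temperature; the bundled solution recipes give
E_Cl ≈ −77.5 mV).

## Synthetic data: what it emulates and what it does not

The generator defines the study conditions used for calibration:

* **Geometry** — sets of 2–4 cells scattered around local centers with
  Gaussian spreads (defaults 40 μm in-plane, 12 μm transverse), rejected
  and redrawn until all pairwise distances satisfy the tested range
  Δxy ≤ 180 μm, Δz ≤ 50 μm (abort after 1000 retries). `ml_pos` is uniform
  in [0.1, 0.9].
* **Wiring** — baselines p_E = 0.42 and p_C = 0.20, the measured pair-level
  rates. The distance model uses per-axis logistic decays
  p(Δ) = p₀/(1 + exp((Δ−d₀)/s)) multiplied across axes; defaults
  (electrical p₀ = 0.65, d₀ = 60 μm in xy and 20 μm in z; chemical
  p₀ = 0.30 with weak decay) were chosen once to match the shape of the
  measured binned curves — smooth, few parameters, recoverable by the
  profile estimator. Profiles may carry hard caps (`z_max`) that force the
  probability to exactly zero, emulating the strict sagittal confinement of
  electrical coupling (no electrical edges beyond Δz ≈ 30 μm).
* **Structure** — a single closure pass in a fixed random order adds the
  third electrical edge of open electrical 2-paths with probability
  `clustering_bias`, closes directed 2-paths with probability
  `transitivity_bias`, and reorients chemical edges downward in `ml_pos`
  with probability `ml_direction_bias`. One pass (no fixed-point iteration)
  keeps the induced bias monotone in the parameter.
* **Weights** — CC log-normal with mean 7.13% and SD 6.02% truncated at the
  1% threshold; IPSC amplitudes log-normal with mean 11.2 pA and SD 9.2 pA
  (the published moments; truncation shifts the realized CC moments
  slightly upward).
* **Event trains** — per cell, a private Poisson process at
  (1−f)·rate plus, for designated pairs, a shared Poisson source at f·rate
  delivered to both with independent Gaussian jitter, emulating a shared
  presynaptic interneuron.
* **Morphology** — labeled point clouds whose z coordinates are Gaussian
  with 2σ defaults 24.1 μm (dendrite) and 41.3 μm (axon), the measured
  density widths.

The generator does not attempt biophysics, development, per-set distance
distributions of the original recordings, or realistic in-plane morphology;
passing tests demonstrate that the estimators recover known generative
structure at realistic sample sizes, not that real MLI data satisfy the
generator's assumptions.

## Numerical and design choices

* Degenerate inputs: coefficients are `NA` (not 0) when no 2-path exists;
  means skip undefined values and report measurable counts; dispersion fits
  require ≥ 3 measurable triplets with distinct dispersions.
* Role assignment in regulating-mutual triads (origin = common source;
  higher cell of the mutual pair = intermediate) is a package convention,
  flagged as such, since only the feedforward role mapping is forced by
  degrees; per-test n is always reported.
* Density widths come from a least-squares Gaussian fit (Nelder–Mead on
  amplitude, center, log σ) to the binned, max-normalized histogram.
* Simulation scales in the test suite (10⁵ triplets for closed-form
  oracles; 20 replicates of 999-sample Monte Carlo tests at ~200 triplets,
  ~140 common-neighbor pairs and 11 feedforward triplets; 200 seeded
  cross-correlogram runs at 10 Hz × 500 s) were chosen to keep each
  statistical check's own error at least ~3× smaller than the tolerance it
  asserts.
* Both dual-connection conventions are reported at the pair level
  (`p_dual_exclusive`, electrical + exactly one chemical direction, and
  `p_dual_any`), since the published headline value is ambiguous between
  them.

## Known limitations

* The nonuniform model's separable distance kernel cannot represent
  xy–z interactions in connection probability.
* The molecular-layer direction model is a two-bin reweighting, not a
  position-resolved kernel.
* Mixed electrical+chemical triad classes (128 combinations) are
  representable as pairs of class ids, but no mixed census is computed;
  the common-neighbor analysis covers the overlap question at equal power
  with far fewer hypotheses.
* Quadruplet-level clustering uses global transitivity; per-node averaging
  would differ on some 4-node graphs.
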