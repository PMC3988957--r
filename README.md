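# mlinet

Motif and null-model analysis of electrical and chemical interneuron
networks recorded with simultaneous multi-cell patch clamp.

## The problem

Molecular layer interneurons (MLIs) of the cerebellar cortex are linked by
two synaptic networks measured on the same cells: an **undirected electrical
network** of gap junctions, quantified by the coupling coefficient
(CC = 100 · ΔV_post / ΔV_pre, an edge existing for CC ≥ 1%), and a
**directed chemical network** of GABAergic synapses, quantified by IPSC
amplitude. Recordings come in simultaneous sets of 2–4 cells in which every
pair is tested both ways, so each set yields a fully observed multiplex
subnetwork plus the 3-D geometry of the somata (sagittal xy, transverse z,
and normalized molecular-layer position).

The scientific question is whether this connectivity is random. `mlinet`
implements the full analysis chain used to answer it:

* **Pair level** — connection probabilities p_E = n_E/n_pairs,
  p_C = n_C/(2·n_pairs), and the six-way pair-category distribution
  (none / electrical only / chemical only / dual / bidirectional /
  bidirectional + electrical) with its independent-wiring closed form.
* **Triplet level** — decomposition of sets into triplets (each quadruplet
  contributes its four triads), exhaustive isomorphism classification
  (4 undirected, 16 directed classes), the transitivity taxonomy of
  directed triads (a class is *transitive* when every 2-path A→B→C is
  closed by A→C; 4 transitive, 7 intransitive, 5 not-applicable classes),
  and motif censuses.
* **Subnetwork statistics** — the clustering coefficient
  C = (closed 2-paths)/(2-paths) of each recorded subnetwork, the
  anticlustering coefficient AC (the same measure on the complement graph),
  and their dependence on the triplet's transverse dispersion (mean Δz).
* **Null models** — uniform and distance-dependent ("nonuniform") random
  connectivity models fitted to the data, sampled by Monte Carlo on the
  recorded geometry, with add-one rank p-values and Bonferroni correction.
* **Overlap of the two networks** — common-neighbor analysis (electrical,
  mixed, chemical, and chemical-chain neighbors) and IPSC cross-correlogram
  synchrony (chance-normalized, bin = 1 ms) as an independent assay of
  shared presynaptic input.
* **Spatial organization** — molecular-layer position normalization,
  origin/intermediate/target role statistics of feedforward motifs, and
  Gaussian 2σ width of morphological density profiles along z.
* **Synthetic data** — a generator reproducing the study conditions
  (pairwise Δxy ≤ 180 μm, Δz ≤ 50 μm; baseline p_E = 0.42, p_C = 0.20;
  logistic distance decay; optional triadic-closure, transitive-closure and
  downward-orientation biases) for calibration and power analysis.

## Worked example

```r
library(mlinet)

geo <- generate_geometry(60, cells_per_set = c(3, 4), seed = 42)
dat <- wire(geo, "structured", clustering_bias = 0.25,
            transitivity_bias = 0.25, seed = 43)

pair_probabilities(dat)
#> Pair statistics over 279 tested pairs:
#>   p_E = 0.466   p_C = 0.228   p(>=1 chemical) = 0.412
#>                  category count probability
#>                      none    86      0.3082
#>           electrical_only    78      0.2796
#>             chemical_only    56      0.2007
#>                      dual    47      0.1685
#>             bidirectional     7      0.0251
#>  bidirectional_electrical     5      0.0179

nm <- fit_null_model(dat, "uniform", p_e = 0.42, p_c = 0.20)
mt <- motif_ratio_test(dat, nm, "chemical", n_samples = 1999, seed = 44,
                       alternative = "greater")
mt$groups
#>        group observed predicted frequency      p
#>   transitive       17    0.0309    0.1069 0.0005
#> intransitive       21    0.1667    0.1321 0.8625

mt$census[mt$census$name == "feedforward",
          c("name", "observed", "predicted", "ratio", "p")]
#>          name observed predicted ratio     p
#>   feedforward       14    0.0247  3.57 0.001

mean_coefficients(dat, "electrical")
#> Subnetwork clustering (electrical): mean C = 0.4414 (n = 29),
#>   mean AC = 0.2564 (n = 47)
```

The structured generator plants triadic closure in both networks; the
census detects it: transitive chemical patterns occur at 3–4 times the
frequency expected under independent wiring at the same rates (ratio 3.57
for the feedforward motif, one-sided Monte Carlo p = 0.001 over 1999
samples), while the intransitive group is not elevated. The electrical
mean clustering coefficient (0.44 over the 29 measurable subnetworks)
likewise exceeds the independent-wiring expectation p/(3−2p) ≈ 0.19.

A thin command-line front end wraps the same functions:

```sh
inst/cli/mlinet simulate --out-dir data --seed 1
inst/cli/mlinet census --cells data/cells.csv --pairs data/pairs.csv --null uniform
```

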