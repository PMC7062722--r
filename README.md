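# edgetic

Edgetic perturbation analysis of condition-specific protein-protein
interaction networks (PPINs) in R.

## What it does, and for whom

Tumorigenesis rewires the interactome in two ways: genes are silenced or
activated, removing or adding whole proteins, and genes switch their
dominant isoform, changing the protein-domain content that physically
mediates binding. Given a global PPIN, gene → transcript → domain
annotations, a domain-domain interaction (DDI) map, and paired
healthy/tumor transcript expression for a patient cohort, `edgetic`
builds each sample's condition-specific network at isoform/domain
resolution and compares the pairs into *edgetic perturbation profiles* —
the specific interactions gained or lost in each patient's tumor. It is
aimed at computational biologists studying network rewiring across cancer
cohorts who want a tested, fully scriptable pipeline with a synthetic
ground-truth generator for validation.

The core objects and conventions:

* **Edge codes** per patient: `10` lost (healthy only), `01` gained
  (tumor only), `11` kept, and `00` at cohort level for edges a patient
  never had. Per cohort, each edge gets `PercGained`/`PercLost` (the
  percentage of patients perturbed) and strict flags (perturbed in every
  patient).
* **Retention rule**: an edge survives contextualization when both genes
  are expressed (two-component Gaussian mixture on pooled
  `log2(abundance+1)`, transcript cut at RSEM ≥ 0.1) and, where DDI
  evidence exists for the pair at all, some DDI pair links the two major
  isoforms' domain sets; pairs with no possible DDI support fall back to
  co-expression.
* **Node rewiring score** = perturbed incident edges / merged-network
  degree; flagged rewired at ≥ 0.5 with degree ≥ 2.
* **Greedy ranking**: each perturbed edge is credited to exactly one
  protein (itself or a first neighbor, strongest claimant first), so
  ranks sum to the number of perturbed edges.
* **Scope**: perturbations reaching ≥ 2 patients in one cohort are
  cancer-specific, in ≥ 2 cohorts multi-cancer, otherwise
  patient-specific.
* **Cluster support**: cohorts are clustered (Ward.D2, Euclidean) on
  binary perturbation signatures, with multiscale-bootstrap AU and plain
  bootstrap BP support per cluster
  (`qnorm(1 - BP_r) = v√r + c/√r`, `AU = 1 - pnorm(v - c)`).

## Worked example

A zero-noise synthetic cohort with planted events, analyzed end to end:

```r
library(edgetic)
spec <- synthetic_spec(noise_sd = 0, dropout_rate = 0, seed = 7)
g    <- simulate_global(spec)     # network + annotations + DDI + design
co   <- simulate_cohort(g, spec)  # paired expression + truth table
an   <- analyze_cohort(g$network, g$annotations, g$ddi, co$expr)
an
#> Cohort analysis [C1]: 20 patients, 270 profile edges (14 ever gained, 46 ever lost)
#> Paired size test [C1] : n = 20 , mean healthy = 256 , mean tumor = 224 ,
#>   W = 210 , p = 1.907e-06 (exact)

head(an$stats[, c("key", "n_lost", "perc_lost", "strict_loss")], 3)
#>           key n_lost perc_lost strict_loss
#> 1 G0002|G0016     20       100        TRUE
#> 2 G0002|G0169     20       100        TRUE
#> 3 G0003|G0014     20       100        TRUE

table(an$causes$cause) / length(an$profiles)
#>     expression isoform_switch
#>             48             12
```

The cohort carries 20 patients; the tumor networks are significantly
smaller than their paired healthy networks (mean 224 vs 256 edges, exact
signed-rank p ≈ 1.9e-06), every planted perturbation is strict
(perturbed in 100% of patients), and per patient 48 perturbations trace
to expression changes and 12 to isoform switches — exactly the planted
design (10 silenced + 5 activated genes, 5 isoform switches). The
built-in `toy9_network()` and `isoform_switch_example()` fixtures
demonstrate the ranking and the domain-gain mechanism on paper-and-pencil
scale; see the vignette in `vignettes/edgetic-methods.Rmd` for the full
model description.

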