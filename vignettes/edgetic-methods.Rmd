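---
title: "Edgetic perturbation analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edgetic perturbation analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgetic)
```

## The problem

Tumors rewire the protein-protein interaction network (PPIN) in two ways:
genes are switched on or off, adding or removing whole proteins from the
interactome, and genes change their dominantly expressed isoform, which can
add or remove the protein domains that physically mediate binding. Comparing
a patient's healthy-tissue interactome with the paired tumor interactome
exposes these *edgetic perturbations* — specific interactions gained or
lost in the tumor — which are candidate biomarkers and therapy targets.

`edgetic` implements this comparison end to end: it contextualizes a global
PPIN to each sample of a paired cohort at isoform/domain resolution, diffs
the pairs into perturbation profiles, aggregates and classifies the
perturbations, scores rewired nodes, tests statistical associations,
clusters cohorts by their perturbation signatures with bootstrap support,
and ships a synthetic-cohort generator with complete ground truth so every
stage is testable without external data.

## Contextualization model

A sample's condition-specific network is the subgraph of the global PPIN
retained by the following rule.

**Gene expression calls.** Gene-level abundance is the sum of the gene's
transcript values (RSEM-like units). One two-component Gaussian mixture is
fitted by EM to the pooled `log2(abundance + 1)` values of the whole cohort
matrix — one fit per dataset, separating transcriptional noise from real
expression. A gene is *expressed* in a sample when the posterior of the
higher-mean component exceeds `gmm_posterior_cut` (default 0.5). The EM is
deterministic: means start at the 25th/75th percentiles, equal weights,
convergence at `gmm_tol = 1e-6` on the log-likelihood or after
`gmm_max_iter = 200` iterations. When the fit is unavailable (< 20
gene-by-sample cells) or degenerate (means closer than half the larger
standard deviation, or a component weight below 0.01), calling falls back
to a plain abundance floor `gmm_floor` (default 1.0).

**Transcript cut.** An isoform counts as expressed when its own value is at
least `transcript_min_expr = 0.1`, inclusive, *and* its gene is called
expressed.

**Major isoform.** The domain content of a gene in a sample is that of its
*major* transcript: the expressed isoform with the highest value, ties
broken by the lexicographically smallest transcript id. If a gene is called
expressed but no isoform reaches the cut, the highest-value isoform is
taken. The alternative — averaging domain content over expressed isoforms —
is not well defined for a discrete domain set, and the isoform-switch
mechanism (a *switch* of the dominant transcript changing the domain
content) presumes a single dominant isoform per condition; we therefore
commit to the major-isoform rule and document it rather than assert it as
the only possible reading.

**Edge retention.** An edge survives when both endpoint genes are
expressed and, *if* domain-domain interaction (DDI) evidence exists for the
pair at all (some DDI pair links the unions of domains over all transcripts
of the two genes), some DDI pair links the two current major-isoform domain
sets. Pairs that could never be DDI-supported are retained on co-expression
alone (`no_ddi_evidence_fallback`), so domain-sparse annotations do not
erase the network.

A consequence worth knowing: retention is *not* monotone in the DDI map.
Adding a pair can create evidence for an edge that was previously retained
by the fallback while its current major isoforms do not link, removing that
edge. The tests assert the true restricted properties (pairs over
unannotated domains are inert; a pair linking an edge's current major
domains guarantees that edge).

## Perturbation profiles and statistics

Each patient's healthy and tumor networks are diffed into codes: `10`
lost (healthy only), `01` gained (tumor only), `11` kept. A cohort profile
stacks the patients over the union of their edges, filling `00` where an
edge was absent from both of a patient's networks. Per edge the package
reports the counts and percentages of patients with each code
(`perc_gained`, `perc_lost`) and strict flags (perturbed in every
patient).

Scope classification: a perturbed (edge, direction) *counts* in a cohort
when perturbed in at least `min_patients = 2` patients there (configurable;
applied within each cohort). Counting in two or more cohorts makes it
*multi-cancer*, exactly one *cancer-specific*, never reaching the
threshold *patient-specific*. Gains and losses are tracked separately
end to end; an edge gained in some patients and lost in others of the same
cohort contributes to both directional tallies.

Cause attribution is a two-way split: if either endpoint changed its
expressed state between conditions the perturbation is an `expression`
event (a silenced gene trivially changes its major transcript, so
expression change takes precedence); otherwise both endpoints stayed
expressed and it is an `isoform_switch`, with the switched endpoints being
those whose major transcript changed — possibly both.

## Node scores and ranking

The *rewiring score* of a node is the fraction of its incident edges in
the merged healthy-union-tumor network that are perturbed; a node is
flagged rewired at score >= 0.5 with merged degree >= 2 (a single perturbed
edge on a two-partner node scores exactly 0.5).

The *greedy neighbor-inclusive ranking* credits each perturbed edge to
exactly one protein. Eligible nodes (degree >= 2, at least one perturbed
incident edge) are processed in order of incident perturbed edges, then
neighborhood perturbed edges, then id; each claims all unclaimed perturbed
edges incident to itself or a neighbor, its rank being the number claimed.
An edge covered by no eligible node — possible only in degenerate
geometries such as an isolated perturbed edge between two degree-1 nodes —
is credited to its stronger endpoint so attribution always partitions the
perturbed set. Nodes touching perturbations but claiming nothing keep a
participation rank of 1. On the built-in nine-edge toy network with edges
b-c, c-d, d-e perturbed this yields rank 3 for node c and rank 1 for b, d
and e.

## Statistical tests

**SMG association.** Edges are classed as first neighbors (an endpoint is
a significantly mutated gene), second neighbors (an endpoint adjacent to an
SMG) or independent. The enrichment test compares the fraction of
perturbed edges among SMG-touching edges against edges touching a
degree-matched random non-SMG set (degree within 10%, nearest degree as
deterministic fallback, sampling without replacement), with a Pearson
chi-squared test without continuity correction on the 2x2 table. Because
the matched set is random the draw is repeated (default 100 times) and the
median p with all replicates is reported; a zero table margin flags the
replicate degenerate with p = 1.

**Paired network sizes.** The two-sided Wilcoxon signed-rank test compares
paired healthy/tumor PPIN sizes. Zero differences are dropped; with up to
25 informative pairs the p-value comes from the exact distribution of the
rank sum over all sign assignments, *conditional on the observed midranks*,
so ties are handled exactly (network sizes are integers and tie-heavy);
beyond that a normal approximation with tie-corrected variance is used.
The exact path is validated against full enumeration and against
`wilcox.test` in tie-free cases, and its type-I error at the 5% level is
checked by simulation.

## Clustering with multiscale bootstrap support

Cohorts are clustered on a binary feature matrix: one column per
(edge, direction) that is a cancer-type perturbation (>= `min_patients`)
in at least one cohort; gains and losses can be used separately or
concatenated. Binary presence was chosen over percentage values because
the downstream support and importance machinery is defined on recoverable
set memberships; the threshold is configurable.

Agglomeration uses the Ward.D2 criterion on Euclidean distances, written
in-package with a deterministic tie-break (merge the minimal-distance pair
whose smallest member labels sort first) so results are invariant to row
order; it is verified against `stats::hclust` and a brute-force
agglomeration oracle in the tests.

Cluster uncertainty follows the multiscale bootstrap: at scales r = 0.5 to
1.4 (ten values), B replicates resample `ceiling(n_features * r)` columns
with replacement and recluster; a cluster is recovered when an identical
membership set appears. Per-scale recovery frequencies are probit
transformed and fitted by weighted least squares as
`qnorm(1 - BP_r) = v * sqrt(r) + c / sqrt(r)`, giving the approximately
unbiased p-value `AU = 1 - pnorm(v - c)` and the plain bootstrap
probability BP at scale 1. Frequencies are clipped to
`[1/(2B), 1 - 1/(2B)]`; only informative scales (frequency strictly
between 0 and 1) constrain the fit — a cluster recovered always (or never)
at nearly every scale carries no curvature information, so its AU falls
back to the plain recovery frequency at scale 1 with a `degenerate_fit`
flag, and the root is 1 by construction. Clusters with AU >= 0.95 are
conventionally selected; their defining features are reported both
exclusively (1 for all members, 0 outside) and inclusively (1 for all
members).

Feature importance ranks the perturbation features by permutation: a
bagged-trees classifier (a random forest with `mtry` equal to the number
of features) predicts the cluster labels, and each feature's importance is
the mean drop in whole-sample prediction accuracy over within-column
permutations (default 50). With the handful of objects these matrices
have, out-of-bag estimates are too noisy to rank on, hence whole-sample
accuracy; constant features score exactly 0 and ties rank by feature id.

## Degree-preserving randomization

Null networks come from repeated double-edge swaps: two random edges
(a,b), (c,d) are replaced by (a,d), (c,b) — orientation chosen uniformly —
whenever neither new edge is a self-loop or already present. The default
`"auto"` target of 10 |E| successful swaps follows the usual
edge-switching practice (bounds of order |E| log(1/eps) appear in the
literature); an attempt budget of 100x the target guards against rigid
graphs (a triangle admits no valid swap and is returned unchanged, with a
warning and a flag rather than an error). Degrees and the node set are
preserved exactly for every seed.

## The synthetic-data generator

`simulate_global()` + `simulate_cohort()` emulate what the pipeline needs
from a real cohort: a scale-free (preferential attachment) or uniform
interaction graph; 1-3 isoforms per gene with background domain content;
paired healthy/tumor samples per patient with log-normal abundance
(`meanlog log(100)`, `sdlog 0.5` — a clear two-component separation from
the off state of ~0.03, as the expression-calling step presumes); the
designated major isoform dominant at least 4-fold so major-isoform
selection stays unambiguous under moderate noise; planted events (gene
silencing, activation, isoform switches), per-cell multiplicative
log-noise and dropout. Defaults are the planted-recovery study conditions
(200 genes, 600 edges, 20 patients, 10 silenced / 5 activated / 5
switches) with mild noise (`noise_sd = 0.1`, `dropout_rate = 0.02`);
recovery checks set both to zero.

DDI support is planted through gene-private *anchor domains*: `AM.<gene>`
on the healthy-major isoform of both endpoints of a supported edge, and
for each switch gene one designated incident "gain" edge supported via
`AS.<gene>` carried only by the switch-target isoform. Shared background
domains carry no DDI pairs. This guarantees that DDI evidence holds on
exactly the supported and gain edges (asserted in the tests) and that
planted events have precisely the intended edgetic consequences: a switch
loses the edges anchored to its old isoform and gains its designated
edge, silencing removes all incident retained edges, activation adds
them.

The ground-truth table applies the package's own retention rule to the
planted on/off and major-isoform states — it is an *internal-consistency*
oracle: it proves the pipeline recovers what was planted, not that the
retention rule matches any external tool. Correctness of the rule itself
is established separately by brute-force oracle equivalence on random
instances. `simulate_multicancer()` arranges cohorts into groups with
shared (multi-cancer), group-level and private silencing events and emits
the expected feature design matrix; group events are silencings only,
which keeps the design matrix derivable by hand while the single-cohort
machinery exercises gains.

What the generator does **not** emulate: library-size and batch effects,
tumor purity, integer read-count noise, correlated co-expression
structure, or realistic domain-family reuse across genes. Passing the
planted-recovery tests therefore demonstrates the pipeline's internal
correctness on idealized inputs, not robustness to every artefact of real
RNA-seq data.

## Problem sizes and determinism

The shipped test-suite and acceptance checks run at desk scale: 200-gene /
600-edge cohorts with 20 patients for recovery, 210 random oracle
instances of up to 50 nodes, 1000 null simulations for calibration, and a
2-group x 3-cohort design with B = 1000 bootstrap replicates over ten
scales for cluster support. Every stochastic step takes an explicit seed
(all randomness flows through R's RNG), and byte-order (C-locale) string
comparison is used for all canonical orderings, so identical inputs and
seeds give identical outputs across machines and locales.

## A short worked example

```{r example}
fx <- isoform_switch_example()
nets <- contextualize_cohort(fx$network, fx$annotations, fx$ddi, fx$expr)
profile <- diff_networks(nets[["S_H"]], nets[["S_T"]])
profile$codes
attribute_profile_causes(profile, "S_H", "S_T", fx$expr,
                         attr(nets, "calls"), fx$annotations)
```

Both edges of the fixture are gained in the tumor sample and attributed to
the isoform switch in DST — the switch-target isoform carries the domain
that the partners' domains interact with.

## Known limitations

* The expression-calling mixture is fitted on pooled cells of one cohort
  matrix; very small or homogeneous matrices fall back to the abundance
  floor, which is a blunt instrument.
* The greedy ranking is a deterministic resolution of an intrinsically
  under-specified exclusive-attribution idea; alternative orderings give
  different (equally defensible) credit assignments away from the
  documented toy behavior.
* AU p-values inherit the usual multiscale-bootstrap caveats: with few
  objects the set of distinct clusterings is small and support values are
  coarse; degenerate (always/never recovered) clusters carry no curvature
  information and are reported by their plain recovery frequency.
* The SMG enrichment test conditions on the observed network and
  perturbation calls; it does not propagate uncertainty from the
  contextualization step.
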