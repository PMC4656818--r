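---
title: "Methods and design notes for omicompare"
author: "omicompare authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for omicompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicompare)
```

omicompare implements a comparative case-versus-control multi-omics
workflow for small-replicate designs: Z-ratio differential expression on
intensity arrays, signed Venn partitioning, hypergeometric pathway
over-representation, 4-plex iTRAQ reporter-ion quantification and
latent-semantic-indexing (LSI) literature scoring. This vignette explains
the models, the tunable parameters, the numerical conventions the tests
pin down, and what the synthetic-data generators do and do not emulate.

## The Z-ratio model

Raw intensities are assumed strictly positive and approximately
log10-normal per array. The pipeline applies, in order:

1. **Global normalization** — each array (column) is rescaled so its total
   intensity equals the mean of all array totals. Only a scalar per column
   is applied, so within-array structure is untouched. An array with zero
   total is an error naming the sample.
2. **Log10 Z-scoring** — intensities below a floor (default 1.0, in raw
   intensity units; zeros would otherwise reach the log) are clipped, then
   each column of log10 values is standardized. The *population* standard
   deviation (divide by $n$) is used per array; this is a documented
   constant of the implementation. The convention is cosmetic downstream:
   both the Z-ratio and the Z-test are invariant to a common per-column
   scale factor.
3. **Z-ratio** — per gene, $d_g = \bar z_A(g) - \bar z_B(g)$ (group means
   over replicate arrays; the mean, not the median, defines the group
   summary), and $\mathrm{Zratio}_g = d_g / \mathrm{SD}(d)$ where
   $\mathrm{SD}$ is the *sample* (n−1) standard deviation of $d$ across
   genes. The returned vector therefore has unit standard deviation: a
   gene's change is measured in units of the standard deviation of the
   average change of all genes. If every $d_g$ is identical (degenerate
   zero-spread case) the function returns zeros instead of dividing by
   zero. Swapping the groups negates every value exactly.
4. **Z-test** — per gene, $T = (\bar z_A - \bar z_B) /
   \sqrt{s_A^2/n_A + s_B^2/n_B}$ with sample variances, two-sided. The
   default reference is the standard normal — the classical Z-test whose
   thresholds (p < 0.05) this workflow historically uses. With only three
   replicates per group that reference is knowingly anti-conservative:
   under a homoskedastic normal null and equal group sizes the statistic
   is exactly Student-t with $n_A + n_B - 2 = 4$ degrees of freedom, so
   normal-referenced p-values pile up near zero
   ($P(p \le 0.05) \approx 0.12$) and are not uniform. `zTest(ref = "t")`
   provides the exact small-sample reference; the package's null
   calibration checks use it, while the default pipeline keeps the
   classical normal reference for parity with the published threshold
   convention. Users testing at three replicates should prefer
   `ref = "t"` when calibrated p-values matter.
5. **FDR** — Benjamini–Hochberg step-up, a thin validated wrapper over
   `stats::p.adjust`, pinned in the tests against a brute-force step-up
   oracle.
6. **Calling** — default rule: (|Z-ratio| ≥ 1.5 **or** p < 0.05) **and**
   q < 0.05. The disjunctive reading of the first two gates mirrors the
   usual "and/or" phrasing of this workflow; all three gates are
   independently switchable (`useZRatio`, `useP`, `useFdr`), so
   conjunctive variants are one flag away. Calls are `up`/`down` by the
   Z-ratio sign, `ns` otherwise.

## Signed Venn partitioning

Each input is a labelled set of identifiers with polarity ±1. Every
identifier in the union is assigned to exactly one region keyed by the
containing sets and the polarity pattern (e.g. `hip+&ctx-`). Categories:
`co_up`/`co_down` when all containing sets agree, `contra` when **any
pair** of containing sets disagrees (the natural generalization beyond two
sets), `unique_up`/`unique_down` for single-set identifiers. The partition
property (disjoint regions covering the union) is enforced by the class
validity and property-tested on random inputs.

Cross-omics reconciliation matches transcript and protein symbols
case-insensitively, with no alias or ortholog mapping — matching is by
symbol equality only, as done when comparing such lists by inspection. If
case-folding would merge two distinct identifiers within one layer, the
function stops rather than guess. Shared symbols are annotated concordant
or discordant by polarity agreement.

## Pathway over-representation

For a gene list of size $n$ drawn from an $N$-gene universe and a pathway
with $K$ members of which $O$ appear in the list: $E = nK/N$, $R = O/E$,
and $p = P(X \ge O)$ for hypergeometric $X$. Conventions:

- pathways must be *populated by at least 2* list members to be reported
  (`minMembers = 2`), and significance additionally requires $R > 1$ and
  $p < 0.05$;
- **no multiple-testing correction across pathways by default** — raw
  hypergeometric p-values are reported, mirroring the workflow this
  implements; `adjust = TRUE` adds a BH column and gates the flag on it;
- the **universe** is the measured background restricted to the
  annotation, set at collection construction (membership is intersected
  with the universe); identifiers in the query list but outside the
  universe are dropped with a warning. A whole-genome background would
  inflate enrichment and is deliberately not the default.

The polarity score of a pathway is $100\,U/(U+D) - 100\,D/(U+D)$ with $U$
and $D$ counted among pathway members present in the up/down lists. The
denominator is the *populated* membership, not the full pathway size, so
the score spans the full ±100 range; a pathway with no populated member
scores 0. Bimodal classification crosses two enrichment runs (up-only and
down-only lists against the same universe): significant in both ⇒
`bimodal`.

## iTRAQ quantification

The design pools two control samples into channels 114 and 115 and two
case samples into 116 and 117. Per peptide: $r_{ctrl} = i_{114}/i_{115}$,
$r_{116} = i_{116}/\mathrm{mean}(i_{114}, i_{115})$, likewise $r_{117}$ —
the case channel over the mean of the two control channels, which keeps
the case ratios invariant under swapping the control labels while
$r_{ctrl} \mapsto 1/r_{ctrl}$. Peptides with a zero denominator are
skipped (and logged); the protein-level value is the **median** over
usable peptides — robust, order-invariant, and agnostic to the unknown
roll-up used by commercial pipelines. `minPeptides` defaults to 1, so
proteins quantified from a single compliant spectrum are kept.

QC: a protein passes only when $0.8 < r_{ctrl} < 1.2$ with *strict*
inequalities — a ratio of exactly 0.8 or 1.2 fails. The (0.8, 1.2) gate is
asymmetric on a ratio scale (0.8 ≠ 1/1.2); the implementation asserts the
documented limits as given rather than symmetrizing them. Failing
proteins stay in the table for the QC report but are never called.

Differential calling, default mode `"any"`: `up` if either case ratio
exceeds 1.2, `down` if either falls below 0.8; if one channel is above 1.2
while the other is below 0.8 the evidence is contradictory and the protein
is left `unchanged` with `conflict = TRUE`. Mode `"both"` requires the two
case channels concordantly outside the same limit — a stricter reading in
which the two case channels must co-identify the change; both behaviors
are first-class because the underlying convention is genuinely ambiguous.

## LSI literature scoring

The term–document matrix over per-gene documents uses **log-entropy
weighting**: local $\log(1 + tf)$, global
$1 + \sum_j p_{ij}\log p_{ij} / \log n$ — the scheme of the classical
gene-literature indexing lineage. A term spread uniformly over all
documents is muted (weight 0); a term confined to one document gets
weight 1. Truncated SVD gives the latent space; documents are represented
as rows of $V_k \Sigma_k$, so at full rank latent document–document
cosines equal raw weighted cosines exactly (pinned at 1e−6 in the tests).
Queries are folded in through the term basis ($U_k^\top q$) with the
stored global weights.

Thresholds: cosine > 0.2 ⇒ explicit, 0.1–0.2 ⇒ implicit, else none; the
boundary value 0.2 itself classes as implicit (explicit is a strict
inequality). A query with no in-vocabulary token scores every gene 0 with
a warning. Multiple interrogation terms are scored as separate per-term
queries, not one joint query. The default rank is `min(300, rank)` — at
that size the decomposition is effectively full-rank for toy corpora, so
implicit (co-occurrence-only) structure only emerges when the caller
truncates; for corpora of tens of documents a rank of about half the
number of documents exposes it, and the package's own recovery checks use
`k = ceiling(nDocs / 2)`.

Word-cloud scoring reproduces the *interface* of noun-phrase dismantling:
phrases are split on whitespace and hyphens, lowercased, punctuation
stripped (idempotent, property-tested); the per-word z-score standardizes
occurrence counts within a dataset, and the optional cosine column anchors
each word's term vector against the latent centroid of a document set.
The exact scoring of the proprietary tools this mirrors is unpublished;
the definitions here are documented and testable replacements, not
re-implementations.

## What the generators emulate — and what they do not

`simulateExpressionStudy` draws per-gene log10 baselines
$\mathcal N(2.5, 0.5)$ with homoskedastic array noise (sd 0.2 in log10
units) for 3 + 3 arrays of one tissue — the three-animals-per-group,
two-genotype design. Planted genes (default 5%) are shifted in the case
group by `effect` standardized units (the log10 shift is `effect` times
$\sqrt{0.5^2 + 0.2^2}$), half up/half down with ties to up;
`plantedGenes` lets two tissue simulations share one coherent signal.
Under the null the per-gene mean-z differences are i.i.d. normal across
genes, so the |Z-ratio| ≥ 1.5 tail matches $2(1 - \Phi(1.5)) = 0.1336$ —
the package's calibration anchor. Not emulated: probe-level effects,
heteroskedastic (intensity-dependent) variance, correlated genes, batch
effects. Passing recovery tests therefore demonstrates correctness of the
statistics, not robustness to real-array artifacts.

`simulateItraqExperiment` draws protein abundances log-normally
(median 1e4, sdlog 0.5), spreads peptides with a shared
ionization-efficiency factor (sdlog 0.8) that cancels in every ratio, and
perturbs each channel with multiplicative noise of the given CV (default
5%, a tight pooled-control setting); planted proteins multiply channels
116/117 by `fold`. With CV = 0 every ratio is exactly 1 — the noiseless
null the tests assert. Not emulated: spectral interference, missing
channels, shared peptides between proteins.

`simulatePathwayAnnotation` gives planted pathways an inclusion rate for
differential genes of `enrichmentFactor` times the background rate
$s/N$ — so planted $R > 1$ holds by construction; sizes vary uniformly
in 10–50.

`simulateLiteratureCorpus` organizes vocabulary into per-keyword context
terms, per-keyword reference documents (keyword + context), and a handful
of shared background *topics* from which every gene draws filler. The
composition (explicit: 2 keyword + 6 context + 4 topic tokens; implicit:
3 context + 9 topic; unlinked: 12 topic) was fixed once so that, after
log-entropy weighting and moderate truncation, explicit links score well
above 0.2 and implicit links land around the 0.1–0.2 band, while unlinked
genes — sharing no term with any keyword context — stay near 0. Topic
sharing (rather than per-gene private filler) is what keeps document norms
stable under truncation and makes the implicit scores graded rather than
0/1. Not emulated: polysemy, real abstract length distributions,
citation structure.

All generators consume their seed in a local RNG scope (the caller's
random stream is untouched) and record it in the returned truth object.

## Problem sizes and determinism

The packaged checks run the null calibration at 2000 genes × (3 + 3)
arrays, recovery at 1000 genes, iTRAQ at 200 proteins × 3 peptides, and
LSI recovery across 20 corpora of 20 genes — sizes at which every
statistical property under test is well-resolved while the whole suite
runs in seconds. The pipeline (`runFullAnalysis`) is deterministic given
seed and configuration: reruns produce bit-identical outputs, verified by
MD5 checksums recorded in the manifest.

## Known limitations

- The normal-referenced Z-test is anti-conservative at the default
  three-replicate design (see above); the FDR gate downstream absorbs much
  of this in practice, and `ref = "t"` is exact, but published-convention
  defaults are what they are.
- A two-factor (e.g. age × genotype) analysis is out of scope; the
  pipeline models exactly one case/control contrast per tissue.
- Enrichment reports raw hypergeometric p-values by default; with many
  pathways the BH option should be used.
- Cross-omics matching is symbol-equality only; identifier drift between
  platforms must be resolved upstream.
- The LSI module scores association strength; it does not reproduce any
  proprietary corpus or its exact scores.
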