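---
title: "Methods: paired CCGG-fragment methylome analysis with helpdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired CCGG-fragment methylome analysis with helpdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helpdm)
```

## Scope and model

`helpdm` analyses restriction-enzyme methylome profiles of paired tumor
(T) and adjacent non-tumor (NT) tissue. The measurement unit is the CCGG
fragment: a genomic interval bounded at both ends by an MspI/HpaII
recognition site, retained when its length falls in the 200–2000 bp size
selection window. Methylation is carried as a normalized per-fragment
score (a log-ratio of methylation-insensitive to methylation-sensitive
digests); the package starts from that normalized score matrix and makes
no attempt to model array probe effects or normalization.

The inferential backbone is deliberately plain:

* per fragment, a **paired t-test** of T vs NT across subjects, on the
  per-subject differences `d = T − NT`; the mean difference is the
  fragment's *delta*. By the assay's sign convention, **negative delta
  means hypermethylated in tumor**.
* **Benjamini–Hochberg step-up FDR** adjustment across fragments;
  significance means adjusted p (`q`) below `alpha` (default 0.05).
* direction (`hyper`/`hypo`) from the sign of delta at `q < alpha`, and a
  magnitude class from `|delta|`: negligible `[0, 0.5)`, small
  `[0.5, 1)`, moderate/large `[1, ∞)` (band edges assigned upward).

No moderated-variance (empirical-Bayes) testing is used: pairing plus a
per-feature t statistic is the method being reproduced, and the
synthetic-data suites test exactly that engine.

## Genomic compartments

Every fragment receives exactly one compartment label with precedence
**PR > GB > IG**:

* **PR** (promoter): overlaps (≥ 1 bp) the 2000 bp immediately upstream
  of a gene's TSS;
* **GB** (gene body): otherwise overlaps a gene body, which by default
  runs from the TSS to the gene end (`gb_start_offset = 0`); an offset of
  2000 bp, which starts the body past the promoter-proximal zone, is
  available as a configuration knob because either reading of a
  TSS-anchored body definition is defensible and the choice is not
  resolvable from first principles;
* **IG** (intergenic): otherwise.

PR and GB labels carry the linked gene (nearest TSS to the fragment
midpoint among qualifying genes; gene id breaks ties). Promoter fragments
additionally receive a subcompartment: **CGI** when overlapping a CpG
island, **CGS** when overlapping a shore — by default the 2000 bp flank on
*both* sides of an island (standard usage), with an `upstream-only` mode
restricted to the lower-coordinate flank — and **other** otherwise; CGI
beats CGS on overlap. Overlap is always ≥ 1 bp, never midpoint
containment: fragments are up to 2 kb long and a midpoint rule would
discard genuine boundary overlaps.

Coordinates are 0-based half-open throughout; gene TSV input declared
1-based inclusive is converted on read. A − strand gene with `tss > tes`
occupies `[tes + 1, tss + 1)`, so mirroring coordinates maps one strand
exactly onto the other; the tests exploit this symmetry.

## Enrichment and categorical tests

Compartment over-representation of the significant (DM) set is tested by
the random-sampling permutation test: `B = 1000` draws of `|DM|` loci
without replacement from the annotated universe, with a one-sided
add-one-smoothed empirical p-value, `p = (1 + #{null ≥ obs}) / (B + 1)`.
Its resolution is `1/(B + 1)`, so a Gaussian approximation from the null
draws' mean and standard deviation is reported alongside for p-values far
below that resolution, labelled as an approximation; an exact
hypergeometric mode (the count's true null distribution under uniform
sampling) is available and anchors the Monte-Carlo mode in tests.
Categorical comparisons (direction × subcompartment grids) use the
Pearson chi-square test without continuity correction; expected counts
below 5 warn rather than refuse.

## DM × DE integration

Significant DM loci are merged with significantly differentially
expressed (DE) genes by location: a record is emitted when the locus lies
in the promoter window or gene body of a DE gene, under the same
annotation rules (IG loci never link). The canonical
methylation–expression relationships are:

| compartment | canonical categories |
|---|---|
| PR | HyperDown, HypoUp |
| GB | HyperUp, HypoDown |

every other sign combination is non-canonical and tabulated as `other`.
The counting unit is the locus: by default each locus keeps one record
(PR relations preferred, then nearest TSS, then gene id — `dedup =
"locus"`), with a `"pair"` mode retaining every (locus, gene) pair; totals
are conserved under both policies and the canonical fraction is reported
as a percentage rounded to one decimal. A locus qualifying as PR of one
gene and GB of another is a promoter record — the same precedence rule the
annotation uses, applied consistently across modules.

## The synthetic cohort generator

No public accession exists for the assay this package models, so the
generator is the canonical input source and is itself first-class, tested
code. It emulates:

* paired T/NT samples for `n_subjects` subjects (default 16, matching the
  adenocarcinoma-subset scale the recovery suites assume);
* non-overlapping genes packed onto chromosomes, with CpG islands created
  over a configurable fraction of promoters;
* fragment loci either placed directly (lengths uniform in 200–2000 bp at
  a configured density) or taken from an in-silico MspI digest of a
  seeded random genome;
* Gaussian scores: `NT = mu_i + b_s + eps`, `T = mu_i + delta_i + b_s +
  eps` with subject effect `b_s ~ N(0, subject_sd²)` and residual
  `eps ~ N(0, residual_sd²)`. The defaults `subject_sd = 0.2`,
  `residual_sd = 0.3` are the package's own choice of a plausible noise
  scale for normalized log-ratio scores — no published value exists for
  this quantity — and are the conditions under which the recovery suites
  state their guarantees;
* planted DM effects: |delta| drawn from a mixture over the magnitude
  bands `[0, 0.5)`, `[0.5, 1)`, `[1, 2]`, sign negative (hyper) with a
  compartment-specific probability;
* planted DE effects coupled to the methylome: every gene with a planted
  DM locus in its promoter or body couples to the *nearest* such locus
  and is differentially expressed — canonically with probability
  `canonical_coupling`, anti-canonically otherwise; uncoupled genes are
  background-DE at `de_rate` with random sign.

Two deliberate departures from fully independent per-locus planting are
worth spelling out, because they are what makes the end-to-end coupling
guarantee achievable at all:

1. **the sign of delta is drawn once per linked gene** (per locus only in
   intergenic space), and
2. **each gene deregulates in at most one compartment** — PR or GB, chosen
   with probability proportional to the compartment DM rates, with the
   within-compartment planting rate calibrated so the *marginal*
   per-locus DM rate equals `dm_rate_by_compartment` exactly (for PR + GB
   rates summing to ≤ 1; beyond that the marginals saturate and a warning
   is raised).

Both choices mirror the loco-regional concordance of methylation change
observed within genes in tumor tissue. They are also structurally
necessary: the canonical map inverts between PR and GB, so a gene with
planted DM in both compartments and a single expression direction would
*necessarily* produce records with contradictory canonical flags, and the
recovered canonical fraction could then never converge to the coupling
parameter regardless of sample size. With gene-coherent planting, the
recovered fraction converges to `canonical_coupling` up to the dilution
contributed by false-positive DM loci (which carry ~50% canonical
records; at `q < 0.05` this adds well under one percentage point).

Default rates (`dm_rate` 0.26/0.38/0.48, `hyper_given_dm` 0.31/0.25/0.06
for PR/GB/IG, `de_rate` 0.35, `canonical_coupling` 0.087) are set once to
the magnitudes reported for this assay class in lung tumors; they are
motivation, not test targets. What the generator does *not* emulate:
probe- and dye-level artefacts, spatially varying locus density, partial
digestion, cellular heterogeneity, or any dependence structure beyond the
gene-level coherence above — so passing recovery suites demonstrate
correctness of the inference machinery under the stated model, not
performance on real arrays.

## Classification and candidate ranking

The discrimination analysis repeats, `n_iterations = 10` times: split
*subjects* (never samples — a subject's T and NT always travel together)
2/3–1/3 into train and test; rank loci by the paired test on training
subjects only; select the top `k` (25 or 100) by q, ties by |delta| then
id; classify held-out samples with a **nearest-centroid** rule (T and NT
centroids over the selected loci, Euclidean distance, ties to NT).
Accuracy is reported both as the average of per-split accuracies and
pooled over all test samples, since either averaging convention is
defensible; sensitivity is tumor recall and specificity non-tumor recall.
Nearest-centroid is the minimal model consistent with building a
classifier from a locus panel; the model family underlying the published
accuracies is not stated anywhere, so no numeric agreement with them is
claimed, and the evaluation here is against planted synthetic truth
(separable cohorts near accuracy 1, null cohorts at chance).

Validation candidates are ranked by **loco-regional consistency**: a
significant locus scores the number of other significant loci on the same
chromosome, same compartment and same direction within a window
(edge-to-edge distance strictly below `window`, default 2000 bp — chosen
strictly so that a zero window always yields zero scores).

## Numerical and design choices

* Ranked outputs are fully deterministic: q ascending, |delta| descending,
  then id.
* Degenerate paired tests: all-zero differences give `t = 0, p = 1`;
  constant non-zero differences give `p = 0` flagged degenerate; fewer
  than two complete pairs skips the feature with a warning. Missing
  values are handled pairwise-complete with n recomputed.
* `bh_fdr` delegates to `stats::p.adjust(method = "BH")` and is tested
  against an exhaustive evaluation of the step-up definition.
* All generator stages derive their RNG streams from one seed by fixed
  offsets, so each stage is individually reproducible and a pipeline run
  is byte-identical under a repeated call.
* Simulation sizes in the tests and the acceptance script (thousands of
  loci, hundreds to a few thousand genes, 16–24 pairs, 20-seed averages)
  are chosen so each suite completes in seconds while keeping binomial
  3-SD bands tight enough to be informative.

## Known limitations

* One TSS/TES per gene; no transcript isoforms, no HpaII star activity or
  partial-digest modeling.
* The permutation test samples uniformly, with no GC- or length-matched
  strata.
* The integration is qualitative (direction × direction accounting); no
  quantitative DM–DE correlation model is fitted.
* Published genome-scale locus counts and classifier accuracies depend on
  raw arrays that were never deposited and are out of reach by design;
  the package's claims are the accounting identities and the synthetic
  recovery properties its tests compute.
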