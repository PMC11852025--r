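---
title: "Surface-proteome marker discovery for sexed bovine spermatozoa: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-proteome marker discovery for sexed bovine spermatozoa: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfmark)
library(dplyr)
```

## The problem

Immunological sperm sexing needs a protein that is specific to X- (or Y-)
chromosome-bearing spermatozoa and reachable by an antibody on the intact
cell. surfmark implements the computational arm of that search for cattle:
starting from label-free (LFQ) quantification of surface-biotinylated
proteins in unsexed (BU), X-sorted (BX) and Y-sorted (BY) sperm — with a
no-biotin negative control (BC) — it filters and imputes the intensity
matrix, tests for differential abundance, profiles per-condition detection,
integrates GO localization and membrane-topology predictions, and ranks
candidate markers. A seeded synthetic-data generator reproduces the
statistical structure of such an experiment so that every stage is testable
without the original instrument data.

## The intensity model and preprocessing

MaxQuant-style protein-groups tables carry one `LFQ intensity <sample>`
column per replicate; an intensity of zero means "not quantified" and is
treated as missing. Reverse-database decoys and contaminants are removed
first (a row flagged as both is counted once, under reverse). Intensities
are log2-transformed and replicates grouped by condition.

Two preprocessing rules follow standard label-free practice:

* **Valid-value filter.** A protein is retained iff some condition (the
  negative control excluded) holds at least `min_valid = 2` observed values.
  We read "at least one group" as *some condition with ≥ 2 valid values*;
  the alternative reading (every group) would discard any protein absent
  from one condition, destroying exactly the absence patterns the analysis
  is after.
* **Detection-limit imputation.** Missingness in surface proteomics is
  dominated by left-censoring: low-abundance proteins fall below instrument
  sensitivity (missing not at random). Missing cells of retained proteins
  are imputed per sample from a downshifted normal,
  $\mathcal{N}(\bar x_s - 1.8\,s_s,\ (0.3\,s_s)^2)$, where $\bar x_s$ and
  $s_s$ are the observed mean and SD of sample $s$. The 1.8/0.3 defaults
  are the widely used downshifted-normal parameters for left-censored LFQ
  data; both are exposed as arguments since no universal calibration
  exists. The control condition is excluded from both rules — it is
  all-missing by design and would otherwise absorb the filter.

Observed values are never modified; `observed` and `imputed` masks travel
with the long intensity tibble so that downstream stages can distinguish
measurement from imputation.

## Moderated differential testing

With three replicates per group, per-protein variance estimates are
unstable. For each contrast (BU–BX, BU–BY, BX–BY) we use an empirical-Bayes
moderated t: per-protein pooled variances $s_g^2$ (with $d_g = n_1+n_2-2$
degrees of freedom) are shrunk toward a prior $s_0^2$ with weight $d_0$,

$$\tilde s^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
  t = \frac{\Delta}{\tilde s\sqrt{1/n_1 + 1/n_2}},$$

referred to a t distribution with $d_g + d_0$ degrees of freedom. The prior
is estimated by moment matching on $\log s_g^2$: its mean and variance are
matched to those implied by the scaled-F marginal of sample variances under
a scaled-inverse-$\chi^2$ prior, inverting the trigamma function by Newton
iteration. When the empirical spread of $\log s_g^2$ does not exceed the
spread expected from sampling alone the prior degrees of freedom are
infinite and every variance shrinks to the mean sample variance. Moment
matching is closed-form and deterministic; the test suite verifies exact
agreement (to 10⁻¹⁰) with the reference empirical-Bayes implementation in
limma, and recovery of $(d_0, s_0^2)$ from simulated variances within
stated bounds in ≥ 90% of seeds.

Significance follows the study rule: BH-adjusted $p < 0.05$ (strict) and
$|\log_2\text{FC}| \ge 2$. We read the fold-change condition as a
threshold, not an equality, and the boundary $p_{\text{adj}} = \alpha$ as
non-significant. By default the test runs on the imputed matrix (the
convention of DEP-style workflows); `observed_only = TRUE` provides a
sensitivity analysis. Each contrast estimates its own prior from its two
groups' pooled variances — with a shared residual structure the estimates
coincide; an explicit `prior` argument lets users share one fit across
contrasts.

## Detection, sets and the heatmap

"Identified" is operationalized as *has an observed LFQ value*:
identification without quantification is not recoverable from a
protein-groups quantification table, so detection counts always come from
the observed mask and never from imputed cells (an invariant the tests
assert). From per-condition detection counts the package derives the
BU/BX/BY Venn partition, the exclusive sets (BX-only, BU-only, BX∩BU) and
the absence sets (absent-in-BX, absent-in-BY; absence is strict: zero
observed replicates).

The heatmap set unions significantly regulated proteins with those
completely absent in BX or BY. Rows are z-scored over observed-plus-imputed
cells and ordered by agglomerative hierarchical clustering with Euclidean
distance and average linkage — the metric/linkage choice is ours (the
convention is not fixed by the analysis it mirrors) and is deterministic
given the input order; never-quantified cells are exported as `NA` (gray in
the plot).

## GO interest and surface accessibility

Fourteen GO identifiers covering plasma membrane (PM), cell surface (CS),
external/anchored/integral membrane components (ESPM, ECESPM, ACPM, ACESPM,
ICESPM, ICPM), cell-wall/outer-membrane externals (ESCW, ESCOM) and
extracellular space (ES) are matched **literally** — no ontology traversal —
because the selection procedure is defined over these exact IDs;
GO:0005887, merged into GO:0005886 in newer ontology releases, is kept as a
separate entry for fidelity. Annotations from a UniProt-style and an
eggNOG-style source are unioned per protein after selecting one
representative ID per protein group (first reviewed majority ID, else the
first).

A protein is *of interest* when it hits any non-ES category; a protein
whose only hit is ES is of interest only if transmembrane, resolved when
topology is joined. It is *surface-accessible* when

1. it hits CS, ESPM, ECESPM, ACESPM, ICESPM, ESCW or ESCOM; or
2. it hits PM, ACPM or ICPM **and** is transmembrane or has an outside
   segment; or
3. it hits ES **and** is transmembrane.

Topology comes from 3line-format predictions (classes TM, SP+TM, GLOB, SP,
BETA, SP+BETA; per-residue codes S/I/O/M/B run-length-encoded into
segments). Transmembrane means a membrane-embedded class with ≥ 1 membrane
region; beta-barrel classes count as transmembrane (none occurred in the
motivating data, but the rule is stated once and kept symmetric). For
signal-peptide-only proteins the mature chain is typically labeled outside,
so SP proteins qualify under rule 2 when segments are available; without
segments, outside status is unknown and conservatively `FALSE`. A protein
with ES-only annotation and unknown topology is therefore not accessible.

Candidate tiers: **accessible** = surface-accessible, detected in ≥ 1
target-condition (BX) replicate and 0 opposite-condition (BY) replicates;
**prioritized** additionally requires ≥ 2 BX replicates and transmembrane
topology. The engine is symmetric (`direction = "BY"`) because nothing in
the rules is specific to X-sperm. Both rules are verified against
brute-force truth-table evaluators, exhaustively over all 2¹⁴ GO subsets
and over all category subsets × topology classes × replicate counts at the
factorized level.

## Enrichment and cross-species similarity

The overrepresentation statistic is generic: for each term of a background
annotation, fold enrichment = observed / expected sample count and a
two-sided Fisher exact p (hypergeometric sum of all tables no more probable
than observed, relative tolerance 10⁻⁷), Bonferroni-corrected over the
number of terms actually tested (not an ontology's size). The sum is
computed directly so it can be checked exactly against definitional
enumeration; two-sidedness matches the convention of the GO-analysis tools
it mirrors.

Cross-species similarity is percent identity from a global
Needleman–Wunsch alignment under an affine gap model (a length-$L$ gap
costs $10 + 0.5L$, BLOSUM62), computed in compiled code with deterministic
tie-breaking (match/mismatch over gap-in-query over gap-in-subject).
Per-segment similarity projects the query's outside segments through the
whole-sequence alignment; gap columns inside a segment count as
non-identical. Published similarity numbers from web alignment tools depend
on tool, matrix and isoform versions, so they are treated as indicative
rather than as test oracles; the aligner is instead validated against
exhaustive enumeration on short sequences and against the reference
pairwise aligner in Biostrings.

## The synthetic-data generator

`simulate_dataset()` emulates the study design: 4 conditions × 3
replicates, with log2 intensities from a hierarchical model — protein means
$\mathcal{N}(25, 2^2)$ (typical LFQ log2 scale), within-group variances
from a scaled-inverse-$\chi^2(d_0 = 4, s_0^2 = 0.25)$ prior, replicate
noise normal. A cell is missing with probability
$\mathrm{logit}^{-1}\!\big((L - x)/w\big)$ with detection limit $L = 22$
and softness $w = 1$, giving a realistic ~10–15% censoring rate in the
sexed conditions; the control condition is entirely missing (no biotin, no
signal). Contaminant and reverse rows are appended and flagged (4% each).
Twenty planted X-specific proteins get +4 log2 units in BX and a BY mean
set $8w$ below the detection limit, so they are absent in BY by
construction; five of them also carry a transmembrane topology and one GO
identifier of interest — these are the ground-truth marker candidates the
prioritized tier must recover. Background proteins carry decoy GO IDs,
with a 5% leak rate of interest IDs to exercise specificity. All values
were fixed once, as the generator's definition of the study conditions,
before being used in any test.

What the generator does **not** emulate: breed/batch structure (the real
samples pool bulls of several breeds per condition), cryopreservation
effects, correlated missingness between peptides of one protein, or
intensity-dependent variance. Passing tests therefore demonstrate that the
pipeline recovers planted structure under idealized MNAR censoring, not
that it is robust to those real-data complications.

Determinism: a single seed drives the whole generator through an isolated
RNG scope; the censoring uniforms are drawn after (and independently of)
the intensities, so lowering the detection limit under the same seed can
only unset missingness (a monotonicity the tests check by common random
numbers). Identical configurations give byte-identical files.

## Numerical and design choices

* Degenerate inputs: all-zero variances raise a degeneracy error; samples
  with < 2 observed values cannot anchor imputation and raise an error
  naming the sample; proteins missing topology are treated as
  globular-unknown with a warning, never dropped silently.
* Zero-SD heatmap rows are assigned z = 0 rather than NaN.
* Clustering ties: `hclust` average linkage with the canonical leaf order;
  identical rows merge at height 0 and are guaranteed adjacent.
* Fisher two-sidedness uses the standard $(1 + 10^{-7})$ relative tolerance
  when comparing table probabilities, matching `stats::fisher.test`.
* The alignment traceback prefers substitution over gap-in-query over
  gap-in-subject at equal score, making outputs reproducible across
  platforms; scores are compared with a 10⁻⁹ tolerance in the traceback to
  absorb floating-point association.
* Problem sizes in the test suite (500–5000 simulated proteins, 10–50
  seeds per property, exhaustive enumerations at category level and for
  tables with row margins ≤ 25, alignment enumeration for sequences up to
  length 6 over a 4-letter alphabet) were chosen to make every property
  check exact or tightly Monte-Carlo-bounded at desk scale.

## Worked example

```{r example, eval = FALSE}
library(surfmark)

# the bundled 19-candidate table through the rule engine
inp <- candidate_example_inputs()
calls <- call_targets(inp$profiles, inp$interest, inp$topo)
glance(calls)
selection_report(calls, inp$interest)

# a fully synthetic experiment, end to end
dir <- tempfile()
sim <- simulate_dataset(sim_config(seed = 1), dir = dir)
res <- run_pipeline(list(
  protein_groups = sim$paths[["protein_groups"]],
  uniprot = sim$paths[["uniprot"]],
  eggnog = sim$paths[["eggnog"]],
  topology = sim$paths[["topology"]],
  seed = 1
))
glance(res$results)
res$report %>% filter(tier == "prioritized")
```

## Known limitations

* The pipeline consumes prediction and annotation *outputs*; it never runs
  an orthology mapper, topology predictor or GO service itself.
* The valid-value filter and imputation operate on the quantification
  table; MaxLFQ normalization, match-between-runs and peptide-level
  aggregation are upstream concerns.
* The interest rule matches GO identifiers literally; datasets annotated
  against newer GO releases may need the (configurable) ID list extended.
* Percent identity is one of several "similarity" definitions; a
  positives-based definition would give systematically higher numbers.
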