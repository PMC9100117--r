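---
title: "Methods: differential protein expression from pooled isobaric-tag reporter ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential protein expression from pooled isobaric-tag reporter ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itraqdiff)
```

## The experimental design this package models

`itraqdiff` operationalizes a discovery workflow for small case-control
proteomics studies that pool their samples: all patients are combined into
one pool and all controls into another, and each pool is labeled with *two*
isobaric reporter tags ("parallel double labeling"). In the 4-plex layout
used throughout, channels 113 and 115 carry the patient pool and channels
114 and 116 the control pool. Every reporter value is referenced to the
113 patient channel, so the 113/113 ratio is identically 1 and the data
reduce to three informative ratios per peptide: 114/113, 116/113 (two
technical views of control vs patient) and 115/113 (a patient-vs-itself
technical replicate).

Pooling sacrifices biological replication; what remains is the *peptide*
dimension. A protein identified from many unique peptides contributes many
quasi-independent measurements of the same underlying channel ratios, and
the pipeline leans on exactly that.

## The two-step qualification and the data-derived threshold

The core statistic of the workflow is the **control/patient value ratio**
of a protein,

$$
\mathrm{cp} \;=\;
\frac{\tfrac{1}{|C|}\sum_{c \in C} r_c}{\tfrac{1}{|P'|}\sum_{p \in P'} r_p},
$$

where $r_c$ is the protein-level ratio-to-reference of channel $c$, $C$ is
the set of control channels and $P'$ the set of *non-reference* patient
channels. The reference channel is excluded from the patient mean because
its ratio is 1 by construction and would otherwise dilute the patient
value. With the default 4-plex, $\mathrm{cp} = \mathrm{mean}(r_{114},
r_{116}) / r_{115}$.

Rather than fixing an arbitrary fold-change cutoff, the threshold on
$\mathrm{cp}$ is derived from the data in two steps, applied to every
protein with **strictly more than** `min_peptides = 10` unique peptide
values:

1. **Comparability.** The peptide-ratio distributions of the two control
   channels are compared with Student's t (equal variance), Wilcoxon
   rank-sum and one-way ANOVA. Within each (method, comparison) family the
   p-values are Benjamini-Hochberg adjusted **across proteins**, and the
   per-protein summary `q_control` is the *minimum* q over methods --
   the conservative direction when the goal is to *assert* similarity.
   A protein passes when `q_control > alpha_comparable` (default 0.01).
2. **Difference.** The non-reference patient channel is compared against
   each control channel with the same methods; `q_diff` is the *maximum*
   q over methods and comparisons -- the conservative direction when the
   goal is to assert a difference. A protein passes when
   `q_diff < alpha_diff` (default 0.05).

The selection threshold is then the arithmetic mean of the qualifying
proteins' cp ratios, and the candidates are **all** proteins -- regardless
of peptide count -- whose cp ratio *strictly* exceeds it. Strictness
matters: on the packaged reference tables the threshold is 1.676 and the
smallest selected ratio is 1.680. Candidates are finally mapped to
reviewed SwissProt entries and deduplicated, keeping the maximum cp ratio
per canonical entry (ties broken by lexicographic source accession) and
recording every contributing accession. A `twofold` flag marks records
with at least one control channel ratio of 2.0 or more.

Both alpha levels are configuration keys. Neither is dictated by the data
alone: 0.01 for comparability sits strictly below every control q in the
packaged qualification table (minimum 0.02) and 0.05 for difference sits
strictly above every printed difference q (maximum 1.63e-2), so the
defaults reproduce the published 21-protein qualifying set. The min/max
reductions are configurable (`control_q_reduction`, `diff_q_reduction`).

### Numerical conventions

* Protein rollup is the **median** over unique peptides by default (mean by
  configuration). The upstream vendor statistic is not published; the
  median is the robust standard for reporter quantification and the choice
  is surfaced, not buried.
* Wilcoxon rank-sum p-values are exact when both groups have at most 25
  observations and the pooled sample is tie-free, otherwise a
  tie-corrected normal approximation with continuity correction is used
  (peptide ratios can tie after rounding). The standalone
  `mann_whitney_u()` used for blot validation switches at a combined
  n of 20, the usual convention for those very small samples.
* When both groups have zero variance, t/ANOVA p is 1 for equal means and
  0 otherwise; a fully tied pooled sample yields Wilcoxon p 1.
* Ratios are carried unrounded internally; rounding to three decimals
  happens only in reports.
* Rows with missing or non-positive channel values are dropped and
  counted, never imputed: the qualification operates on complete ratio
  vectors.

## Score tiers and interactome topology

Network-analysis relationship scores (0-100) produced by an external
machine-learning system are consumed as a table, never recomputed: the
scoring model is proprietary and only its published score-to-tier mapping
is implemented. Tiers are `very_strong` above 91, `strong` above 76 up to
91, `medium_strong` from 40 to 76, and `weak` below 40. The published
interval notation pins the integer boundaries (76 is medium-strong, 91 is
strong); for real-valued scores the half-open reading (76, 91] = strong is
adopted.

The topology layer answers a deliberately simple question on an
undirected gene graph: which candidates have *direct* edges to disease
effector genes (organized into pathophysiological motifs such as
"elevated cytosolic calcium levels" or "glycogenolysis blockade") or to
other candidates, and which are isolated? Membership of a candidate in an
effector set (containment) is reported separately from adjacency to one.
Gene matching is case-insensitive exact string matching; alias resolution
is out of scope because alias tables vary by database release. The
packaged interactome is built solely from the published interactor lists;
arbitrary SIF / edge-list imports are supported through the same reader,
and neighborhoods around the candidates can be exported as SIF and
GraphML for rendering elsewhere.

## Blot validation and cohort statistics

Western-blot band intensities are normalized per lane against the loading
control *before* technical replicates are averaged (the order matters for
ratios), and patient vs control levels are compared per protein with the
Mann-Whitney test. Stars follow the usual figure convention (`*` p < 0.05,
`**` p < 0.01, `***` p < 0.001) while the significance flag uses
p <= 0.05. Note that complete separation at 7 vs 6 samples gives an exact
p of 2/1716 = 0.00117 -- two stars, not three: no arrangement at these
sample sizes can reach p < 0.001, which is worth knowing before powering
a validation cohort.

Cohort demographics use a Pearson chi-square without continuity
correction on the 2x2 sex table and a Mann-Whitney comparison of ages.
The age SD uses the population divisor $n$ by default because that is the
convention the published summaries follow (the sample divisor is one
configuration switch away). The chi-square and Mann-Whitney *p*-values on
such small tables depend on conventions (correction, tie handling) that
published summaries rarely state, so the test surface here is the
percentages and moments, not those p-values.

## What the synthetic generator emulates -- and what it does not

`generate_dataset()` simulates the pooled double-labeling design
faithfully: both patient channels share one latent level (they are the
same pool under two labels), control channels carry a planted
control/patient fold on a `frac_differential` share of proteins, each
peptide observes every channel through i.i.d. multiplicative log-normal
noise, peptide counts follow a shifted Poisson (minimum 1), and a share of
peptides is flagged non-unique. Defaults, chosen once as a realistic
discovery experiment and not revisited: 200 proteins, 20% differential,
folds uniform on 1.4-4.5 (the candidate range observed in muscle reporter
data), `lambda = 14` so the >10-unique-peptide stratum is well populated,
`noise_sigma = 0.2` on the natural-log scale (a typical reporter-ion CV),
balanced channel biases, 10% non-unique peptides. The generator is
seed-deterministic to the byte and restores the caller's RNG state.

Two features of real data are deliberately *not* modeled by default:
ratio compression (a known isobaric-tag artifact; the published procedure
does not correct for it, so neither does the default simulation) and a
biological background of small but consistent shifts. The second omission
has a visible consequence that users of the recovery metrics should
understand. In the published data the qualifying set was dominated by
proteins with modest ratios (1.14-1.68), which pulled the mean-of-
qualifying threshold *below* the candidate range. With exact-null
backgrounds, the qualifying set is essentially the planted-differential
set, the derived threshold sits near the *center* of the planted fold
distribution, and strict above-threshold selection recovers only the
upper half of the planted effects: sensitivity against the planted truth
hovers near 0.5 even though the false-discovery proportion is ~0. That is
a property of the mean-threshold procedure on a two-population world, not
an implementation artifact, and it is the main caveat when reading
synthetic recovery numbers as evidence about real data. On null data
(no planted effects) the same procedure selects essentially nothing,
which the test suite verifies over 20 seeds.

## Problem sizes and orchestration

The test suite and acceptance script run the full pipeline at 200
proteins x ~15 peptides (single seeds for the recovery and bracketing
checks, 20 seeds for the null-selection bound) and exercise the
fixture-backed paper-scale computations, which are instantaneous. These
sizes were chosen as the package's own evaluation scale: large enough for
the binomial bounds to be meaningful, small enough to iterate on.

Orchestration is function-level by design: `run_diff()`,
`run_topology()` and `run_report()` chain the stages, write versioned
plain-TSV reports (diffable, reproducible byte-for-byte on identical
inputs) and log stage counts; `read_pipeline_config()` reads a flat YAML
configuration for scripted use. The package targets interactive R and
Rscript use rather than a standalone shell tool.

## Known limitations

* No moderated-variance (limma-style) modeling; the published procedure
  is test-based and is reproduced as such.
* No isotope-impurity or ratio-compression correction.
* The interactome layer answers direct-edge questions only; path-based
  or diffusion analyses are out of scope.
* Pooled designs cannot separate biological from technical variation;
  nothing in this package pretends otherwise.
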