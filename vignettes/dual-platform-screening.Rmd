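---
title: "Evaluating dual-platform newborn screening for inborn errors of metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating dual-platform newborn screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbsdual)
```

## The screening problem

Population newborn screening (NBS) for inborn errors of metabolism (IEMs)
classically relies on tandem mass spectrometry (MS/MS): amino acids,
acylcarnitines, free carnitine and succinylacetone are quantified in a dried
blood spot and compared against center-specific cutoffs. MS/MS is sensitive
but unspecific — most screen positives are false alarms — and some disorders
present with analytes that are normal at day 3–7 of life. Gene-panel
sequencing (NGS) from the same blood spot inverts the trade-off: a
genotype-based rule produces very few positives, almost all of which are
confirmed, but it misses cases whose causal variants are absent from the
panel or classified as variants of uncertain significance (VUS).

`nbsdual` implements both first-tier classifiers, the combined
referral/recall workflow, the performance arithmetic of a multicenter
screening programme, carrier-frequency estimation with Hardy–Weinberg
incidence projection, and a synthetic-cohort generator so that the whole
pipeline can be validated without access to subject-level data.

## The genotype-based rule

For a gene $g$ with inheritance mode $I_g \in \{\mathrm{AR}, \mathrm{XL}\}$,
a *qualifying allele* is a pathogenic (P) or likely pathogenic (LP) variant
call; a homozygous call contributes two alleles, a heterozygous or
hemizygous call one. A subject is screen-positive when some in-panel gene
satisfies:

* **AR**: a homozygous P/LP variant, or two *distinct* heterozygous P/LP
  variants. Phase is unobserved in singleton screening, so two distinct
  heterozygous alleles are assumed *in trans*; trio phasing is out of scope.
* **XL, male**: at least one qualifying allele (hemizygous or
  het-reported).
* **XL, female**: a homozygous P/LP genotype. Heterozygous females are
  carriers, not screen-positive; programmes that wish to report them can
  opt in via `as_nbs_panel(..., xl_female_het_positive = TRUE)`.

VUS, likely-benign and benign calls never qualify, even when paired with a
P allele — this is exactly what makes several true cases genetic-screen
negative. Genes absent from the sequencing panel (`in_panel = FALSE`) never
trigger, which reproduces the one diagnosed case whose gene was off-panel.
The classifier is deterministic; when several genes trigger, the first in
lexicographic order is reported and all are retained in the `reason`
string.

Both properties that make this rule safe to automate are enforced by
property-style tests: upgrading any variant along
B→LB→VUS→LP→P can never flip a positive call to negative, removing a
variant can never flip a negative call to positive, and the implementation
agrees with an independent brute-force oracle that enumerates every
genotype of up to three variants per gene.

## The analyte-cutoff rule

Each MS/MS marker $m$ has a center-specific threshold $t_m$ and a
direction: accumulation markers (e.g. C3, Phe, C4, C8, citrulline, and all
ratio markers such as C3/C2 and Phe/Tyr) flag **above** the cutoff,
deficiency markers (free carnitine C0, methionine) flag **below** it. A
profile is positive when at least one marker is abnormal:

$$\text{abnormal}(x_m) = \begin{cases} x_m > t_m & \text{direction high} \\
x_m < t_m & \text{direction low} \end{cases}$$

Two numerical conventions deserve a note:

* **Strict inequality.** A value exactly at its cutoff is normal. The
  convention is arbitrary but fixed, and the packaged subject fixtures are
  consistent with either choice.
* **Citrulline flags high.** Citrin deficiency (NICCD) and citrullinemia
  are screened through *elevated* citrulline; the diagnosed NICCD subject
  had a normal (low-side) citrulline at first screening and was missed by
  MS/MS, which only a high-direction cutoff reproduces. Low citrulline is
  an OTC-deficiency signature but is not used as a screening flag here.

Cutoffs are per-center metadata (`as_cutoff_set`); the packaged
`reference_cutoffs()` set is assembled from the per-case values printed for
the diagnosed subjects and is the simulator default. Units are per-marker
metadata: values reported in mg/dL are compared against a cutoff declared
in the same unit rather than silently converted.

## Referral, recall and outcome labelling

A newborn positive on either platform is referred. Genetic positives are
always recalled; MS/MS-only referrals are thinned by a per-center recall
probability, reflecting observed attrition between screen positivity and
recall review. Outcomes are labelled per modality:

* positive ∧ confirmed → **TP**;
* positive ∧ recalled ∧ ¬confirmed → **FP**;
* positive ∧ never recalled → **unknown** (excluded from the PPV
  denominator — their outcome was never ascertained);
* ¬positive ∧ confirmed (via the other platform's referral) → **FN**;
* otherwise **TN**.

Consequently **PPV is confirmed cases over *recalled* positives**, not over
all positives. Many references define PPV over all screen positives; the
recalled-denominator convention is the one consistent with every per-center
and pooled value in the fixture tables, so it is the package default and is
stated prominently wherever PPV is reported. Pooled (`Total`) rows are
always computed from pooled counts, never by averaging per-center
percentages.

Printed percentages use half-up rounding (`round_half_up`), not R's
round-half-to-even, because screening reports round 5 upward; the same rule
is applied to "1 in N" incidence reciprocals (29,601/2 = 14,800.5 renders
as 1/14,801). Precision is configurable per table since published tables
mix one- and two-decimal output.

## Carrier frequencies and Hardy–Weinberg projection

A *carrier* is an unaffected subject with at least one qualifying
heterozygous allele in a gene. By default only P/LP alleles count
(`rule = "any_PLP_het"`); whether VUS carriers should count is genuinely
open, so `rule = "any_variant"` is available. Biallelic (affected)
subjects are excluded from the numerator by default, with
`include_affected = TRUE` as a documented option.

Under random mating, carrier frequency $c$ and disease-allele frequency
$q$ satisfy $c = 2q(1-q)$ and the projected recessive-disease incidence is
$q^2$. The rare-disease approximation uses $q = c/2$; the exact mode
inverts the quadratic, $q = (1-\sqrt{1-2c})/2$, defined for $c \le 1/2$.
For every carrier frequency at or below 1/40 the two modes agree within 3%
relative, which is why the rare approximation is the default calibration
throughout.

## What the synthetic cohort emulates

`cohort_config()` defaults encode the study conditions the package is
designed around:

| parameter | default | rationale |
|---|---|---|
| centers | 8 centers, observed sizes and recall rates | multicenter structure with one low-recall center |
| `carrier_freq` per gene | 1/42 (PAH) … 1/1480 (DBT) | printed carrier frequencies; ETFA (off-panel) set to 1/1000 and X-linked OTC to $q = 10^{-4}$, both unprinted, chosen as realistic for a Chinese newborn population |
| `penetrance_biochemical` | 17/24 | observed share of genotype-positive newborns who were truly diseased; the complement becomes genetic-screen false positives |
| `attenuation_prob` | 2/23 | observed share of diagnosed cases whose primary markers stayed within cutoffs (missed by MS/MS) |
| `vus_case_share` | 5/23 | observed share of diagnosed cases carrying one VUS allele (missed by the genetic rule) |
| `msms_fp_rate` | 0.0164 | background healthy-profile positive probability; together with detected cases this lands the overall MS/MS positive rate near 1.71% |

These three mechanism rates are *calibrations to observed shares, not
estimates*: the source data offer no replication to estimate them from, so
the defaults simply reproduce the observed frequencies of each
false-call mechanism.

Analyte values are modelled as independent per-marker log-normals. For a
healthy subject, each marker's location is set so that its tail mass beyond
the cutoff equals $1-(1-\pi)^{1/K}$ for $K$ simulated markers and
per-subject background rate $\pi$ (so *some* marker crosses with
probability $\pi$). Diseased, non-attenuated subjects draw their disease's
primary markers strictly beyond the cutoff; attenuated subjects strictly
within it. This structure is deliberately minimal: it reproduces positive
*rates*, classifier behaviour and workflow arithmetic, but not the
covariance of real acylcarnitine profiles, gestational-age or birth-weight
effects, or analytical drift. Ratio markers are drawn directly rather than
derived from their component analytes. A passing pipeline on simulated
data therefore validates the *logic* of the screening programme, not the
biochemical realism of any marker distribution.

Variant identities are drawn from a hotspot catalogue seeded with the
variants reported in the healthy population (e.g. MMACHC c.609G>A,
c.658_660delAAG, c.482G>A; SLC22A5 c.1400C>G, c.51C>G), so that variant
spectrum tallies behave realistically. A single integer seed governs all
randomness; the generator restores the caller's RNG state, and identical
configurations produce byte-identical cohorts.

## Problem sizes and test design

The package's statistical checks use cohort sizes chosen for adequate
power at desk scale: carrier-frequency parameter recovery runs at
$n = 50{,}000$ (three binomial standard errors distinguish the configured
frequencies), genotype-frequency recovery and the end-to-end qualitative
comparison of the two platforms at $n = 100{,}000$ (expected false-call
mechanism counts are large enough that their ordering is stable), and
determinism/homogeneity checks at a few thousand. The fixture-driven
checks — the 23 diagnosed subjects and the per-center count table — are
exact and run in milliseconds.

## Known limitations

* ACMG classification is an *input*; the package neither scores evidence
  nor reclassifies variants, so its genetic calls are only as good as the
  upstream classifications.
* Copy-number genotypes and the read-level variant-calling pipeline are
  out of scope; variant tables arrive as HGVS-labelled calls.
* Confirmatory biochemistry is represented as a boolean diagnosis label,
  not modelled assays.
* Carrier counts behind the published per-gene frequencies are not
  redistributable; they enter as simulator inputs and fixture constants,
  and carrier-frequency code is validated by parameter recovery on
  simulated cohorts instead.
* The recalled-positives PPV convention and the strict-inequality cutoff
  convention are fixed package-wide; programmes using other conventions
  should derive their metrics from the labelled outcome table directly.
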