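---
title: "Methods: simulating and evaluating a centralised medulloblastoma diagnostics pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating a centralised medulloblastoma diagnostics pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbdx)
```

## Scope and design

`mbdx` models a national centralised molecular-diagnostics pathway for
medulloblastoma, the commonest malignant embryonal brain tumour of childhood.
In such a pathway, local treatment centres submit frozen and FFPE tumour
material to a national reference centre, which performs specimen quality
control, DNA-methylation and RNA-based molecular subgrouping, copy-number
assays for *MYC*/*MYCN* amplification on several platforms, β-catenin IHC and
mutation testing for WNT pathway activation, central histology review, and
finally WHO-2016 classification and clinical-trial risk stratification —
all inside a clinically mandated turnaround window.

Patient-level data from such audits are typically not released. The package
therefore pairs every analysis stage with a seeded synthetic-cohort generator
whose defaults encode the published cohort-level characteristics of a 135
patient national audit: the subgroup mix, biomarker prevalences, specimen
yield and quality distributions, assay failure rates and turnaround-time
distributions. All downstream modules (QC gating, subgroup classification,
copy-number calling, consensus integration, benchmarking, stratification) are
ordinary analysis code that run identically on real tabular inputs of the
same shape.

## The synthetic cohort generator

### What it emulates

* **Cohort composition.** Patients are drawn from a multinomial over the four
  consensus molecular subgroups with default priors WNT 0.10, SHH 0.30,
  Group3 0.24, Group4 0.36. The WNT/Group3/Group4 fractions are the published
  cohort fractions; SHH receives the remainder so the priors sum to one
  (the published per-subgroup counts include six unclassifiable patients and
  do not form a simplex on their own).
* **Biomarkers.** Conditional on subgroup: *CTNNB1* mutation (0.90) and
  chromosome-6 monosomy (0.88) in WNT; *TP53* mutation (0.21) and *MYCN*
  amplification (0.18) enriched in SHH; *MYC* amplification (0.24) in Group3;
  LCA histology enriched in Group3. The generator never assigns *MYC* and
  *MYCN* amplification to the same patient.
* **Molecular profiles.** Methylation beta values follow a block-structured
  centroid model: a shared background level of 0.2, plus one disjoint
  50-probe marker block per subgroup elevated by `signal_separation`
  (default 0.40), plus additive Gaussian noise (`noise_sd`, default 0.10),
  clipped to [0, 1]. Expression profiles use the same block structure on a
  nonnegative abundance scale. This is deliberately the simplest generative
  structure that a rank-4 nonnegative factorisation can recover.
* **Copy-number tracks.** A per-probe log2-ratio track is generated alongside
  the beta values. Focal amplification adds an amplitude drawn uniformly from
  [1, 3] over a 50-probe locus (the spread models tumour-content dilution and
  intra-tumoural heterogeneity and is what makes the array platform
  imperfectly sensitive); chromosome-6 monosomy shifts all chr6 probes by
  −0.5.
* **Raw assay data.** iFISH is simulated at per-nucleus resolution
  (target/control signal counts, with a clonal amplified fraction of 30–90%
  of nuclei in amplified tumours and a 1% background elsewhere); MLPA as
  target and four reference probe signals with multiplicative measurement
  noise, a 9% technical-spike rate (false positives) and a 20% degradation
  rate on amplified samples (false negatives). These rates were chosen once
  so that, at cohort scale, the platform comparison reproduces the
  qualitative published ordering — iFISH most accurate, array fully specific
  but insensitive, MLPA sensitive but false-positive-prone — and they live in
  `cohort_config(assay_params = ...)`, where setting them to zero makes every
  platform recover ground truth exactly.
* **Specimens and failures.** Baseline specimen draws always pass every QC
  gate (dsDNA truncated above the 2000 ng full-panel threshold, RIN above 5);
  all QC failures are produced by explicit per-patient failure processes with
  configurable rates (low DNA 0.015, low RNA 0.13, low RIN 0.27, iFISH
  technical failure 0.13, MLPA reference dropout 0.07), each recorded with a
  reason code. This keeps failure prevalence exactly interpretable and makes
  the zero-failure configuration a clean positive control. A consequence is
  that the descriptive "92% exceeded 2000 ng" figure of the emulated audit is
  not a separate dial; only the per-assay failure rates are.
* **Timelines.** Stage durations are log-normal (positive, right-skewed,
  matching the published boxplot shapes): surgery-to-receipt with median 14
  days, iFISH processing/reporting and histology/review stages with medians
  of 4–8 days. A 12% delay process appends extra days attributed to
  personnel availability (53%), additional central review (33%) or IHC
  repeats (14%). Receipt-to-report is the maximum of the two processing
  chains plus any delay.

### What it does not emulate

Profiles are block-structured with independent Gaussian noise: there is no
probe-level correlation structure, no real 450k annotation, no batch or
cross-platform effects, and expression is simulated at abundance level (no
read-level RNA-seq). Histology is a label, not an image. Passing tests on
this generator therefore demonstrate that the analysis machinery is correct
and well calibrated for data with the assumed structure — not that the
classifier would meet the same operating characteristics on real arrays.

One published inconsistency is inherited knowingly: the audit reports a
median surgery-to-receipt interval of 14 days (mean 24), yet counts only
13/115 patients as failing a 10-day-receipt + 28-day-reporting trial rule.
Those two statements cannot both hold under any i.i.d. timeline model. The
generator follows the published distribution, so simulated cohorts lose far
more patients to the turnaround rule than the published funnel does; the
funnel worked example instead evaluates the rule engine on the published
funnel counts directly.

## Subgroup classification

The classifier follows the metagene strategy: rank-4 NMF on the nonnegative
training matrix (beta values are used directly — no M-value transform, which
would break nonnegativity), multiplicative updates under the Frobenius
objective, best of 50 random restarts (basis `W` drawn uniformly per restart;
`H` initialised by nonnegative least squares per sample, which makes the fit
equivariant under sample permutation), stopping at a relative error change
below 1e-6 or 200 iterations. Each metagene is mapped to the subgroup with
the largest mean training projection under a greedy bijection. New profiles
are projected onto the fixed basis by nonnegative least squares and
unit-normalised, and a linear SVM (cost 1) assigns the label.

"Resampling confidence" is implemented as the cheapest scheme consistent
with an 80% vote threshold: B = 1000 bootstrap resamples of the training
projections, each refitting the SVM; a profile's confidence is the fraction
of ensemble votes agreeing with its modal label, and calls under 0.80 are
non-classifiable (NC). The ensemble is built once at fit time from a seed
derived from `nmf_seed`, so classification is deterministic and costs one
projection plus B ensemble predictions per profile. NC samples are excluded
from subgroup-dependent downstream rules and surface as "unclassifiable" in
WHO accounting.

Two subtleties are worth recording. First, whether the original pathway's
SVM consumed metagene projections or full profiles is not documented;
projections were chosen (smaller, noise-suppressed, and the metagenes are
the point of the factorisation). Second, at a centroid midpoint the
confidence is a symmetry argument: with an exactly mirror-symmetric basis
and training set the bootstrap votes split evenly and the call is NC. After
NMF on one finite noisy training draw the basis is only approximately
symmetric, and the midpoint vote of a particular fitted model can land
anywhere; the test suite therefore verifies the symmetric scenario
constructively rather than pretending any single NMF fit is symmetric.

## Copy-number calling

* **iFISH** (`score_ifish`): a nucleus is amplified at target:control ≥ 4 or
  ≥ 10 target signals; a sample is amplified when ≥ 5% of ≥ 50 scorable
  nuclei are amplified, and fails below 50 scorable nuclei. The numeric
  thresholds are cited, in the pathway this models, to an external scoring
  protocol rather than restated; they are module constants, overridable per
  call.
* **MLPA** (`call_mlpa`): dosage ratio against the mean of four reference
  loci; ratio > 3.0 is amplified, (1.3, 3.0] is reported as gain (not
  amplification — chosen to separate high-level amplification from
  single-copy gains; no published cut-off exists), and a missing or
  non-positive reference fails the assay.
* **Methylation array** (`call_array_cn`): fixed 50-probe bins within
  chromosomes (a changepoint segmentation would be overkill for
  block-simulated tracks and is documented as non-equivalent to real-array
  segmentation); focal amplification when a locus-overlapping bin reaches
  log2 ≥ 1.5; chr6 monosomy when the chr6 median is ≤ −0.3 with a neutral
  autosomal baseline (median within ±0.1).

## Consensus integration

The WNT consensus call is `positive` on *CTNNB1* mutation, or on any two of
the four WNT measures (IHC ≥ 10% nuclear β-catenin, chr6 monosomy,
methylation subgroup WNT, RNA-seq subgroup WNT). The mutation is an
independent arm, not a fifth counted measure — the alternative reading was
rejected because the rule names it separately. Unknown fields use
three-valued logic: `negative` requires the knowns to rule out ever reaching
the rule; otherwise the call is `indeterminate`, so partial panels never
silently default to negative. The implementation is verified against a
brute-force oracle that enumerates every completion of the unknowns over all
3^5 panel states.

Pathologist consensus is a majority of exactly three blinded reviews.
Variant reconciliation classifies each case as concordant, changed (both
calls definitive and different), assigned (local unassigned, central
definitive) or unresolved (central MB-NOS), with the changed percentage
computed over locally assigned cases and the assigned/combined percentages
over all cases. (The emulated audit prints "30/135, 20%" for assignments;
30/135 is 22.2%, and the package reports the arithmetic value.)

## Stratification

WHO-2016 classes are WNT-activated; SHH-activated TP53-mutant and wild-type
(an SHH tumour with unknown TP53 status reports as wild-type, the non-mutant
default); Group3 and Group4; and unclassifiable for NC/absent subgroup
calls. Trial eligibility requires age in [3, 23) years (the "3–22 years"
window read as inclusive–exclusive whole-year bounds; configurable),
complete biomarker data, surgery-to-receipt ≤ 10 days and receipt-to-report
≤ 28 days, no high-risk biology (MYC/MYCN amplification and/or LCA on the
*central* variant call) and no high-risk clinical features (R+/M+). Unknown
fields disqualify with reasons; they never raise. Eligible WNT-consensus
positive patients enter the favourable-risk arm.

The pre-review baseline risk uses only what existed locally — local variant
and clinical stage — because no formal baseline is published; the
post-review risk is high on amplification, central LCA or SHH-TP53-mutant
status, favourable on WNT consensus, and the delta is flagged when the two
differ and the post-review risk is known.

Turnaround thresholds are the sample mean plus one sample standard deviation
per stage; "exceeded" is strict, so a case exactly at the threshold is on
time.

## Numerical and reporting conventions

Percentages are reported both raw and rounded half-away-from-zero to
integers; the raw values are authoritative (the emulated audit's own
rounding is not always arithmetically consistent, e.g. 88/99 printed as
88%). QC thresholds are strict inequalities exactly as worded, with tumour
content inclusive at ≥ 60%. The full diagnostic panel additionally requires
methylation eligibility, so the eligibility hierarchy holds even for
specimens failing on DNA volume. Failed assays are excluded from
benchmarking denominators, never imputed. All randomness flows from the
configuration seed through `with_seed()`, which restores the caller's RNG
stream; regenerating a cohort from the same configuration is byte-identical.

## Problem sizes used in the tests

Unit tests run on 600-probe, 25–120-patient cohorts with reduced NMF
restarts and bootstrap sizes; the cohort-level checks use a 200-sample
training cohort with 1,000 held-out profiles for label recovery (macro
recall ≥ 0.95 at the default separation 0.40 / noise 0.10), a 1,000-patient
cohort for the platform error ordering, and the default 135-patient
configuration, run twice, for end-to-end determinism. These sizes were
chosen as the smallest at which the binomial noise on the tested fractions
is comfortably below the asserted margins.

## Known limitations

The generator's independence assumptions (probes, patients, failure
processes) are stronger than reality; the array segmentation is not a
changepoint method; second-generation Group3/Group4 subtypes are carried
only as a pass-through annotation concept, not modelled; *APC*-mutant WNT
tumours (a known blind spot of *CTNNB1*-based testing) are not simulated;
and the blinded-IHC review set is reconstructed from published marginals
rather than the unpublished case-level composition.
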