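---
title: "Evaluating ambulatory ECG rhythm annotations against a consensus panel"
author: "rhythmconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating ambulatory ECG rhythm annotations against a consensus panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmconcord)
```

## The evaluation problem

Multi-day ambulatory ECG (Holter) recordings are annotated beat by beat,
either by human technicians or by automated readers. Judging which reader is
safer requires more than a beat-level agreement score: what matters
clinically is whether a *patient's* critical arrhythmia is reported at all
over the full recording, and how many false alarms a physician must review.
`rhythmconcord` implements that evaluation: given beat-level (or
episode-level) annotation tracks from two reading methods and a
gold-standard adjudication, it derives arrhythmia episodes, samples
fixed-length strips for adjudication, scores reader-versus-gold concordance
with explicit overlap rules, and aggregates patient-level accuracy
statistics with bootstrap confidence intervals.

The pipeline has five stages, each an exported function:

1. `derive_episodes()` — beat stream to rhythm episodes;
2. `sample_strips()` — quota-limited random search for adjudication strips;
3. `match_strip()` / `adjudicate_strips()` — concordance verdicts;
4. `patient_outcomes()` + `cohort_metrics()` / `rr_missed_diagnosis()` —
   patient-level statistics;
5. `generate_cohort()` / `render_beats()` — a synthetic cohort generator so
   that every stage is testable without patient data.

## Arrhythmia taxonomy

`rhythm_taxonomy()` fixes the class thresholds. The *critical* tier
contains findings that must always reach a physician: atrial fibrillation
(AF) sustained for at least 30 s, supraventricular tachycardia (SVT) for at
least 30 s, ventricular tachycardia (VT) for at least 10 s at a mean rate
of at least 120 bpm, sinus arrest/asystole (an inter-beat gap of at least
3.5 s) and third-degree AV block of any duration. The *noncritical* tier
holds reportable findings below those thresholds: pauses of 2.0–3.5 s,
VT/SVT runs of at least 3 beats under the critical duration, second-degree
AV block (types 1 and 2 are deliberately not distinguished), premature
atrial and ventricular complexes, ectopic atrial rhythm (at least 3 atrial
ectopics in a row), and idioventricular rhythms, split into IVR and
accelerated IVR at a 60 bpm mean rate.

All thresholds compare inclusively at the lower bound (`>=`) and
exclusively at the upper bound (`<`): a 30.0-s AF run is critical, a 3.5-s
gap is asystole, a 2.0-s gap is a pause. Three classification corners were
genuinely open and are resolved as follows:

* **SVT at exactly 30 s.** The critical definition ("at least 30 s") and
  the noncritical one ("up to 30 s") meet at the boundary; the package
  assigns exactly 30 s to the critical tier, keeping the two tiers
  disjoint.
* **AF shorter than 30 s** belongs to no reporting tier (criticality
  `"other"`): the noncritical class list contains no short-AF class, so
  such runs are excluded from both accuracy tiers rather than silently
  folded into one.
* **VT of at least 10 s but under 120 bpm** fails the critical rate floor,
  and the noncritical VT class is explicitly "under 10 s"; such runs are
  also assigned `"other"`.

Intervals are half-open `[start, end)` in 0-based sample coordinates on a
fixed 300 Hz clock. A run's episode extends from its first beat onset to
its last beat onset plus one median RR interval — this keeps duration
monotone in beat count — but never past the next annotated event, so
adjacent runs stay disjoint and no beat can belong to two tachyarrhythmia
episodes. Episode mean rate is 60 divided by the mean RR over the run, not
an instantaneous maximum.

## Strip sampling and the source population

Strips are `34 s * 300 Hz = 10,200` samples long. Recordings are visited
in a seeded uniform-random permutation; for each recording and class with
any reader-annotated episode, one strip is emitted, at most one per
recording and class, and the search stops per class once its quota
(default 500 for critical, 250 for noncritical classes) is filled. The
number of recordings visited up to that point is the class's *source
population*: counts found in the searched fraction are later scaled to the
full cohort by `cohort_size / recordings_searched`
(`weight_to_population()`), so `strips_selected / recordings_searched`
estimates per-recording detection prevalence.

The window placement inside a recording is not constrained by the study
design, so the package chooses: windows are centred on the episode
midpoint, clamped to the recording bounds, and anchored at the onset for
episodes longer than one strip (shifted, never truncated). When several
episodes of a class qualify in one recording, the earliest one is used;
when both readers flag the class, one shared strip serves both
(`trigger_reader = "both"`), mirroring a pooled selection from either
method's annotations. Sinus rhythm, sinus bradycardia and noise strips can
be sampled as extra classes to blind human adjudicators, but never enter
accuracy metrics.

## Concordance rules

Within a strip, a reader's annotation is compared with the panel's per
class (`overlap_rules()`):

* sustained tachyarrhythmias: at least 80 % of the panel episode covered,
  in duration *and* in beat type;
* asystole and pauses: at least 90 % duration overlap;
* second- and third-degree AV block: presence of any such event within the
  strip;
* single ectopic beats: position within ±45 samples (150 ms);
* noise marks: at least 80 % duration overlap.

The denominator is always the panel annotation. The published rule text
("80 % overlap in beat type and duration") does not say whether this is one
combined criterion or two; the package reads it conjunctively — both
fractions must reach 0.80 — which is the stricter and more symmetric
interpretation. When the reader fragments one panel episode into several,
the union of the reader's episodes within the panel span is measured, so
fragmentation alone is not penalised. Beat-type overlap needs beat tracks;
when only episode lists are available it falls back to class-label
agreement. Episodes truncated by the strip are assessed on their in-window
portion; minor beat-to-beat discrepancies below the thresholds never flip
a verdict.

Each (strip, reader, class) gets exactly one verdict: TP, FN (with
`misclassified_as` set to the reader class maximally overlapping the panel
event, ties broken critical-first then alphabetically), FP (with the
panel's class at that locus), or TN. A reader episode spanning two panel
episodes of different classes is attributed by maximal overlap — another
documented choice where the design was open. For readers listed in
`missed_beat_alias_readers` (by convention the technician method), a bare
"missed beat" (blocked-beat) annotation counts as concordant second-degree
AV block.

`apply_variant()` implements the misclassification-insensitive sensitivity
analysis: FP/FN of a critical class that the other track labelled as a
*different* critical class are excluded (such events still reach a
physician), as are second-degree AV block false positives. Excluded rows
keep their slot so the verdict partition stays intact.

## Patient-level statistics

A patient is a false negative for reader R and class c when the panel
confirmed the class, R detected no concordant episode, and the other
reader detected one. Patients missed by every reader are undetectable by
construction and count for nobody — a conservative property inherited from
the sampling design. Rates per 1,000 patients divide by the effective
population (source population, scaled to the cohort). FP burden is also
reported per 1,000 patient-days, with the median and IQR taken across
per-class rates (the original construction is ambiguous; per-class is the
package's documented choice, using type-1 quantiles so that two classes
yield exactly their own rates as the IQR).

Confusion statistics (sensitivity, specificity, PPV, NPV, accuracy, F1 as
the harmonic mean of PPV and sensitivity) are computed from verdict counts;
ratios with a zero denominator are reported as `NA`, never 0 or 100.
Confidence intervals are percentile bootstrap with 1,000 replications,
resampling *patients* (the unit of the reported rates), never strips;
replicates on which a statistic is undefined are dropped and counted. The
relative risk of a missed diagnosis is the ratio of the two readers'
weighted FN rates, with a patient-resampling bootstrap CI, a log-normal
approximation CI on the raw counts, and a two-sided Fisher exact p-value
(`stats::fisher.test`; the test suite cross-checks it against an exhaustive
hypergeometric enumeration). Non-overlapping CIs between methods are a
report annotation, not a hypothesis test.

## The synthetic cohort generator

No public data set with this structure exists, so `generate_cohort()`
creates one. It emulates: recording durations from a normal distribution
(mean 14, sd 10 days) truncated to the 1–31-day device range; per-class
episode processes as Poisson events in time with log-normal durations
chosen to straddle the taxonomy thresholds (AF around 45 s, VT around 9 s,
gaps around 3 s, so every boundary is exercised); tachyarrhythmia rates
from normal distributions (VT centred at 140 ± 25 bpm, straddling the
120 bpm floor); and a log-normal sinus RR process (0.8 s mean). The
consensus panel equals the ground truth — the panel is the gold standard by
definition — with an optional perturbation knob reserved for robustness
studies.

Readers are imperfect through four mechanisms (`reader_model()`):
episode-level detection probability, false events placed uniformly over
event-free time (draws colliding with a same-class truth episode are
dropped), Gaussian boundary jitter with re-classification of the jittered
interval through the taxonomy (so a 3.6-s asystole jittered to 3.4 s is
honestly reported as a pause), and a misclassification table over reported
classes. `render_beats()` turns any episode plan into a beat track:
irregular `af_beat`s (i.i.d. log-normal RR with high coefficient of
variation — sufficient because the pipeline consumes labels, not
waveforms), fast regular runs for VT/SVT, beat-free spans with anchor
beats at both edges for gaps (so derived gap durations are exact), blocked
and escape beats for AV block, and single ectopics that replace any base
beat within a quarter second.

What the generator does *not* model: raw ECG voltages or QRS morphology,
panel disagreement and consensus resolution, and human-workflow effects
such as fatigue or information overload. Passing tests therefore
demonstrate the correctness of the evaluation machinery under the stated
statistical structure, not the clinical performance of any real reader.

## What the recovery study estimates

The validation suite generates 2,000-patient cohorts with reader
detection probabilities 0.986 and 0.803 on AF and distinct false-event
rates on VT, then checks that the pipeline recovers the generative
quantities. One subtlety deserves emphasis: because exactly one strip per
patient and class is adjudicated, anchored at the earliest episode either
reader detected, the estimand is the *conditional per-episode* sensitivity

$$\mathrm{sens}_R = \frac{p_R}{p_A + p_B - p_A p_B},$$

and the generative relative risk of a missed diagnosis is
$(1-p_B)\,p_A \,/\, \big((1-p_A)\,p_B\big)$ — both independent of how many
episodes a patient has. The same conditioning affects the published study
design: patients missed by both methods are invisible, so all reported
sensitivities are relative to the jointly detected population. The suite
verifies recovery within three Monte-Carlo standard errors and
bootstrap-CI coverage of the generative RR in at least 93 of 100 seeded
repeats.

## Numerical choices and problem sizes

* All randomness flows through explicit integer seeds (cohort generation,
  strip-search permutation, bootstrap); identical seeds give bit-identical
  outputs.
* Windows are shifted, never truncated; degenerate inputs (empty tracks,
  single beats, zero-event cohorts) return empty-but-typed results rather
  than errors, while contract violations (unsorted tracks, unknown labels,
  pause plans under 2.0 s, searched populations exceeding the cohort)
  raise immediately.
* Validation problem sizes are the package's own choices, balancing
  statistical resolution against desk-scale runtimes: 2,000-patient
  cohorts with 100 repeats for RR coverage, 1,000 random strips against
  the brute-force matcher, exhaustive Fisher tables for group sizes up to
  15 plus a seeded random sample up to 30, and a 4,000-patient
  demonstration cohort in the acceptance script.

## Limitations

Episode derivation trusts the beat labels; it performs no signal-level QRS
detection or re-classification. Third-degree AV block is accepted only as
an explicit annotation, not inferred from blocked-beat patterns. The
technician "missed beat" alias is realised through the beat-class mapping.
Subgroup tables (by sex or monitoring duration) are not produced, though
the grouping keys exist on every output. The optional WFDB annotation
importer is not provided; beat tracks are exchanged as JSONL or CSV.
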