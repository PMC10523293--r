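---
title: "Multi-source detection of housing instability in EHR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-source detection of housing instability in EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hinstab)
```

## The problem

Housing instability is a social determinant of health strongly associated
with substance use disorders (SUDs), overdose, and poor care outcomes, yet
it is documented erratically in electronic health records. Three largely
disjoint kinds of documentation coexist:

* **Structured diagnosis codes.** ICD-10-CM Z59* ("problems related to
  housing and economic circumstances") attached to billing encounters.
  Cheap to query, known to undercount.
* **Semi-structured addresses.** Free-text address fields that sometimes
  hold the address of a community shelter or treatment residence, a literal
  "HOMELESS" line, or a generic city/state placeholder.
* **Unstructured clinical notes.** Free-text mentions of homelessness,
  shelter names, and housing concepts, with all the hazards of clinical
  language: negation ("she denied being homeless"), third-party experiencers
  ("found a homeless person..."), stale history, and paradoxical phrasing.

`hinstab` implements each channel as an independent detector producing
*evidence flags* `(patient_id, source, method, provenance)`, fuses them into
per-patient identification sets over sources $\{D, A, N\}$ (diagnosis,
address, notes), decomposes the union into the 7 Venn regions, aggregates to
census tracts under codes-only versus all-sources modes, and quantifies
reviewer concordance with Fleiss' kappa. A seeded synthetic EHR generator
with planted ground truth makes every stage testable without protected
health information.

## Channel models and their parameters

### Diagnosis codes

Cohorts and evidence are defined by dot-stripped, case-insensitive ICD
prefix matching: a pattern `T40.5` matches the 7-character billing code
`T40.5X1A`, and `F14.` matches `F140`. Dot-stripping is deliberate — billing
extracts vary in dot usage, and one canonical form avoids dialect bugs.
Stimulant cohort: F14*, F15*, T40.5*, T43.6*; opioid cohort: F11*,
T40.0*–T40.4*, T40.6*; concurrent evidence is its own `both` category, not a
tie to break. Housing evidence is any Z59* code (the whole family, not just
Z59.0 — the sub-code restriction is left to the pattern file). Poisoning
episodes are T40* or T43.6*.

### Addresses

Addresses are normalized to a canonical key — uppercase, punctuation
stripped, USPS suffix abbreviation (STREET→ST), unit designators removed,
`line1|city|state|zip5` — and matched exactly against a curated directory of
community housing resources. A fuzzy pass (normalized Levenshtein
similarity, default threshold 0.92, on by default with full logging) absorbs
single-character typos; ambiguous fuzzy candidates emit a warning and **no**
evidence. Only the most recent address per patient is evaluated, mirroring
the practical limitation of EHR address data. A literal "homeless" token in
line 1 is evidence (`literal_homeless`); a generic placeholder address (city
or state but no street line) is counted descriptively and is **never**
evidence, because an unspecified address does not imply a housing issue.
Resources whose only role is residential SUD treatment count as evidence by
default — such stays imply a disrupted living environment under the
inclusive reading — but `include_treatment = FALSE` excludes them, since
they can overestimate homelessness proper.

### Notes: keywords, shelters, concepts

Sentence segmentation is rule-based (sentence punctuation and newlines) with
exact character offsets, so every mention span slices back to the note text.
Keyword matching is token-sequence based against a seed lexicon
("homeless", "unhoused", "unstable housing", ...), longest match winning.
The lexicon ships as a starting point and is extensible via YAML; no claim
is made that it reconstructs any particular site's list.

Qualification is a NegEx-style window rule rather than parsing: within the
sentence, a negation cue within $W = 6$ tokens before **or after** the match
(the "and she denied" pattern requires post-position cues), a third-party
experiencer cue or a history cue before the match. Precedence:
negated > third_party > historical > affirmed. Affirmed and (by default)
historical mentions become evidence; historical counts because no temporal
filter is imposed on the phenotype — a strict-current-only switch exists.
Third-party mentions never count by default.

Shelter-by-name matching reuses the same directory as the address channel.
Shelter mentions are **never** negation-qualified: even "did not go to
Hope House" or an information-giving mention signals that a provider
perceived a housing need. Aliases that collide with lexicon keywords are
rejected at directory load.

The concept channel is a deterministic dictionary NER (longest-match over
1–5-token windows) against a concept vocabulary, followed by a
normalized-exact knowledgebase linker. Recognized spans missing from the
vocabulary are counted as `recognized_unlinked` — this reproduces, rather
than fixes, the characteristic bias of dictionary linking: matches are
limited to the target vocabulary, which may lack housing phrasings
("couch surfing"), trading recall for precision. A licensed clinical
terminology cannot be shipped, so the package carries a ~100-concept
synthetic mini-vocabulary with the real schema; a full vocabulary drops in
via the same TSV format. An adapter seam (`recognizer =`) accepts an
external trained model producing spans of the same shape.

### Fusion and reporting

Flags fuse to per-patient subsets of $\{D, A, N\}$; duplicates are
idempotent and adding flags is monotone. The Venn partition's 7 regions sum
to the union and each source total to its 4 regions — these conservation
laws are tested on randomized fixtures. Percentages are reported at 1
decimal place, **round-half-up**, matching the presentation granularity of
published clinical tables (base R's banker's rounding would print 58.45 as
58.4). Tract aggregation compares per-tract counts under codes-only versus
all-sources; patients without a tract go to a sentinel "unknown" tract, and
per-tract increases sum to $|D \cup A \cup N| - |D|$.

### Concordance statistics

Fleiss' kappa is computed as
$\kappa = (\bar P - \bar P_e)/(1 - \bar P_e)$ with
$P_i = \frac{1}{r(r-1)}\sum_j n_{ij}(n_{ij}-1)$ and
$\bar P_e = \sum_j p_j^2$; it is undefined when all mass is in one category.
Chi-squared tests report adjusted standardized residuals
$r_{ij} = (O_{ij}-E_{ij})/\sqrt{E_{ij}(1-\text{row}_i/N)(1-\text{col}_j/N)}$
to localize deviations. Fisher's exact test uses the two-sided
point-probability rule over full enumeration of margin-fixed tables (guarded
at $10^7$ tables, with a small relative tolerance for floating-point ties),
falling back to a seeded Monte-Carlo estimate over `r2dtable` simulations
when enabled. No multiple-testing correction is applied — raw p-values are
reported. The adjudication sampler draws a seeded, without-replacement,
note-level stratified sample per detection method and emits a review sheet
with blank rating columns; adjudication categories default to binary
(extraction correct / incorrect), a documented choice since richer category
sets (e.g. an "ambiguous" option for shelter-role cases) are equally
defensible.

## The synthetic world

The generator states one world and stays there; its defaults are not tuned
to make tests pass.

* `housing_prevalence = 0.292`: the published prevalence of
  housing-instability evidence in an SUD population.
* `sensitivity = (diagnosis 0.6, address 0.17, note 0.7)`: per-source
  probabilities that a truly unstable patient is documentable via that
  source, chosen once so the synthetic Venn structure qualitatively matches
  the published pattern (notes the largest identification set, addresses the
  smallest, codes in between). The published per-source coverages (58.5%,
  16.3%, 70.1% of the union) motivate the ordering; no attempt is made to
  reproduce the published counts, which depend on private data.
* `specificity_noise` (0.002/0.002/0.004): small false-documentation rates
  among stable patients; address noise is realized only as a resource
  address, never a literal "HOMELESS" line (noise realism choice).
* Documentation events are independent across sources given truth — the
  minimal assumption when only marginals and Venn counts are published; a
  shared-latent-severity correlation knob exists but is off by default.
* Notes per patient: negative binomial (size 0.4, mu 5) truncated to
  [1, 50]. The real-scale distribution (mode 1, median ~200, mean ~900) is
  infeasible and irrelevant at desk scale; what matters — mode 1, heavy
  right tail — is preserved.
* Mention phrasing: each note-documented patient gets one guaranteed
  evidential sentence (shelter-by-name with probability 0.35, else an
  affirmed keyword template); additional mentions are drawn with
  negated/historical/third-party template rates (0.10/0.08/0.03), and
  undocumented patients carry non-evidential distractor mentions at rate
  0.05. Cohort-conditional demographics anchor to the published contrasts
  (59.7% vs 47.2% male, 19% vs 5% Black for stimulant vs opioid cohorts);
  remaining cells are realistic choices, not reproductions.

What a green test establishes: that the detectors recover exactly what the
generator planted (recall 1.0 on documented channels), that negation and
experiencer handling suppress the planted counterexamples, and that fusion
arithmetic is conservative. What it does not establish: performance on real
clinical prose — the templates are short, clean sentences; real notes have
section headers, copy-paste, misspellings, and phrasing the seed lexicon
does not cover. The out-of-vocabulary planting (couch surfing at rate 0.05)
exists precisely to keep the dictionary-NER bias visible rather than to
simulate its real magnitude.

## Numerical and design choices

* Round-half-up at 1 d.p. for all reported percentages.
* The fuzzy-address threshold 0.92 was fixed before any testing against the
  generator; the published work is silent on typo handling.
* Z59 sub-codes: the whole Z59* family counts, following the stated use of
  the family; restricting to Z59.0 is a one-line pattern-file change.
* Degenerate inputs: empty encounter lists classify as `none`; an empty
  dataset round-trips; kappa on a single-category matrix raises an
  undefined-kappa error instead of returning 0/0.
* The published triple-overlap percentage (286 of the union printed as
  3.4%) is arithmetically inconsistent with the printed union; the package
  always reports recomputed percentages.
* Published tract deltas (111 missed tracts, 7.8%) imply ~1,423 populated
  tracts; the synthetic world defaults to 100 integer tract ids, so tract
  statistics are structural (missed/increased/conservation), not magnitudes.

## Known limitations

Rule-based segmentation mis-splits abbreviations ("Dr. Smith"); the window
qualifier has no scope model, so a cue can qualify across an intervening
clause; the dictionary NER cannot recognize inflections absent from the
vocabulary; address matching has no geocoding, so two spellings of one
street that normalize differently stay distinct; and elective-homelessness
phrasing ("living on the streets but does have a home") is surfaced as
affirmed evidence — by design, such language is flagged for human review,
not resolved.
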