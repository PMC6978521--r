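---
title: "PGHD workflows over FHIR: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PGHD workflows over FHIR: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pghdflow)
```

## The workflow model

`pghdflow` models patient-generated health data (PGHD) collection as two
mirrored actions mediated by a FHIR R4 server. On the practitioner side, an
instrument hosted in a repository is *requested* for a patient: one
`ServiceRequest` per instrument, carrying either a questionnaire reference
(through a configurable extension) or the instrument's ontological coding,
plus an instant or period-bound weekly/monthly schedule. On the patient
side, each request is resolved back to its instrument, a session is
administered on the device, and the results are encoded as FHIR resources,
packaged into a transaction bundle tagged with the patient (subject) and
requester, and submitted only after explicit consent.

Everything is exercised against an in-memory mock store rather than a live
EHR. The store is a test double: it implements exactly the interactions the
workflow uses (create, read, search by `patient`/`status`, atomic
transaction) behind a stub bearer token, and logs every interaction so
tests can prove a negative — e.g. that withholding consent produces zero
server traffic. The SMART OAuth launch is deliberately out of scope; the
stub token stands in for it.

## Resource model and validation

Resources are element trees (nested lists mirroring FHIR JSON). Two
validation layers exist because they answer different questions:

* `fhir_check_structure()` asks *is this well-formed R4?* It walks a static
  element-definition table (path, cardinality, datatypes) transcribed once
  from the published R4 definitions for the eleven supported resource
  types. Issue codes are closed: `cardinality-min`, `cardinality-max`,
  `wrong-type` (including a choice element populated with several
  variants), and `unknown-element` — the last at warning severity only,
  because FHIR is open-content: unknown elements are preserved verbatim and
  round-trip safely.
* `validate_response()` asks *does this response faithfully reflect its
  questionnaire?* Unknown linkIds, type mismatches (a choice answer must be
  one of the offered options), unanswered required-and-enabled items,
  answers on disabled items, a wrong questionnaire reference, and duplicate
  linkIds. Enabled-ness is recomputed with the same evaluator the session
  engine uses — one evaluator, two call sites — so the generator and the
  validator cannot drift apart.

Serialization is canonical (keys in definition order, UTF-8, no trailing
whitespace), which makes equal trees byte-equal and keeps golden-file and
dual-store comparisons exact. Numbers are normalized to double on parse:
JSON has a single number type, and mixed integer/double representations
would otherwise break tree identity.

## Schedules

All dates are UTC calendar dates; slots are inclusive at day granularity
(surveys are a daily-cadence activity, which makes sub-day timing
immaterial). Weekly slots are consecutive 7-day windows from the
period start, the last truncated at the period end; monthly slots step by
calendar month with rollback clamping at short months (Jan 31 → Feb 28). An
instant request is due immediately and never expires — the alternative (a
same-day deadline) seemed stricter than any clinical reading supports. A
recurring schedule is one `ServiceRequest` with occurrence timing, not one
request per slot. Missed slots stay unfillable: a report fulfils the slot
whose window contains its date, preserving measurement-timing integrity.
Duplicate detection ignores the requester, so a second clinic re-ordering
the same instrument on the same schedule is refused — request fatigue is a
patient-level, not clinic-level, budget.

## Sessions and skip logic

Supported item types: `boolean`, `integer`, `decimal`, `string`, `text`,
`date`, `choice` (single-select), `display`, `group`. Multi-select,
attachment and quantity items are rejected explicitly with the offending
linkId — a bounded interpreter beats a silently lossy one. Groups flatten
into the step stream with the group header retained as a display step.
`enableWhen` supports `=`, `!=` and `exists`; multiple conditions AND
together (the conservative default). Conditions may only reference linkIds
that occur earlier in document order, which makes single-pass
administration sound. The finalized `QuestionnaireResponse` carries one
item per answered (issued and enabled) step; disabled and deliberately
skipped optional items are omitted entirely rather than emitted empty.
Only completed sessions can be reported; partially answered sessions are
not submittable as in-progress responses (the alternative was considered
and rejected to keep report semantics unambiguous).

## The adaptive stand-in

The external computer-adaptive testing provider is replaced by a bundled
reference service so adaptive sessions are testable offline. The model is
ours, chosen to be standard and deterministic, and should not be read as a
reconstruction of any real provider's engine:

* Graded response model. Item *j* with discrimination $a_j$ and strictly
  increasing thresholds $b_{j1} < \dots < b_{jm}$:
  $P^*_{jk}(\theta) = \mathrm{logistic}(a_j(\theta - b_{jk}))$, category
  probabilities $P_{jk} = P^*_{jk} - P^*_{j,k+1}$ with $P^*_{j0} = 1$,
  $P^*_{j,m+1} = 0$.
* Scoring: expected a posteriori under a standard-normal prior on a fixed
  61-point quadrature grid over $[-4, 4]$. With nothing administered the
  estimate is the prior, $(\theta, \mathrm{SE}) = (0, 1)$.
* Selection: the unadministered item maximizing Fisher information
  $I_j(\theta) = \sum_k (\partial P_{jk}/\partial\theta)^2 / P_{jk}$ at the
  current estimate; ties break by bank order.
* Stopping: posterior SD $\le$ 0.3 (the conventional reliability-0.91
  cutoff for T-scored instruments) or bank exhaustion. The completed
  response embeds $50 + 10\hat\theta$ as a score extension.

One numerical note: the EAP posterior SD is *not* guaranteed to shrink at
every single step — an answer inconsistent with the running estimate can
widen the posterior slightly. What is guaranteed, and what the tests
assert, is that Fisher information accumulates additively and the SE ends
well below its prior value of 1.

The wire shape of the next-question exchange is kept behind one adapter:
the client POSTs its in-progress `QuestionnaireResponse` whose `identifier`
carries only a freshly generated random UUID; the service replies with the
same response plus a contained `Questionnaire` that grows by exactly one
item, or with status `completed`. Payloads are retained verbatim on both
sides, so the privacy property — no patient-derived substring ever crosses
the wire — is checked by string-scanning actual transcripts against
high-entropy synthetic patient fields (16-character random tokens; an
accidental substring hit is implausible, so a clean scan is informative).
Authentication is a static Basic credential pair from configuration.

## Encoding matrix

The coding map (`default_coding_map()`, also shipped as
`inst/extdata/coding-map.json`) binds each result kind to its terminology
and its fixed FHIR result shape: LOINC for step count (55423-8) and blood
pressure (panel 85354-9, components 8480-6/8462-4), a project-local system
for active tasks. Units are fixed per kind — steps, mmHg, degrees, seconds
— and mismatches are errors, never conversions: silent unit conversion in
clinical data is how wrong numbers get charted. The Amsler-grid observation
carries a boolean abnormality flag beside the `Media` image; the matrix
fixes only the resource types, and a boolean is the most conservative
scalar summary of a grid finding. Raw task records
(tapping/peg-hole/paced-addition) travel as base64 JSON attachments in a
`DocumentReference`, mirroring how a mobile framework would preserve
sensor-level detail. Phone health-record exports arrive as DSTU2
`Observation`s and are mapped element-wise to R4 (`category` becomes an
array, `comment` becomes `note[].text`, values carry over bit-exact);
other DSTU2 resource types are refused by design in this iteration.

Bundles are `transaction` (atomic), not `collection`: all-or-nothing is the
safer default for clinical writes, and the mock store enforces full
rollback when any entry fails validation. One bundle is emitted per request
fulfilment; per-instrument bundles were the plausible alternative and the
choice is isolated in `assemble_report()`.

## The synthetic world, and what green tests establish

`generate_fixtures()` emulates a hospital repository and its patients:
high-entropy synthetic names/identifiers, static questionnaires with 4–8
mixed-type items and skip logic at density 0.3 (roughly one conditional
item per short survey — typical of PRO instruments), adaptive stubs, and
device ValueSets drawn from the coding map. Item banks default to 8 items
with 5 response options, discriminations in [0.8, 2.5] and centered,
ordered thresholds — the range reported for well-calibrated PRO banks.
Identical seeds give byte-identical corpora, which is what makes the
dual-store reusability comparison exact.

What the synthetic world does *not* emulate: real terminology bindings
beyond the shipped map, profile-level (e.g. US Core) constraints, FHIR
versioning/history/paging, network latency and OAuth. A green suite
establishes that the workflow logic, validation rules and exchanges are
correct over this stated world — not that any specific EHR will accept the
output unchanged.

## Numerical and degenerate-input choices

* Quadrature: 61 equally spaced nodes on $[-4, 4]$; category probabilities
  floored at $10^{-300}$ in log-likelihood accumulation and $10^{-12}$ in
  information denominators to avoid 0/0 at extreme traits.
* The zero-administered EAP returns exactly $(0, 1)$ rather than the
  grid-truncated prior moments (which differ from 1 by <0.2%).
* Empty instrument lists, empty reports, and period ends before starts are
  precondition errors, not empty successes.
* Classification ties: the first mapped coding in a ValueSet wins;
  unclassifiable repository entries are skipped with a warning when
  listing (a shared repository holds other apps' resources) but are hard
  errors when classified directly.

## Known limitations

* The R4 element-definition table covers the eleven resource types the
  workflow touches, with their complete mandatory elements; it is not a
  full StructureDefinition engine and does no terminology validation.
* The DSTU2→R4 mapper handles `Observation` only.
* The adaptive service is unidimensional and returns scores only at
  completion.
* `enableWhen` comparison operators (`>`, `<`, …) and `enableBehavior = "any"`
  are not implemented; conditions AND together.
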