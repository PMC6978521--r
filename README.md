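# pghdflow

Patient-generated health data (PGHD) — validated survey outcomes,
connected-device measurements, sensor-driven active tasks — rarely reaches
the medical record in a standardized form. `pghdflow` implements the full
request-to-report lifecycle over HL7 FHIR R4 as a desk-testable R package,
for health-informatics developers and researchers who need to prototype and
verify standards-compliant PGHD workflows without a live EHR:

* **Instruments** hosted in a FHIR repository are listed and classified into
  four categories: static surveys (`Questionnaire`), computer-adaptive
  surveys (`Questionnaire` + adaptive extension pointing at a next-question
  service), device-recorded measures and active tasks (`ValueSet` codings
  bound through an editable coding map).
* **Requests**: one `ServiceRequest` per instrument, with instant or
  period-bound weekly/monthly schedules carried as occurrence timing, slot
  enumeration, due/overdue status, and duplicate-dispatch protection keyed
  on (patient, instrument, schedule).
* **Sessions**: a headless step interpreter for static questionnaires
  (groups flattened, `enableWhen` skip logic with `=`, `!=`, `exists`, AND
  semantics) and a client for the adaptive next-question exchange that sends
  only a random session UUID — never patient content.
* **Adaptive service**: a bundled, deterministic stand-in for an external
  computer-adaptive testing provider. Items follow the graded response
  model: item *j* with discrimination *a<sub>j</sub>* and thresholds
  *b<sub>j1</sub> < … < b<sub>jm</sub>* has cumulative category
  probabilities *P\*<sub>k</sub>(θ) = logistic(a<sub>j</sub>(θ −
  b<sub>jk</sub>))*; the trait θ is scored by expected a posteriori (EAP)
  under a N(0, 1) prior on a 61-point grid over [−4, 4]; each next item
  maximizes Fisher information *I(θ) = Σ<sub>k</sub> (dP<sub>k</sub>/dθ)² /
  P<sub>k</sub>*; sessions stop at posterior SD ≤ 0.3 or bank exhaustion,
  and the completed response embeds a T-score (50 + 10 θ).
* **Encoding & reporting**: every instrument kind encodes to its fixed FHIR
  result shape (step count → `Observation` integer quantity; blood pressure
  → systolic/diastolic components in mmHg; Tower of Hanoi → boolean; Stroop
  → duration; Amsler grid → `Observation` + `Media`; tapping/peg/paced →
  `Observation` + `DocumentReference`; phone health-record exports are
  mapped DSTU2 → R4). Results are bundled as transaction bundles tagged
  with subject and requester, gated on patient consent, and submitted.
* **Validation**: structural/cardinality checking against a shipped R4
  element-definition table, plus semantic concordance of each
  `QuestionnaireResponse` with its source `Questionnaire`.
* **Testbed**: an in-memory mock FHIR store (create/read/search/transaction,
  stub bearer auth, append-only request log) and a deterministic synthetic
  fixture generator, so everything runs offline.

## Worked example

```r
library(pghdflow)

compute_slots(pghd_schedule("weekly", "2020-01-01", "2020-01-28"))
#> # A tibble: 4 × 4
#>   index start      end        fulfilled
#>   <int> <date>     <date>     <lgl>
#> 1     0 2020-01-01 2020-01-07 FALSE
#> 2     1 2020-01-08 2020-01-14 FALSE
#> 3     2 2020-01-15 2020-01-21 FALSE
#> 4     3 2020-01-22 2020-01-28 FALSE
```

Four seven-day windows tile the 28-day period exactly; a report dated
inside a window marks that slot fulfilled, and `request_status()` derives
due/overdue/completed from the slots and the clock.

```r
set.seed(1)
demo <- pghd_demo_e2e(mock_store(), seed = 1)
demo$summary
#> # A tibble: 9 × 4
#>   request          resourceType          location                            status
#> 1 servicerequest-1 QuestionnaireResponse QuestionnaireResponse/questionna…   submitted
#> 2 servicerequest-2 Observation           Observation/observation-7           submitted
#> 3 servicerequest-3 Observation           Observation/observation-8           submitted
#> ...                                      (5 blood-pressure Observations)
#> 8 servicerequest-4 QuestionnaireResponse QuestionnaireResponse/questionna…   submitted
#> 9 servicerequest-5 QuestionnaireResponse QuestionnaireResponse/questionna…   submitted
```

One seeded world: five instruments (two static surveys, one adaptive
survey, a step-count and a blood-pressure device) are ordered for the first
synthetic patient, administered, encoded and submitted — nine tagged
resources persisted, every one passing `fhir_check_structure()` with zero
errors and retrievable by patient search. Each persisted blood-pressure
`Observation` carries the LOINC panel code 85354-9, systolic/diastolic
components (8480-6 / 8462-4) in mmHg, the patient as subject, the ordering
practitioner as performer, and a `basedOn` link to its `ServiceRequest`.

Adaptive progress is inspectable the broom way:

```r
srv <- adaptive_service(synthetic_item_bank(n_items = 6, seed = 1))
# ... run_adaptive(session, srv, script) ...
tidy(srv)     # per-item trace: linkId, score, running theta and SE
glance(srv)   # one row per session: n_items, theta, se, t_score
autoplot(srv) # SE trajectory per session
```

## Acceptance script

`scripts/acceptance.R` re-runs the whole lifecycle from scratch at a given
seed — fixture generation, request dispatch, static and adaptive sessions,
device import, encoding, consent-gated submission — against two
independently configured mock stores, verifies that the persisted element
trees are identical modulo server-assigned ids and structurally valid, and
writes the machine-readable report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Command line

A thin CLI ships in `inst/cli/pghd`:

```sh
inst/cli/pghd validate <file.json> [--ndjson]   # issues + OperationOutcome
inst/cli/pghd fixtures --seed 7 --out corpus.ndjson
inst/cli/pghd demo --seed 1
```

See `vignette("pghd-workflows")` for the model, tunable parameters, and the
limits of what the synthetic testbed establishes.
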