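[
  {
    "kind": "survey_static",
    "category": "survey_static",
    "system": "urn:pghdflow:survey",
    "code": "static-survey",
    "display": "Static survey",
    "result_types": "QuestionnaireResponse",
    "unit": null
  },
  {
    "kind": "survey_adaptive",
    "category": "survey_adaptive",
    "system": "urn:pghdflow:survey",
    "code": "adaptive-survey",
    "display": "Adaptive survey",
    "result_types": "QuestionnaireResponse",
    "unit": null
  },
  {
    "kind": "step_count",
    "category": "device_recorded",
    "system": "http://loinc.org",
    "code": "55423-8",
    "display": "Number of steps in unspecified time pedometer",
    "result_types": "Observation",
    "unit": "steps"
  },
  {
    "kind": "blood_pressure",
    "category": "device_recorded",
    "system": "http://loinc.org",
    "code": "85354-9",
    "display": "Blood pressure panel with all children optional",
    "result_types": "Observation",
    "unit": "mmHg"
  },
  {
    "kind": "range_of_motion",
    "category": "active_task",
    "system": "urn:pghdflow:active-task",
    "code": "range-of-motion",
    "display": "Range of motion (knee, shoulder)",
    "result_types": "Observation",
    "unit": "deg"
  },
  {
    "kind": "tapping_speed",
    "category": "active_task",
    "system": "urn:pghdflow:active-task",
    "code": "tapping-speed",
    "display": "Tapping speed",
    "result_types": "Observation,DocumentReference",
    "unit": "taps/s"
  },
  {
    "kind": "peg_hole",
    "category": "active_task",
    "system": "urn:pghdflow:active-task",
    "code": "nine-peg-hole",
    "display": "9 peg hole test",
    "result_types": "Observation,DocumentReference",
    "unit": "s"
  },
  {
    "kind": "paced_addition",
    "category": "active_task",
    "system": "urn:pghdflow:active-task",
    "code": "paced-serial-addition",
    "display": "Paced serial addition test",
    "result_types": "Observation,DocumentReference",
    "unit": "{score}"
  },
  {
    "kind": "tower_of_hanoi",
    "category": "active_task",
    "system": "urn:pghdflow:active-task",
    "code": "tower-of-hanoi",
    "display": "Tower of Hanoi",
    "result_types": "Observation",
    "unit": null
  },
  {
    "kind": "stroop",
    "category": "active_task",
    "system": "urn:pghdflow:active-task",
    "code": "stroop-test",
    "display": "Stroop test",
    "result_types": "Observation",
    "unit": "s"
  },
  {
    "kind": "spatial_span",
    "category": "active_task",
    "system": "urn:pghdflow:active-task",
    "code": "spatial-memory-span",
    "display": "Spatial memory span",
    "result_types": "Observation",
    "unit": "{score}"
  },
  {
    "kind": "amsler_grid",
    "category": "active_task",
    "system": "urn:pghdflow:active-task",
    "code": "amsler-grid",
    "display": "Amsler grid",
    "result_types": "Observation,Media",
    "unit": null
  },
  {
    "kind": "health_record",
    "category": "device_recorded",
    "system": "urn:pghdflow:health-record",
    "code": "fhir-dstu2",
    "display": "Phone health-record export (FHIR)",
    "result_types": "Observation",
    "unit": null
  }
]
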