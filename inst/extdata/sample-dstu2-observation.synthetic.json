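{
  "resourceType": "Observation",
  "id": "dstu2-obs-01",
  "status": "final",
  "category": {
    "coding": [
      {
        "system": "http://hl7.org/fhir/observation-category",
        "code": "vital-signs"
      }
    ]
  },
  "code": {
    "coding": [
      {
        "system": "http://loinc.org",
        "code": "29463-7",
        "display": "Body weight"
      }
    ]
  },
  "effectiveDateTime": "2019-06-02",
  "valueQuantity": {
    "value": 57.6,
    "unit": "kg",
    "system": "http://unitsofmeasure.org",
    "code": "kg"
  },
  "comment": "self-measured, reading 1"
}
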