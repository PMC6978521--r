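[
  {
    "linkId": "itm-01",
    "text": "Synthetic bank item 1",
    "discrimination": 2.48114580635447,
    "thresholds": [-0.876169297471643, -0.541294958116487, -0.11942026282195],
    "options": [
      {
        "system": "urn:pghdflow:adaptive-option",
        "code": "itm-01-opt-0",
        "display": "Option 0"
      },
      {
        "system": "urn:pghdflow:adaptive-option",
        "code": "itm-01-opt-1",
        "display": "Option 1"
      },
      {
        "system": "urn:pghdflow:adaptive-option",
        "code": "itm-01-opt-2",
        "display": "Option 2"
      },
      {
        "system": "urn:pghdflow:adaptive-option",
        "code": "itm-01-opt-3",
        "display": "Option 3"
      }
    ]
  },
  {
    "linkId": "itm-02",
    "text": "Synthetic bank item 2",
    "discrimination": 2.14641772389878,
    "thresholds": [-0.678719338355586, -0.295791596081108, 0.23376023680903],
    "options": [
      {
        "system": "urn:pghdflow:adaptive-option",
        "code": "itm-02-opt-0",
        "display": "Option 0"
      },
      {
        "system": "urn:pghdflow:adaptive-option",
        "code": "itm-02-opt-1",
        "display": "Option 1"
      },
      {
        "system": "urn:pghdflow:adaptive-option",
        "code": "itm-02-opt-2",
        "display": "Option 2"
      },
      {
        "system": "urn:pghdflow:adaptive-option",
        "code": "itm-02-opt-3",
        "display": "Option 3"
      }
    ]
  },
  {
    "linkId": "itm-03",
    "text": "Synthetic bank item 3",
    "discrimination": 1.09197173055727,
    "thresholds": [-1.21268561992329, -0.864534849091433, -0.337810964044183],
    "options": [
      {
        "system": "urn:pghdflow:adaptive-option",
        "code": "itm-03-opt-0",
        "display": "Option 0"
      },
      {
        "system": "urn:pghdflow:adaptive-option",
        "code": "itm-03-opt-1",
        "display": "Option 1"
      },
      {
        "system": "urn:pghdflow:adaptive-option",
        "code": "itm-03-opt-2",
        "display": "Option 2"
      },
      {
        "system": "urn:pghdflow:adaptive-option",
        "code": "itm-03-opt-3",
        "display": "Option 3"
      }
    ]
  },
  {
    "linkId": "itm-04",
    "text": "Synthetic bank item 4",
    "discrimination": 0.943991211988032,
    "thresholds": [-0.277984231803566, 0.51488431354519, 0.973176715592854],
    "options": [
      {
        "system": "urn:pghdflow:adaptive-option",
        "code": "itm-04-opt-0",
        "display": "Option 0"
      },
      {
        "system": "urn:pghdflow:adaptive-option",
        "code": "itm-04-opt-1",
        "display": "Option 1"
      },
      {
        "system": "urn:pghdflow:adaptive-option",
        "code": "itm-04-opt-2",
        "display": "Option 2"
      },
      {
        "system": "urn:pghdflow:adaptive-option",
        "code": "itm-04-opt-3",
        "display": "Option 3"
      }
    ]
  },
  {
    "linkId": "itm-05",
    "text": "Synthetic bank item 5",
    "discrimination": 1.88706320126075,
    "thresholds": [-0.845755211520009, -0.0927445513894781, 0.70162502063904],
    "options": [
      {
        "system": "urn:pghdflow:adaptive-option",
        "code": "itm-05-opt-0",
        "display": "Option 0"
      },
      {
        "system": "urn:pghdflow:adaptive-option",
        "code": "itm-05-opt-1",
        "display": "Option 1"
      },
      {
        "system": "urn:pghdflow:adaptive-option",
        "code": "itm-05-opt-2",
        "display": "Option 2"
      },
      {
        "system": "urn:pghdflow:adaptive-option",
        "code": "itm-05-opt-3",
        "display": "Option 3"
      }
    ]
  }
]
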