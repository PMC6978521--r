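{
  "resourceType": "Questionnaire",
  "id": "static-q-01",
  "url": "urn:pghdflow:questionnaire:static-q-01",
  "title": "Synthetic static survey static-q-01",
  "status": "active",
  "item": [
    {
      "linkId": "static-q-01-item-01",
      "text": "Synthetic question 1",
      "type": "boolean",
      "required": true
    },
    {
      "linkId": "static-q-01-item-02",
      "text": "Synthetic question 2",
      "type": "boolean",
      "enableWhen": [
        {
          "question": "static-q-01-item-01",
          "operator": "=",
          "answerBoolean": false
        }
      ],
      "required": false
    },
    {
      "linkId": "static-q-01-item-03",
      "text": "Synthetic question 3",
      "type": "boolean",
      "enableWhen": [
        {
          "question": "static-q-01-item-01",
          "operator": "=",
          "answerBoolean": false
        }
      ],
      "required": false
    },
    {
      "linkId": "static-q-01-item-04",
      "text": "Synthetic question 4",
      "type": "choice",
      "enableWhen": [
        {
          "question": "static-q-01-item-02",
          "operator": "=",
          "answerBoolean": true
        }
      ],
      "required": false,
      "answerOption": [
        {
          "valueCoding": {
            "system": "urn:pghdflow:answers",
            "code": "static-q-01-item-04-opt-1",
            "display": "Choice 1"
          }
        },
        {
          "valueCoding": {
            "system": "urn:pghdflow:answers",
            "code": "static-q-01-item-04-opt-2",
            "display": "Choice 2"
          }
        },
        {
          "valueCoding": {
            "system": "urn:pghdflow:answers",
            "code": "static-q-01-item-04-opt-3",
            "display": "Choice 3"
          }
        }
      ]
    },
    {
      "linkId": "static-q-01-item-05",
      "text": "Synthetic question 5",
      "type": "integer",
      "enableWhen": [
        {
          "question": "static-q-01-item-03",
          "operator": "=",
          "answerBoolean": true
        }
      ],
      "required": true
    },
    {
      "linkId": "static-q-01-item-06",
      "text": "Synthetic question 6",
      "type": "integer",
      "enableWhen": [
        {
          "question": "static-q-01-item-01",
          "operator": "=",
          "answerBoolean": false
        }
      ],
      "required": true
    }
  ]
}
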