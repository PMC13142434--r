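[
  {
    "type": "CategoricalVariant",
    "id": "catvar-braf-v600e-protein",
    "label": "BRAF V600E",
    "declaredProfile": "ProteinSequenceConsequence",
    "constraints": [
      {
        "type": "DefiningAlleleConstraint",
        "allele": {
          "type": "Allele",
          "location": {
            "type": "SequenceLocation",
            "sequenceId": "NP_004324.2",
            "start": 599,
            "end": 600
          },
          "state": "E"
        }
      }
    ]
  }
]
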