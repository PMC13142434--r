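[
  {
    "type": "CategoricalVariant",
    "id": "catvar-tp53-cnloss",
    "label": "TP53 CNLoss",
    "declaredProfile": "CategoricalCNV",
    "constraints": [
      {
        "type": "FeatureContextConstraint",
        "feature": "TP53"
      },
      {
        "type": "DefiningLocationConstraint",
        "location": {
          "type": "SequenceLocation",
          "sequenceId": "GRCh38:chr17",
          "start": 7668402,
          "end": 7687538
        },
        "matchMode": "OVERLAPS"
      },
      {
        "type": "CopyChangeConstraint",
        "copyChange": "LOSS"
      }
    ]
  }
]
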