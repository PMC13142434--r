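[
  {
    "type": "CategoricalVariant",
    "id": "catvar-bcr-abl1-fusion",
    "label": "BCR::ABL1 fusion",
    "declaredProfile": "GeneFusion",
    "constraints": [
      {
        "type": "FeatureContextConstraint",
        "feature": "BCR"
      },
      {
        "type": "FeatureContextConstraint",
        "feature": "ABL1"
      },
      {
        "type": "AdjacencyConstraint",
        "sideA": "BCR",
        "sideB": "ABL1",
        "ordered": true
      }
    ]
  }
]
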