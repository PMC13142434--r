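[
  {
    "type": "CategoricalVariant",
    "id": "catvar-pten-lof",
    "label": "PTEN loss-of-function variants",
    "declaredProfile": "FunctionVariant",
    "constraints": [
      {
        "type": "FeatureContextConstraint",
        "feature": "PTEN"
      },
      {
        "type": "FunctionConstraint",
        "term": "loss_of_function",
        "useHierarchy": true
      }
    ]
  }
]
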