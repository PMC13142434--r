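[
  {
    "type": "CategoricalVariant",
    "id": "catvar-braf-v600e-genomic",
    "label": "BRAF c.1799T>A (genomic)",
    "declaredProfile": "CanonicalAllele",
    "constraints": [
      {
        "type": "DefiningAlleleConstraint",
        "allele": {
          "type": "Allele",
          "location": {
            "type": "SequenceLocation",
            "sequenceId": "GRCh38:chr7",
            "start": 140753335,
            "end": 140753336
          },
          "state": "T"
        }
      }
    ]
  }
]
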