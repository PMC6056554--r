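{
  "mode": "Access",
  "declaredUses": {
    "research_disease_specific": [
      "cancer"
    ]
  },
  "acceptedTerms": [
    "no_collaboration_terms"
  ]
}
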