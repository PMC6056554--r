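{
  "adamVersion": "1.0",
  "header": {
    "profile_id": "CANCER-RES-0001",
    "profile_version": "2026-09-19/1.0",
    "resource_reference": "doi:10.5072/synthetic-cancer-cohort",
    "resource_name": "Synthetic cancer cohort (demonstration)"
  },
  "bodies": [
    {
      "permissions": {
        "research_disease_specific": {
          "value": "Limited",
          "freeText": "Use permitted for research on diseases cancer, and melanoma"
        },
        "profit_use": {
          "value": "Forbidden"
        }
      },
      "terms": {
        "no_collaboration_terms": {
          "value": "Untrue",
          "freeText": "Co-authorship with the resource custodian is required"
        }
      },
      "meta": {
        "mode_of_sharing": {
          "value": "Discovery and Access"
        }
      }
    }
  ]
}
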