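{
  "adamVersion": "1.0",
  "header": {
    "profile_id": "MINIMAL-0001",
    "profile_version": "2026-09-19/1.0",
    "resource_reference": "doi:10.5072/synthetic-minimal"
  },
  "bodies": [
    {
      "permissions": {
        "research_use": {
          "value": "Unrestricted"
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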