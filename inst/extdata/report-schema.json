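{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "dtcprs run report",
  "description": "Machine-readable summary of one processed genome. Keyed by the anonymous identifier; never contains an email address, the uploaded filename, or raw genotype calls.",
  "type": "object",
  "required": ["unique_id", "vendor_dialect", "qc", "ancestry", "scores",
               "tool_version", "timestamp"],
  "properties": {
    "unique_id": {"type": "string", "pattern": "^id_[0-9a-z]{9}$"},
    "vendor_dialect": {"enum": ["23andme", "ancestry", "myheritage", "generic"]},
    "source_digest": {"type": "string", "pattern": "^[0-9a-f]{32}$"},
    "qc": {
      "type": "object",
      "properties": {
        "total_lines": {"type": "integer"},
        "n_calls": {"type": "integer"},
        "n_missing": {"type": "integer"},
        "n_rejected": {"type": "integer"},
        "yield": {"type": "number"},
        "yield_pass": {"type": "boolean"},
        "harmonization": {"type": "object"}
      }
    },
    "ancestry": {
      "type": "object",
      "properties": {
        "label": {"enum": ["AFR", "AMR", "EAS", "EUR", "SAS"]},
        "margin": {"type": "number"},
        "n_sites": {"type": "integer"},
        "assigned": {"type": "boolean"}
      }
    },
    "scores": {
      "type": "array",
      "items": {
        "type": "object",
        "properties": {
          "trait_id": {"type": "string"},
          "raw_sum": {"type": "number"},
          "zero_centered": {"type": "number"},
          "z_score": {"type": "number"},
          "population": {"enum": ["AFR", "AMR", "EAS", "EUR", "SAS"]},
          "scaling": {"enum": ["ANALYTIC_1KG", "EMPIRICAL"]},
          "n_used": {"type": "integer"},
          "n_frequency_filled": {"type": "integer"},
          "n_missing": {"type": "integer"}
        }
      }
    },
    "tool_version": {"type": "string"},
    "timestamp": {"type": "string"}
  }
}
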