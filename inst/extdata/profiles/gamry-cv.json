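{
  "profile_id": "gamry-cv",
  "identifiers": [
    {"scope": "filename", "pattern": "\\.[Dd][Tt][Aa]$", "required": true},
    {"scope": "header", "pattern": "^TAG=CV$", "required": false},
    {"scope": "table-name", "pattern": "^CURVE", "required": false}
  ],
  "data_map": {
    "table": 1,
    "x_column": "Vf",
    "y_column": "Im",
    "t_column": "T"
  },
  "metadata_map": [
    {"source": "SCANRATE", "target": "scan_rate",
     "transform": {"type": "scale", "factor": 1}},
    {"source": "TEMPERATURE", "target": "temperature"},
    {"source": "TITLE", "target": "sample_id"},
    {"source": "computed:potential_window", "target": "potential_vertex1"},
    {"source": "computed:n_cycles", "target": "n_cycles"}
  ],
  "output_policy": "one-file-per-cycle"
}
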