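{
  "profile_id": "palmsens-cv",
  "identifiers": [
    {"scope": "filename", "pattern": "\\.[Cc][Ss][Vv]$", "required": true},
    {"scope": "header", "pattern": "^method=", "required": false}
  ],
  "data_map": {
    "table": "data",
    "x_column": "potential",
    "y_column": "current",
    "t_column": "time"
  },
  "metadata_map": [
    {"source": "scan_rate", "target": "scan_rate"},
    {"source": "instrument", "target": "instrument_model"},
    {"source": "computed:n_cycles", "target": "n_cycles"}
  ],
  "output_policy": "one-file-per-cycle"
}
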