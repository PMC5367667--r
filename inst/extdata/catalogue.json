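{
  "format": "tnm-staging-catalogue",
  "version": 1,
  "tables": [
    {
      "tumor_type": "lung",
      "selectors": {},
      "file": "lung.json"
    }
  ]
}
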