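{
  "title": "fearsis equilibria report",
  "required": ["R0", "pdpf", "flags"],
  "required_flags": ["pfp_exists", "pfp_degenerate", "cep_exists"]
}
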