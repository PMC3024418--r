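{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "HaploPop pipeline report",
  "type": "object",
  "required": ["seed", "n", "nHaplotypes", "sharing", "diversity",
               "rarefaction", "snn", "neutrality", "network", "parsimony"],
  "properties": {
    "seed": {"type": "integer"},
    "n": {"type": "integer"},
    "nHaplotypes": {"type": "integer"},
    "sharing": {"type": "object"},
    "diversity": {"type": ["array", "object"]},
    "rarefaction": {"type": "object"},
    "snn": {"type": "object"},
    "neutrality": {"type": "object"},
    "network": {"type": "object"},
    "parsimony": {"type": "object"},
    "parsimonyScores": {"type": "object"}
  }
}
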