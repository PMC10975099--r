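# Example dialect config: maps each checker's severity vocabulary onto the
# unified 0-4 interaction-strength scale. An entry is either a code, or a
# map with `default` and `recommendations` for labels that split by the
# professional recommendation text.
webmd:
  "0 Interactions Found": 0
  "Unknown": 0
  "Minor": 1
  "Monitor closely": 2
  "Serious": 3
  "Don't use together": 4
drugscom:
  "Unknown": 0
  "No interactions found": 0
  "Minor": 1
  "Moderate": 2
  "Major":
    default: 3
    recommendations:
      "Contraindicated": 4
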