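{
  "label": "hemorrhage",
  "rgb": [255, 0, 0],
  "coded_category": {
    "scheme": "SCT",
    "value": "49755003",
    "meaning": "Morphologically altered structure"
  },
  "coded_type": {
    "scheme": "SCT",
    "value": "50960005",
    "meaning": "Hemorrhage"
  },
  "segment_number": 1
}
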