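{
  "habitat": {
    "NumberOfCells": 200,
    "NumberOfRsrcsInEachCell": 25,
    "Distribution": "100r"
  },
  "species": [
    {
      "id": "warbler",
      "NumberOfItems": 400,
      "DirectOffspring": 2,
      "IndirectOffspring": 2
    },
    {
      "id": "cuckoo",
      "NumberOfItems": 40,
      "DirectOffspring": 0,
      "IndirectOffspring": -2,
      "Distribution": "100r"
    }
  ],
  "interactions": [
    { "species_a": "cuckoo", "species_b": "warbler" }
  ],
  "generations": 200,
  "seed": 1
}
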