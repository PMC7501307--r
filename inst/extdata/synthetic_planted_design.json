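{
  "codes": {
    "A": "11111",
    "R": "00000",
    "N": "10101",
    "D": "11000",
    "C": "01010",
    "Q": "11100",
    "E": "10111",
    "G": "00100",
    "H": "11001",
    "I": "00110",
    "L": "01111",
    "K": "10100",
    "M": "10000",
    "F": "01000",
    "P": "00011",
    "S": "00101",
    "T": "00111",
    "W": "11011",
    "Y": "11010",
    "V": "01011"
  },
  "planted_accessions": ["PLNT0001", "PLNT0002", "PLNT0003", "PLNT0004", "PLNT0005"],
  "noise_accessions": ["NOIS0001", "NOIS0002", "NOIS0003"],
  "f": 5,
  "seed": 424242,
  "balanced": true
}
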