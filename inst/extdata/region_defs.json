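{
  "nasopharyngeal": {
    "S": {"structure": "brainstem",   "face": "S"},
    "I": {"structure": "mandible",    "face": "S"},
    "A": {"structure": "mandible",    "face": "A"},
    "P": {"structure": "spinal_cord", "face": "A"},
    "L": {"structure": "body",        "face": "L"},
    "R": {"structure": "body",        "face": "R"}
  },
  "oropharynx": {
    "S": {"structure": "mandible",    "face": "S"},
    "I": {"structure": "hyoid",       "face": "S"},
    "A": {"structure": "mandible",    "face": "A"},
    "P": {"structure": "spinal_cord", "face": "A"},
    "L": {"structure": "body",        "face": "L"},
    "R": {"structure": "body",        "face": "R"}
  },
  "tongue_base": {
    "S": {"structure": "mandible",    "face": "S"},
    "I": {"structure": "hyoid",       "face": "I"},
    "A": {"structure": "mandible",    "face": "A"},
    "P": {"structure": "hyoid",       "face": "P"},
    "L": {"structure": "body",        "face": "L"},
    "R": {"structure": "body",        "face": "R"}
  },
  "hypopharynx": {
    "S": {"structure": "hyoid",       "face": "I"},
    "I": {"structure": "cricoid",     "face": "I"},
    "A": {"structure": "cricoid",     "face": "A"},
    "P": {"structure": "spinal_cord", "face": "A"},
    "L": {"structure": "body",        "face": "L"},
    "R": {"structure": "body",        "face": "R"}
  },
  "carotid_space": {
    "S": {"structure": "mandible",    "face": "I"},
    "I": {"structure": "cricoid",     "face": "I"},
    "A": {"structure": "hyoid",       "face": "A"},
    "P": {"structure": "spinal_cord", "face": "P"},
    "L": {"structure": "body",        "face": "L"},
    "R": {"structure": "body",        "face": "R"}
  }
}
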