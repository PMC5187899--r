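{
  "dialect": "expasy-peptidecutter",
  "version": "1.0",
  "comment": "Positional cleavage-rule tables. 'p1' enzymes cleave after a residue in p1 unless p1prime is in the blocked set for that residue; 'cleave_triplets' (P2,P1,P1') override a block, 'block_triplets' veto an otherwise allowed site (Keil exceptions). 'pepsin' enzymes use the two-clause context rule over P3..P2': clause A cleaves when P3 not in {H,K,R}, P2 != P, P1 != R, P1' in 'set', P2' != P; clause B cleaves when P3 not in {H,K,R}, P2 != P, P1 in 'set', P1' present, P2' != P. Context positions named in a clause must exist.",
  "enzymes": {
    "trypsin": {
      "type": "p1",
      "blocked": { "K": "P", "R": "P" },
      "cleave_triplets": ["WKP", "MRP"],
      "block_triplets": ["CKD", "DKD", "CKH", "CKY", "CRK", "RRH", "RRR"]
    },
    "chymotrypsin_high": {
      "type": "p1",
      "blocked": { "F": "P", "Y": "P", "W": "MP" },
      "cleave_triplets": [],
      "block_triplets": []
    },
    "chymotrypsin_low": {
      "type": "p1",
      "blocked": { "F": "P", "L": "P", "Y": "P", "W": "MP", "M": "PY", "H": "DMPW" },
      "cleave_triplets": [],
      "block_triplets": []
    },
    "pepsin_pH1.3": { "type": "pepsin", "set": "FL" },
    "pepsin_pH>2": { "type": "pepsin", "set": "FLWY" }
  }
}
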