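{
  "target": "ACE",
  "comment": "Synthetic reconstruction of a four-feature ACE-inhibitor pharmacophore (A/D/N/H) arranged as in the lisinopril binding mode at the ACE C-domain active site: negative ionizable group toward the catalytic Zn2+, donor toward the ALA354 backbone carbonyl, acceptor toward the HIS353/HIS513 pocket, hydrophobe in the VAL518 S1' pocket. Coordinates are constructed, not published model data.",
  "features": [
    { "type": "NEG_IONIZABLE", "center": [0.0, 0.0, 0.0], "radius": 1.5, "weight": 1 },
    { "type": "HBD", "center": [3.0, 1.2, 0.8], "radius": 1.5, "weight": 1 },
    { "type": "HBA", "center": [2.2, -2.0, 1.0], "radius": 1.5, "weight": 1 },
    { "type": "HYDROPHOBE", "center": [-3.5, 1.8, -0.5], "radius": 1.7, "weight": 1 }
  ]
}
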