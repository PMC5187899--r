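# Known bioactive oligopeptides matched by the in-silico digestion pipeline.
# One row per (sequence, bioactivity); a sequence may appear more than once.
sequence,bioactivity,source
VAY,ACE inhibition,literature
PL,ACE inhibition,literature
SF,ACE inhibition,literature
IF,ACE inhibition,literature
AR,ACE inhibition,literature
EY,ACE inhibition,literature
AY,ACE inhibition,literature
AF,ACE inhibition,literature
GF,ACE inhibition,literature
SY,ACE inhibition,literature
AY,Antioxidation,literature
VL,Glucose uptake stimulation,literature
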