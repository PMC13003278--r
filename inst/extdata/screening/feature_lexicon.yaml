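# Feature id -> synonyms (lowercase). Unit tokens that are unambiguous for a
# feature (e.g. khz, oersted) are listed as synonyms so that sentences like
# "at 300 khz" are attributed without a spelled-out feature name.
H:
  - "field amplitude"
  - "magnetic field amplitude"
  - "amf amplitude"
  - "applied field"
  - "field strength"
  - "oe"
f:
  - "frequency"
  - "khz"
  - "mhz"
C_SPION:
  - "concentration"
  - "mg ml-1"
  - "mg/ml"
T:
  - "temperature"
d_TEM:
  - "core diameter"
  - "particle size"
  - "particle diameter"
  - "mean diameter"
Ms:
  - "saturation magnetization"
  - "saturation magnetisation"
Hc:
  - "coercivity"
  - "coercive field"
Mr:
  - "remanence"
  - "remanent magnetization"
SAR:
  - "sar"
  - "specific absorption rate"
  - "specific loss power"
  - "heating power"
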