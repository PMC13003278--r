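# Feature id -> mapping of unit surface form (lowercase, ascii minus) to the
# canonical unit string.
H:
  "oe": "Oe"
  "oersted": "Oe"
  "ka m-1": "kA/m"
  "ka/m": "kA/m"
  "mt": "mT"
f:
  "khz": "kHz"
  "mhz": "MHz"
  "hz": "Hz"
C_SPION:
  "mg ml-1": "mg/mL"
  "mg/ml": "mg/mL"
  "g l-1": "g/L"
T:
  "k": "K"
d_TEM:
  "nm": "nm"
Ms:
  "emu g-1": "emu/g"
  "emu/g": "emu/g"
  "emu cm-3": "emu/cm3"
  "am2 kg-1": "Am2/kg"
  "ka m-1": "kA/m"
Hc:
  "oe": "Oe"
  "mt": "mT"
  "ka m-1": "kA/m"
Mr:
  "emu g-1": "emu/g"
  "emu/g": "emu/g"
SAR:
  "w g-1": "W/g"
  "w/g": "W/g"
  "w gfe-1": "W/gFe"
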