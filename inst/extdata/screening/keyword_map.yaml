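# Default screening keyword-to-weight map (word n-grams, lowercase).
# Replace with a corpus-specific map for real screening runs.
"superparamagnetic iron oxide": 5
"iron oxide": 3
"magnetic hyperthermia": 5
"hyperthermia": 3
"specific absorption rate": 5
"sar": 2
"ferrite": 2
"nanoparticle": 1
"nanoparticles": 1
"alternating magnetic field": 4
"magnetic field": 2
"heating efficiency": 3
"intrinsic loss power": 3
"magnetite": 2
"spion": 3
"spions": 3
"calorimetric": 2
"magnetization": 1
"coercivity": 1
"heat dissipation": 2
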