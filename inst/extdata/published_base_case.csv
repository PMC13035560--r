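scenario,strategy,cost,effect
base,triclofos,11.41,0.940
base,midazolam,114.46,0.792
base,dexmedetomidine,75.97,0.933
base,propofol,114.26,0.972
base,general_anesthesia,415.18,0.980
fee270,triclofos,12.29,0.940
fee270,midazolam,159.87,0.792
fee270,dexmedetomidine,90.60,0.933
fee270,propofol,332.61,0.972
fee270,general_anesthesia,415.18,0.980
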