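sInstrument    R-AXIS IV
a3fPhi         0.0 0.0 1.0
a3fCircle      0.0 0.0 0.0
a4cSpindle
nIP_num        2
ImhCompression RATIO 8
nFast          3000
nSlow          3000
fPixelSize     100.0
a2fXray1       1500.0
a2fXray2       1500.0
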