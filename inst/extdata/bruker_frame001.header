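FORMAT : 86
DETTYPE: PLATINUM135
NROWS  : 1024
NCOLS  : 1024
PIXSIZE: 89.99
NPIXELB: 1
NEXP   : 1 0 0 32 0
CCDPARM: 3.83 1.00 0.00 0.00 350000.0
CENTER : 512.25 511.70
ANGLES : 0.0 358.75 0.0 0.0
AXIS   : 3
INCREME: 0.5
MACH3  : KAPPA
KAPPA  : 50.0
CORRECT: 0138_1024_180s._fl
WARFIL : 0138_1024_180s._ix
DARK   : 0138_01024_00010._dk
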