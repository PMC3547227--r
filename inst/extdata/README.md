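# Header fixture grammars

The two files here are plain-text reconstructions of the information
content of real detector image headers.  They are **synthetic
fixtures**: the binary layouts of the real R-AXIS and Bruker formats
are not reproduced, only the fields a data-processing program extracts,
one record per line, UTF-8.

## R-AXIS dialect (`raxis_scan001.header`)

`key value value ...`, whitespace separated.

| key              | meaning                                              |
|------------------|------------------------------------------------------|
| `a3fPhi`         | spindle start, offset, rotation range per frame (deg)|
| `a3fCircle`      | goniometer start angles: omega, chi, swing theta     |
| `a4cSpindle`     | spindle orientation (`cw`/`ccw`); often left empty   |
| `nIP_num`        | image-plate count (two plates alternate)             |
| `ImhCompression` | overflow handling; `RATIO R`: stored values >= 32768 decode to `(v - 32768) * R` |
| `nFast`,`nSlow`  | pixel counts (mandatory)                             |
| `fPixelSize`     | pixel size, micrometres (mandatory)                  |
| `a2fXray1/2`     | direct-beam centre, fast/slow pixel coordinates      |

No gain field exists in this dialect (gain defaults to 1.0
ADU/photon), and neither the fast/slow axis convention nor the
goniometer axis layout is recorded — both are audit findings.

## Bruker dialect (`bruker_frame001.header`)

`KEY : values`, colon separated.

| key       | meaning                                                   |
|-----------|-----------------------------------------------------------|
| `ANGLES`  | goniometer start angles in order 2theta, omega, phi, chi  |
| `AXIS`    | scan axis code: 2 = omega, 3 = phi                        |
| `NPIXELB` | bytes per stored pixel (mandatory); 1-byte storage uses a 255 sentinel plus an end-of-image overflow table |
| `NEXP`    | exposure record; 4th numeric field = baseline offset (ADU)|
| `CCDPARM` | CCD parameters; 1st numeric field = gain (ADU/photon)     |
| `CENTER`  | beam centre (pixels)                                      |
| `INCREME` | rotation per frame (deg)                                  |
| `NROWS`,`NCOLS`,`PIXSIZE` | geometry (mandatory); pixel size in um    |
| `MACH3`,`KAPPA` | goniometer model / fixed kappa angle                |
| `CORRECT`,`WARFIL`,`DARK` | flood-field, unwarp and dark-current correction references |
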