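{
  "comment": "Microstructural dMRI protocol: conventional DWI-style PGSE, long-Delta PGSE, cosine OGSE at nominal 17/33 Hz. Printed TE of the DWI row (59.5 ms) cannot host delta+Delta=62 ms, so the waveform window uses 63 ms and the printed value is kept as te_printed_ms. Printed effective td values are stored verbatim; computed td uses the timings. The DWI row prints no b list; the standard two-point 0/1000 set is used.",
  "gamma": 2.675e8,
  "sequences": [
    {
      "label": "DWI",
      "family": "pgse",
      "delta_ms": 18.0,
      "Delta_ms": 44.0,
      "TE_ms": 63.0,
      "te_printed_ms": 59.5,
      "td_printed_ms": 36.8,
      "b_values_s_mm2": [0, 1000]
    },
    {
      "label": "PGSE",
      "family": "pgse",
      "delta_ms": 15.9,
      "Delta_ms": 119.2,
      "TE_ms": 145.0,
      "td_printed_ms": 26.7,
      "b_values_s_mm2": [0, 250, 500, 750, 1000, 1400, 1800]
    },
    {
      "label": "OGSE_17Hz",
      "family": "ogse",
      "delta_ms": 64.2,
      "Delta_ms": 72.7,
      "n_cycles": 1,
      "f_nominal_hz": 17,
      "TE_ms": 145.0,
      "td_printed_ms": 15.0,
      "b_values_s_mm2": [0, 250, 500, 750, 1000]
    },
    {
      "label": "OGSE_33Hz",
      "family": "ogse",
      "delta_ms": 64.2,
      "Delta_ms": 72.7,
      "n_cycles": 2,
      "f_nominal_hz": 33,
      "TE_ms": 145.0,
      "td_printed_ms": 7.5,
      "b_values_s_mm2": [0, 100, 200, 300]
    }
  ]
}
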