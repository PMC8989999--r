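# Demo pipeline config: three reporter channels, three conditions
# (labels follow the pH 7.6 / pH 5.8 + lysine / pH 4.4 time-course design).
seed: 42
out_dir: "."
quant:
  crosstalk_factor: 0.456
  crosstalk:
    receiver: gad      # eGFP receives bleed-through
    donor: adi         # from the CFP-like donor (mCerulean)
stats:
  pairs:
    - [gad, cad]
    - [adi, gad]
    - [adi, cad]
conditions:
  - name: "pH7.6_t0"
    time_min: 0
    n_fields: 2
    cells_per_field: 150
    background_mean: 8
    background_sd: 1
    channels:
      - {name: gad, fluorophore: eGFP,      on_fraction: 0.10, family: normal,    loc: 60,  scale: 15, off_level: 5}
      - {name: adi, fluorophore: mCerulean, on_fraction: 0.05, family: normal,    loc: 40,  scale: 10, off_level: 5}
      - {name: cad, fluorophore: mCherry,   on_fraction: 0.05, family: lognormal, loc: 4.0, scale: 0.5, off_level: 5}
  - name: "pH5.8_Lys_t150"
    time_min: 150
    n_fields: 2
    cells_per_field: 150
    background_mean: 8
    background_sd: 1
    channels:
      - {name: gad, fluorophore: eGFP,      on_fraction: 0.60, family: normal,    loc: 120, scale: 25, off_level: 5}
      - {name: adi, fluorophore: mCerulean, on_fraction: 0.30, family: normal,    loc: 80,  scale: 18, off_level: 5}
      - {name: cad, fluorophore: mCherry,   on_fraction: 0.83, family: lognormal, loc: 4.8, scale: 0.7, off_level: 5}
  - name: "pH4.4_t300"
    time_min: 300
    n_fields: 2
    cells_per_field: 150
    background_mean: 8
    background_sd: 1
    channels:
      - {name: gad, fluorophore: eGFP,      on_fraction: 0.99, family: normal,    loc: 200, scale: 35, off_level: 5}
      - {name: adi, fluorophore: mCerulean, on_fraction: 0.477, family: normal,   loc: 110, scale: 22, off_level: 5}
      - {name: cad, fluorophore: mCherry,   on_fraction: 0.83, family: lognormal, loc: 5.2, scale: 0.8, off_level: 5}
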