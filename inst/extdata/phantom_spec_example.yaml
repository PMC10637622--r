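# Example phantom spec for `qvbridge phantom --spec <this file> --out <dir>`.
rows: 64
cols: 64
n_slices: 40
pixel_spacing_mm: [0.8, 0.8]
slice_thickness_mm: 3.0
origin_mm: [-100, -80, 50]
background_hu: 0
series_description: "ABD PEL Portal Venous 3.0mm"
seed: 1
lesions:
  - center_mm: [-74.4, -55.2, 110]
    radii_mm: [16, 12, 20]
    hu: 60
    label_value: 1
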