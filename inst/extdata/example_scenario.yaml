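# Example dccsim scenario: right fronto-parietal circular craniectomy,
# radius 40 mm, 10% whole-brain swelling on the idealized adult head.
geometry:
  semi_axes: [80, 66, 59]   # mm; ~1.3 l cavity
  h_mm: 16                  # target element size, mm
openings:
  - kind: unilateral_circular
    radius_mm: 40
    axis: [1, 0, 0.35]      # centroid -> opening centre direction
material:
  mu: 1.0e4                 # shear modulus, Pa
  Kbulk: 3.0e4              # bulk modulus, Pa
  k_hyd: 6.7e-12            # tissue hydraulic conductivity, m^2/(Pa s)
vascular:
  Lp: 2.7e-12               # vascular wall conductivity, m/(Pa s)
  SV: 7000                  # vascular density, 1/m
  pv: 4000                  # microvascular pressure, Pa
  Lpl: 3.75e-4              # lymphatic wall conductivity, m/(Pa s)
  SlVl: 7000                # lymphatic density, 1/m
  pl: 0                     # lymphatic pressure, Pa
swelling:
  lambda_g: 1.1             # growth stretch ratio (10% linear swelling)
  injured_regions: whole_brain
solver:
  n_load_steps: 5
icp_method: avg_total_pressure
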