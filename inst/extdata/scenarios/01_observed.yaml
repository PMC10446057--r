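name: observed
description: >
  Observed powder-pouring shift in a naturally ventilated paint factory:
  2000 kg TiO2 from big bags, 260 kg TiO2 and 422 kg Micro Mica from
  small bags, followed by a simulated emission-free cleaning phase.
environment:
  V_room: {kind: uniform, min: 1300, max: 1500}
  AER: {kind: uniform, min: 2, max: 8}
  V_NF: {kind: uniform, min: 1, max: 2}
  beta: {kind: triangular, min: 0.649, mode: 3.2, max: 10}
Q_lev: 0
gap: 0
N_iterations: 10000
oelvs:
  TiO2: 10
  MicroMica: 5
  inorganic_dust: 5
tasks:
  - name: "TiO2 big bags"
    substance: TiO2
    n_repetitions: 4
    t_pouring: {kind: uniform, min: 21, max: 25}
    t_G: {kind: uniform, min: 11, max: 13}
    G: {kind: triangular, min: 0.43, mode: 0.87, max: 1.74}
  - name: "TiO2 small bags"
    substance: TiO2
    n_repetitions: 10
    t_pouring: 2
    t_G: 2
    G: {kind: triangular, min: 0.95, mode: 1.90, max: 3.80}
  - name: "Micro Mica small bags"
    substance: MicroMica
    n_repetitions: 17
    t_pouring: {kind: uniform, min: 1, max: 2}
    t_G: 1
    G: {kind: triangular, min: 1.85, mode: 3.7, max: 7.4}
  - name: "Simulated cleaning"
    substance: MicroMica
    n_repetitions: 1
    t_pouring: 10
    t_G: 10
    G: 0
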