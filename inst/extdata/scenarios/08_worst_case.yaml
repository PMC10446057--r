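name: worst_case
description: >
  Worst case combining the precautionary conditions: widened G bounds,
  halved beta (0.325, 1.6, 5) m3/min, 100 m3 room and AER 0.4 to 1.6 1/h.
environment:
  V_room: 100
  AER: {kind: uniform, min: 0.4, max: 1.6}
  V_NF: {kind: uniform, min: 1, max: 2}
  beta: {kind: triangular, min: 0.325, mode: 1.6, max: 5}
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
    G: {kind: triangular, min: 0.87, mode: 0.87, max: 3.48}
  - name: "TiO2 small bags"
    substance: TiO2
    n_repetitions: 10
    t_pouring: 2
    t_G: 2
    G: {kind: triangular, min: 1.90, mode: 1.90, max: 7.60}
  - name: "Micro Mica small bags"
    substance: MicroMica
    n_repetitions: 17
    t_pouring: {kind: uniform, min: 1, max: 2}
    t_G: 1
    G: {kind: triangular, min: 3.7, mode: 3.7, max: 14.8}
  - name: "Simulated cleaning"
    substance: MicroMica
    n_repetitions: 1
    t_pouring: 10
    t_G: 10
    G: 0
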