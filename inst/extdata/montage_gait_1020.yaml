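# motor-cortex montage, earlobe reference (A1/A2)
# Positions: idealized 10-20 layout on a unit sphere (x right,
# y anterior, z up); arbitrary units -- only relative distances matter.
reference_note: motor-cortex montage, earlobe reference (A1/A2)
targets: [Cz, CP1, CP2]
electrodes:
  - {label: FC3, x: -0.635947, "y": 0.462522, z: 0.617774}
  - {label: FC1, x: -0.340147, "y": 0.452072, z: 0.824579}
  - {label: FCz, x: 0.000000, "y": 0.382683, z: 0.923880}
  - {label: FC2, x: 0.340147, "y": 0.452072, z: 0.824579}
  - {label: FC4, x: 0.635947, "y": 0.462522, z: 0.617774}
  - {label: C5, x: -0.923880, "y": 0.000000, z: 0.382683}
  - {label: C3, x: -0.707107, "y": 0.000000, z: 0.707107}
  - {label: C1, x: -0.382683, "y": 0.000000, z: 0.923880}
  - {label: Cz, x: 0.000000, "y": 0.000000, z: 1.000000}
  - {label: C2, x: 0.382683, "y": 0.000000, z: 0.923880}
  - {label: C4, x: 0.707107, "y": 0.000000, z: 0.707107}
  - {label: C6, x: 0.923880, "y": 0.000000, z: 0.382683}
  - {label: CP5, x: -0.848835, "y": -0.412671, z: 0.330427}
  - {label: CP3, x: -0.635947, "y": -0.462522, z: 0.617774}
  - {label: CP1, x: -0.340147, "y": -0.452072, z: 0.824579}
  - {label: CPz, x: 0.000000, "y": -0.382683, z: 0.923880}
  - {label: CP2, x: 0.340147, "y": -0.452072, z: 0.824579}
  - {label: CP4, x: 0.635947, "y": -0.462522, z: 0.617774}
  - {label: CP6, x: 0.848835, "y": -0.412671, z: 0.330427}
  - {label: Pz, x: 0.000000, "y": -0.707107, z: 0.707107}
neighbors_small:
  Cz: [FCz, C1, C2, CPz]
  CP1: [CPz, C1, CP3]
  CP2: [CPz, C2, CP4]
neighbors_large:
  Cz: [FCz, C1, C2, CPz, CP3, CP4]
  CP1: [FCz, C1, C2, CPz, CP3, CP4]
  CP2: [FCz, C1, C2, CPz, CP3, CP4]
neighbors_war:
  Cz: [FC3, FC1, C3, C4, Pz]
  CP1: [FC3, FC1, C3, C4, Pz]
  CP2: [FC3, FC1, C3, C4, Pz]
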