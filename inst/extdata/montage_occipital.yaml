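# occipital/parietal montage, vertex reference
# Positions: idealized 10-20 layout on a unit sphere (x right,
# y anterior, z up); arbitrary units -- only relative distances matter.
reference_note: occipital/parietal montage, vertex reference
targets: [O1, O2, Oz]
electrodes:
  - {label: O1, x: -0.309017, "y": -0.951057, z: 0.000000}
  - {label: O2, x: 0.309017, "y": -0.951057, z: 0.000000}
  - {label: Oz, x: 0.000000, "y": -1.000000, z: 0.000000}
  - {label: PO3, x: -0.314415, "y": -0.926952, z: 0.204703}
  - {label: PO4, x: 0.314415, "y": -0.926952, z: 0.204703}
  - {label: PO7, x: -0.587785, "y": -0.809017, z: 0.000000}
  - {label: PO8, x: 0.587785, "y": -0.809017, z: 0.000000}
  - {label: POz, x: 0.000000, "y": -0.923880, z: 0.382683}
  - {label: P1, x: -0.250547, "y": -0.769492, z: 0.587459}
  - {label: P2, x: 0.250547, "y": -0.769492, z: 0.587459}
  - {label: P3, x: -0.480804, "y": -0.769563, z: 0.420238}
  - {label: P4, x: 0.480804, "y": -0.769563, z: 0.420238}
  - {label: Pz, x: 0.000000, "y": -0.707107, z: 0.707107}
neighbors_small:
  Oz: [O1, O2, POz]
  O1: [Oz, PO3, PO7]
  O2: [Oz, PO4, PO8]
neighbors_large:
  Oz: [PO3, PO4, POz, P1, P2, Pz]
  O1: [POz, P1, P3, Pz]
  O2: [POz, P2, P4, Pz]
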