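# Eight named study configurations: hot inserts (spheres S0-S6, bottles
# B1-B6, thorax bottles T1-T4, bed bottles C1-C4) in air, cold water, warm
# (radioactive) water, a thorax body, or on the camera bed with/without
# water bags. Concentrations in MBq/ml; centres in mm (grid-centred
# coordinates, z along the scanner axis); volumes in ml. An insert may give
# `activity_MBq` instead of `concentration` (converted by the loader).
# `excluded` lists inserts simulated but left out of quantification analysis
# (S0 too small; S1 invisible in warm background; C1 activity assay
# unusable). Ring inserts are spaced as widely as the 222 mm cylinder
# allows (spheres at radius 88 mm around the central 113 ml sphere,
# bottles at 80 mm): tighter packing lets a neighbour's spill contaminate
# an object's background shell and bias the adaptive segmentation's
# SBR estimate.
configs:
  spheres_air:
    medium: air
    projection_duration_s: 20
    background_concentration: 0.0
    excluded: [S0]
    inserts: &spheres
      - {label: S0, kind: sphere, volume_ml: 0.5, concentration: 3.19, centre: [88.0, 0.0, 0.0]}
      - {label: S1, kind: sphere, volume_ml: 1.0, concentration: 3.19, centre: [44.0, 76.21, 0.0]}
      - {label: S2, kind: sphere, volume_ml: 2.0, concentration: 3.19, centre: [-44.0, 76.21, 0.0]}
      - {label: S3, kind: sphere, volume_ml: 4.0, concentration: 3.19, centre: [-88.0, 0.0, 0.0]}
      - {label: S4, kind: sphere, volume_ml: 8.0, concentration: 3.19, centre: [-44.0, -76.21, 0.0]}
      - {label: S5, kind: sphere, volume_ml: 16.0, concentration: 3.19, centre: [44.0, -76.21, 0.0]}
      - {label: S6, kind: sphere, volume_ml: 113.0, concentration: 3.19, centre: [0.0, 0.0, 0.0]}
  spheres_cold_water:
    medium: cold_water
    projection_duration_s: 30
    background_concentration: 0.0
    excluded: [S0]
    inserts: *spheres
  spheres_warm_water:
    medium: warm_water
    projection_duration_s: 30
    background_concentration: 0.49
    excluded: [S0, S1]
    inserts: *spheres
  bottles_air:
    medium: air
    projection_duration_s: 20
    background_concentration: 0.0
    excluded: []
    inserts: &bottles
      - {label: B1, kind: cylinder, volume_ml: 8.5, concentration: 5.11, centre: [80.0, 0.0, 0.0]}
      - {label: B2, kind: cylinder, volume_ml: 8.5, concentration: 5.11, centre: [40.0, 69.282, 0.0]}
      - {label: B3, kind: cylinder, volume_ml: 12.0, concentration: 5.11, centre: [-40.0, 69.282, 0.0]}
      - {label: B4, kind: cylinder, volume_ml: 12.0, concentration: 5.11, centre: [-80.0, 0.0, 0.0]}
      - {label: B5, kind: cylinder, volume_ml: 16.0, concentration: 5.11, centre: [-40.0, -69.282, 0.0]}
      - {label: B6, kind: cylinder, volume_ml: 34.0, concentration: 5.11, centre: [40.0, -69.282, 0.0]}
  bottles_warm_water:
    medium: warm_water
    projection_duration_s: 20
    background_concentration: 0.104
    excluded: []
    inserts: *bottles
  thorax:
    medium: thorax
    projection_duration_s: 20
    background_concentration: 0.0
    excluded: []
    inserts:
      - {label: T1, kind: cylinder, volume_ml: 34.0, activity_MBq: 300.0, centre: [0.0, -16.0, 0.0]}
      - {label: T2, kind: cylinder, volume_ml: 34.0, activity_MBq: 302.9, centre: [42.0, 10.0, -70.0]}
      - {label: T3, kind: cylinder, volume_ml: 34.0, activity_MBq: 302.9, centre: [0.0, 24.0, 0.0]}
      - {label: T4, kind: cylinder, volume_ml: 34.0, activity_MBq: 302.9, centre: [-40.0, -63.6, -50.0]}
  bottles_on_bed:
    medium: bed
    projection_duration_s: 10
    background_concentration: 0.0
    water_bags: false
    excluded: [C1]
    inserts: &bed_bottles
      - {label: C1, kind: cylinder, volume_ml: 34.0, concentration: 5.11, centre: [-55.0, -68.4, -45.0]}
      - {label: C2, kind: cylinder, volume_ml: 163.0, activity_MBq: 854.0, centre: [25.0, -56.4, -45.0]}
      - {label: C3, kind: cylinder, volume_ml: 182.0, activity_MBq: 846.5, centre: [-45.0, -55.3, 45.0]}
      - {label: C4, kind: cylinder, volume_ml: 199.0, activity_MBq: 1182.6, centre: [45.0, -54.4, 45.0]}
  bottles_on_bed_bags:
    medium: bed
    projection_duration_s: 10
    background_concentration: 0.0
    water_bags: true
    excluded: [C1]
    inserts: *bed_bottles
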