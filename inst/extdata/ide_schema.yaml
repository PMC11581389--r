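# Clinical feature schema for invasive-disease-event (IDE) prediction.
#
# 28 features, one entry per column of the encoded patient matrix, in the
# order used throughout the package.  `kind` is one of continuous / ordinal /
# nominal / binary.  Non-continuous features list their admissible levels
# together with the numeric code each level is mapped to (ordinals:
# consecutive integers in clinical order; nominals and binaries: integers in
# the order the levels are listed).  `percent` carries the marginal level
# percentages of the study population used as simulator defaults (NA rows
# excluded; renormalised to 1 at load time).  Continuous features carry the
# population median and quartiles plus plausible extremes as a 5-point
# quantile spec (min, q1, median, q3, max); the simulator interpolates these
# piecewise-linearly.
schema_version: "1.0"
label: ide
id_column: patient_id
features:
  - name: age
    kind: continuous
    quantiles: [25, 45, 52, 62, 92]
  - name: previous_tumors
    kind: binary
    levels: [absent, present]
    codes: [0, 1]
    percent: [97.4, 2.6]
  - name: breast
    kind: binary
    levels: [right, left]
    codes: [0, 1]
    percent: [50.0, 49.7]
  - name: histological_type
    kind: nominal
    levels: [ductal, lobular, others]
    codes: [0, 1, 2]
    percent: [84.4, 8.0, 7.6]
  - name: intraductal_component
    kind: ordinal
    levels: [absent, not typed, G1, G2, G3]
    codes: [0, 1, 2, 3, 4]
    percent: [73.6, 16.7, 2.4, 2.3, 3.4]
  - name: multifocality
    kind: binary
    levels: [absent, present]
    codes: [0, 1]
    percent: [82.2, 17.8]
  - name: angioinvasion
    kind: nominal
    levels: [absent, focal, extensive, not typed]
    codes: [0, 1, 2, 3]
    percent: [63.4, 18.7, 5.9, 12.0]
  - name: er
    kind: continuous
    quantiles: [0, 1, 60, 90, 100]
  - name: pgr
    kind: continuous
    quantiles: [0, 0, 25, 73, 100]
  - name: ki67
    kind: continuous
    quantiles: [0, 10, 20, 39, 95]
  - name: her2_neu_score
    kind: ordinal
    levels: ["0", "1", "2", "3"]
    codes: [0, 1, 2, 3]
    percent: [27.8, 22.3, 12.9, 14.2]
  - name: her2
    kind: binary
    levels: [negative, positive]
    codes: [0, 1]
    percent: [64.0, 17.5]
  - name: grading
    kind: ordinal
    levels: [G1, G2, G3]
    codes: [0, 1, 2]
    percent: [9.2, 44.4, 43.1]
  - name: diameter
    kind: ordinal
    levels: [T1a, T1b, T1c, T2, T3, T4]
    codes: [0, 1, 2, 3, 4, 5]
    percent: [3.3, 9.2, 41.1, 36.2, 2.3, 4.5]
  - name: lymph_node_status
    kind: ordinal
    levels: [N0, N1, N2, N3]
    codes: [0, 1, 2, 3]
    percent: [51.9, 34.9, 7.6, 4.6]
  - name: slnb
    kind: nominal
    levels: [not performed, negative, positive]
    codes: [0, 1, 2]
    percent: [77.1, 14.1, 6.9]
  - name: alnd
    kind: binary
    levels: [not performed, performed]
    codes: [0, 1]
    percent: [13.7, 84.3]
  - name: eradicated_nodes
    kind: continuous
    quantiles: [0, 12, 18, 24, 45]
  - name: metastatic_nodes
    kind: continuous
    quantiles: [0, 0, 0, 2, 35]
  - name: surgery
    kind: binary
    levels: [mastectomy, conserving-surgery]
    codes: [0, 1]
    percent: [38.5, 61.5]
  - name: chemotherapy
    kind: binary
    levels: ["no", "yes"]
    codes: [0, 1]
    percent: [32.6, 67.1]
  - name: chemotherapy_scheme
    kind: nominal
    levels: [not received, C1, C2, C3, C4, C5]
    codes: [0, 1, 2, 3, 4, 5]
    percent: [32.6, 17.1, 22.0, 0.4, 16.1, 10.9]
  - name: chemotherapy_completion
    kind: binary
    levels: ["yes", "no"]
    codes: [1, 0]
    percent: [63.8, 34.8]
  - name: trastuzumab
    kind: binary
    levels: ["no", "yes"]
    codes: [0, 1]
    percent: [86.2, 13.8]
  - name: trastuzumab_completion
    kind: binary
    levels: ["yes", "no"]
    codes: [1, 0]
    percent: [12.1, 87.6]
  - name: hormone_therapy
    kind: binary
    levels: ["no", "yes"]
    codes: [0, 1]
    percent: [25.6, 73.5]
  - name: hormone_therapy_scheme
    kind: nominal
    levels: [not received, H1, H2, H3, H4, H5, H6, H7]
    codes: [0, 1, 2, 3, 4, 5, 6, 7]
    percent: [25.6, 3.9, 0.6, 15.7, 34.3, 5.2, 4.0, 9.0]
  - name: hormone_therapy_completion
    kind: binary
    levels: ["yes", "no"]
    codes: [1, 0]
    percent: [55.6, 41.1]
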