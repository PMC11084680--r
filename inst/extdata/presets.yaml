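# Named simulation scenarios. Survival fractions and loss fractions encode
# the magnitudes the package is validated against; plaque sizes and burdens
# are plausible assumptions (no measured size distributions exist), not
# measured facts. All lengths in micrometers, ages in months.
schema_version: 1
defaults:
  roi: [200, 200, 80]
  section_thickness: 40
  sampling_interval: 2
  mounted_thickness: 20
  target_Lv: 0.05
  orientation: isotropic
  plaque_count: 6
  plaque_radius: [7, 11]
  min_edge_separation: 4
  threshold_d: 20
  proximity_mode: full_3d
  probe_radius: 5
  guard_z: 1
  n_probes: 500
  n_subjects: 6
  survival_near: 1.0
  survival_distant: 1.0
presets:
  DG-12m:
    kind: afferent
    region: DG
    age: 12
    survival_near: 0.40    # severe near-plaque loss (~60% reduction)
    survival_distant: 1.0
  Cg-12m:
    kind: afferent
    region: Cg
    age: 12
    survival_near: 0.55    # medium near-plaque loss (~45% reduction)
    survival_distant: 1.0
  S1BF-12m:
    kind: afferent
    region: S1BF
    age: 12
    survival_near: 0.75    # mild near-plaque loss (~25% reduction)
    survival_distant: 1.0
  CA1-12m:
    kind: afferent
    region: CA1
    age: 12
    survival_near: 0.75
    survival_distant: 1.0
  global-12m:
    kind: afferent
    region: M1
    age: 12
    plaque_count: 0
    survival_near: 0.50    # uniform ~50% loss of monoaminergic-type afferents
    survival_distant: 0.50
  18m-cortex:
    kind: afferent
    region: Cg
    age: 18
    n_subjects: 7
    survival_near: 0.60    # ~40% global loss of cholinergic-type afferents
    survival_distant: 0.60
  "null":
    kind: afferent
    region: M1
    age: 12
    survival_near: 0.70    # equal survival in both zones: no local effect
    survival_distant: 0.70
  fig4-12m:
    kind: afferent_panel
    age: 12
    regions: [DG, Cg, S1BF, CA1]
    survival_near: {DG: 0.40, Cg: 0.55, S1BF: 0.75, CA1: 0.75}
    survival_distant: 1.0
  NbM-18m:
    kind: neuron
    region: NbM
    age: 18
    roi: [400, 400, 960]
    n_true: 5000
    loss_fraction: 0.20    # modest basal-forebrain neuron loss
    section_interval: 6
    n_subjects: 4
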