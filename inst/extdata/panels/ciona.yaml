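species: Ciona intestinalis
classes:
  GABAergic:
    - "GAD1/2 (GAD1, GAD2)"
    - "VGAT"
  Cholinergic:
    - "VAChT"
    - "CHAT"
  Glutamatergic:
    - "VGlut"
provenance:
  GABAergic: "Glutamate decarboxylase 1/2 and the vesicular GABA transporter."
  Cholinergic: "Vesicular acetylcholine transporter and acetylcholine transporter."
  Glutamatergic: "Vesicular glutamate transporter."
notes: >-
  Larval-brain atlas; neuron selection was cluster-based upstream (Syt1,
  Celf3/4/5, Rlbp1 among others), so supply the neuronal cell list as a
  whitelist.
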