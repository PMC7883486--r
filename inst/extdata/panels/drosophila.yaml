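species: Drosophila melanogaster
classes:
  Cholinergic: ["VAChT"]
  Glutamatergic: ["VGlut"]
  GABAergic: ["Gad1"]
  Aminergic: ["Vmat"]
gating: "nSyb > 1, elav > 1 and Syt1 > 1"
provenance:
  Cholinergic: "Vesicular acetylcholine transporter."
  Glutamatergic: "Vesicular glutamate transporter."
  GABAergic: "Glutamic acid decarboxylase 1."
  Aminergic: "Vesicular monoamine transporter."
notes: >-
  Applies to both the larval and the adult brain atlas. The gating rule
  follows the published parameter table; the comma there reads as the
  AND connective (pan-neuronal elav plus synaptic nSyb and Syt1), which is
  an interpretation of the printed comma-separated rule.
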