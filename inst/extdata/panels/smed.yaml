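species: Schmidtea mediterranea
classes:
  Aminergic:
    - "dd_Smed_v4_19744_0_1 (Vmat)"
    - "dd_Smed_v4_12700_0_1 (SerT)"
    - "dd_Smed_v4_21108_0_1 (Ddc)"
    - "dd_Smed_v4_8392_0_1 (Tph)"
    - "dd_Smed_v4_16581_0_1 (Th)"
  Cholinergic:
    - "dd_Smed_v4_11968_0_1 (Chat)"
    - "dd_Smed_v4_6208_0_1 (Chat)"
  GABAergic:
    - "dd_Smed_v4_12653_0_1 (Gad)"
    - "dd_Smed_v4_6616_0_19 (TauT)"
    - "dd_Smed_v4_11826_0_1 (GAT)"
  Glutamatergic:
    - "dd_Smed_v4_10192_0_1 (Vglut)"
  Glycinergic:
    - "dd_Smed_v4_5713_0_1 (GlyT)"
gating: "dd_Smed_v4_4222_0_1 > 1"
provenance:
  Aminergic: "Vesicular monoamine transporter plus biosynthesis enzymes."
  Cholinergic: "Two choline acetyltransferase transcript models."
  GABAergic: "Gad, TauT and the GABA transporter GAT."
  Glutamatergic: "Vesicular glutamate transporter."
  Glycinergic: "Glycine transporter."
notes: >-
  Neurons are first selected by synaptotagmin (Syt, dd_Smed_v4_4222_0_1)
  expression; the gating rule above encodes that selection.
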