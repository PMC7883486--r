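species: Reptiles (Pogona vitticeps, Trachemys scripta)
classes:
  Glutamatergic:
    - "SCL17A7 (SLC17A7, VGlut1)"
  GABAergic:
    - "GAD2"
provenance:
  Glutamatergic: >-
    Printed as SCL17A7 in the source (presumably the vesicular glutamate
    transporter SLC17A7 / VGlut1); both spellings resolve.
  GABAergic: "Glutamic acid decarboxylase 2."
notes: >-
  Dorsal-pallium atlases for lizard and turtle; neuron selection was
  cluster-based upstream, so supply the neuronal cell list as a
  whitelist.
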