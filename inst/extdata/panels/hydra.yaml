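species: Hydra vulgaris
classes:
  GABAergic: ["PNPO"]
  Cholinergic: ["ChT"]
provenance:
  GABAergic: >-
    PNPO (pyridoxine-5'-phosphate oxidase) produces the active vitamin B6
    cofactor of glutamate-to-GABA conversion; used as the GABAergic marker
    in the Hydra nerve-net atlas.
  Cholinergic: >-
    ChT (choline transporter) translocates choline into
    acetylcholine-synthesizing neurons.
notes: >-
  Neuron selection for this atlas was done upstream (FACS-sorted neurons);
  supply the neuronal cell list as a whitelist rather than a gating rule.
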