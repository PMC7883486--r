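species: Danio rerio
classes:
  Cholinergic:
    - "slc18a3a (VAChT)"
    - "slc44a2 (ChT2)"
    - "slc44a5a (ChTl5a)"
    - "slc44a5b (ChTl5b)"
  GABAergic:
    - "gad1b"
    - "gad2"
    - "slc32a1 (VGAT)"
  Glutamatergic:
    - "slc17a6b (VGlut 2.1)"
  Glycinergic:
    - "slc6a9 (GLYT1)"
gating: >-
  gad1b > 1 or gad2 > 1 or slc32a1 > 1 or slc17a6b > 1 or slc18a3a > 1 or
  slc44a2 > 1 or slc44a5b > 1 or slc44a5a > 1 or slc6a9 > 1
provenance:
  Cholinergic: "VAChT plus three choline-transporter-like genes."
  GABAergic: "Both gad paralogs and the vesicular GABA transporter."
  Glutamatergic: "Vesicular glutamate transporter 2.1."
  Glycinergic: "Glycine transporter 1."
notes: >-
  The source marker table for this panel is captioned with another
  species but lists zebrafish gene symbols; the panel follows the gene
  symbols. The published selection rule joins the nine markers with
  commas and a final "and"; a conjunction would select almost no cells,
  so the rule is encoded as the union (OR) of marker-positive cells —
  an interpretation, flagged as such.
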