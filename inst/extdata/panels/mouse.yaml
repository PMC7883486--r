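species: Mus musculus
classes:
  GABAergic:
    - "Gad1"
    - "Gad2"
  Glutamatergic:
    - "Slc17a7 (VGlut1)"
    - "Slc17a6 (VGlut2)"
    - "Slc17a8 (VGlut3)"
  Cholinergic:
    - "Slc18a3 (VAChT)"
    - "Gm5741"
    - "Slc5a7 (Cht1)"
    - "Slc6a5 (Glyt2)"
  Aminergic:
    - "Slc18a2 (Vmat2)"
    - "Th"
gating: >-
  Syt1 > 1, Slc17a7 > 1, Slc17a6 > 1, Slc17a8 > 1, Gad1 > 1, Gad2 > 1,
  Slc18a3 > 1, Gm5741 > 1, Slc5a7 > 1, Slc18a2 > 1 or Th > 1
provenance:
  Cholinergic: >-
    VAChT, Gm5741 (a guanine nucleotide-binding protein subunit gamma
    reported as cholinergic-expressed in the source atlas) and Cht1.
    Glyt2 (glycine transporter 2) is recorded here exactly as the source
    sentence attaches it to the cholinergic list; the wording is
    ambiguous and it may instead define a glycinergic class — kept as
    written, not guessed.
  Aminergic: >-
    Vmat2 and Th, used jointly because their expression does not
    perfectly overlap.
notes: >-
  Young-adult and aging brain atlases share this panel. The published
  selection row joins eleven markers with commas and a final "and"; as a
  conjunction it would select almost no cells, so the commas are read as
  the union (OR) of marker-positive cells — an interpretation, flagged
  as such (the gating string therefore spells the final connective "or").
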