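---
title: "Quantifying neurotransmitter co-expression in single-cell data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neurotransmitter co-expression in single-cell data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotransmitr)
```

## The question

Neurons are conventionally classified by the single neurotransmitter
they release — "one neuron, one transmitter", Dale's principle. In
single-cell RNA-seq a neuron's transmitter phenotype is read off the
expression of canonical marker genes: vesicular transporters,
biosynthetic enzymes and membrane transporters (VAChT/ChAT/ChT for
acetylcholine, Gad/VGAT for GABA, VGlut for glutamate, and so on). When
the marker panels of two classes light up in the same cell, that cell is
a candidate dual-transmitter neuron. `cotransmitr` packages this
analysis: classify every cell against species-specific marker panels and
count, exactly, how many cells fall into every possible combination of
transmitter classes — the quantity displayed in UpSet plots.

## The procedure and its assumptions

The pipeline is deliberately simple and fully deterministic:

1. **Normalization.** Raw counts are log-normalized per cell with a
   fixed scale factor $s$ (default 10,000): a count $c$ in a cell with
   library size $T$ becomes $\ln(1 + c\,s/T)$. The natural logarithm is
   used; this is stated explicitly because thresholds are applied on
   this scale. Cells with $T = 0$ normalize to all-zero rows rather
   than erroring, so degenerate inputs flow through. Because the
   transform is per-cell, subsetting cells commutes with normalization
   (subsetting *genes* does not, since it changes $T$).
2. **Neuron selection.** A boolean gating rule over gene thresholds
   (e.g. `"nSyb > 1 and elav > 1 and Syt1 > 1"`) selects the neuronal
   population, or an externally supplied cell whitelist is used for
   atlases whose neuron selection was cluster-based upstream. The rule
   grammar supports `and`/`or`/`not`, parentheses, `>` and `>=`, with
   precedence NOT > AND > OR. A comma is accepted as a synonym for the
   adjacent keyword connective, matching the style in which such rules
   are commonly printed.
3. **Classification.** A cell is positive for a class iff *any* of the
   class's resolved markers exceeds the threshold (default 1, on the
   normalized layer, strictly greater). OR-over-markers is the
   substantive modelling choice: marker panels are unions of
   alternative evidence, so a partially resolvable panel (a marker
   missing from an annotation) degrades gracefully instead of silencing
   the class.
4. **Counting.** Per-cell class sets are reduced to the combination
   lattice. For a subset $S$ of classes, the *exclusive* count is the
   number of cells whose class set equals $S$ (the conventional UpSet
   bar); the *inclusive* count is the number of cells whose class set
   contains $S$ (the convention of in-text statements such as "134
   neurons co-express GABA and acetylcholine"). The two are related by
   the Möbius / inclusion–exclusion transform over the subset lattice:

   $$\mathrm{incl}(S) = \sum_{T \supseteq S} \mathrm{excl}(T)
     \qquad
     \mathrm{excl}(S) = \sum_{T \supseteq S}
     (-1)^{|T \setminus S|}\, \mathrm{incl}(T).$$

   Both conventions are always reported side by side with explicit
   column names, because published counts mix them and the two can
   differ substantially when overlaps are large.

## A worked decomposition

Published co-expression counts are usually inclusive. Consider a larval
tunicate brain of 644 neurons with inclusive counts GABA 495,
acetylcholine 152, glutamate 19, GABA∩ACh 134, GABA∩Glut 18, ACh∩Glut 2
and triple 2. The transform recovers the exclusive lattice:

```{r ciona}
cls <- c("GABA", "ACh", "Glut")
incl <- c(GABA = 495, ACh = 152, Glut = 19,
          `GABA+ACh` = 134, `GABA+Glut` = 18, `ACh+Glut` = 2,
          `GABA+ACh+Glut` = 2)
exclusive_from_inclusive(incl, cls, total_cells = 644)
```

Only one cell is glutamatergic-only, and 130 of the 644 cells express
none of the three panels. That all exclusive counts are non-negative is
itself informative: it confirms the inclusive reading of such published
counts is internally consistent (an exclusive reading would require a
negative number of glutamatergic-only cells, since 18 + 2 + 2 > 19).
`exclusive_from_inclusive()` checks lattice monotonicity and rejects
non-realizable inputs, naming the offending subset. The empty-set
inclusive count equals the population size, which in-text counts rarely
state; it is passed as `total_cells`, and when it is unknown the class
union is taken as the universe with a warning.

## Marker panels are data

Panels ship as YAML fixtures under
`system.file("extdata", "panels", package = "cotransmitr")` for eight
species groups (hydra, planarian, nematode, fly, tunicate, zebrafish,
reptiles, mouse), so new species need no code changes. Conventions:

* Gene entries may carry aliases, `"unc-25 (Gad)"`: the dataset gene
  symbol is the primary ID and is tried first, then the aliases in
  order. Matching is exact and case-sensitive by default (panels mix
  conventions such as `VAChT`, `slc18a3a`, `Gad1`); a case-insensitive
  switch exists.
* A gene may appear in only one class unless explicitly allowed —
  none of the shipped panels share genes, and silent sharing would make
  dual counts tautological.
* Classes that resolve to zero genes in a given matrix are dropped with
  a warning, never an error; their absence is recorded in the
  resolution report.
* Ambiguities in the sources are recorded, not resolved: the reptile
  glutamatergic marker is printed `SCL17A7` in its source (presumably
  `SLC17A7`), so both spellings resolve; the mouse panel keeps `Glyt2`
  inside the cholinergic gene list exactly as its source sentence reads,
  with a provenance note flagging that it may instead define a
  glycinergic class. Aminergic subtypes (serotonergic, dopaminergic,
  tyraminergic) are handled by panel design and can be collapsed with
  `merge_classes()`, a union over membership columns.
* Two shipped gating rules required an interpretation: the fly rule's
  commas are read as AND (pan-neuronal *and* synaptic markers), while
  the zebrafish and mouse selection rows — commas over nine and eleven
  markers — are read as OR, because those rules *build* the neuronal
  set from marker-positive cells and a conjunction would select almost
  nothing. Both fixtures flag this in their notes.

## The synthetic generator

`generate_dataset()` plants known structure so the whole pipeline can be
validated offline. Each cell draws a class subset from
`subset_prevalence`; markers of planted-positive classes draw counts
from a negative binomial with mean `mu_marker` and size `dispersion`,
all other genes from `mu_background`; independent Bernoulli dropout
zeroes each entry with probability `dropout`. Draw order is documented
(subsets per cell, then counts cells-outer/genes-inner, then the dropout
uniforms in the same order) so a seed reproduces a dataset bit-exactly.

The generator emulates exactly the features the thresholding rule is
sensitive to — sparsity, over-dispersion, dropout, and overlapping
class structure — and deliberately nothing else: no library-size
heterogeneity, batch effects, doublets or ambient RNA. Passing recovery
tests therefore show that the counting machinery is exact and that
classification degrades as dropout theory predicts; they do not show
that a threshold of 1 is optimal for any particular real atlas.

Under this model the expected fraction of cells *called* positive for a
class has a closed form (`expected_called_frequency()`): a positive
marker is detected with probability
$(1-d)\bigl(1 - (1 + \mu_m/\theta)^{-\theta}\bigr)$, an off-class marker
with the analogous background expression, and a class with $k$ markers
is called when any is detected. This is the honest version of the
"planted prevalence thinned by dropout" argument: at realistic settings
the negative binomial's own zero mass (about 2% at $\mu = 50,
\theta = 1$) and background false positives are not negligible, and the
validation suite tests against the exact expectation rather than the
$p\,(1-d^k)$ shorthand, which it uses only where it is exact
(zero background, near-Poisson dispersion). The closed form assumes
every non-zero count clears the threshold after normalization, which
holds whenever library sizes sit well below the scale factor — true for
all shipped simulation settings.

Simulation sizes in the test suite (5,000 cells for frequency recovery,
hundreds of cells for property checks, 10 seeds per claim) were chosen
so that a 3-standard-error band is a few times narrower than the
smallest effect asserted; marker panels in the recovery study use three
markers per class so that the probability of a planted class leaving no
trace is below $10^{-5}$ per cell and exact-subset recovery of a
noiseless population is expected with high probability.

## Numerical and interface choices

* Internal orientation is fixed at cells × genes; both readers
  normalize to it. The Matrix-Market reader detects the common
  genes-as-rows dialect by matching dimensions against the label
  tables and transposes on load; a square mismatch is an error, not a
  guess.
* Duplicate gene IDs are aggregated by summation on load (warned):
  summation preserves totals and is order-invariant, unlike
  first-wins.
* Thresholds are strict (`>`), matching the printed "> 1" convention;
  `>=` is available in the grammar. Values exactly at the threshold do
  not pass.
* Atoms referencing genes absent from a matrix evaluate FALSE with a
  warning rather than erroring, because panels span genome versions.
* All tabular outputs are tab-separated, UTF-8, Unix-newline, and
  byte-deterministic; combination labels join class names with `+` in
  panel-declaration order, the empty set is `"none"`. Combination
  tables sort by descending exclusive count with lexicographic
  tie-break and omit zero rows except `"none"`, which is always
  reported so the exclusive column always sums to the population size.
* The lattice transforms use the $O(k\,2^k)$ superset zeta/Möbius
  recursion in integer-exact double arithmetic; class universes are
  capped at 24 classes, far beyond any transmitter panel.
* Comparisons across datasets (`compare_datasets()`) are descriptive:
  percentages of each dataset's own total, differences and ratios,
  plus a normal-approximation interval for orientation. No hypothesis
  testing or multiplicity machinery is attached, because the intended
  use is side-by-side description of populations (larva vs adult,
  young vs aged), not inference.

## Limitations

* Classification is hard-thresholded; no attempt is made to model
  expression magnitude beyond presence/absence, and no
  ortholog mapping is done between species — panels must be written in
  each dataset's own gene namespace.
* Whitelist-based neuron selection reproduces an upstream analysis
  only as faithfully as the supplied whitelist; cluster-based
  selections cannot be recomputed here.
* The dimensionality-reduction / clustering stages of a standard
  single-cell workflow (variable genes, PCA, UMAP, graph clustering)
  are intentionally out of scope; use a general single-cell framework
  for those and feed the resulting counts or whitelists into this
  package.
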