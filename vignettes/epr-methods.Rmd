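---
title: "Methods: enzyme profile relatedness from binary secretome observations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enzyme profile relatedness from binary secretome observations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epr)
```

## The model

The unit of comparison is an *observation*: the pairing of a CAZy family
with a predicted molecular function, written `FAMILY:EC`
(`GH1:3.2.1.37`) or `FAMILY:unknown` when the family call carries no EC.
The same EC number in two families is two distinct observations — the
pairing, not the function alone, is the trait. A genome's predicted
secretome becomes a binary profile over the observation vocabulary, and a
set of genomes becomes an m × n 0/1 matrix.

Relatedness between two genomes is the Yule dissimilarity of their rows,

$$d = \frac{2\,C_{TF}\,C_{FT}}{C_{TT}\,C_{FF} + C_{TF}\,C_{FT}} \in [0,2],$$

where $C_{TT}$ counts observations both genomes have, $C_{FF}$ observations
both lack, and $C_{TF}, C_{FT}$ the one-sided ones. The deliberate property
is symmetry between presence and absence: a clade can be held together as
much by the enzymes its members jointly *lack* as by the ones they share,
and a presence-only measure such as Jaccard would miss half of that signal.
The score is a dissimilarity, not a metric — the triangle inequality is not
guaranteed — and downstream clustering consumes it as-is.

The assumptions, then: annotations are trustworthy at the family+EC level,
secretion status is decided upstream (three tools, majority vote), and gene
gain and loss are equally informative. Nothing here models expression,
copy number (deliberately: redundancy collapses to presence), or sequence
divergence within a family.

## From protein records to the matrix

1. **Secretion consensus.** A protein enters the analysis iff ≥ 2 of its 3
   tool calls are positive (`consensus_secreted`). A missing tool call is an
   input error, never an implicit negative.
2. **Half-count scoring.** Each retained record distributes mass 1 over its
   observations: an unambiguous call adds 1; a call indecisive among k
   functions adds 1/k to each (`accumulate_scores`). The two-way case is the
   common one; 1/k generalizes it by mass conservation, and the same rule
   covers indecision across families. Scores are exact small-integer
   rationals, so three 1/3 contributions reach *exactly* 1 — under doubles,
   `1/3 + 1/3 + 1/3` may fall a ULP short and silently drop a presence.
3. **Binarization.** Present iff score ≥ 1. The boundary is included
   because a single fully annotated protein scores exactly 1 and must
   register; "above one / below one" phrasing leaves the point itself open,
   and excluding it would mean no unambiguous singleton gene ever counts.
4. **Singleton filter.** Observations private to one genome are removed —
   but only under the kingdom-scale `"dikarya"` profile, where genome
   quality is heterogeneous; the within-genus profile keeps them. Distances
   are accordingly computed post-filter for `"dikarya"`, pre-filter for
   `"genus"`.

Genome-level quality control (`filter_genomes`) applies four independent
rules (partial assembly; genus with < 4 assemblies; < 40 observations;
failed tree placement), each with a reason code. Genus counts are taken
once on the full input set: the rule is a single pass, not an iterated
fixpoint, which keeps the report deterministic and idempotent. The
40-observation boundary is inclusive ("fewer than 40" excludes), and the
count is taken after consensus and annotation but before singleton removal.
The tree-placement rule formalizes "at least three congeners next by" as:
the smallest enclosing clade with ≥ 4 leaves contains ≥ 3 other leaves of
the same genus. That reading is interpretive — "next by" has no unique
formalization — and the clade-size floor of 4 is simply the smallest
neighbourhood able to contain the leaf plus three congeners.

## Grouping

Complete linkage (merge criterion: smallest maximum inter-cluster
distance) builds the dendrogram; merge heights are then non-decreasing by
construction. `stats::hclust` provides the agglomeration with its own
deterministic tie-breaking. Flat clusters cut every merge above a height
threshold, so each cluster's internal cophenetic diameter is bounded by the
threshold; the shipped presets are 0.15 (within-section ring), 0.3
(genus/section scale) and 0.7 (phylum scale). Cuts exactly at a merge
height keep the merge.

The two-dimensional map is metric MDS, implemented as SMACOF majorization
with `n_init` random starts drawn from one seeded stream; the returned
configuration is the one with smallest final Kruskal stress-1,

$$\sigma_1 = \sqrt{\sum_{i<j}(d_{ij}-\delta_{ij})^2 \Big/ \sum_{i<j} d_{ij}^2}.$$

Metric MDS (not non-metric) is the default reading of the reference
routine; none of the pre-installed MDS implementations combine metric
fitting with seeded multi-restart, hence the in-package implementation.
Because restarts are drawn sequentially from the seed, runs are reproducible
and prefix-nested: best-of-20 can never be worse than best-of-1 with the
same seed. The published map used 50,000 initiations; that remains a config
value, while tests run at desk scale (tens).

Partition agreement is quantified by the adjusted Rand index
(`congruence`), chance-corrected so random labelings score near 0.

## Section profiling

`section_summary` computes, per section over its members' rows: total
distinct observations (union), shared observations (intersection), distinct
functions (the `unknown` token counts once — it is a function, not an EC
number), function overlap between families (distinct ECs appearing in ≥ 2
families; counted once per EC however many extra families, and `unknown`
excluded), absent observations (global union minus section union — the
universe is the current analysis, not an external catalog), and the
present:absent ratio. Ratio boundaries partition cleanly: < 1 → type III,
[1, 2] → type II, > 2 → type I; a section lacking nothing has infinite
ratio and is type I. Only *present* observations feed these statistics:
half-weight evidence that never reached 1 contributes neither observations
nor functions.

## The synthetic world

`generate()` emits annotation, secretion and taxonomy tables whose pipeline
image has the hierarchical structure the analysis assumes:

* a **core** shared by every genome (default 24 observations in a
  295-observation universe — the scale of the real vocabulary);
* disjoint **signature blocks** at phylum (25), genus (12) and section (20)
  level, so every genome carries its lineage's nested signatures and
  structurally *lacks* every sibling lineage's — shared absence is built
  in, not emergent;
* per-species Bernoulli extras (rate 0.05) from the unallocated remainder,
  flip noise (0.02) over the whole universe, a fraction of presences
  realized as paired two-way indecisive records (0.1), and non-secreted
  decoy proteins (0.1 of records) that must be removed by the consensus
  gate.

Defaults give 32 genomes carrying ~80–95 observations each, inside the
40–144 span reported for real genomes. One point deserves emphasis: the
Yule score only sees the four contingency counts, so *section-level
signatures alone cannot encode a hierarchy* — two genomes from different
sections have identical counts whether they share a phylum or not, as long
as signatures are disjoint. Phylum- and genus-level blocks are therefore
part of the stated world; without them no threshold could separate phyla
better than sections, and the phylum-cut property would be unattainable by
construction rather than by implementation error.

With all corruption rates at zero the pipeline reproduces the intended
presence sets exactly (tested as an identity), which is what makes the
generator usable as an oracle. What a green recovery test does *not*
establish: anything about real annotation error structure (errors here are
independent Bernoulli flips; real CUPP/gene-model errors are correlated
within families and genomes), realistic family size distributions, strain
sampling, or taxonomy label quality.

## Numerical and format choices

* Scores: exact rationals; presence threshold `score >= 1` exact. A
  tolerance (1e-9) exists only on the plain-numeric input path.
* Yule 0/0: when $C_{TF}C_{FT}=0$ the score is 0 even if the denominator
  also vanishes — continuity with the numerator-zero family and the
  convention of the standard implementation.
* Matrices round-trip TSV bit-exactly for 0/1 and to 1e-12 for distances;
  asymmetry beyond 1e-12 on write is an error, not a warning.
* Newick branch lengths split each merge ultrametrically (leaves of a
  height-h merge sit at depth h/2), so re-parsed cophenetic distances equal
  merge heights to 1e-9.
* Observation strings: canonical form is family-first `FAMILY:EC`; readers
  accept both orders and both `:`/`;` separators. Subfamily suffixes
  (`GH5_5`) collapse to the family by default, with a switch to retain
  them, since the observation vocabulary is defined at family level.
* CLI config files are JSON (jsonlite), the serialization available in the
  supported environment.

## Limitations

The package consumes annotations and secretion calls; it does not run gene
prediction, signal-peptide tools or the peptide-pattern annotator, nor
build the reference phylogeny for the placement check. The Yule score's
non-metricity means MDS stress and dendrogram shape should be read as
descriptive, not inferential; no significance testing of distances or
clusters is provided. Published headline values tied to the 465-genome
download are out of desk-scale reach and are deliberately not asserted
anywhere in the test suite.
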