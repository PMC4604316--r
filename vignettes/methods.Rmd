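---
title: "Methods: compartment-aware pan-genome and phenotype bias analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment-aware pan-genome and phenotype bias analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizendo)
```

## The problem

Collections of closely related bacterial isolates — for example strains of a
single 16S OTU sampled from the rhizosphere (root-adjacent soil) and the root
endosphere (internal root tissue) of one host plant — can hide substantial
functional diversity. `rhizendo` implements the comparative analyses such a
collection calls for, organised around one canonical container: a binary
strains-by-features presence/absence matrix, where the features may be
ortholog clusters, phenotype or pathway calls, phenotype-microarray carbon
sources, metabolic-model growth predictions, or model reactions.

Four questions are addressed:

1. **Which gene families are core, and which are compartment-biased?**
   (occupancy-Venn partition of ortholog clusters)
2. **How similar are the strains' marker genes?** (majority-rule consensus
   and percent identity)
3. **Are traits, pathways or substrate classes distributed non-homogeneously
   between compartments?** (contingency chi-square, asymptotic and
   permutation)
4. **How accurate are metabolic-model growth predictions?** (confusion
   counts against observed utilization)

## Occupancy partition of the pan-genome

Every feature is classified by its *occupancy* in each compartment group:
`all` (present in every member genome), `none` (absent from every member), or
`some`. The cross-classification gives a 3×3 table whose `(all, all)` cell is
the core genome and whose `(some, none)` / `(none, some)` cells are the
compartment-exclusive pan genes. The `(none, none)` cell is structurally
zero because features absent everywhere are rejected at load time — an
all-absent feature carries no information and usually indicates an id
mismatch.

Degenerate group sizes resolve cleanly: for a compartment with a single
genome a feature is either `all` or `none`; `some` is impossible, and the
synthetic generator refuses to plant it. Per-genome accessory averages
(exclusive count / group size) are rounded to the nearest integer, halves
away from zero, which reproduces conventional reporting (3212/15 → 214).

```{r venn}
pg <- generate_pangenome(sim_truth(seed = 1))
m <- presence_from_clusters(pg$clusters, names(pg$labels))
partition_compartments(m, pg$labels)
```

## Consensus identity

The consensus of a pre-aligned marker-gene alignment takes, per column, the
most frequent base among `A/C/G/T`. Two numerical choices are deliberate and
documented because the convention is otherwise ambiguous:

* **Gaps and `N` never vote** and are excluded from both the difference
  count and the denominator of the similarity — they are not nucleotides. A
  column with no informative base becomes `-`.
* **Ties break toward the alphabetically smallest base** (A < C < G < T), so
  the consensus is deterministic. Any fixed rule would do; this one is easy
  to reason about in tests.

Similarity is `100 × (1 − differences / comparable columns)`, reported to
one decimal, and is symmetric in its two arguments. The package does not
compute alignments; input must be pre-aligned FASTA.

## Contingency chi-square and the permutation null

Compartment bias of a binary trait is tested on the 2×2 table of compartment
× positive/negative counts with the plain Pearson statistic (no continuity
correction), df = (r−1)(c−1), and the asymptotic chi-square p-value. With
typical group sizes (here 4 vs 15) expected cells are routinely below 5, so
`chi_square()` raises a `rhizendo_small_expected` warning and the
recommended small-sample result is the **label-permutation p-value**:
strains are reassigned to compartments at random (group sizes preserved) and

```
p = (1 + #{permutations with chi2 >= observed}) / (n_perm + 1)
```

The "isolates as random effects" framing motivates this
permutation-over-isolates null; no random-effects likelihood is fitted. The
"multivariate" panel test stacks per-compartment positive counts of K traits
into a 2×K table; this is one defensible reading of a multivariate
contingency analysis and is labelled as such. Multiple-testing correction is
off by default (per-test alpha reporting); Benjamini–Hochberg is available
behind `p_adjust = "BH"`.

**A calibration caveat that matters.** A permutation test on a 2×2 binary
table is exact but *conservative*: its null distribution is discrete (with 4
rhizosphere strains, at most five atoms), so the achieved type-I rate at
nominal 0.05 is about 0.02 in this design — and stays below 0.04 even for
balanced groups of 100+100 strains. The test suite therefore asserts the
validity bound (rate ≤ 0.05) and the calibration of the asymptotic reference,
and keeps a strict 0.05 ± 0.02 calibration band as a deliberately failing
assertion with this analysis recorded alongside: no valid non-randomized
permutation test can meet it on such tables. Green power results
(planted-effect recovery) are unaffected by this conservatism.

## Carbon-utilization class bias

Phenotype-microarray calls (190 sole carbon sources) are analysed three
ways: per-strain positive counts with per-compartment ranges; the
all/none/differential partition of compounds within a strain group (the
three counts always sum to the compound total); and per-class bias calls.

For a class test, all strain×compound calls in the class are **pooled** into
one 2×2 table per compartment. Pooling matches the idea of testing
"utilization of compound groups" as units, but treats calls within a strain
as independent, which overstates the effective sample size; the strain-label
permutation test — which keeps each strain's call vector intact — is offered
as the robust alternative and takes precedence for the verdict when
computed. A class is called biased toward the compartment with the larger
pooled fraction only when significant at the configured alpha (default 0.01
for classes, 0.05 for trait panels). Single-compound bias is scored as the
difference of compartment utilization fractions (no significance claim),
with lexicographic tie-breaks for a deterministic top-k ranking.

## Model validation

Growth predictions are scored against observations over the strains and
compounds present in both matrices; unshared ids are excluded and listed,
never silently dropped into the denominator. Per-strain accuracy is
`100 (TP+TN) / shared`; the overall figure pools strain-compound pairs
(the per-strain mean is also reported, since pooling vs averaging is a
reporting choice that matters when strains differ). Per-compound
false-negative counts surface systematic model failures — the situation
where every strain grows on a substrate but no model predicts it. The
reaction-content bookkeeping reuses the occupancy partition verbatim
(`reaction_venn()` delegates to `partition_compartments()`), collapsed into
core / shared / compartment-unique categories.

## The synthetic world

The generators produce inputs with the statistical structure the analysis
assumes, so every stage is testable offline and parameter recovery is
measurable. Defaults (shipped in `inst/extdata/study_profile.json`) mirror a
real two-compartment collection: 4 rhizosphere + 15 endosphere strains; a
planted occupancy Venn of 3255 core, 731 all-R/some-E, 52 some-R/all-E, 3157
some/some, 268 R-exclusive and 3212 E-exclusive clusters; model-reaction
categories 1151/175/1/105; 190 compounds in 9 classes; a 1500-site marker
with per-site substitution rate 0.006 (chosen so expected identities sit
near the observed ~99.4%); and a 0.24 prediction error rate (chosen so
pooled accuracy sits near the reported 76%). Class utilization fractions
(0.55/0.35 for the four rhizosphere-biased classes, 0.25/0.55 for the five
endosphere-biased ones) put per-strain substrate counts in the observed
70–95 range.

Two planting modes exist because they answer different questions. **Exact
mode** realizes occupancy cell counts exactly (subsets for `some` cells are
drawn uniformly among proper non-empty subsets), so recovery tests can
assert equality. **Bernoulli mode** draws presence independently per genome,
giving the randomness needed for type-I and power properties. Every
generator is a pure function of (parameters, seed); sub-streams are derived
from the master seed so individual artifacts are reproducible in isolation.
When a bundle is written to disk, features that happened to be drawn absent
everywhere are not written (a real assay export only lists observed
features), keeping every bundle loadable under the strict reader.

What the generator does **not** emulate: phylogenetic correlation between
strains (presence draws are independent given compartment), linkage between
gene clusters, plate-level or replicate noise structure in the microarray
calls, and alignment indels (substitutions only). A green recovery test
therefore establishes correctness of the bookkeeping and calibration of the
tests under exchangeability — not robustness to phylogenetic confounding,
which a real collection always carries.

## Determinism and reporting

`run_full_analysis()` writes every report as TSV with a `#` header recording
package version, seed, permutation count and alpha levels; numeric cells are
formatted with fixed `%.6g` so identical config + seed gives byte-identical
files. JSON is the supported config format (no YAML parser is assumed
present). The CLI mirrors the stages as subcommands (`pangenome`,
`consensus`, `enrich`, `carbon`, `validate`, `simulate`, `all`).

## Known limitations

* Biolog replicate reconciliation is out of scope: the reader accepts
  pre-binarized matrices and leaves replicate merging to the user.
* The stacked 2×K "multivariate" construction is sensitive only to
  *differences in direction or strength* across traits, not to a uniform
  shift shared by all traits (a uniform shift changes row margins, not
  column ratios); per-trait 2×2 results are always reported alongside.
* Pooled class tests inherit the independence caveat above; prefer the
  permutation verdict.
* No multiple-sequence alignment, phylogenetics, ortholog inference, model
  reconstruction or flux analysis — those live upstream in dedicated tools.
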