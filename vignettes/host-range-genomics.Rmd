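---
title: "Relating gene content to host-range phenotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating gene content to host-range phenotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(panphen)
library(dplyr)
```

## The problem

Obligate epibiotic parasites such as the saccharibacterium TM7x grow
attached to the surface of *Actinomyces* host cells. Across a panel of host
strains, the response to infection is not binary: some strains are
**resistant** (the epibiont never establishes), and the **susceptible**
strains split further into **permissive** hosts, whose culture density
crashes precipitously a few passages after infection and then recovers, and
**nonpermissive** hosts, which carry the parasite indefinitely with no
growth-crash. `panphen` provides the comparative-genomics and phenotyping
machinery for studies of this kind:

1. **Pangenome set algebra** — from a gene-cluster membership table, find
   the clusters core to all genomes, exclusive to a phenotype group, or
   single-copy in every genome.
2. **Functional enrichment** — score each annotated function (typically a
   Pfam accession) for differential presence across the phenotype groups.
3. **Gene-tree topology screening** — among single-copy core gene trees,
   find those whose sequence variants separate the phenotype groups.
4. **Growth phenotyping** — classify strains as
   resistant/permissive/nonpermissive from serial-passage density and
   parasite-score trajectories, and locate crash points.
5. **Synthetic data** — generators with known ground truth for all three
   input types, so the whole pipeline is testable without any genome
   downloads.

## The enrichment statistic

For each function, presence in a genome means that at least one gene
cluster annotated with that function has a positive gene count there. With
$G$ phenotype groups of sizes $n_1,\dots,n_G$ and per-group presence counts
$k_1,\dots,k_G$, the enrichment score is the Rao score statistic of
association between group membership and presence — computed as the Pearson
chi-square statistic on the $2 \times G$ present/absent table:

$$ X^2 \;=\; \sum_{g=1}^{G}\sum_{a\in\{1,0\}}
   \frac{(O_{ag}-E_{ag})^2}{E_{ag}},
   \qquad E_{ag} = \frac{n_g\,(\sum_h O_{ah})}{N}, $$

with $N=\sum_g n_g$. The p-value is the upper tail of $\chi^2_{G-1}$, and
q-values are Benjamini–Hochberg adjusted over the full universe of tested
functions. Properties worth knowing:

* $0 \le X^2 \le N$, and $X^2 = N$ exactly when presence coincides with a
  group-subset boundary. With the 10/3/10 group sizes used throughout, a
  function present in all resistant and no susceptible genomes scores 23 —
  as do all perfectly susceptible-exclusive functions.
* No continuity correction and no minimum-expected-count rule are applied.
  This is deliberate: the statistic must stay well defined for groups of
  three genomes, and the published scores this package reproduces (via
  `score_observations()`) are only recovered without small-sample
  adjustments. A consequence is that p-values for small groups are
  approximate; the package treats the score as the primary ranking quantity
  and the q-value as a secondary confidence guide.
* Degrees of freedom stay at $G-1 = 2$ even for functions reported under
  combined headings such as "nonpermissive + resistant": the reference
  scores for such rows match the three-group statistic, not a merged
  two-group one.

A function's **associated groups** are those in which at least half its
genomes carry it (`associated_groups()`, inclusive cutoff). The inclusive
boundary matters: a function in exactly 5 of 10 resistant genomes counts as
resistant-associated, which is what reproduces the reference assignments. A
fraction-above-the-mean rule was considered and rejected because it
disagrees with those assignments at the 0.5 boundary.

Two choices were genuinely open and are exposed as options: functions are
keyed by accession (`annotation_source = "annotation"` merges by
description text instead), and only annotated functions enter the
multiple-testing universe. Reproducing printed q-values would additionally
require the original full genome set, so q-values are validated only
structurally (step-up rule, monotonicity, null behaviour), never against
printed values.

## Core-set semantics

Presence is `count >= 1`; copy-number information is retained but collapsed
for set algebra. `core_clusters()` defaults to strict presence-in-all;
because draft assemblies can lose genes for methodological reasons, a
relaxation (`min_presence < 1`) is available but off by default.
`single_copy_core()` requires exactly one copy in every genome — the
precondition for building one-leaf-per-genome gene trees.
`exclusive_core()` requires presence in every in-group genome and absence
from every out-group genome; the in/out groups must be disjoint but need
not be complementary.

## Topology screening

Each single-copy-core gene cluster has a tree whose leaves map to genomes
and hence to phenotype groups. Three constraint topologies are screened:

* `ALL_MONO` — each of the three groups can be made monophyletic;
* `R_SISTER_NP` — additionally, the resistant and nonpermissive clades are
  sisters (their union is also monophyletic);
* `P_NP_SPLIT` — for two-group trees over the susceptible genomes, some
  edge separates permissive from nonpermissive leaves.

Approximate-ML gene trees are rarely fully resolved, so polytomies are read
as *unspecified hierarchy*: a constraint holds if **some** resolution of
the polytomies displays the required clades. For unrooted splits this is
decided by the minimal-connecting-subtree characterisation (the Steiner
subtrees of the two sides may share at most one vertex); for rooted clades
by the MRCA rule (every child subtree of the set's MRCA lies entirely
inside or outside the set). The clades each constraint requires are
pairwise disjoint or nested, so per-clade refinements compose into a single
resolution; both shortcuts are verified against exhaustive enumeration of
binary refinements on a randomized battery of small trees in the test
suite.

Two consequences of the permissive polytomy reading are documented rather
than hidden: a star tree matches every applicable constraint, and
under-resolved trees inflate match counts. The screen therefore reports the
number of internal edges per tree so downstream users can filter trivial
matches.

**Rooting.** With all three groups monophyletic, an unrooted tree cannot
distinguish the `ALL_MONO` and `R_SISTER_NP` shapes (contracting each clan
leaves a three-leaf star), so both are evaluated on rooted trees. The
default rooting is `as-parsed` — the orientation recorded in the tree file,
which is what a screening script consuming tree-builder output sees —
with `midpoint` and explicit-`outgroup` options. Classification is
exclusive and most-specific-first: a tree matching `R_SISTER_NP` is not
also counted under `ALL_MONO`.

## Growth phenotyping

The published crash calls were visual; the computational recast needs
numeric conventions, all exposed as arguments:

| parameter | default | meaning |
|---|---|---|
| `drop_fraction` | 0.5 | density/control ratio that defines a crash |
| `recovery_fraction` | 0.8 | ratio that must be regained to end the crash |
| `establish_score` | 0.1 | parasite score below which the epibiont counts as absent |
| `establish_passages` | 5 | passage from which establishment is judged |

Densities are always compared with the strain's own host-alone control at
the same passage, which removes medium- and strain-specific growth-rate
confounds and makes calls invariant to joint rescaling. The resistant call
uses only the parasite score (never density), because resistance manifests
as failure to establish, not as any density pattern; the remaining strains
are permissive if a crash is found and nonpermissive otherwise. Crash
timing by colony counts is known to lead the optical-density crash by about
a passage, so any fixed threshold is a convention, not an estimate — which
is why the acceptance surface for this module is recovery of simulated
phenotypes rather than reproduction of published curves.

## The synthetic generators

All generators are pure functions of their config (including the seed); a
rerun writes byte-identical files.

**Pangenome.** Defaults mirror the study conditions this package was built
around: 23 genomes in groups of 10 resistant / 3 nonpermissive /
10 permissive; 346 core clusters; 464 susceptible-, 51 resistant-, and 28
nonpermissive-exclusive planted clusters; 11,483 noise clusters present
independently with $\theta = 0.15$, chosen once so per-genome repertoires
land in the observed ~1700–2800 band and the total matches the ~12,400
cluster scale. A 0.16 duplicate-copy probability on core clusters mirrors
the observed single-copy-to-core ratio (291 of 346). Planted clusters are
noise-free by construction; what the generator does **not** emulate is
assembly incompleteness (patchy presence correlated with genome quality),
homoplasy, or annotation error, so passing tests show the statistics behave
correctly under the assumed model, not that real assemblies are free of
those artifacts.

**Gene trees.** Concordant trees join random within-group subtrees under
the resistant-sister-to-nonpermissive nesting (or a plain two-clade split
for permissive/nonpermissive leaf sets); discordant trees join all leaves
in random order. Polytomies are introduced by contracting random internal
edges with a configurable probability. Branch lengths are exponential and
ignored by the screen.

**Passage dynamics.** No mechanistic model of epibiont/host passaging has
been published, so this module is explicitly a stand-in: a minimal
discrete-passage sketch in which naive and resistant-variant host
subpopulations grow logistically within each 24 h passage, parasite load
grows in proportion to load × naive hosts (saturating at a cap), naive
hosts die in proportion to per-host load, variants emerge at a small rate
and are immune but still carry the parasite at reduced efficiency
(`variant_carriage`), and every passage ends in a 1:10 dilution. The
presets are: resistant = no attachment (`alpha = 0`), nonpermissive =
carriage without damage (`delta = 0`), permissive = both positive. This
reproduces the qualitative signatures the classifier needs — a single
precipitous crash, earlier crashes at higher dose across at least six
orders of magnitude, recovery driven by variant takeover, and stable
carriage after recovery — and makes no quantitative claim about real
cocultures; it is not fit to data. Measurement noise is lognormal on
density and shared between coculture and control, so a dose-0 run tracks
its control exactly.

```{r passage-example, fig.width = 6, fig.height = 4}
df <- simulate_passages(passage_sim_config("permissive", dose = 3, seed = 1))
classify_hosts(df)
```

## Numerical choices and degenerate inputs

* Score ties are broken lexicographically by accession, so reports are
  fully reproducible.
* A function present in all or no genomes scores 0 by definition (the
  chi-square table is degenerate, not an error).
* Trees: support values are parsed and ignored; branch lengths are ignored
  for matching; a cluster that is not single-copy across its tree's leaf
  genomes is skipped with a warning rather than silently screened.
* Genomes present in a matrix but missing from the phenotype map are a hard
  error unless `allow_unlabeled = TRUE` drops them with a warning — silent
  label mismatch being the likeliest user error.
* Passage series must cover the control at every passage, have strictly
  increasing passage indices, and a positive control density; violations
  are data errors, not silent `NA`s.

## Validation problem sizes

The test suite validates the set algebra against brute-force loops on over
1000 random matrices, the topology calls against exhaustive refinement
enumeration on 500+ random trees of up to 8 leaves, planted-function
recovery and null false-discovery behaviour on study-scale and 300-function
null pangenomes (200 replicates), and phenotype recovery on a
3 phenotypes × 5 doses × 20 seeds grid. These sizes were chosen to make
sampling error negligible relative to the pass thresholds while keeping a
full run in the low minutes on a single core; `scripts/acceptance.R` reruns
the same measurements from scratch under a caller-supplied seed.

## Known limitations

* The enrichment statistic conditions on presence/absence only; copy-number
  dosage effects are invisible to it.
* Polytomy-permissive matching inflates match counts on poorly resolved
  trees (deliberately, with the internal-edge count as the filter handle);
  conversely requiring strict bipartitions would miss true but unresolved
  concordance.
* The rooted constraints inherit whatever rooting the tree files record
  unless told otherwise; midpoint rooting assumes a roughly clock-like
  gene tree.
* The passage model is qualitative; crash *durations* in particular depend
  on the variant-emergence rate, for which no measurement exists.
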