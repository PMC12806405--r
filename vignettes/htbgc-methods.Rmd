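---
title: "Detecting horizontally transferred biosynthetic gene clusters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontally transferred biosynthetic gene clusters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htbgc)
```

## The problem

Within one metagenomic sample, dozens of genome bins (MAGs) coexist, and
their biosynthetic gene clusters (BGCs) — the contiguous gene cassettes
encoding secondary metabolites such as thiopeptides or quorum-sensing
autoinducers — are prime material for horizontal gene transfer (HGT).
A recently transferred BGC betrays itself in three ways: it is nearly
identical to a cluster carried by taxonomically distant genomes in the
same sample; it has no counterpart in reference genomes of its own
species or genus; and, gene by gene, it sits phylogenetically closer to
the co-sampled distant genomes than to its own taxon's references.
`htbgc` operationalises exactly this three-stage argument and reports
one verdict per candidate, together with the inferred donor taxon.

## Stage 1: gene cluster families and taxonomic outliers

BGCs are compared by the Jaccard distance on the union of their per-gene
domain labels and partitioned into gene cluster families (GCFs) by
single linkage at a distance cutoff (default 0.3). This stand-in metric
is deterministic and dependency-free; users with a BiG-SCAPE network can
inject its edges verbatim through `read_bigscape_network()`, so the
clusterer and the external tool are interchangeable behind the same
partitioning contract.

Within a GCF, each member genome *i* receives the mean exponential
rank distance to the other members,

$$\bar D_i = \frac{1}{n-1}\sum_{j \ne i} D_{ij}, \qquad
D_{ij} = \begin{cases} 2^{\,7-\mathrm{index}(t^\*)} & \text{some rank matches}\\
999 & \text{no rank matches,}\end{cases}$$

where $t^\*$ is the deepest of the seven ranks (Domain = 0 … Species = 6)
at which the two classifications agree. Two genomes of the same species
are at distance 2; sharing only a domain costs 128; fully disjoint
classifications get the sentinel 999. A genome is an outlier under the
mean rule when $\bar D_i > 2\,\bar D_{\mathrm{all}}$, with
$\bar D_{\mathrm{all}}$ the mean over unordered genome pairs;
alternatively a Z-score rule flags $Z_i = (\bar D_i-\mu)/\sigma > 2$.

Choices worth stating explicitly:

* **Unknown ranks never match** — not even another unknown. Two
  unclassified genomes are no evidence of relatedness. A deep literal
  match below an unknown gap (same genus, unknown family) still scores
  by the deepest match, since the formula only consults the deepest
  matching rank.
* **Label matching is exact string equality** after trimming and prefix
  removal. Synonymous names (Firmicutes vs Bacillota) are distinct
  labels and must be normalised upstream.
* **The 999 sentinel participates in every mean** unmodified; no
  exclusion rule is applied.
* **Pair-mean normalisation.** The textbook normalisation
  $\frac{1}{n(n-1)}\sum_i\sum_{j>i} D_{ij}$ divides an upper-triangle
  sum by twice the number of summed pairs; we follow the evident intent
  (mean over unordered pairs). The literal reading halves
  $\bar D_{\mathrm{all}}$ and doubles the mean rule's stringency; it is
  available as `pair_mean = "printed"` for anyone who wants it.
* **Minimum family size is 3** for outlier detection: with two members
  the "outlier" is symmetric and undefined. Smaller families are skipped
  with a recorded reason, not silently dropped.
* **Sample standard deviation** (n − 1) for the Z rule, the conservative
  choice at the small family sizes where the rule operates; a
  `sd_type = "population"` switch exists. When $\sigma = 0$ (all genomes
  equidistant) there are no Z outliers.
* One genome can contribute several BGCs to a family; outlier status is
  computed **per genome** and propagated to each of its BGCs.

A useful consequence of the algebra: with $k$ same-species carriers at
mutual distance 2 and one cross-phylum genome at 128, the intruder
exceeds $2\bar D_{\mathrm{all}}$ only for $k \ge 4$ (at $k = 3$,
$128 < 2 \times 65$). Detection of a single transfer therefore needs
the recipient family to be carried by at least four related genomes —
this drives the synthetic generator's defaults below.

## Stage 2: isolation against own-taxon references

Each outlier BGC is re-clustered, at the same cutoff, together with the
BGCs of reference genomes matching its own genome at species level plus
genus-level type-strain surrogates. A vertically inherited cluster finds
its relatives there and co-clusters; a transferred one remains a
singleton ("isolated"). Reference genomes are supplied locally through a
manifest (`genome_id`, `lineage`, `path`) — no live database queries.
An empty reference set (taxon absent from the collection) counts as
isolated but marks the final call `low_confidence`. The isolation
decision is monotone in the cutoff, and the nearest reference distance
is always reported.

## Stage 3: per-gene phylogenetic distances and the paired test

For each gene $g$ of a candidate, the representative distance to a group
(the co-sampled family members, "bins"; or the selected reference BGCs,
"refs") is the minimum over that group's homologs,
$d_{\mathrm{rep}}(g) = \min D(g)$, and a gene that cannot be aligned
against a group is assigned the sentinel distance 1. Distances come
from per-gene trees (patristic path sums via `ape`) when supplied, and
otherwise from a Jukes–Cantor transformation
$-\tfrac34\ln(1-\tfrac43 p)$ of the mismatch proportion over non-gap
columns of the stored (aligned, equal-length) gene sequences, capped at
10.0 when $p \ge 0.75$. In the alignment-free route a reference gene is
considered alignable only when its BGC shares at least one domain label
with the candidate and the gene slot has equal length — fully unrelated
references contribute the sentinel, as they would fail alignment in
practice.

The paired vector of per-gene $(d_{\mathrm{bins}}, d_{\mathrm{refs}})$
values is tested one-sided for "bins closer" — the direction that
supports horizontal acquisition — with the Wilcoxon signed-rank test by
default (exact in the tie-free small-n regime), a paired t-test on
request, or `auto` (t when the differences pass a Shapiro–Wilk screen at
$\alpha=0.05$). Zero differences are dropped; absolute ties get average
ranks; a two-sided flag exists for users who prefer reporting both
directions. A p-value requires at least 5 genes — the smallest n at
which the one-sided exact signed-rank tail can reach 0.05 — and smaller
candidates are reported `untestable` rather than dropped.

One caveat is surfaced rather than hidden: the sentinel 1 for unaligned
genes can be *smaller* than genuine patristic distances on long
branches, which would bias the comparison toward the unaligned group.
The rule is implemented verbatim, and a warning is emitted whenever an
aligned distance exceeds 1.

The final verdict is the conjunction: **HTBGC** iff outlier-flagged AND
isolated AND direction bins-closer AND $p < \alpha$ (default 0.05,
strict inequality).

## Orchestration

`detect_htbgc()` is the single entry point and returns a classed result
with `print`, `summary` and `as.data.frame` methods; `run_detection()`
drives it from file paths or a YAML config, and `inst/cli/htbgc.R`
exposes `detect` / `simulate` / `evaluate` / `rates` subcommands for
shell use. Optional ANI-based dereplication (fastANI-format input,
99% threshold) keeps one representative per redundancy component — the
largest genome when lengths are supplied, otherwise the
lexicographically smallest id. Coordinates are 1-based inclusive
throughout; minus-strand CDS sequences from region GenBank files are
stored reverse-complemented so alignment-free comparisons are
orientation-invariant. Donor taxonomy is the lowest common lineage of
the family's non-outlier genomes, `"unclassified"` when not even the
domain is shared. The "similar BGCs within the same genus" column
counts same-family BGCs whose genome shares the recipient's genus. The
command-line tool applies the conventional per-sample floor of 20 MAGs;
the library function leaves the floor at 0 so programmatic users decide
themselves. Per-candidate failures are caught and reported as rows with
a reason, never aborting the batch, and identical inputs give
byte-identical reports.

## The synthetic benchmark: what it emulates and what it does not

`simulate_community()` generates annotation-level communities — records,
not reads; read simulation, assembly and binning are deliberately out of
scope since assembly artefacts would confound the evaluation of the
decision engine itself. Defaults (the benchmark's study conditions):
10 genomes in 2 phyla of 5, each phylum one genus split into species of
3 + 2; 5 native BGC families per phylum carried by every genome of the
genus; 8 genes of 600 nt per BGC; transfers cross-phylum at 2% per-site
mutation. Gene sequences evolve hierarchically with cumulative per-rank
substitution probabilities 0.001/0.01/0.03/0.06/0.10/0.15/0.25 (species
to domain), so sequence divergence increases with taxonomic distance;
one same-lineage reference strain per species carries the genus's
families at 0.5% divergence. Mutations substitute to a uniformly chosen
different base (the substitution model behind a bare "2% mutation" is
unspecified; uniform is the neutral choice).

Two generator decisions follow from the stage-1 algebra rather than
from data: transfers default to **cross-phylum** recipients, because
the rank-distance rule is provably blind to same-species transfers
(distance 2 on both sides), and donors are drawn from **distinct
families**, because two same-phylum recipients of one family mask each
other under the mean rule (each drags $\bar D_{\mathrm{all}}$ up past
the other's $2\bar D_{\mathrm{all}}$ threshold). Both are flags
(`cross_phylum_only`, `distinct_families`) that can be turned off to
study exactly those blind spots.

What the fixture does *not* emulate: partial transfers, post-transfer
rearrangement, chimeric bins, fragmented BGCs, incomplete reference
collections, and label noise in taxonomy. Passing the benchmark
demonstrates that the decision engine recovers clean planted events
under its own model's assumptions — not that real-data recall reaches
the same level.

`evaluate_detection()` scores calls against the planted truth
(precision/recall/F1 with 0/0 defined as 0); `roc_auc()` is the
tie-corrected rank statistic, identical to trapezoidal integration of
the ROC sweep, fed by the only continuous per-candidate confidence the
pipeline produces, $-\log_{10} p$ (untestable candidates score 0).
`f1_across_scales()` mirrors the robustness analysis across dataset
scales with a Kruskal–Wallis comparison; at annotation level
"sequencing depth" has no meaning, so community size is the scale axis
and no numeric target is attached. Transfer-rate tables round half-up
to 2 decimals (matching how such percentages are conventionally
printed), merge zero-transfer genera into "Others", and are tested to
conserve counts under every grouping; contingency tests use Pearson's
chi-squared without continuity correction or Fisher's exact test, with
`auto` switching to Fisher when any expected cell is below 5.

## Numerical and testing notes

Problem sizes in the test suite were chosen to keep the full run within
a couple of minutes on one core while still exercising every decision
path: 1,000 random profile pairs for the distance oracle, 500 random
families of size 3–12 for the outlier rules, exhaustive $2^n$
enumeration of signed-rank tails for $n \le 12$, and 20 simulated
communities (10 with 10 planted transfers, 10 without) for parameter
recovery. Random-number use is confined to the generator and the tests;
the detection path itself is deterministic.

## Known limitations

* The domain-Jaccard stand-in ignores gene order, copy number and
  sequence similarity of shared domains; real composite indices are
  sharper. The network-injection path exists precisely for that reason.
* Mean-rule blindness to shallow (within-genus) transfers and to
  multiply transferred families is inherent to taxonomy-only outlier
  detection, not an implementation artefact; the generator can
  reproduce both blind spots.
* The sentinel-1 rule can understate the distance to an unalignable
  group (see the stage-3 caveat).
* Reference coverage gates confidence: calls made with an empty
  reference set are flagged `low_confidence` and should be treated as
  provisional.
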