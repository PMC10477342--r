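---
title: "Detecting and dating ancient whole-genome duplications with wgdtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating ancient whole-genome duplications with wgdtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdtrace)
```

## The inference problem

A whole-genome duplication (WGD) doubles every chromosome at a single moment.
Tens of millions of years later its traces survive as (i) paralogous gene
pairs whose synonymous divergence Ks clusters around a common value, (ii)
duplicated collinear blocks — runs of genes in conserved order — stacked over
each region of an unduplicated relative, and (iii) gene trees in which the
copies of two descendant species either separate by species (independent
duplications) or interleave (a duplication predating their split). wgdtrace
implements this whole evidence chain, together with the LTR retrotransposon
insertion clock and a per-pathway metabolite differential-abundance score
used in the same kind of genome study, and a forward-time simulator that
generates genomes with *known* duplication histories so every stage can be
validated against truth.

The chain is: homolog detection → collinear block chaining → synteny depth
ratios → per-anchor Ks (NG86) → block-median Ks distribution → Gaussian
mixture peak fitting (BIC) → rate correction → clock dating, plus the
gene-tree shared-vs-independent test.

## The simulator and what it emulates

`simulate_scenario()` evolves one ancestral genome forward through an ordered
event list: speciations copy the genome into a new lineage; each WGD
duplicates every chromosome (appended as new chromosomes) and then deletes
each *newly created* duplicate gene independently with probability
1 − retention (fractionation), closing ranks so gene order stays dense.
Between events every CDS accumulates codon-aware point substitutions:
candidate mutations are uniform over sites and alternative bases, synonymous
candidates (under the standard genetic code) are always accepted,
nonsynonymous candidates with probability omega, and stop-creating
candidates never — ORFs stay intact while the *synonymous* substitution rate
is exactly the scenario's `synonymous_rate` r per synonymous site per year.
A pair separated t years ago therefore has expected synonymous divergence
2·r·t, and the truth log records that closed form for every duplicate and
ortholog pair. Candidate counts per branch are Poisson(3L·r·Δt), which makes
this calibration exact in expectation; the NG86 estimator then recovers the
*realised* substitution history, multiple hits included, through its
Jukes–Cantor correction.

The default study scenario, `polygonaceae_scenario()`, is fixed once: an
ingroup carrying WGDs at 55.8 and 40.7 My (per-duplicate retention 0.7) and
an outgroup split 110 My ago with no polyploidy; r = 4.3 × 10⁻⁹ puts the two
paralog cohorts at truth Ks 0.48 and 0.35 — two adjacent peaks inside the
0.3–0.5 window, the regime in which single-peak fitting misleads and
resolving two components matters. 1,000 ancestral genes on 5 chromosomes at
100 codons each keep the run desk-scale (about a minute end to end); the
Ks-recovery property tests use 300-codon genes, where counting noise per
pair is small enough for a 10 % relative-error bound.

What the simulator does *not* emulate — inversions and translocations,
tandem-array expansion, codon-usage bias, rate heterogeneity among genes,
gene conversion between duplicates — means passing tests certify the
inference machinery, not robustness to every feature of real genomes.
Rearranged genomes would fragment blocks and lower depth-ratio support
before breaking the ratio itself.

## Homology and collinearity

`find_homolog_pairs()` stands in for an all-vs-all similarity search:
Smith–Waterman alignment under BLOSUM62 with BLAST-style affine gaps
(open 11, extend 1; a length-L gap costs open + L·extend), preceded by a
shared 5-mer prefilter (two shared words required) that keeps the quadratic
search desk-scale without losing genuine anchors — the test suite asserts
both subset-ness and zero truth-anchor loss against exhaustive mode.
Reporting thresholds are identity ≥ 0.4 and coverage ≥ 0.4 with at most
`top_n` partners per gene; E-values are deliberately not modelled (they need
a database-size model and add nothing at this scale).

`detect_collinear_blocks()` works in gene-rank space (0-based rank per
chromosome — dot-plot practice), not base pairs. Anchors are chained by an
O(n²) dynamic programme: chains strictly monotone on both axes (orientation
+ or −), consecutive anchors at most `max_gap = 25` ranks apart, score =
3 per anchor − 0.1 per skipped rank. Chains are extracted greedily by
descending score so each anchor joins at most one block (keeping depth
counts well-defined), and chains shorter than `min_anchors = 5` are
discarded. Tandem duplicates (adjacent ranks sharing a partner) collapse to
one anchor before chaining. The chain score is verified against exhaustive
enumeration of all monotone chains on small anchor sets. The published tool
this mirrors does not print its chaining constants; these defaults are this
package's own and all are arguments.

`synteny_depth()` counts, for every reference gene, the blocks whose
reference-side span covers its rank; `depth_ratio()` reports each genome's
multiplicity as the modal coverage depth seen on the *other* genome's genes,
reduced to smallest terms — an unduplicated outgroup against a
twice-duplicated ingroup reads 1:4, with support = the share of covered
genes sitting exactly at the mode.

## Ks estimation and peak fitting

`ng86()` implements Nei–Gojobori (1986) counting: per-codon synonymous site
fractions (changes to stops count as nonsynonymous, so sites sum to 3 per
codon), difference counts averaged over all substitution orders that avoid
stop codons, proportions averaged over the two sequences, and Jukes–Cantor
correction Ks = −¾·ln(1 − 4/3·pS). Estimates with pS or pN ≥ 3/4 are flagged
invalid (saturated) rather than extrapolated. The implementation is checked
codon-by-codon against an independent pathway-enumeration oracle. NG86 was
chosen over ML codon models because it is classical, assumption-light and
oracle-checkable; the Ks field of every anchor row keeps the door open for
alternative estimators.

Each block is summarised by the *median* Ks of its valid anchors — one value
per block, so a handful of giant blocks cannot drown the distribution — and
`fit_ks_mixture()` fits Gaussian mixtures with k = 1..5 components to the
block medians inside (0.02, 2.0] (below: allelic/tandem noise; above:
saturation). The EM runs several seeded restarts per k (quantile spread,
k-means and random draws), a 10⁻³ floor on component standard deviations
prevents single-point collapse, and k is selected by BIC with ties broken
toward fewer components. The fit is deterministic given its seed and is
cross-checked against an independent mixture implementation in the tests.

## Rate correction and dating

Lineages drift in rate, so raw paralog peaks of different species are not on
one clock. `rate_correct()` uses ortholog Ks peaks of each ingroup species
against a shared outgroup: species i is rescaled by c_i = mean(ortholog
peaks)/ortholog peak_i, after which peaks born at the same event coincide.
The study this design follows cites a rate-correction method without
printing its formula; this outgroup-anchored scaling is the package's own
stated stand-in and is exercised by algebraic and simulation tests.
`date_wgd()` is then pure clock algebra T = Ks/(2r) (in My), with an
interval from peak ± 1 sd — a fit-uncertainty band, not a credible interval.

## The shared-vs-independent gene-tree test

`extract_collinear_groups()` takes connected components of the anchor graph
(within- and between-species blocks), keeping genes with at least one
between-species anchor; groups larger than 2^(assumed WGDs) copies per
species are flagged. Trees are neighbour-joining on pairwise K2P distances
of the members' codon sequences — deterministic, dependency-light and
sufficient for a topological question on 4–8 leaves; `group_gene_trees()`
accepts any externally supplied tree via its return structure if an ML
upgrade is wanted.

The verdict: root the tree on a randomly drawn gene of the focal species and
ask whether the two species' copy sets separate. Operationally
`classify_wgd_topology()` tests whether the *other* species' genes form a
clade in the rooted tree, which is exactly the unrooted monophyly of the
focal species' copy set. This operationalisation matters: testing only the
*remaining* focal genes would be structurally unable to return
"independent" for balanced groups, because a root inside a species clade
always splits that clade's remnant. Duplications confined to each lineage
separate the species' copies (→ independent); duplications predating the
split pair orthologs across species and interleave them (→ shared).
Verdicts require at least two remaining focal genes and at least two
other-species genes — a single foreign tip is trivially a clade and carries
no signal. Groups failing preconditions, overflowing the copy cap, or
containing a saturated (infinite) distance are reported unresolved and
excluded from the shared/independent denominator; how fractionated groups
were handled in the original analysis is unstated, so both the rooting count
(`n_rootings`, majority vote) and the copy cap are exposed parameters.

## The LTR insertion clock

At insertion a retrotransposon's 5′ and 3′ LTR are identical; each then
accumulates substitutions independently, so their divergence K dates the
insertion as T = K/(2r). Only elements with both LTRs present are admitted.
`k2p_distance()` implements the Kimura two-parameter distance
K = −½·ln(1 − 2P − Q) − ¼·ln(1 − 2Q) (P transitions, Q transversions),
flagging saturation instead of returning complex logs; it collapses to the
Jukes–Cantor form when transversions run at twice transitions, and is
cross-checked against an independent phylogenetics implementation. Unequal
LTRs are globally aligned (match 2, mismatch −3, gap 5 + 2L) before the
distance. `burst_histogram()` bins ages half-open `[kw, (k+1)w)`; a burst
centred exactly on a bin edge can place its mode in either adjacent bin,
which the tests acknowledge rather than hide.

## Metabolite DA scores

`call_differential()` log2-transforms abundances, takes a Welch two-sample
t-test per metabolite and a geometric fold change (second group over first —
the group vector's level order fixes the direction, so reversing it flips
every sign), and calls up/down at fold change ≥ 2 (or ≤ ½) with p < 0.05 —
raw p-values by default, matching practice of applying the thresholds
directly to targeted metabolite panels; an FDR adjustment is one argument
away. `da_score()` is (n_up − n_down)/n_diff over a pathway's differential
metabolites, ±1 when all move one way. The definition's denominator is
ambiguous between differential and all annotated metabolites; differential
is the default (it is the only reading that attains ±1 exactly) and the
annotated variant is available and labelled.

## Numerical and degenerate-input conventions

* All randomness flows from explicit integer seeds; `with_seed()` restores
  the caller's RNG state, and pipeline stages derive sub-seeds
  deterministically from one top-level seed.
* Local alignment scores are floored at 0; an all-mismatch pair emits no
  anchor rather than a negative score.
* Empty inputs return empty, typed results (empty cohort, empty histogram,
  all-zero depth profile with modal depth 0) — errors are reserved for
  contract violations (negative ages, zero rates, unknown ids, internal
  stop codons, saturated inputs where a number is required).
* NJ branch lengths are clamped at 0; taxa are ordered by label before the
  NJ call so ties break deterministically.
* Ties in mixture BIC go to fewer components; ties between chain
  orientations go to the forward strand.

## Worked example

```{r example, eval = FALSE}
library(wgdtrace)

scen <- polygonaceae_scenario(seed = 1)   # two WGDs + outgroup, known truth
sim  <- simulate_scenario(scen)
inf  <- wgd_inference(sim, seed = 1, date_rate = scen$synonymous_rate)

inf$depth_ratio$label      # "1:4"  (outgroup : double-WGD ingroup)
inf$mixture                # 2 components, means ~0.35 and ~0.48
inf$dates                  # clock ages of the two fitted peaks

ltr_insertion_time(K = 0.0096, rate = 1.6e-9)   # 3.0 My
```

Run sizes in this vignette and the test suite (1,000 ancestral genes for the
depth/peak checks, 200-gene scenarios for tree-test properties, 200–300
element LTR cohorts) are the package's chosen desk-scale study conditions:
large enough for modal depths, mixture selection and verdict frequencies to
stabilise, small enough to run interactively.

## Known limitations

* The simulator's clean collinearity flatters block detection; real
  assemblies need rearrangement-tolerant chaining upstream.
* NG86 underestimates Ks under strong transition bias or codon-usage bias;
  peaks beyond Ks ≈ 1.5 are dominated by saturation regardless of estimator.
* NJ on K2P distances can misplace very short internal branches — WGDs
  separated by a few My will blur the shared/independent signal before the
  statistics fail.
* The rate correction assumes rate constancy *within* each lineage since the
  outgroup split; it removes between-lineage differences only.
* DA scores inherit the raw-p threshold convention: with many metabolites
  and no planted effects, some pathways will show nonzero scores by chance.
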