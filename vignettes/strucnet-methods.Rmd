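---
title: "Methods: phenotype sub-networks with a structural overlay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype sub-networks with a structural overlay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strucnet)
```

This vignette documents the models, parameter choices and numerical
conventions behind each stage of the pipeline, and what the synthetic-data
tests do and do not establish about behavior on real data.

## Network assembly

Protein records from different interaction databases are treated as the
same protein when they share a UniProt accession, an identical amino-acid
sequence, or a gene identifier; the partition of records into unified nodes
is the transitive closure over those three equivalence keys, computed as
connected components of a bipartite record–key graph so the result cannot
depend on input order. Three conventions are worth stating:

- **Sequence equality is exact** string equality after uppercasing and
  whitespace stripping. No fuzzy matching is attempted — near-identical
  isoforms stay distinct unless another key links them.
- **Any shared accession merges.** Records may carry several accessions;
  a single common accession suffices.
- **Self-interactions are dropped after unification** (and counted in the
  run log). The downstream edge score is the mean of the two endpoint
  scores, which is degenerate for a self-loop, and the phenotype
  sub-networks this pipeline targets contain none.

When equal-size components tie for the major component, the component
containing the lexicographically smallest node id wins, making reruns
reproducible.

## Prioritization

The consensus score combines three guilt-by-association views of the same
seed set. The published description of the combined method leaves the
component update rules to the original prioritization tool; the versions
here are declared, parameterized approximations with the same contracts.

**NetScore** (message passing): seeds start at 1, everything else at 0.01,
and each iteration applies `s <- (s + neighbour mean of s)/2`. Seeds are
re-initialized to 1 at each repetition boundary and on output, so the seed
signal is never diluted away. Defaults are 3 repetitions of 2 iterations —
the published defaults of the tool family this emulates — and both knobs
are exposed.

**NetZcore** (randomization z-scores): one neighbour-averaging pass on the
real network is compared with the same pass on 100 degree-preserving
randomizations (edge-swap rewiring with 10·|E| attempted swaps each). The
z-score strips away what a node would score by virtue of its degree alone.
Nodes whose propagated value has zero variance across randomizations
(graphs invariant under all degree-preserving swaps, e.g. a triangle) get
z = 0 and are logged. One integer seed governs all randomizations.

**NetShort** (seed-aware shortest paths): edges touching seeds are
shortened — length `1/(1 + seed(u) + seed(v))` with the 0/1 seed
indicator — and a node's raw score is `1/(1 + mean of squared weighted
distances to the seeds)`. The *squared* distance is a deliberate choice:
with the plain mean, every interior node of a path with seeds at both ends
scores identically (the distance sum is constant along the path), so the
score could not distinguish nodes central to the seed set from peripheral
ones. The concave penalty of the square restores that ordering. Distances
to unreachable seeds are capped at the largest finite distance + 1.

**NetCombo** standardizes each component score vector to zero mean and unit
variance before averaging — the three methods have incomparable raw scales,
and without standardization whichever method has the widest spread would
dominate — then min–max normalizes to [0, 1]. Degenerate normalization
(all scores equal) maps everything to 1.0 with a warning, so "every node is
a seed" does not silently produce NaN.

Edge scores are exactly `(s(u)+s(v))/2`. The sub-network keeps edges with
score **strictly greater** than the cutoff; whether a boundary edge is kept
was left open by the published tables, and strictness was fixed once for
determinism. The default cutoff 0.178 is the published common cutoff for
the two metastasis sub-networks; the hub rule (degree ≥ 12, inclusive) and
the significance level 0.05 are likewise surfaced as config keys with the
published values as defaults.

## Structural overlay

Structures are atom tables parsed from PDB-format text. Alternate
locations keep the highest-occupancy conformer (ties → altloc "A");
selenomethionine is read as methionine; other heteroatoms are excluded;
insertion codes are preserved and author residue numbering is never
renumbered — all cross-references go through explicit residue maps.

An interface is the pair of residue sets whose heavy atoms come within
5.0 Å (inclusive) across two chains. The cutoff is a convention of the
interface-template field rather than a published value of this study, and
it is configurable.

Redundancy clustering groups structures with TM-score > 0.5 *and*
RMSD < 2.5 Å, by single linkage; the TM-score is normalized by the length
of the **longer** structure of a pair, stated explicitly because the score
is otherwise asymmetric. Representatives are the longest member (ties →
smallest id).

Template matching is rigid and sequence-order-preserving over the
half-interface residues (which keep their relative spacing but need not be
contiguous); flexible refinement of the kind done by full docking engines
is intentionally out of scope. Acceptance thresholds are RMSD ≤ 2.0 Å and
coverage ≥ 0.5 of the half. Candidate placements are ranked by coverage
first and RMSD second: a three-residue fragment can superpose spuriously
well, so RMSD alone would favour tiny partial matches over complete ones.
Assembled models are rejected when more than 5 heavy-atom pairs across the
partners come closer than 2.5 Å.

The energy function is a shipped 20×20 residue-contact potential,
`e(i,j) = −(h_i + h_j)/2` on a consensus hydrophobicity scale, summed over
cross-interface residue pairs whose contact centres (C-beta, C-alpha for
glycine) lie within 7 Å. It preserves the two properties the pipeline
relies on — negative = favorable, and hydrophobic interfaces rank below
indifferent ones — and makes no claim to physical binding free energies.
Models are filtered at energy < 0 *before* the per-pair best-model
selection (the published order of those two steps is not stated; filtering
first is the stricter reading), and energy ties break to the smaller
template id.

## Statistics

The organism-composition test is the upper-tail hypergeometric probability
P(X ≥ k), computed from exact log-space point masses. Chains are counted
**with multiplicity** per model that uses them — the published margin of
150 chains for 75 used templates only adds up under usage counting — and
chains with unknown source organism are excluded from both numerator and
denominator. Term enrichment is the right-sided hypergeometric test with
Bonferroni step-down correction, read as the Holm procedure (the standard
interpretation of that option name), with plain Bonferroni available as a
config switch. The two-tailed Fisher exact p sums hypergeometric point
probabilities at most as large as the observed table's (with the customary
`1 + 1e-7` relative tolerance, matching the standard R implementation the
study cites); the odds ratio reported is the sample odds ratio `ad/bc`,
flagged when a zero cell makes it degenerate.

## Variant mapping

Sequence-to-structure maps come from a global alignment of the full
sequence against the chain-derived sequence; maps with identity below 0.9
over aligned columns are rejected outright rather than silently truncated.
Variants whose annotated wild-type residue disagrees with the mapped
structure residue are flagged as mismatches and excluded from location
counts.

Accessibility uses deterministic near-uniform point sampling (a Fibonacci
sphere, 960 points per atom by default) over spheres expanded by a 1.4 Å
water probe — the rolling-probe accessibility contract; the closed-form
area of an isolated sphere anchors correctness to within the sampling
tolerance. Relative accessibility divides by extended-state (Gly-X-Gly)
reference areas shipped with the package. The core threshold is relative
accessibility < 5%, the common convention of the accessibility tool the
study names (which does not print its cutoff); it is configurable.

Classification gives interface membership precedence over the
surface/core split, since an interfacial residue can be buried in the
complex. For the Fisher preference test the published convention —
interface as a subset of the surface — is the default 2×2 construction
(interface vs non-interface *surface* counts, variants against residue
availability); a second convention contrasting interface against all
non-interface residues is implemented and labelled, because the exact
margin construction behind the published odds ratio is ambiguous. Interface
variants are counted per variant, not per (variant, interface) pair.

The hot-spot rule is a declared simplification of empirical hot-spot
predictors: an interface residue is flagged when its relative accessibility
in the complex is ≤ 20% and its summed contact potential is ≤ −1.0. The
published predictor's accuracy claim is not reproduced and none is made
here.

## Synthetic data: what it emulates, and what it does not

`gen_network()` emulates the integrated human interactome at reduced size:
a preferential-attachment background whose default attachment parameter
(13) gives a mean degree of about 26, matching the ~27 of the full
11,123-protein network the study assembled, at the default simulated size
of 500 nodes. The phenotype module is planted by *resampling* its internal
pairs at `enrichment_factor ×` background density — replacing, not adding
to, the background edges inside the module — so that factor 1 reproduces
the background law exactly and the module is statistically invisible, the
null condition the recovery benchmarks require. At the benchmark settings
(module 20 of 500, factor 8, half the module as seeds) the consensus
prioritization recovers withheld members with AUROC well above 0.9.

`gen_complex()` builds two idealized poly-alanine α-helices (2.3 Å C-alpha
radius, 1.5 Å rise, 100° turn, with backbone N/C/O and a C-beta stub per
residue) facing each other, with chain B translated so the closest
inter-chain heavy-atom distance equals the requested gap *exactly*; the
ground-truth contact sets are computed by direct enumeration, independent
of the interface-extraction code they test. Ideal helix geometry was chosen
precisely because that closed form exists. Template libraries default to
gaps of 3.0–3.8 Å, giving half-interfaces of 6–9 residues — enough for the
three-point minimum of rigid matching — with hydrophobic substitutions at
the contact residues so interfaces score favorably. `gen_globule()` packs
four helices into a bundle whose inward residues are genuinely buried,
providing a real core for accessibility tests. Organism labels are drawn
at the configured microbial fraction, defaulting to the published
background share 4918/11255 ≈ 0.437, with the within-group Bacteria:Viruses
and Eukaryota:Archaea splits matching the published table. Variant
placement probabilities default to (core 0.35, surface 0.58, interface
0.07), the observed split of mapped cancer variants in the study.

What passing these tests shows: the algorithms implement their stated
contracts, exactly where exact answers exist (superposition, contact sets,
tail probabilities) and within stated tolerances where sampling is
involved. What they do not show: performance on real interactomes (whose
noise is not preferential-attachment noise), real sidechain packing (the
toys carry stub sidechains, so substituted bulky residues read as buried
against their full reference areas), or physical energetics.

## Numerical conventions and problem sizes

All randomness flows from explicit integer seeds and generators restore
the caller's RNG state, so every run is bit-reproducible. Degenerate cases
are handled loudly: flat score vectors normalize to 1.0 with a warning,
zero-variance z-scores become 0 with a log line, unresolved seeds warn and
are reported, empty interfaces and empty sub-networks are flagged. Ties
break lexicographically everywhere a choice is needed (component, cluster
representative, best model). The test-suite and default pipeline sizes —
500-node networks, 100 randomizations, 30-residue chains, a few hundred
sampled points per atom — were chosen so the full benchmark battery,
including the twenty-replicate null recovery run, completes in a few
minutes on one CPU while keeping every tolerance comfortably met; all are
config keys that scale up.

## Known limitations

- The propagation update rules are approximations of the cited tool's
  internals, not line-for-line ports; their defaults are exposed.
- Template matching assumes comparable residue-number spacing between
  template half and target; structures with wildly gapped numbering will
  match conservatively (lower coverage).
- The contact potential ranks models; its magnitudes are unitless.
- Hot-spot flags are rule-based hints, not validated predictions.
- The per-pair model tables assume binary complexes; higher-order
  assemblies are out of scope.
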