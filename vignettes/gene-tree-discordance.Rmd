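---
title: "Gene-tree discordance, coalescent ILS tests and hybridization networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-tree discordance, coalescent ILS tests and hybridization networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilsnet)
```

`ilsnet` works at the gene-tree level of a phylogenomic study: its inputs
are collections of estimated gene trees (Newick, with bootstrap supports as
internal node labels) and a species tree, and its outputs are per-branch
conflict summaries, a simulation-based test of whether incomplete lineage
sorting (ILS) alone explains the discordance, and fitted hybridization
networks with inheritance probabilities. This vignette explains the models,
the tunable parameters, and the design decisions, in that order.

## The model

All coalescent machinery runs in **coalescent units** (CU; 1 CU = 2N
generations). Under the multispecies coalescent (MSC), gene lineages
entering a species-tree branch of length *t* CU with *k* lineages coalesce
with exponential waiting times at rate *k(k−1)/2*; lineages that fail to
coalesce pass rootward, and everything coalesces above the root. Two
closed-form consequences carry the whole package:

* a rooted triple whose pair-MRCA and triple-MRCA are separated by an
  internal path of *t* CU is concordant with probability
  $1 - \tfrac{2}{3}e^{-t}$, each alternative having $\tfrac{1}{3}e^{-t}$;
* the same expression holds for the quartet drawn around an internal
  branch of length *t*, which makes the concordant quartet fraction $\hat p$
  invertible to a branch length, $\hat T = -\ln(\tfrac{3}{2}(1-\hat p))$.

Hybridization is modelled as one or more **reticulations** on the species
tree: a reticulation (recipient edge, donor edge, γ, τ) sends each gene
down the *minor displayed tree* — the recipient clade regrafted onto the
donor edge, entered at its midpoint with τ extra CU of pendant length —
with probability γ, and down the unmodified tree otherwise. Expected
rooted-triple probabilities are the γ-weighted mixture of the two displayed
trees' MSC probabilities, and the fit maximizes the multinomial
pseudo-log-likelihood of the observed triple counts. This triple-based
pseudo-likelihood deliberately replaces a full gene-tree-topology
likelihood: the quantities of interest are structural (which taxon is the
hybrid; γ near 0.5), not absolute likelihood values, and triples keep the
optimization two-dimensional and deterministic.

## Parameters that matter

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `min_support` | 50 | bootstrap % | gene-tree edges below it are uninformative for concordance counting, the conventional filter for ML gene trees |
| ICA prevalence | 0.05 | fraction | conflicting bipartitions rarer than 5% of the counts at a node are noise, not signal |
| `replicates_per_branch` | 1000 | draws | quartet-sampling Monte-Carlo size; s.e. of QC ≈ 0.02 at this size |
| `draws` (branch lengths) | 2000 | draws | per-branch quartet draws behind $\hat p$; O(1) per branch rather than exhaustive |
| CU cap | 10 | CU | $e^{-10} \approx 4.5\times10^{-5}$ discordance is below Monte-Carlo resolution; larger values are unidentifiable |
| terminal CU | 1 | CU | terminal branches carry one lineage and are unidentifiable from topology frequencies; the value is cosmetic |
| `n_sim` | 20000 | trees | null-set size for the ILS test; large enough that null-histogram noise is negligible against a 500–1500-tree observed set |
| `overlap_threshold` | 0.75 | fraction | operationalizes "largely overlapping" distance distributions; see below |
| `improvement_threshold` | 1% of \|PL\| | log-lik | a reticulation must buy at least this much pseudo-log-likelihood to be retained |
| `tau_max`, grid | 10, 21×21 | CU | donor-attachment length search range and grid before coordinate refinement (tolerance 1e-4) |

The ILS verdict is intentionally rule-based: the overlap coefficient
$\sum_b \min(f^{obs}_b, f^{sim}_b)$ over 0.05-wide normalized-RF bins must
reach the threshold for `ILS-sufficient`. A two-sample KS test is computed
and reported but never drives the verdict — with 20,000 simulated trees it
rejects for effect sizes far below biological relevance. The 0.75 default
is this package's operationalization of a judgement that is usually made
visually, and it is surfaced in every report.

## The synthetic-data generator

`sample_yule_species_tree()`, `simulate_msc_gene_trees()`,
`simulate_network_gene_trees()` and `perturb_gene_trees()` emulate the
statistical structure of transcriptome-derived single-copy gene-tree sets:
9–26 taxa, hundreds to ~1,400 genes, discordance from coalescent-unit
internal branches plus at most a few reticulations with γ near 0.5, edge
supports, and missing taxa. Estimation error is modelled at the topology
level — each internal edge is NNI-rearranged with probability
`nni_noise_prob` (an edge rearrangement swaps two of the four incident
subtrees chosen uniformly, so a third of rearrangements are silent), with
supports drawn from a low range (0–49) on perturbed edges and a high range
(80–100) elsewhere, so the default `min_support = 50` filter is exercised
by construction. What the generator does **not** emulate: sequence-level
noise and alignment error, gene duplication/loss, rate variation among
lineages, or recombination within loci. Passing tests therefore show the
inference machinery is correct under the stated model, not that any real
dataset satisfies that model.

All randomness flows from explicit integer seeds; stage seeds are derived
from a master seed by a fixed hash so adding or removing one stage never
changes another's stream.

## Numerical and design choices

* **RF distances are unrooted and topological.** Distances are normalized
  by the shared-taxon maximum 2(n−3) so gene trees with missing taxa remain
  comparable; trees sharing < 4 taxa with the reference are excluded and
  counted.
* **Polytomies are first-class.** An unresolved node never counts as a
  conflicting split — it is uninformative (conflict mapping), unresolved
  (triples/quartets), or contributes fewer splits (RF).
* **Support semantics.** Splits carrying a support annotation must meet
  `min_support`; splits without any annotation pass the filter, so fully
  resolved trees from simulators or methods that do not emit supports are
  usable without a fake-support step.
* **Missing before uninformative.** When a species-tree bipartition
  restricted to a gene's taxa becomes trivial, the gene is *missing* at
  that node regardless of its resolution elsewhere.
* **One vote per gene.** A gene tree may contain several bipartitions
  incompatible with a node; only its strongest-supported one is counted,
  and the most frequent alternative across genes is reported as "top".
* **QS orientation.** The two discordant quartet resolutions are anchored
  to the branch's subtree groups (group 1 with group 3 vs group 1 with
  group 4). A per-replicate lexicographic assignment would randomize the
  t₁/t₂ split and push QD toward 1; group anchoring keeps QD a genuine
  skew measure. QD is undefined (printed `-`) when no discordant replicate
  was seen.
* **Ties.** A reference bipartition tied with its top alternative keeps a
  positive ICA sign (the magnitude is reported, the tie visible in the
  counts); QC is negated unless the concordant count is the strict
  maximum; equal-scoring NNI neighbours in the species-tree search are
  broken by canonical Newick order, and all output trees order children by
  their smallest descendant label.
* **Search.** Species-tree inference is NNI hill-climbing from the
  majority consensus of complete gene trees, with exhaustive quartet
  scoring (no sampling) — correctness over speed at ≤ 26 taxa. The score
  surface is benign in the moderate-ILS regimes the tests target; a
  constrained dynamic-programming search is out of scope.
* **Guide trees for the ILS test.** A supplied species tree with branch
  lengths is used as the CU guide tree directly; otherwise lengths are
  estimated by quartet-frequency inversion. Two caveats are documented
  rather than hidden: (i) estimating CU lengths from the same gene trees
  absorbs part of any reticulation signal into shorter branches, and
  (ii) a topology *inferred* from hybrid-bearing gene trees is itself
  distorted (the hybrid tip is drawn toward its donor), which can flip the
  ILS verdict. In the bundled analysis the γ = 0.5 fixture drops from
  overlap ≈ 0.63 (true topology) to ≈ 0.82 (distorted inferred topology);
  supplying an externally supported topology is the remedy, exactly as
  upstream coalescent species trees are supplied in practice.
* **Greedy multi-reticulation.** Further reticulations are added with
  earlier ones frozen (no joint refit), reflecting that the regimes of
  interest carry one or two reticulations; pseudo-likelihoods across
  different reticulation counts are not nested test statistics, hence the
  explicit improvement threshold instead of a likelihood-ratio rule.
* **τ is weakly identified.** The donor-attachment length only lengthens
  minor-tree paths; fits frequently return τ̂ = 0 even when data were
  generated with τ > 0. γ — the quantity of scientific interest — is
  unaffected in our recovery experiments.

## Problem sizes in the tests

The test suite exercises the study-scale settings the methods are meant
for: 8–16 taxa; 200–2,000 gene trees for conflict mapping, γ fitting and
species-tree recovery; 20,000-tree null sets for the ILS test; 50,000
three-taxon simulations against the MSC closed form; 1,000 random tree
pairs against a brute-force RF oracle; and 20-seed repetitions for the
calibration, power, specificity and determinism properties. These sizes
are the package's definition of "desk scale" for a ≤ 26-taxon problem.

## Known limitations

* Quartet evaluation uses induced gene-tree quartets, not per-quartet
  likelihoods on alignments; alignment-level quartet sampling is out of
  scope, the score formulas are unchanged.
* The pseudo-likelihood's absolute values are not comparable to full
  network likelihoods; only rankings and γ estimates are meaningful.
* Base CU lengths are plug-in estimates during network fitting (only γ and
  τ are free), a documented bias source under very strong ILS.
* One tip per species; no gene duplication/loss, no polyploid
  hybridization models, no divergence dating.
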