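# ilsnet

Gene-tree discordance, coalescent ILS tests, and hybridization networks
for phylogenomic gene-tree sets.

Phylotranscriptomic studies routinely end up with hundreds to a few
thousand single-copy nuclear gene trees that disagree with each other and
with the species tree. `ilsnet` implements the gene-tree-level half of that
workflow for people who already have the gene trees (from IQ-TREE, RAxML,
...) and want to know *why* they conflict:

1. **Where is the conflict?** Per-branch concordance/conflict counts with a
   bootstrap filter, the internode certainty (ICA) score, and
   quartet-sampling branch scores (QC/QD/QI).
2. **Is incomplete lineage sorting (ILS) enough to explain it?** Simulate a
   null set of gene trees under the multispecies coalescent (MSC) from a
   coalescent-unit guide tree and compare Robinson–Foulds (RF) distance
   distributions.
3. **If not, is it hybridization?** Fit inheritance probabilities (γ) for
   every candidate reticulation by rooted-triple pseudo-likelihood and rank
   the candidates.

A seeded synthetic-data generator (species trees, MSC gene trees, network
gene trees, estimation noise) makes the whole chain testable end to end
without any sequence data.

## The statistics in brief

* **MSC closed form.** A rooted triple whose two internal nodes are
  separated by *t* coalescent units (CU, 1 CU = 2N generations) resolves
  concordantly with probability `1 − (2/3)·e^(−t)` and each alternative
  with `(1/3)·e^(−t)`. This drives the simulator, the branch-length
  estimator (inversion `T = −ln((3/2)(1 − p))` of the concordant quartet
  fraction *p*), and the network likelihood.
* **ICA.** With reference-bipartition frequency p₀ and conflicting
  alternatives p₁…pₘ (prevalence ≥ 5%), `ICA = 1 + Σ pᵢ·log_n(pᵢ)` over the
  n retained bipartitions, negated when an alternative outnumbers the
  reference; 1 means no conflict, 0 maximal two-way conflict.
* **Quartet sampling.** Per branch, replicates draw one taxon from each of
  the branch's four subtrees plus one gene tree;
  `QC = 1 + Σ pᵢ·log₃(pᵢ)` over the three resolution frequencies (sign
  flipped when a discordant resolution dominates),
  `QD = 1 − |t₁−t₂|/(t₁+t₂)` (printed `-` when no discordance was seen),
  `QI` = informative fraction.
* **ILS test.** Overlap coefficient `Σ min(f_obs, f_sim)` between the two
  normalized-RF histograms (bin width 0.05); verdict `ILS-sufficient` iff
  overlap ≥ 0.75 (configurable). A two-sample KS test is reported but not
  used for the verdict.
* **Network fit.** For a reticulation with inheritance probability γ, each
  gene follows the minor (donor) displayed tree with probability γ; triple
  probabilities are the γ-mixture of the two displayed trees' MSC
  probabilities, and `PL(γ, τ) = Σ n·log p(γ, τ)` is maximized by grid scan
  plus coordinate refinement. γ is reported with its complement (donor
  side / species-tree side).

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data: `01_simulate.R` builds two 800-gene, 9-taxon fixtures (one pure-MSC,
one with γ = 0.5 gene flow into tip `A` from the `(F,G)` clade),
`02_species_tree.R` infers/scales the species tree, `03_conflict.R` maps
conflict, `04_ils_test.R` runs the coalescent simulation test and
`05_network.R` the network scan. Outputs land under `results/`. What they
print (abridged):

```
== msc fixture ==       overlap : 0.893 (threshold 0.75)  verdict : ILS-sufficient
== network fixture ==   overlap : 0.636 (threshold 0.75)  verdict : ILS-insufficient

top candidate reticulations:
 recipient donor     gamma tau     logpl    delta
         A   F+G 0.4644587   0 -30039.60 3151.610
         A     G 0.4089633   0 -30060.79 3130.415

selected: gene flow into {A} from the {F,G} branch
inheritance probabilities: 0.464 (donor side) / 0.536 (species-tree side)
```

Read: the ILS-only fixture's discordance is fully explained by the
coalescent null (histogram overlap 0.894), the reticulate fixture's is not
(0.635); the scan then ranks the true donor branch first and recovers an
inheritance probability pair close to the simulated 0.5/0.5. The same
stages are available as one call, `run_pipeline(pipeline_config(...))`,
which writes the per-stage TSV/JSON artifacts and a JSON manifest.

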