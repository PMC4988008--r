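---
title: "Methods: models, simulators and numerical choices in chemevolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulators and numerical choices in chemevolve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemevolve)
```

# Scope

`chemevolve` packages the comparative molecular-evolution toolkit used to
study insect chemoreceptor (odorant receptor, Or; gustatory receptor, Gr)
gene families across closely related *Drosophila* species: repertoire
bookkeeping with pseudogene classification, Nei–Gojobori (NG86) dN/dS
divergence with exact Wilcoxon rank tests, parsimony duplication–loss
reconciliation of gene trees against a species tree, and branch-site
codon-model likelihood-ratio tests for episodic positive selection. A
built-in birth–death simulator produces codon alignments with known ground
truth, so every downstream stage is testable without any external data.

This vignette records the models, their assumptions, the tunable parameters
and their defaults, and the numerical and design choices made where the
design was genuinely open. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

# Pseudogene classification

A candidate gene model is classified from its CDS against an intact
reference homolog. Disruptions detected are a mutated start codon, a
premature stop codon, and a frameshift (CDS length not divisible by three).
The rule is **conjunctive**: a candidate is a pseudogene when a disruption
causes loss of at least 20 % of the reference protein **and** at least one
transmembrane (TM) segment. The conjunctive reading follows the sentence
structure of the published rule; an either-sufficient variant is available
via `rule = "either"` in `classify_gene_model()`. Candidates missing ≥ 20 %
of the reference without any lesion are `partial` (assembly truncation) and
are excluded from both loci and functional counts, which is the only
convention under which the repertoire identity
`functional = loci − pseudogenes` holds.

Mutated start codons are rescued at the next in-frame ATG and the lost
fraction is measured from the reference N terminus — the least destructive
reading of a rule that the source material leaves open.

TM segments are predicted with a deterministic Kyte–Doolittle hydropathy
scan (window 19, mean threshold 1.6, minimum segment 15 aa, merge gap
< 5 aa), a transparent stand-in for neural topology predictors. For the
highly hydrophobic 7-TM chemoreceptors this is adequate and fully testable:
a synthetic protein of 21-residue leucine blocks separated by 15-residue
aspartate linkers yields exactly seven segments, and every window decision
in that fixture is unambiguous. The predictor is *not* a general-purpose
topology tool; marginally hydrophobic helices in real proteins can be
missed, which is why classifier guarantees are stated only for lesions whose
lost fraction lies outside the ambiguous band [0.18, 0.22].

# NG86 divergence

`ng86_codon_sites()` counts synonymous site fractions per codon position
among single-nucleotide neighbours, excluding mutations to stop codons from
the denominator, so `s + n = 3` holds exactly for all 61 sense codons.
`ng86_codon_differences()` averages synonymous/nonsynonymous step counts
uniformly over all stop-free mutational pathways between two codons (up to
3! pathways). Proportions are Jukes–Cantor corrected,
`d = −(3/4)·log(1 − (4/3)p)`; saturated pairs (`p ≥ 3/4`) are flagged
undefined rather than dropped silently. Both primitives are verified against
exhaustive enumeration for all 61 codons and all 61 × 61 codon pairs.

Percent identity uses the full alignment length (gap columns included in the
denominator) by default; the gap-free convention is available through
`count_gap_columns = FALSE`, since alignment tools differ and the choice
changes reported values for gappy pairs.

Wilcoxon tests are computed exactly by enumeration for small samples
(signed rank: all 2^n sign vectors for n ≤ 20; rank sum: all C(m+n, m)
assignments for m + n ≤ 20), with mid-ranks for ties, so exactness is
retained in tied data where `stats::wilcox.test` falls back to an
approximation. Larger samples use the normal approximation with continuity
and tie corrections. Two-sided p-values use the doubling convention.

# Reconciliation

`lca_map()` maps each gene-tree node to the last common ancestor of its
descendants' species; `annotate_events()` labels a node a duplication iff it
maps to the same species node as one of its children, and counts losses per
edge by the path-depth rule (k species-tree edges crossed ⇒ k − 1 losses
under a speciation parent, k under a duplication parent). Weighted cost
defaults are duplication 1.5 and loss 1.0, the settings used in the
published reconciliations. The loss rule is verified exclusively against a
brute-force enumeration over all ancestrally consistent mappings, so the
formula cannot drift from the definition.

`rearrange_weak_edges()` greedily applies the cost-minimising NNI move among
internal edges whose bootstrap support falls below 0.9 (the published edge
threshold), repeating until no move improves the cost; equal-cost candidates
are resolved by the lexicographically smallest canonical newick, making the
search deterministic. This is a documented approximation to rearrangement
modes of reconciliation software whose exact search strategy is not
described in the source material; rerooting is deliberately not part of the
move set (trees are analysed rooted), and non-binary inputs are rejected
rather than resolved silently.

`infer_gains_losses()` computes Sankoff minimum-change integer ancestral
copy numbers (unit cost per copy change), resolving ties toward the smaller
state, and reports per-branch gains/losses as child − parent.

# Codon model and branch-site test

The substitution process is MG94×HKY on the 61 sense codons:
single-nucleotide changes have rate
`(κ if transition else 1) · π_j · (ω if nonsynonymous else 1)`, zero
otherwise. Frequencies default to F3x4 estimated from the alignment (with a
pseudocount warning for empty position/nucleotide cells). The generator is
reversible; matrix exponentials use the symmetrised eigendecomposition
(√π similarity scaling), which is numerically stable for reversible
generators.

**Normalisation.** Within a site-class mixture all class generators share a
single normalisation constant, the background-mixture expected flux
(`mixture_flux()`). Branch lengths are therefore expected substitutions per
codon site for a background branch, while classes with higher ω evolve
proportionally faster — the episodic acceleration that the branch-site test
detects. Normalising each class separately would silently equalise rates
across classes and reduce the test to a composition-only comparison; the
single-class case is unaffected by the choice.

**Branch-site model.** For a designated foreground branch, the alternative
model lets a fraction `p2` of sites evolve at `ω2 ≥ 1` on that branch while
the remaining sites (and all background branches) evolve at a shared `ω1`
(bounded in (0, 1] by default). The null fixes `ω2 = 1`. This is a fixed
two-class simplification of adaptive branch-site random-effects approaches,
which adapt the class count per branch; the fixed form captures the reported
quantities (ω1, ω2, and ω2 % = 100·p2) at desk scale.

**Optimisation.** Branch lengths enter through the input tree's proportions
times one free scale factor, fitted together with κ and a gene-wide ω by
Nelder–Mead under the single-class model (`fit_single_omega()`). This
replaces per-branch length optimisation: at desk scale the input trees are
either simulator truth or NJ estimates whose proportions are already
data-driven, and profiling a single scale keeps each gene-set fit in
seconds. Per-branch tests then either profile (ω1, p2, ω2) jointly
(`optimize_background = TRUE`, slower) or fix ω1 at the gene-wide estimate
and optimise (p2, ω2) using cached outside-subtree partial likelihoods, so
that only the foreground branch's transition matrix is recomputed per
evaluation. Three deterministic multi-starts guard against local optima,
the null solution is included among the alternative's starts (guaranteeing
`lnL_alt ≥ lnL_null` up to tolerance 1e-6), and parameters are transformed
(logit for p2 and bounded ω's) so the search is unconstrained.

**Inference.** The LRT null is the 50:50 chi-bar mixture of a point mass at
zero and χ²(1), reflecting the `ω2 = 1` boundary; a plain χ²(1) switch is
available and is more conservative. Within a gene set, raw p-values over all
tested branches are Holm-adjusted (FWER); across gene sets,
Benjamini–Hochberg q-values (FDR) are computed over the pooled within-set
adjusted values. Per-site posteriors for the ω2 class are reported as naive
empirical Bayes at the MLEs, with an optional 10 × 10 uniform-grid
empirical-Bayes average over (p2, ω2 ∈ [1, 50]); sites above 0.95 are
flagged. Exact hierarchical Bayes site identification is out of scope; the
grid variant is an approximation and the NEB values are always available
alongside.

# Synthetic data

`simulate_gene_family()` runs a Gillespie birth–death process along each
species-tree branch: per-lineage exponential waiting times for duplication,
loss and pseudogenization. Pseudogenized copies persist as vestiges — they
speciate but have no further events and evolve neutrally (ω = 1) from the
moment of pseudogenization, the biological reading of relaxed constraint.
Lost copies are deleted with the loss recorded on the species-tree edge.
Seeds are mandatory; identical configuration and seed give bytewise
identical output.

`sim_codon_alignment()` evolves codon sites on a fixed tree under the
site-class mixture, with designated foreground branches using each class's
foreground ω. The root sequence is drawn from the configured codon
frequencies; stop codons cannot arise because the state space is the 61
sense codons. There is no indel, intron/splice or assembly-gap simulation,
and splice-isoform counts are injected as table rows rather than simulated
mechanistically (no generative process for them is described in the source
material). Consequently, passing tests demonstrate correctness of the
algorithms under the model's assumptions — gap-free alignments, a correct
tree, stationary frequencies, no recombination — not robustness to
alignment error or model misspecification in real data.

The default nine-species framework (`melanogaster_group_tree()`) is a
melanogaster-group-like rooted tree: an ananassae-like outgroup, a
suzukii–takahashii clade and a melanogaster subgroup, with branch lengths
of 0.04–0.30 expected substitutions per codon site chosen once as a
plausible desk-scale depth for the group. The designated foreground branch
in the packaged analyses is the internal edge leading to the
suzukii–takahashii clade (0.10), the analogue of testing nodes leading to
*D. suzukii*.

# Verification strategy and problem sizes

Every algorithmic stage is checked against an independent oracle: NG86
against neighbour/pathway enumeration (all codons, all codon pairs);
pruning likelihoods against exhaustive internal-state summation on
fixtures of ≤ 4 taxa and ≤ 5 sites (relative error < 1e-10); matrix
exponentials against scaled series summation; reconciliation against
brute-force minimisation over all consistent mappings, run as a systematic
randomised sweep (four species-tree shapes on 2–4 leaves × 15 random gene
trees of 2–6 leaves each, fixed seed); Wilcoxon p-values against full
enumeration for all fixtures with n ≤ 12; Sankoff states against exhaustive
state search.

Stochastic calibration of the branch-site machinery uses 80 uniform-ω gene
sets (300 codons, 9 taxa) for the type-I error check and 12 gene sets
(500 codons, 9 taxa, p2 = 0.1, ω2 = 5 on the foreground branch) for power
and parameter recovery, sizes chosen so the full suite completes in a few
minutes on one CPU. At these conditions the test is strongly conservative
(chi-bar null; empirical type-I well below nominal), recovers ω̂2 > 1
essentially always, and recovers median ω̂2 and p̂2 close to truth; the
family-wise (Holm over all 16 branches) detection rate of the foreground
branch is materially lower than the raw-p rate, as expected when a moderate
effect on a 0.10-length branch must survive a 16-fold step-down correction.

# Known limitations

- The TM predictor is a hydropathy heuristic, not a topology model.
- The branch-site engine fixes branch-length proportions from the input
  tree and uses a fixed two-class foreground; synonymous rate variation and
  adaptive class counts are not modelled.
- The grid empirical-Bayes posterior is a coarse approximation.
- NG86 with Jukes–Cantor correction mildly underestimates divergence at
  high saturation; saturated pairs are flagged, not repaired.
- NNI-only rearrangement explores a subset of the tree space a full
  reconciliation search would consider.
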