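---
title: "Methods: mean-field coevolution analysis for RNA structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mean-field coevolution analysis for RNA structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical model behind `rnadca`, the
parameters that matter, the numerical conventions, and — importantly —
what the synthetic-data tests do and do not establish.

## The model and its inference

An alignment of M homologous RNA sequences over L columns is modelled as
i.i.d. draws from a pairwise Potts model (a Markov random field) on the
5-state alphabet `(-, A, C, G, U)`:

$$P(A_1,\dots,A_L) = \frac{1}{Z}\exp\Big\{\sum_{i<j} e_{ij}(A_i,A_j) +
\sum_i h_i(A_i)\Big\}.$$

The couplings $e_{ij}$ are what we want: unlike correlation measures they
separate *direct* interactions from correlations inherited through
intermediate positions. Exact maximum likelihood is intractable, so the
package uses the small-coupling (mean-field) approximation throughout:

1. **Reweighting.** Alignments oversample some clades. Each sequence gets
   weight $1/n_m$ where $n_m$ counts sequences (itself included) at
   $\ge$ 90% identity; identity counts gap–gap column matches as matches
   (the simplest definition consistent with "pairwise identity" on
   aligned rows). $M_\mathrm{eff}=\sum_m w_m$ is the effective sample
   size. The threshold is exposed (`reweight`, default 0.9).
2. **Pseudocounted marginals.** Weighted frequencies are mixed with the
   uniform distribution, $f = (1-\lambda)f_\mathrm{data} + \lambda/q$
   ($\lambda/q^2$ for pairs), which keeps all entries positive and keeps
   pair marginals exactly consistent with single-column marginals. The
   default $\lambda = 0.5$ is the customary mean-field choice for
   strongly reweighted alignments; it is a documented assumption, not a
   fitted value, and is configurable (`pseudocount`).
3. **Inversion.** The connected-correlation matrix
   $C_{(i,A),(j,B)} = f_{ij}(A,B) - f_i(A)f_j(B)$ is built over the four
   non-gap states (the gap is the reference state — the common mean-field
   convention, fixed as a package constant) and inverted with a dense
   solve; couplings are $e_{ij}(A,B) = -(C^{-1})_{(i,A),(j,B)}$,
   zero-padded on the reference state and shifted to the zero-sum gauge.
   No regularisation beyond the pseudocount is applied; a singular $C$
   raises an error advising a larger $\lambda$. Fields are recovered from
   the mean-field self-consistency relation but only couplings feed
   scoring.
4. **Scoring.** $F_{ij} = \lVert e_{ij}\rVert_F$ (all five states by
   default; `include_gap = FALSE` drops the gap contribution — the
   literature is split on this, both variants are tested) followed by the
   average product correction
   $F^\mathrm{apc}_{ij} = F_{ij} - F_{i\cdot}F_{\cdot j}/F_{\cdot\cdot}$.
   MI (natural log; any base only rescales rankings) and MIapc come from
   the same marginals.

### Numerical notes on the APC

Means in the APC exclude the (undefined) diagonal, the standard
convention of the product-correction literature. Two consequences worth
knowing:

* A *constant* score matrix is annihilated exactly; a general separable
  background $v_iv_j$ is strongly suppressed but not exactly zeroed —
  exact annihilation of arbitrary rank-one matrices would require
  diagonal-inclusive means, which the undefined diagonal rules out.
* The pseudocount admixture contributes a systematic rank-one term
  $\lambda(1-\lambda)(f_i-1/q)(f_j-1/q)$ to $C$. At $\lambda=0.5$ this
  sets a sample-size-independent floor on spurious couplings (it is
  largely removed later by the APC); the independence-limit test of the
  suite therefore runs at small $\lambda$, where spurious couplings decay
  as $1/\sqrt{M}$ as expected.

## Secondary structure prediction

The pair-score matrix for a specific target row is built in three steps:
prefill −1 for target pairs that are not Watson–Crick (A·U, G·C) or
wobble (G·U), 0 for compatible pairs; sort the covariance scores and keep
only the `top_k` largest (default: the alignment length L); write each
retained score into its target cell only if both columns map to target
residues and those residues are compatible. The cap is the essential
guard against overpairing — true pairs scale with L while candidate
pairs scale with L² — and its effect can be examined with `topk_sweep()`.

The fold maximises total pair score over nested structures with a minimum
hairpin loop of `min_loop = 3` unpaired nucleotides strictly between the
ends. Conventions chosen where the problem is genuinely open:

* pairs with non-positive cell score are never formed — a zero-score
  compatible pair adds nothing and would only overpair, and −1 cells can
  never improve an optimum, so forbidding them outright is behaviourally
  identical to allowing-but-never-choosing;
* traceback precedence is fixed (pair > bifurcation at the smallest split
  > leave i unpaired > leave j unpaired) so outputs are deterministic;
* evaluation with zero predictions reports precision 1.0 with an explicit
  `no_predictions` flag, avoiding 0/0.

Consensus-structure curation maps each consensus pair onto the target,
keeps only WC/wobble-compatible, non-conflicting, nested, loop-legal
pairs, and can optionally extend kept helices by adjacent compatible
pairs. Extension is off by default: it is a per-family editorial decision
and the package exposes the mechanism, not specific edits.

## Tertiary contacts and enrichment

Trivially proximal pairs carry no information about the 3D fold, so the
candidate list drops `|i−j| < 5` and, for every secondary pair (k,l), the
25 pairs (k±0,1,2; l±0,1,2). Exclusions are bookkept with the first
matching reason (unmappable → near-diagonal → ss-neighborhood), so
retained + excluded always partitions the candidates. The "secondary
structure" used for the exclusion is whatever curated structure the
caller supplies — PDB-derived when evaluating, consensus-derived when
predicting blind.

True positives are pairs within 4 or 8 Å minimal heavy-atom distance
(hydrogens excluded, highest-occupancy altloc conformer only, waters and
hetero residues dropped). PDB residues index sequentially along the
chain and are reconciled to the alignment target by exact substring
matching of the one-letter sequences, with the offset reported.

The enrichment scan slides a window of `Y = round(0.10 × list length)`
(half-up, floored at 1 — the rounding direction is unstated in the
enrichment literature, so it is fixed here) in steps of 1. At offset X
the null model draws the window i.i.d. from the pairs of rank > X, whose
TP fraction is $r_0(X)$; the P-value is the exact binomial tail
$P[\mathrm{Bin}(Y, r_0) \ge T(X,Y)]$ computed as an explicit PMF sum
(lists are small; no normal approximation). The scan summary reports the
first X at which p exceeds α = 0.01 — the depth to which the ranking
remains significantly enriched — with the sensitivity and precision of
those X predictions (precision is NA at X = 0).

Restraint export maps each selected pair to one representative base atom
per nucleotide — N1 for purines, N3 for pyrimidines — with a flat-bottom
upper bound (default 8 Å), in TSV and Rosetta `AtomPair ... BOUNDED`
forms. The single-atom rule is an explicit placeholder for a full
atom-pair mapping table and is configurable (`atom_rule`).

## The synthetic generator: what it emulates, what it does not

`sample_potts_alignment()` draws alignments from a ground-truth Potts
model with

* planted nested helices whose column pairs carry couplings rewarding the
  six WC/wobble combinations (strength 2.0 by default — strong, as base
  pairing is under direct selective constraint),
* planted tertiary pairs with the same coupling shape at strength 0.8 —
  deliberately *much weaker*, matching the observation that tertiary
  covariation is a faint signal,
* random background fields (sd 0.2) for composition bias, a gap state
  held near 5% marginal frequency, and
* phylogenetic redundancy modelled as duplication-plus-noise: a fraction
  (default 20%) of rows are copies of others with 2% per-column mutation.

Defaults n = 70, M = 1000 describe a mid-sized family with comfortable
statistics. Sampling runs one independent Gibbs chain per output
sequence, 1000 burn-in sweeps each, vectorised across chains. This
deviates from single-chain burn-in-plus-thinning on purpose: independent
chains make the "samples are independent draws" premise of the
reweighting tests exactly true and are far faster in pure R; the
manifest records chains and burn-in.

What the generator does **not** emulate: tree-structured phylogenetic
correlation (redundancy is flat duplication), insertions and alignment
error, non-canonical base-pair geometries, and any relationship between
coupling strength and 3D distance beyond the planted contact list. A
green synthetic test therefore establishes algorithmic correctness and
the direct-vs-indirect disentangling property under the model's own
assumptions — not performance on curated natural families.

Two comparison conventions used by the property tests: score margins
between directly coupled and distance-2 pairs are compared after scaling
each score matrix by the standard deviation of its off-diagonal entries
(Fapc is in coupling units, MI in nats; raw margins are not comparable),
and "comparable precision" for the fold comparison means the
coupling-driven mean precision may not trail the MI-driven one by more
than 0.10.

## Known limitations

* Mean-field inversion is biased for strong couplings (the two-site
  recovery test runs at moderate coupling, where the bias is a few
  percent); no pseudolikelihood or Boltzmann-machine refinement is
  provided.
* No pseudoknots: crossing pairs are parsed and reported but never
  predicted, and the Nussinov fold is strictly nested.
* No thermodynamic energy model; the fold uses statistical scores only.
* PDB parsing covers the coordinate section of single-model files; no
  mmCIF.
* L² memory for the pair-frequency array: fine for family alignments
  (L ≲ 500), not for ribosomal-scale molecules.
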