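---
title: "Methods: codon-model selection tests and diel-state inference"
author: "photodiel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-model selection tests and diel-state inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, its numerical
design and the choices made where the design was genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R`
do not themselves compute.

## The inference problem

Cone photoreceptors serve bright-light vision and rod photoreceptors
dim-light vision, with largely disjoint phototransduction gene sets.
Episodic positive selection on the cone-expressed genes of a lineage is
read as evidence of adaptation to daytime activity, on rod-expressed
genes as adaptation to night activity, and on both as cathemerality
(activity unconfined to a portion of the 24-hour cycle). A branch without
any signal is assumed to retain its ancestor's state. The package infers
those per-branch signals from coding-sequence alignments with codon
substitution models, converts them to states with the voting rule, and
propagates the states over a user-defined tree of focal lineages.

## The codon engine

All tests run on a Goldman–Yang-type Markov model over the 61 sense
codons of the standard genetic code. For codons differing at exactly one
nucleotide position, the instantaneous rate is `pi_j * kappa^[ti] *
omega^[ns]`; other off-diagonal entries are zero. Codon frequencies
default to F3x4 (position-specific nucleotide frequencies renormalized
over sense codons); F61-with-pseudocount and equal frequencies are
available for sensitivity checks. The choice of frequency model is the
one piece of the original analyses that published tables do not pin down,
which is why the validation suite compares test *statistics* computed
from published inputs, never fitted frequency-dependent parameter values.

Site-class mixtures assign one omega per class per branch partition
(background vs foreground, or reference vs test). All class matrices are
rescaled by a single common factor — the expected rate of the
background-partition mixture — so that branch lengths are expected
substitutions per codon under the background process and classes keep
their correct relative rates. (The standalone `buildRateMatrix` rescales
to unit expected rate, the convention its callers expect for a single
matrix; the mixture scaling generalizes it.) The simulators use exactly
the same convention, which is what makes parameter-recovery checks
meaningful.

Likelihoods are computed by Felsenstein pruning in compiled code
(RcppArmadillo), with per-node rescaling of partial likelihoods against
underflow, transition matrices obtained by symmetric eigendecomposition
in the pi-weighted inner product (negative round-off entries clamped at
zero), site patterns compressed with multiplicity weights, and two
structural optimizations: subtree partials are shared between site
classes that use identical omegas throughout the subtree (for the
branch-site model, classes differ only on the foreground edge), and for
tip edges only the needed columns of P(t) are formed. Codons containing
ambiguous bases and gap codons are treated as fully missing (all-ones
partials); partial ambiguity is not resolved.

## Fitting

Free parameters are optimized by L-BFGS-B on transformed coordinates:
log scale for kappa (bounds 0.05–50), omegas (1e-4–999, with class-0
omegas of the branch-site model capped at 1 and positive-selection
omegas floored at 1), the RELAX exponent k (0.01–50), and additive
log-ratio coordinates for class proportions (bounded at ±20, so
proportions never reach exact zero). The 999 omega bound is deliberately
visible in reported fits: a fitted omega at the cap is flagged
`capped`. Gradients are forward differences that reuse the cached
objective value; convergence uses `factr = 1e8` (absolute log-likelihood
tolerance around 2e-8, far below the ~1e-5 differences that would matter
for any LRT here) with at most 500 iterations per start.

Each fit runs a grid of start values (the conventional four: kappa 0.5
and 3 crossed with omega 0.5 and 2) and keeps the best; a spread of best
log-likelihoods above 0.01 units across starts is flagged, mirroring the
multi-start robustness convention. Alternatives of nested pairs are
additionally warm-started at the null optimum, and the warm-start point
itself remains a candidate, so `logL_alt >= logL_null` holds exactly
(the null always lies on the alternative's boundary: omega2 = 1, omega3
= 1 or k = 1). Two-delta-L values in (-1e-6, 0) are clamped to zero;
anything more negative raises an error, because with warm starting it
can only be an optimizer failure.

### Branch lengths: the two-step profile

Branch lengths are estimated once per gene and then held fixed in both
members of every nested comparison: first maximum-likelihood GTR branch
lengths on the underlying nucleotides (via phangorn), then a codon M0
fit with a free global scale (and free kappa and omega) that converts
them to substitutions per codon. This is the standard two-step used by
selection-analysis suites; re-optimizing all lengths inside every
nested fit would multiply the cost of the replicate batteries roughly
twentyfold while leaving the df-1 LRTs unchanged in structure, and
fixing identical lengths in null and alternative keeps each pair exactly
nested. The same profile optionally applies to kappa (`fixKappa`): the
battery and calibration runs profile kappa at the per-gene M0 estimate;
direct calls to `fitCodonModel` keep kappa free by default.

One identifiability caveat follows from fixed lengths. Branch lengths
are expressed in background-process units, so on a foreground branch
whose omega differs strongly from the background, the observed
substitution load and the omega are confounded when the length is held
fixed. For the branch-site model this is second order (only a small
site fraction is selected), but for the two-ratio branch model — where
every site feels the foreground omega — it would bias the foreground
omega toward the background value. The branch-model chain therefore
frees a single multiplier on the foreground edge lengths in all three
of its fits (`optimizeFgScale`), which restores the separation: the
multiplier absorbs the substitution count, the omega is determined by
the nonsynonymous/synonymous composition, and every LRT in the chain
still differs by exactly one parameter.

Trees are handled unrooted (the likelihood is root-invariant under
reversibility). With a single outgroup taxon this means the ingroup stem
and the outgroup terminal edge are the same unrooted branch; the bundled
species tree names that merged edge as the root focal branch, which is
exactly how a-priori foreground labeling behaves in standard codon-model
software.

## The tests

* Branch model: two-ratio vs one-ratio (df 1), then two-ratio vs
  two-ratio with foreground omega fixed at 1 (df 1, run only when stage
  one is significant); a PSG call needs both stages significant at
  alpha = 0.05 and fitted foreground omega > 1.
* Branch-site: the four-class model with omega2 >= 1 on the foreground
  against omega2 = 1, referred to chi-square with df 1. The mixture
  alternative (a 50:50 point-mass/chi-square reference) is noted but not
  used — df 1 matches the convention of the analyses this package
  follows, and makes the test conservative, which the type-I
  calibration in the acceptance suite confirms empirically.
* BUSTED-style: three classes, omega1 <= omega2 <= 1 shared across
  partitions, the third class free (>= 1) on the foreground in the
  alternative and capped at 1 in the null; df 1 is a documented
  approximation (the reference tool mixes chi-squares), so published
  p-values of that tool are never used as validation targets. The
  battery applies Bonferroni correction over the gene panel.
* RELAX-style: three reference classes; test-branch omegas are the
  reference omegas raised to k. Null fixes k = 1; df 1. Significant
  k < 1 is relaxation, k > 1 intensification. Unlabeled branches default
  to the reference set.

Site identification under the branch-site alternative: NEB is the
plug-in posterior of membership in classes 2a + 2b at the MLEs; BEB is a
grid-integrated empirical-Bayes approximation (5-point grids over
omega0 and omega2, a 15-point triangle grid over the proportions, with
grid weights proportional to the data likelihood). The exact grid of the
original BEB implementation is not published to reproducible precision,
so the approximation is validated by its agreement with NEB on
well-separated simulations (mean absolute difference below 0.15) rather
than against external numbers.

## The diel rule

`classifyBranchSignal` votes: cone-only PSGs give diurnal, rod-only
nocturnal, both cathemeral. Genes annotated with photoreceptor class
"both" (recovery proteins such as recoverin that act in cones and rods
alike) never vote — a branch whose only signal is such a gene keeps its
ancestor's state. The functional-role column (activation/recovery) is
metadata only: cone arrestin, with a recovery role but cone-specific
expression, votes diurnal, and rhodopsin kinase votes rod; excluding
recovery-role genes from voting would contradict the published state
assignments that the bundled case study reproduces. An override
(`votingClasses`) lets both-class genes vote for cathemerality when a
user wants that reading. Propagation is a preorder walk; a signal-less
root takes `rootPrior` (default "unresolved"). The alternative
interpretation of a cathemeral signal — separate diurnal and nocturnal
episodes at different times — is an annotation on the report, not a
distinct state.

## The synthetic-data generator

`generateDielStudy` inverts a prescribed history into selection regimes:
every branch whose state differs from its parent's (and a root differing
from the root prior) places branch-site selection (omega2 = 8 on about
10% of sites, classes 2a/2b split in the 0.75:0.15 background
proportions) on one sampled cone gene (diurnal shift), one rod gene
(nocturnal), or one of each (cathemeral). All other gene-branch
combinations evolve under the purifying mixture (omega0 = 0.1, p0 =
0.75, p1 = 0.15). Site classes are fixed per site across the tree except
for the foreground switch, mirroring the fitted models' assumptions.
Edges are sampled from exact eigendecomposition transition matrices, not
by Gillespie simulation. Default sizes are desk scale: a 12-taxon
species tree whose edges (0.08–0.55 expected substitutions per codon)
are plausible for mammal-order divergences, 400 codons per gene, a
12-gene panel (5 cone, 5 rod, 2 both-class). Seeds are explicit and the
caller's RNG state is restored.

What the generator does **not** emulate: indels and alignment error,
codon usage bias beyond the frequency model, rate variation beyond the
discrete classes, selection on more than one site fraction, and
non-stationarity. Passing the end-to-end tests therefore shows that the
pipeline recovers histories when its own model family generated the
data, not that real alignments meet those assumptions.

## Validation design and problem sizes

The suite uses exhaustive-state-sum oracles (every internal-node state
combination, independent of the pruning code) on trees with up to three
internal nodes; direct-count oracles for frequencies, identities and
rate-matrix structure; distributional checks of simulated pair
frequencies against pi-weighted transition matrices at 50,000 codons;
and seed-pinned batteries chosen to keep the full suite within a desk
session: 100 null replicates and 50 power replicates at 12 taxa and 300
codons for the branch-site calibration, single seed-pinned RELAX
recoveries at 400 codons, and one full 12-gene end-to-end study (seed
42) with a 15-branch focal tree. The oracle-calls path (true regimes fed
directly to the propagation step) must recover the generating history
exactly, isolating test error from reconstruction error.

## Known limitations

- The chi-square df-1 conventions are deliberate simplifications; they
  are conservative for the branch-site test and approximate for the
  BUSTED-style test.
- BEB is a coarse-grid approximation, suitable for ranking sites, not
  for reproducing site lists of other implementations digit by digit.
- The bundled SWS1 tuning rules (and the non-164 LWS rules) are
  editable defaults marked `synthetic-default` in their source column;
  only the position-164 LWS pair (+6 nm forward, -7 nm reverse) is
  treated as fixed. Users analyzing new opsins should replace the
  defaults from the primary tuning literature.
- The bundled gene annotation covers the genes named in the case study;
  a full panel for new data must be supplied by the user.
- With one outgroup taxon the root focal branch is the merged unrooted
  stem (see above); adding outgroup taxa separates it.
- QC thresholds (`minLenFrac` 0.5, `maxMissingFrac` 0.2, `minIdentity`
  0.4, ambiguity threshold 2 Ns) are documented defaults for the stated
  filtering intents, not claims about any published analysis; all are
  overridable.
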