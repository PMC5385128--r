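---
title: "Codon models of selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon models of selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonsel)
```

# The model family

codonsel implements maximum-likelihood inference under Goldman–Yang-style
codon substitution models, the family behind PAML/codeml analyses of
positive selection and selection divergence in protein-coding genes. The
state space is the 61 sense codons of the standard nuclear code (stop
codons are excluded entirely; other genetic codes can be selected by NCBI
id). The instantaneous rate from codon $i$ to codon $j$ is

$$
q_{ij} \propto
\begin{cases}
0 & \text{more than one nucleotide change, or } j \text{ a stop},\\
\pi_j & \text{synonymous transversion},\\
\kappa \pi_j & \text{synonymous transition},\\
\omega \pi_j & \text{nonsynonymous transversion},\\
\omega \kappa \pi_j & \text{nonsynonymous transition},
\end{cases}
$$

with $\kappa$ the transition/transversion rate ratio, $\omega = d_N/d_S$
the selection parameter, and $\pi$ the equilibrium codon frequencies
(F3x4 by default, as in codeml; F1x4, equal, and empirical-codon are
available). The chain is time-reversible, which the code exploits twice:
transition probabilities come from a symmetrized eigen-decomposition
($P(t) = U e^{\Lambda t} U^{-1}$, checked in the tests against a generic
matrix exponential to $10^{-9}$), and all likelihoods are invariant to root
placement (trees are internally reduced to their unrooted form).

Site-class mixtures share $\kappa$, $\pi$ and branch lengths and differ in
their $\omega$ structure:

* **M0** — one $\omega$ for all sites and branches.
* **free-ratio** — one class, but an independent $\omega$ on every branch;
  reported per branch as $d_N$, $d_S$, and $\omega = d_N/d_S$.
* **M2a_rel** — three classes: purifying ($0 < \omega_0 < 1$), neutral
  ($\omega_1 = 1$), and a third class with a free shared $\omega_2 > 0$.
* **Clade Model C (CmC)** — as M2a_rel, except the third class has distinct
  background ($\omega_2$) and foreground ($\omega_3$) values on the two
  branch partitions; the LRT of CmC against M2a_rel (df = 1) tests
  *selection divergence*.
* **Branch-site model A** — four classes ($0$, $1$, $2a$, $2b$) in which
  classes $2a/2b$ allow $\omega_2 \ge 1$ on the foreground branches only;
  the LRT against the null with $\omega_2 = 1$ (df = 1) tests *positive
  selection* on the foreground.

Following the procedure this family of analyses conventionally uses, both
LRTs are referred to $\chi^2_1$. For the branch-site test the null
hypothesis places $\omega_2$ on the boundary, so $\chi^2_1$ is conservative;
the package reports the $\chi^2_1$ p-value because that is the convention
the analyses it reproduces apply, and the simulation tests confirm the
realized size stays at or below the nominal level.

## Branch lengths and class rates

Branch lengths are expected substitutions per codon *averaged over site
classes*. Internally each class's generator is therefore scaled by the
mixture-average raw flux of its branch partition, so that a purifying class
evolves proportionally slower than a selected class on the same branch.
(Rescaling each class to unit rate individually would silently erase the
rate contrast between classes; the test suite pins the correct behaviour
through parameter-recovery and power checks.)

The default fitting strategy is two-stage, a documented and cheaper
approximation to re-optimizing every branch length under every model:

1. fit M0, estimating $\kappa$, $\omega$ and all branch lengths;
2. fit the site-class models with branch lengths fixed at the M0 values
   times one free multiplicative rescale.

Joint estimation under any model is available via
`branch_lengths = "estimate"`.

## Optimization

Mixture likelihoods of this kind are multimodal. `fit_codon_model()` runs
bounded L-BFGS-B on transformed parameters — $\log$ for $\kappa$, $\omega$'s
and the branch-length scale, additive log-ratio for the class proportions —
with box bounds $\omega \in [10^{-6}, 999]$ (the branch-site alternative
constrains its selected class to $[1, 999]$). The default start is
dispersed over `restarts` deterministic jitters of a standard initial
point; the LRT wrappers additionally warm-start the alternative model at
the fitted null (a feasible point of the alternative, which guarantees the
nested-likelihood ordering up to optimizer noise) plus one
divergence-oriented start so the foreground-elevated mode is explored.
Non-convergence is reported in the `converged` flag, never silently.
Felsenstein pruning runs in compiled code with per-node rescaling, and is
validated against brute-force enumeration over internal-node states on
4-taxon trees.

## Empirical-Bayes site identification

`site_class_posteriors()` reports, per site, the posterior probability of
membership in each class. `"neb"` evaluates $P(k \mid x_s) \propto p_k
L_s(k)$ at the MLEs and is exactly checkable by hand from the cached
per-class site likelihoods (the tests do this). `"beb"` averages the same
quantity over a uniform grid on the class proportions (simplex step 0.1)
and a 10-point grid on the selected-class $\omega$, with the remaining
parameters at their MLEs — a deliberately simple rendering of the
Bayes-empirical-Bayes idea of integrating out mixture-weight uncertainty;
it is labelled as such in output and is not a reimplementation of any
specific published grid. Divergent sites are flagged at posterior > 0.75
(configurable); raising the threshold can only remove flags.

## dN/dS decomposition

For the free-ratio report each branch length $t$ is decomposed using the
mutational-opportunity convention: with $\rho_N(\omega)$ the proportion of
the substitution rate that is nonsynonymous at the branch's $\omega$, and
$f_N = \rho_N(1)$, $f_S = 1 - f_N$ the proportions of nonsynonymous and
synonymous sites,

$$
d_N = \frac{t\,\rho_N}{3 f_N}, \qquad d_S = \frac{t\,(1-\rho_N)}{3 f_S},
$$

so $d_N/d_S$ equals the branch's ML $\omega$ identically (a test asserts
this to $10^{-10}$).

# The synthetic-data generator

`simulate_alignment()` evolves codon alignments under any of the model
structures above: a class is drawn per site, the root codon from $\pi$,
and states evolve branch by branch (parent-first traversal) with the
class- and partition-appropriate transition matrices; the truth record
keeps the per-site class and every ancestral state. One seeded generator
is consumed in a fixed order (site classes, root states, then branches),
so equal specs give byte-identical output.

`make_study_like_fixture()` provides the study-regime presets used across
the tests: 8 taxa, one foreground tip, and site-class mixtures dominated by
strong purifying selection, the regime typical of mammalian vision-gene
panels (most sites near $\omega \approx 0.05$, a small neutral class, and a
small selected or divergent class):

* `m0-purifying`: $\omega = 0.05$;
* `m2arel-null`: $p = (0.75, 0.05, 0.20)$, $\omega_0 = 0.05$,
  $\omega_2 = 0.5$ — the null regime for the clade-model size check;
* `cmc-divergent`: same proportions, background $\omega_2 = 0.1$,
  foreground $\omega_3 = 3$;
* `branchsite-positive`: $p_0 = 0.8$, $p_1 = 0.1$, foreground
  $\omega_2 = 5$ on the selected classes.

The fixture tree totals ~1.2 substitutions per codon with the foreground
tip on a 0.20-substitutions branch. That length was chosen so the
foreground lineage of a 600-codon alignment carries on the order of a
hundred expected substitutions — enough information for branch-wise
inference; with a much shorter foreground branch the branch-site ML
estimate collapses onto the null for most replicates and no method could
attain the intended detection rates. Alignments default to 600 codons,
matching the length scale of typical opsin/crystallin coding sequences.

What the generator does *not* emulate: indels (gaps can only be injected
as a masking process), codon-frequency biases (presets use uniform $\pi$),
rate variation beyond the defined class structures, alignment error, and
isoform or ortholog misassignment. Passing tests therefore demonstrate
correctness of the inference machinery under the model, not robustness to
real-data artifacts.

## Test problem sizes

The simulation-based checks run at deliberately modest sizes: parameter
recovery at 1,000 codons; clade-model power at 12 replicates of 600 codons
and size at 24 null replicates (pass bounds from the exact binomial tails
at the targeted 80% power and 5% size); branch-site power at 4 strong-effect
replicates. These sizes make the whole suite reproducible on a single CPU
while keeping the binomial envelopes meaningful.

# The spectral-tuning predictor

The five-sites rule predicts the wavelength of maximal absorption of
mammalian long-wavelength (L) cone opsins from the residues at five sites
(human L-opsin numbering): 180, 197, 277, 285, 308. Anchored at
genotype SHYTA = 560 nm, the substitutions S180A, H197Y, Y277F, T285A and
A308S shift $\lambda_{max}$ down by 7, 28, 7, 15 and 16 nm additively, and
their reverses shift it up by the same amounts; all $2^5$ genotypes fall in
[487, 560] nm. Residues outside the canonical alternatives make the
prediction unavailable rather than guessed. The additive constants are
taken as definitive; published panels occasionally print a value that
disagrees with the additive sum by 1 nm (e.g. 552 for SHFTA where the
constants give 553), and the predictor does not special-case such entries.

Because species sequences differ in length, genotype extraction is
alignment-mediated: the query is globally aligned
(`Biostrings::pairwiseAlignment`, BLOSUM62, gap open 10 / extend 0.5) to an
annotated reference that carries the canonical numbering, and residues are
read off the mapped columns — robust to indels and truncations. The
bundled reference is a synthetic sequence (labelled as such) whose only
meaningful content is the annotated site positions; any correctly numbered
real L-opsin sequence can be substituted. Site 233 (S/T, transmembrane
domain 5, a spectrally relevant position whose quantitative effect is
unresolved) is reported alongside but never enters the prediction.

# Numerical choices and degenerate inputs

* Codons containing N or other ambiguity become the missing state and
  contribute all-ones partial vectors (exact marginalization), as do gaps.
* Alignment columns can be filtered by an `all-gap` (default) or `any-gap`
  (cleandata-like) policy; both are provided because published analyses
  rarely state which was used.
* F3x4/F1x4 products renormalize over sense codons; exact zeros are floored
  at $10^{-12}$ so the generator stays irreducible on degenerate toy data.
* Terminal stop codons are silently stripped by translation; internal stops
  are hard errors naming the offending codon, mirroring the discard rule
  used when screening genome-derived coding sequences.
* Invariant sites drive site-wise $\omega$ to its lower bound; all-gap
  sites return `NA`.
* Tiny negative LRTs from optimizer noise (within $10^{-6}$) are clamped to
  zero; anything larger is an error, never silently accepted.

# Known limitations

* The branch-site null is a boundary case; df = 1 is the reproduced
  convention, and conservative.
* The `"beb"` grid is a simplified rendering of grid-averaged empirical
  Bayes, not a reimplementation of any specific published scheme; `"neb"`
  is the default precisely because it is exactly checkable.
* Two-stage branch-length estimation is an approximation; joint estimation
  is available but not the tested default path.
* No indel model, no synonymous-rate variation, no M7/M8-style beta
  mixtures, no multi-level branch partitions beyond
  foreground/background.
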