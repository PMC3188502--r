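---
title: "Inferring binding-site formation by local sequence duplication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring binding-site formation by local sequence duplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupscan)
```

## The question

Transcription factor binding sites cluster tightly inside cis-regulatory
modules. How do new sites arise next to existing ones? Point mutations alone
form isolated sites slowly, because a functional site must first be seeded
by a marginally binding sequence. A local duplication, by contrast, copies
an existing site a few tens of base pairs away and hands selection a
ready-made seed — for the same factor or, after divergence, for a different
one. `dupscan` implements the statistical machinery to detect this mode of
evolution from sequence alone: model-free similarity statistics that reveal
an excess of near-identical sequence pairs at short range, and an explicit
evolutionary likelihood that asks, for a pair of annotated binding sites,
whether their sequences are better explained by common or by independent
descent.

## Model-free layer: autocorrelation and similarity information

The autocorrelation `Pi(r) = P(r) - pbar^2` compares the probability that
two nucleotides `r` bp apart are identical with the match probability
`pbar^2 = sum_alpha p_alpha^2` of two random letters of the local
composition. The composition term is evaluated in a local window (default
500 bp, truncated at module edges) centred on each pair's midpoint; we
centre on the midpoint because the statistic should be symmetric in the two
pair members. Changing the window length moves the baseline of the profile
but not its short-range structure, which is the part carrying the signal.

`Pi(r)` counts single matched letters; clustering of matched letters into
motif-length words is what distinguishes duplicated sites from compositional
drift. The pair detector therefore finds, at fixed lag `r` and word length
`l`, the set of non-overlapping left positions maximising the summed
similarity, with every pair above a threshold `q_c`. This is a
weighted-interval-scheduling problem; the recursion

    S_x = max(S_{x-1}, S_{x-l} + k(x) * [k(x) >= q_c])

with backtracking gives the exact global optimum in linear time (ties
prefer `S_{x-1}`, making the reported set leftmost-minimal, a determinism
choice with no effect on the optimum). Similarity is exact nucleotide
identity — no transition/transversion weighting — and windows touching an
ambiguous `N` are disqualified rather than partially matched.

Raw pair counts mean nothing without a null: compositionally biased
sequence produces similar pairs by chance. The calibration null is a
first-order Markov chain fitted *per module* (single- and di-nucleotide
frequencies), from which 1000 realisations per module are drawn by default
(configurable; the suite uses 120–300 to keep runtimes at desk scale). The
excess pair count is converted to information units,

    I~(r, l) = (n - n0) * H(qbar; q0) / N ,

where `H(q; q0) = l [ q ln(q/q0) + (1-q) ln((1-q)/(1-q0)) ]` is the binary
relative entropy between the observed mean pair similarity and the
background match probability `q0 = sum p0^2`. The threshold `q_c` is not a
free dial: it is selected by scanning the achievable grid `{ceil(q0*l)/l,
..., 1}` and keeping the value that maximises `I~` — a maximum-likelihood
choice (scanning below `q0` is pointless because `H` vanishes there). A
negative excess is reported as computed and flagged, never clipped: silent
clipping would hide a miscalibrated null. Summing `I~` over lags per word
length and locating the maximum recovers the characteristic motif length;
on synthetic modules with planted 7-mers the scan peaks at 6–8 bp.

## Evolutionary layer: common versus independent descent

Each factor's position weight matrix `q_i(alpha)` defines an additive
(Halpern–Bruno) fitness landscape `f_i(alpha) = ln(q_i(alpha)/p0(alpha))`,
scaled in units of the effective population size. Its defining property is
that the motif distribution is the stationary state of the
mutation–selection–drift dynamics, and that the mean fitness of motif-drawn
sites equals the motif's sequence information `I`. Substitution rates are
Kimura–Ohta: `u(alpha->beta) = mu * m(alpha->beta) * g(s)` with
`g(s) = s/(1-e^{-s})` and `s` the fitness difference. We set `mu = 1` and
measure the evolutionary distance `t` in expected neutral substitutions per
site, since `t` and `mu` are not separately identifiable.

Two mutation models are available. The default weights mutation by the
background, `m(alpha->beta) = p0(beta)`, which makes the neutral process
stationary at `p0`, the selected process stationary at `q_i`, and detailed
balance exact — the property the common-descent likelihood relies on. The
`uniform` model (`m = 1`) is retained as an option; with a non-uniform
background its stationary distribution is `q_i/p0` renormalised rather than
`q_i`, and the package emits a message when this approximation is
triggered.

Propagators `G_i(t) = exp(t R_i)` are computed by symmetrised
eigendecomposition of the reversible 4x4 rate matrices (exact to rounding;
entries below zero by less than 1e-12 are clipped and rows renormalised).
For a site pair (a, b) bound by factors A and B, the two hypotheses are:

* independent descent: `P_ind = Q_A(a) Q_B(b)`;
* common descent: a duplicated ancestor `c`, stationary in the A- or
  B-ensemble with equal prior, diverged for time `t` under each factor's
  landscape. Detailed balance turns the ancestor sum into
  `Q_A(a) * sum_c G_A(c|a;t) G_B(b|c;t)` per column.

The duplication score `S = ln(P_dup/P_ind)` is a proper log-likelihood
ratio: `E_ind[e^S] = 1` exactly, `E_ind[S] <= 0 <= E_dup[S]`, and `S -> 0`
as `t -> infinity` — common descent becomes undetectable once divergence
erases the shared history. These identities are verified exhaustively for
short motifs in the test suite.

When motif lengths differ the pair is compared over `min(L_A, L_B)`
gaplessly aligned columns; the offset maximises `P_dup` at the working `t`
(ties to the smallest offset) and the *same* columns enter `P_ind`, so the
ratio stays well-defined; the unaligned overhang contributes its motif
marginal to both and cancels in `S`. Indels and spacing changes between
sites are deliberately not modelled: the score captures sequence similarity
within site pairs only.

The single distance parameter `t*` is fitted by maximising the total score
`sum S(pair, t)` over a grid of 30 log-spaced points in `[1e-3, 1e3]`
(units of 1/mu). A maximum on the grid boundary is flagged: it means the
data carry no interior duplication signal. An alternative distribution-level
likelihood-ratio fit is possible in principle; total-score maximisation is
used because it is what the simulation protocol validates directly
(recovery of `t*` within a factor two of the true mean divergence time).

## Mixture decomposition and controls

The observed score distribution of nearby pairs (default: mutual distance
up to 50 bp) is decomposed as
`Q(S) = (1-rho) Q_ind(S) + rho Q_dup(S)`. `Q_ind` is estimated
nonparametrically (kernel density) from pairs in a common module at large
distance (default >= 100 bp): using same-module pairs assigns shared local
composition (GC content) to the background rather than to spurious common
descent. `Q_dup` is a two-parameter Gaussian location–scale component with
its location constrained above the background mean, since duplicated pairs
score higher. The fit maximises the likelihood over a coarse grid refined
by Nelder–Mead. Two devices keep `rho` identifiable when the data carry no
excess: the location constraint (a duplication component sitting on top of
`Q_ind` would make `rho` arbitrary), and a likelihood-ratio acceptance gate
(the mixture must beat the pure background model by a chi-squared margin at
three free parameters, otherwise the conservative `rho = 0` is reported).
Without the gate the estimator is undefined at the null; with it, the mean
recovered `rho` over replicates is unbiased to within a few percent at
planted fractions 0, 0.25 and 0.5.

Evidence is summarised by `Lambda = n * D`, the number of pairs times the
relative entropy between the observed near-score distribution and `Q_ind`,
computed on a common binning with both distributions normalised (so
`D >= 0` by Gibbs' inequality). The bootstrap interval on `rho` resamples
pairs; `Lambda` rescaled to the lower bound is reported as the conservative
evidence. Two controls accompany the fit: the distance-resolved profile
`D(r)` (decaying with distance when the duplicated fraction is local), and
a factor-pair scramble test comparing per-factor-pair mean scores with
their distribution after permuting scores across pairs
(Kolmogorov–Smirnov), which checks that the signal is not driven by a few
factor combinations.

## Adaptive potential: binding correlations

The binding correlation `C(A->B) = sum_i sum_alpha q^A_i(alpha)
ln(q^B_i(alpha)/p0(alpha))` is the mean fitness of A-drawn sites under B's
landscape — a cross entropy. Exactly, `C(A->A) = I_A` and
`C(A->B) = I_A - D(Q_A || Q_B) <= I_A`; the relevant comparison point is
the background fitness `-D(P0 || Q_B) <= 0`. A duplicated A-site whose
correlation with B sits well above background is a usable seed from which
selection can build a functional B-site. Alignment of unequal-length
motifs maximises `C` over full-overlap offsets (the offset is reported);
results are given in nats and bits.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

* `sample_markov()` draws background modules from the fitted first-order
  chain;
* `plant_correlated_modules()` plants exact or noised duplicate pairs at
  controlled lags in ~1 kb Markov modules, returning the truth table;
* `simulate_pair_ensemble()` follows the duplication–divergence protocol:
  per factor pair, duplication events with ancestors drawn with equal
  probability from either motif ensemble, divergence times exponential with
  mean `tau_bar`, and site pairs drawn per position from the two
  propagators at that time; independent pairs are drawn directly from the
  motif distributions. The protocol-scale ensemble is 500 events x 50
  pairs = 25000 pairs per factor pair; the suite and the acceptance script
  run a desk-scale 100 x 10 version with six factor pairs (four different,
  two equal), `tau_bar = 0.4`, and synthetic length-8 motifs drawn from a
  symmetric Dirichlet (concentration 0.25, a realistic ~1.4 nats of
  information per position). `tau_bar` is a free configuration parameter;
  validation is relative to the configured value.

All generators take explicit seeds and are bit-reproducible; a single RNG
stream per ensemble drives the draws in a documented order. What the
generator does *not* emulate: indel and repeat-expansion dynamics,
epistasis within sites (the landscape is additive), correlated columns in
real position weight matrices, and heterogeneous local GC structure beyond
first order. Passing tests therefore demonstrate the correctness and
calibration of the inference machinery under its own model assumptions, not
the empirical conclusions obtainable only from curated genomic data.

## Numerical choices and degenerate inputs

* Pseudocounts: motifs and backgrounds receive a total pseudocount of 0.5
  per position/estimate (distributed proportionally to the background for
  motifs, uniformly for the background itself) so that logarithms and
  rates are always finite.
* `g(s)` is evaluated in branch-stable form (`1 + s/2` near zero,
  `-s e^s/(1-e^s)` for negative `s`), exact at `g(0) = 1` and overflow-free
  at `|s| = 700`.
* DP ties prefer the skip branch; the brute-force enumeration oracle agrees
  with the DP optimum on every random instance tried (thousands of cases).
* Sites at module edges: flanks truncate; an empty flank falls back to the
  module-wide composition with a warning. Annotations whose module cannot
  supply a full motif-length window are skipped with a warning.
* `N` symbols never match, are excluded from composition counts, and
  disqualify extraction windows.
* Site curation iterates its three filters (factor in >= 2 modules, no
  overlap, no X chromosome) to a fixed point, making it idempotent.
* Degenerate mixture inputs (zero-variance background sample, undersized
  samples) are rejected with errors rather than fitted.

## Problem sizes

The test suite and `scripts/acceptance.R` use: 12 modules of 800 bp with 4
planted pairs each and 300 Markov null realisations for the similarity
layer; exhaustive enumeration over all sequence pairs for motif lengths 2–3
for the likelihood identities; 6 factor pairs x (100 events x 10 pairs +
1000 independent pairs) for the simulation protocol; and 100 replicates of
n = 300 mixtures per planted fraction. These sizes give stable statistics
(Monte-Carlo error well inside the asserted tolerances) at about two
minutes of total compute.

## Known limitations

The additive landscape ignores epistasis between positions within a site,
which is known to bias `t` estimates downward; energy-based fitness models
would refine the distance scale but not the descent classification. The
score is blind to spacing changes between sites, so duplication events
followed by indels are detected only through their residual point-substituted
similarity. `Q_dup` is a location–scale family, a deliberate simplification
of the true (mixture-over-times) common-descent score distribution; it is
adequate for estimating `rho` but not for interpreting the component's
shape. Finally, module *prediction* from similarity scores is outside the
package's scope.
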