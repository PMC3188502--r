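# dupscan

Statistical inference of **binding-site formation by local sequence
duplication** in cis-regulatory modules.

Regulatory modules in higher eukaryotes are dense clusters of transcription
factor binding sites. A new functional site rarely arises from random
background by point mutations alone — selection needs a *seed* sequence with
marginal binding to latch onto. A local duplication of an existing site
places exactly such a seed a few tens of base pairs away, where it can
diverge into a site for the same or a different factor. `dupscan` provides,
for computational and evolutionary genomicists, the complete inference
chain to detect and quantify this mode of evolution from sequence data:

1. **Model-free similarity statistics.** Distance-resolved sequence
   autocorrelation Π(r) = P(r) − p̄², and the total similarity information
   of non-overlapping site pairs at lag *r* and word length *ℓ*,
   Ĩ(r, ℓ) = Δn · H(q̄; q₀) / N, where the maximum-similarity pair set is
   found exactly by a dynamic-programming recursion
   S_x = max(S_{x−1}, S_{x−ℓ} + k(x)·[k(x) ≥ q_c]) and the excess Δn is
   calibrated against a per-module first-order Markov null.
2. **An evolutionary likelihood for site pairs.** Halpern–Bruno fitness
   landscapes f_i(α) = ln(q_i(α)/p₀(α)) built from position weight
   matrices, Kimura–Ohta substitution rates u = μ·m·s/(1−e^(−s)), and the
   propagators G(t) = e^(tR) that yield the likelihoods of independent
   descent, P_ind = Q_A(a)·Q_B(b), and of common descent via a duplicated
   ancestor, P_dup. The duplication score S = ln(P_dup/P_ind) is a proper
   log-likelihood ratio (E_ind[e^S] = 1).
3. **Mixture quantification.** The score distribution of nearby pairs is
   decomposed as Q = (1−ρ)·Q_ind + ρ·Q_dup to estimate the duplicated
   fraction ρ, with total evidence Λ = n·D (D the relative entropy between
   observed and background score distributions), a distance-resolved
   profile D(r), and a factor-pair scramble control.
4. **Adaptive potential.** Binding correlations
   C(A→B) = Σ q^A_i(α) ln(q^B_i(α)/p₀(α)) measure how useful duplicated
   A-sites are as seeds for B-sites, against the identities C(A→A) = I_A
   and background fitness −D(P₀‖Q_B).

A synthetic-data layer (Markov backgrounds, planted duplicate pairs,
duplication–divergence pair ensembles) generates every input the pipeline
needs, so the whole analysis can be exercised and validated without
external genome resources. Standard formats are supported throughout:
FASTA for modules, BED6+1 for site annotations, JASPAR-style matrix files
for motifs.

## Worked example

Simulate a duplication–divergence ensemble for one factor pair, recover the
divergence time, and estimate the duplicated fraction of a 50:50 mixture:

```r
library(dupscan)
bg <- background(p0 = rep(0.25, 4))
set.seed(2)
motifs <- list(bcd = random_motif(8, "bcd", concentration = 0.25),
               kr  = random_motif(8, "kr",  concentration = 0.25))

cfg <- simulation_config(list(c("bcd", "kr")), motifs, bg,
                         tau_bar = 0.4, n_events = 100,
                         pairs_per_event = 10, n_independent = 1000,
                         seed = 3)
ens <- simulate_pair_ensemble(cfg)
#> <simulated_ensemble> 2000 pairs (common: 1000, independent: 1000),
#>                      1 factor pair(s), tau_bar = 0.4

st <- infer_tstar(subset(ens$pairs, label == "common"), motifs, bg)
st
#> <score_table> 1000 pairs, t* = 0.3039, mean S = 5.041
```

The fitted evolutionary distance t\* = 0.30 (in expected neutral
substitutions per site) recovers the simulated mean divergence time
τ̄ = 0.4 within the grid resolution, and common-descent pairs score
strongly positive (mean S ≈ 5 nats favours duplication). Mixing 150
common-descent with 150 independent scores and fitting the mixture
against the independent background:

```r
scores <- infer_tstar(ens$pairs, motifs, bg, t_grid = st$t_star)$scores$S
near <- c(sample(scores[ens$pairs$label == "common"], 150),
          sample(scores[ens$pairs$label == "independent"], 150))
far <- scores[ens$pairs$label == "independent"]
fit_mixture(near, far, n_boot = 100, seed = 4)
#> <mixture_fit> rho = 0.423 [0.354, 0.519], mu_dup = 5.80, sigma_dup = 4.08
#>   n = 300, D = 4.1011 nats, Lambda = 1230.32
```

The planted duplicated fraction 0.5 lies inside the bootstrap interval of
the estimate ρ̂ = 0.42, and the evidence Λ = n·D is overwhelming. The
binding correlation quantifies the seeding potential between the two
(here unrelated) motifs:

```r
binding_correlation(motifs$bcd, motifs$kr, bg)
#> <correlation_record> C(bcd -> kr) = -3.488 nats (-5.032 bits), offset 0
#>   I_a = 2.273, I_b = 2.534, background fitness = -2.640 nats
```

A C value below the background fitness (−2.64 nats) says duplicated *bcd*
sites are no better seeds for *kr* than random sequence — as expected for
independently drawn motifs; correlated motif pairs score far above it.

A thin command-line wrapper over the same functions is installed at
`inst/cli/dupscan` (subcommands `autocorr`, `pairsim`, `curate`,
`bindcorr`, `simulate`).

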