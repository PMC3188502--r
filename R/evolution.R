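#' Information-based (Halpern-Bruno) fitness landscape of a motif
#'
#' The additive landscape assigns each position-nucleotide combination the
#' scaled fitness contribution
#' \deqn{f_i(\alpha) = \ln\frac{q_i(\alpha)}{p_0(\alpha)},}
#' so that the motif distribution Q is the mutation-selection-drift
#' equilibrium of the substitution process built on it. Fitness values are
#' dimensionless (scaled in units of the effective population size). The mean
#' fitness of sites drawn from the motif equals the sequence information:
#' `sum_i sum_alpha q_i(alpha) f_i(alpha) = I`.
#'
#' @param motif a [motif()] object.
#' @param background a [background()] object.
#' @return object of class `"fitness_landscape"`: list with `motif`,
#'   `background` and `f` (L x 4 matrix).
#' @export
build_fitness <- function(motif, background) {
  f <- log(motif$freq) - rep(log(background$p0), each = motif$length)
  dimnames(f) <- list(NULL, DNA_BASES)
  structure(list(motif = motif, background = background, f = f),
            class = "fitness_landscape")
}

#' Scaled fitness of a site sequence under a landscape
#'
#' `F(a) = sum_i f_i(a_i)`; additive over positions, maximal at the motif
#' consensus.
#'
#' @param landscape a [build_fitness()] object.
#' @param sequence DNA string or integer-coded sequence of the motif length.
#' @return scaled fitness (dimensionless).
#' @export
site_fitness <- function(landscape, sequence) {
  s <- if (is.character(sequence)) seq_to_int(sequence) else as.integer(sequence)
  if (length(s) != nrow(landscape$f))
    stop("sequence length != motif length")
  if (anyNA(s)) return(NA_real_)
  sum(landscape$f[cbind(seq_along(s), s)])
}

#' Kimura-Ohta fixation factor
#'
#' `g(s) = s / (1 - exp(-s))`, the ratio of the fixation probability of a
#' mutant with scaled selection coefficient `s` to the neutral fixation
#' probability. Evaluated in a numerically stable form: `g(0) = 1` by the
#' series limit, `g(s) ~ s` for large positive `s`, and
#' `g(s) ~ |s| e^{-|s|}` for large negative `s`.
#'
#' @param s scaled selection coefficient(s).
#' @return fixation factor(s), always > 0.
#' @export
kimura_g <- function(s) {
  out <- numeric(length(s))
  small <- abs(s) < 1e-8
  out[small] <- 1 + s[small] / 2            # series: 1 + s/2 + s^2/12 - ...
  pos <- !small & s > 0
  out[pos] <- s[pos] / (1 - exp(-s[pos]))
  neg <- !small & s < 0
  out[neg] <- -s[neg] * exp(s[neg]) / (1 - exp(s[neg]))
  out
}

#' Kimura-Ohta substitution process on a fitness landscape
#'
#' Builds the per-position 4 x 4 rate matrices
#' \deqn{u(\alpha \to \beta) = \mu\, m(\alpha \to \beta)\, g(s), \qquad
#'       s = f_i(\beta) - f_i(\alpha),}
#' combining mutation with the fixation probability of the mutant. Under the
#' default background-weighted mutation model, `m(alpha -> beta) =
#' p0(beta)`, the neutral process is stationary at the background and the
#' selected process is stationary at the motif distribution `q_i`, with
#' detailed balance `q_i(alpha) u(alpha->beta) = q_i(beta) u(beta->alpha)`
#' holding exactly. The `"uniform"` model (`m = 1` for every substitution)
#' is also available; its stationary distribution is proportional to
#' `q_i / p0` and the motif distribution is stationary only for uniform
#' background. Each rate matrix is reversible, so propagators can be computed
#' by symmetrized eigendecomposition (cached here).
#'
#' @param landscape a [build_fitness()] landscape.
#' @param mu neutral rate scale; time is measured in units of 1/mu
#'   (default 1, not separately identifiable from t).
#' @param mutation_model `"background"` (default) or `"uniform"`.
#' @return object of class `"substitution_process"`: list with `landscape`,
#'   `mu`, `mutation_model`, `R` (list of L rate matrices, rows summing to
#'   0), `stationary` (list of L distributions) and the cached spectral
#'   decompositions.
#' @export
build_rates <- function(landscape, mu = 1,
                        mutation_model = c("background", "uniform")) {
  mutation_model <- match.arg(mutation_model)
  p0 <- landscape$background$p0
  L <- nrow(landscape$f)
  R <- vector("list", L)
  stationary <- vector("list", L)
  decomp <- vector("list", L)
  for (i in seq_len(L)) {
    f <- landscape$f[i, ]
    s <- outer(f, f, function(a, b) b - a)     # s[alpha, beta]
    if (any(!is.finite(s))) stop("non-finite selection coefficient")
    m <- if (mutation_model == "background")
      matrix(rep(p0, each = 4), 4, 4) else matrix(1, 4, 4)
    u <- mu * m * matrix(kimura_g(as.vector(s)), 4, 4)
    diag(u) <- 0
    diag(u) <- -rowSums(u)
    pi_i <- if (mutation_model == "background") landscape$motif$freq[i, ]
            else { w <- landscape$motif$freq[i, ] / p0; w / sum(w) }
    # symmetrize: D^{1/2} R D^{-1/2} is symmetric for a reversible chain
    sq <- sqrt(pi_i)
    sym <- (u * outer(sq, 1 / sq))
    sym <- (sym + t(sym)) / 2                  # kill rounding asymmetry
    e <- eigen(sym, symmetric = TRUE)
    R[[i]] <- u
    stationary[[i]] <- pi_i
    decomp[[i]] <- list(V = e$vectors, lambda = e$values, sq = sq)
  }
  structure(list(landscape = landscape, mu = mu,
                 mutation_model = mutation_model,
                 R = R, stationary = stationary, decomp = decomp),
            class = "substitution_process")
}

#' Evolutionary propagator G(t)
#'
#' Per-position transition-probability matrices `G_i(t) = exp(t R_i)` of the
#' substitution process, computed from the cached symmetrized
#' eigendecomposition of the reversible rate matrices. Entries below zero by
#' rounding (> -1e-12) are clipped and rows renormalised.
#'
#' @param process a [build_rates()] process.
#' @param t evolutionary distance in units of 1/mu (expected neutral
#'   substitutions per site); must be >= 0.
#' @return object of class `"propagator"`: list with `process`, `t` and `G`
#'   (list of L stochastic matrices, `G[[i]][a, b] = P(a -> b in time t)`).
#' @export
propagate <- function(process, t) {
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop("t must be a single non-negative number")
  L <- length(process$R)
  G <- vector("list", L)
  for (i in seq_len(L)) {
    d <- process$decomp[[i]]
    symexp <- d$V %*% (exp(t * d$lambda) * t(d$V))
    g <- symexp * outer(1 / d$sq, d$sq)
    g[g < 0] <- 0
    g <- g / rowSums(g)
    dimnames(g) <- list(DNA_BASES, DNA_BASES)
    G[[i]] <- g
  }
  structure(list(process = process, t = t, G = G), class = "propagator")
}

#' A pair of binding-site sequences with their evolutionary machinery
#'
#' Bundles two motif-oriented site sequences with their motifs, the shared
#' background, and the cached substitution processes needed to evaluate the
#' likelihoods of independent and common descent. When the motif lengths
#' differ the pair is compared over `min(L_A, L_B)` gaplessly aligned
#' columns; the alignment offset is chosen where the likelihood is evaluated
#' (see [p_duplication()]).
#'
#' @param seq_a,seq_b site sequences (strings), lengths matching their
#'   motifs.
#' @param motif_a,motif_b [motif()] objects.
#' @param background shared [background()].
#' @param distance genomic distance r in bp between the 5'-most start
#'   coordinates (optional, used by downstream distance profiles).
#' @param mu,mutation_model passed to [build_rates()].
#' @return object of class `"site_pair"`.
#' @export
site_pair <- function(seq_a, seq_b, motif_a, motif_b, background,
                      distance = NA_real_, mu = 1,
                      mutation_model = "background") {
  a <- if (is.character(seq_a)) seq_to_int(seq_a) else as.integer(seq_a)
  b <- if (is.character(seq_b)) seq_to_int(seq_b) else as.integer(seq_b)
  if (length(a) != motif_a$length) stop("seq_a length != motif_a length")
  if (length(b) != motif_b$length) stop("seq_b length != motif_b length")
  if (anyNA(a) || anyNA(b)) stop("ambiguous bases not allowed in site pairs")
  proc_a <- build_rates(build_fitness(motif_a, background),
                        mu = mu, mutation_model = mutation_model)
  proc_b <- build_rates(build_fitness(motif_b, background),
                        mu = mu, mutation_model = mutation_model)
  structure(list(a = a, b = b, motif_a = motif_a, motif_b = motif_b,
                 background = background, distance = distance,
                 process_a = proc_a, process_b = proc_b,
                 mutation_model = mutation_model),
            class = "site_pair")
}

# Aligned column indices at a given offset. The longer motif is shifted by
# `offset`; returns per-aligned-column indices into A and B plus overhang
# columns of the longer motif.
.pair_alignment <- function(pair, offset) {
  La <- pair$motif_a$length; Lb <- pair$motif_b$length
  Lmin <- min(La, Lb)
  if (offset < 0 || offset > abs(La - Lb)) stop("offset out of range")
  if (La >= Lb) {
    ia <- offset + seq_len(Lmin); ib <- seq_len(Lmin)
    over <- list(which = "a", cols = setdiff(seq_len(La), ia))
  } else {
    ia <- seq_len(Lmin); ib <- offset + seq_len(Lmin)
    over <- list(which = "b", cols = setdiff(seq_len(Lb), ib))
  }
  list(ia = ia, ib = ib, overhang = over, aligned_length = Lmin)
}

# Product of overhang marginals (identical factor in P_ind and P_dup, so it
# cancels in the duplication score but keeps both likelihoods normalised
# over the full pair space).
.overhang_prob <- function(pair, al) {
  ov <- al$overhang
  if (!length(ov$cols)) return(1)
  if (ov$which == "a")
    prod(pair$motif_a$freq[cbind(ov$cols, pair$a[ov$cols])])
  else
    prod(pair$motif_b$freq[cbind(ov$cols, pair$b[ov$cols])])
}

#' Likelihood of a site pair under independent descent
#'
#' Product over aligned columns of `q^A_i(a_i) q^B_j(b_j)`; unaligned
#' overhang columns of the longer motif contribute that motif's marginal so
#' the likelihood is comparable with [p_duplication()] over the same
#' columns. Independent of evolutionary distance by construction.
#'
#' @param pair a [site_pair()].
#' @param offset gapless alignment offset in `[0, |L_A - L_B|]`
#'   (default 0; the score functions pass the offset selected for
#'   [p_duplication()]).
#' @return probability.
#' @export
p_independent <- function(pair, offset = 0) {
  al <- .pair_alignment(pair, offset)
  pa <- prod(pair$motif_a$freq[cbind(al$ia, pair$a[al$ia])])
  pb <- prod(pair$motif_b$freq[cbind(al$ib, pair$b[al$ib])])
  pa * pb * .overhang_prob(pair, al)
}

#' Likelihood of a site pair under common descent (duplication)
#'
#' Joint probability that the two sites descend from a duplicated common
#' ancestor `c` and diverged for an evolutionary distance `t` under
#' selection to bind their respective factors. With the ancestor stationary
#' in the A-ensemble, detailed balance of the substitution dynamics rewrites
#' the ancestor sum as
#' \deqn{P^{(A)}(a, b; t) = Q_A(a) \sum_c G_A(c \mid a; t)\, G_B(b \mid c; t)}
#' per aligned column; the B-ancestral term is built symmetrically, and the
#' two histories are weighed with equal prior probability:
#' `P_dup = (P^(A) + P^(B)) / 2`. At `t = 0` this collapses to a point mass
#' on identical aligned sequences; as `t -> infinity` it converges to
#' [p_independent()], so common descent becomes undetectable.
#'
#' @param pair a [site_pair()].
#' @param t evolutionary distance (>= 0), units of 1/mu.
#' @param offset alignment offset; `NULL` (default) selects, for unequal
#'   motif lengths, the offset maximising the likelihood (ties to the
#'   smallest offset).
#' @return probability, with the chosen offset as attribute `"offset"`.
#' @export
p_duplication <- function(pair, t, offset = NULL) {
  if (t < 0) stop("t must be >= 0")
  if (pair$mutation_model == "uniform" &&
      max(abs(pair$background$p0 - 0.25)) > 1e-9)
    message("uniform mutation model with non-uniform background: ",
            "motif stationarity (and the detailed-balance rewriting) ",
            "holds only approximately")
  Ga <- propagate(pair$process_a, t)$G
  Gb <- propagate(pair$process_b, t)$G
  offsets <- if (is.null(offset))
    0:abs(pair$motif_a$length - pair$motif_b$length) else offset
  best <- -Inf; best_o <- offsets[1]
  for (o in offsets) {
    al <- .pair_alignment(pair, o)
    pA <- 1; pB <- 1
    for (k in seq_len(al$aligned_length)) {
      i <- al$ia[k]; j <- al$ib[k]
      a <- pair$a[i]; b <- pair$b[j]
      MA <- Ga[[i]] %*% Gb[[j]]     # sum_c G_A(a->c) G_B(c->b)
      MB <- Gb[[j]] %*% Ga[[i]]
      pA <- pA * pair$motif_a$freq[i, a] * MA[a, b]
      pB <- pB * pair$motif_b$freq[j, b] * MB[b, a]
    }
    p <- 0.5 * (pA + pB) * .overhang_prob(pair, al)
    if (p > best) { best <- p; best_o <- o }
  }
  structure(best, offset = best_o)
}
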