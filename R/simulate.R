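#' Sample sequences from a first-order Markov chain
#'
#' Generates sequences whose single- and di-nucleotide statistics match a
#' [background()] model; this is the null background used throughout the
#' similarity analysis.
#'
#' @param background a [background()] with a dinucleotide matrix.
#' @param length sequence length in bp.
#' @param n_sequences number of sequences.
#' @param seed optional RNG seed.
#' @return character vector of `n_sequences` sequences.
#' @export
sample_markov <- function(background, length, n_sequences = 1,
                          seed = NULL) {
  if (is.null(background$dinucleotide))
    stop("background carries no dinucleotide conditionals")
  tr <- background$dinucleotide
  if (any(!is.finite(tr)) || any(abs(rowSums(tr) - 1) > 1e-6))
    stop("degenerate transition matrix")
  if (any(diag(tr) >= 1 - 1e-12) && any(diag(tr) < 1 - 1e-12))
    stop("absorbing state in transition matrix")
  if (!is.null(seed)) set.seed(seed)
  raw <- markov_sample_cpp(background$p0, tr, as.integer(length),
                           as.integer(n_sequences))
  vapply(raw, int_to_seq, character(1))
}

#' Random position weight matrix
#'
#' Draws each position of a motif from a symmetric Dirichlet; smaller
#' `concentration` gives peakier (more informative) motifs. A convenience
#' generator for simulations and validation.
#'
#' @param length motif length L.
#' @param name motif name.
#' @param concentration Dirichlet concentration per nucleotide
#'   (default 0.3; ~1.3 nats of information per position at uniform
#'   background).
#' @param seed optional RNG seed.
#' @return a [motif()] object.
#' @export
random_motif <- function(length, name = "motif", concentration = 0.3,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(stats::rgamma(length * 4, shape = concentration), length, 4)
  motif(g / rowSums(g), name = name)
}

# draw n sequences (rows) from a motif's product distribution
.sample_from_motif <- function(motif, n) {
  L <- motif$length
  out <- matrix(0L, n, L)
  for (i in seq_len(L))
    out[, i] <- sample.int(4L, n, replace = TRUE, prob = motif$freq[i, ])
  out
}

#' Simulation configuration for binding-site pair ensembles
#'
#' @param motif_pairs list of length-2 character vectors of factor names
#'   (equal motif lengths within a pair; pairs of equal factors are
#'   allowed).
#' @param motifs named list of [motif()] objects.
#' @param background shared [background()].
#' @param tau_bar mean divergence time of the exponential distribution
#'   (units of 1/mu); must be > 0.
#' @param n_events duplication events per factor pair.
#' @param pairs_per_event site pairs drawn per event.
#' @param n_independent independent-descent pairs per factor pair
#'   (default `n_events * pairs_per_event`).
#' @param seed RNG seed (the ensemble is bit-reproducible given the
#'   configuration and seed).
#' @param mutation_model,mu passed to [build_rates()].
#' @return object of class `"simulation_config"`.
#' @export
simulation_config <- function(motif_pairs, motifs, background, tau_bar,
                              n_events = 500, pairs_per_event = 50,
                              n_independent = NULL, seed = 1,
                              mutation_model = "background", mu = 1) {
  stopifnot(tau_bar > 0, n_events >= 1, pairs_per_event >= 1)
  n_independent <- n_independent %||% (n_events * pairs_per_event)
  for (fp in motif_pairs) {
    if (length(fp) != 2L) stop("each motif pair must name two factors")
    if (any(!fp %in% names(motifs)))
      stop("unknown factor in pair: ", paste(fp, collapse = ", "))
    if (motifs[[fp[1]]]$length != motifs[[fp[2]]]$length)
      stop("simulated factor pairs must have equal motif lengths (",
           paste(fp, collapse = ", "), ")")
  }
  structure(list(motif_pairs = motif_pairs, motifs = motifs,
                 background = background, tau_bar = tau_bar,
                 n_events = as.integer(n_events),
                 pairs_per_event = as.integer(pairs_per_event),
                 n_independent = as.integer(n_independent),
                 seed = as.integer(seed),
                 mutation_model = mutation_model, mu = mu),
            class = "simulation_config")
}

#' Simulate binding-site pair ensembles of common and independent descent
#'
#' For every configured factor pair (A, B), common-descent pairs are
#' generated by the duplication-divergence protocol: for each of `n_events`
#' duplication events the last common ancestor `c` is drawn with equal
#' probability from the A- or the B-ensemble (per-position motif
#' distribution), the divergence time `tau` is drawn from an exponential
#' distribution with mean `tau_bar`, and `pairs_per_event` site pairs are
#' drawn per position as `a ~ G_A(. | c; tau)`, `b ~ G_B(. | c; tau)` under
#' selection to bind A and B respectively. Independent-descent pairs are
#' drawn directly as `a ~ Q_A`, `b ~ Q_B`. A single RNG stream (seeded from
#' the configuration) drives the whole ensemble, in the order: per factor
#' pair, ancestors and times first, then pair draws event by event, then
#' independent pairs.
#'
#' @param config a [simulation_config()].
#' @return object of class `"simulated_ensemble"`: list with `pairs`
#'   (data.frame: `factor_a`, `factor_b`, `label` in {common, independent},
#'   `event`, `tau`, `seq_a`, `seq_b`) and `config`.
#' @export
simulate_pair_ensemble <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("config must be a simulation_config")
  set.seed(config$seed)
  motifs <- config$motifs
  proc <- lapply(motifs, function(m)
    build_rates(build_fitness(m, config$background), mu = config$mu,
                mutation_model = config$mutation_model))
  rows <- list()
  for (fp in config$motif_pairs) {
    fa <- fp[1]; fb <- fp[2]
    L <- motifs[[fa]]$length
    n_ev <- config$n_events; ppe <- config$pairs_per_event
    anc_from_a <- runif(n_ev) < 0.5
    taus <- rexp(n_ev, rate = 1 / config$tau_bar)
    anc <- matrix(0L, n_ev, L)
    for (e in seq_len(n_ev)) {
      src <- if (anc_from_a[e]) motifs[[fa]] else motifs[[fb]]
      anc[e, ] <- .sample_from_motif(src, 1)
    }
    A <- matrix(0L, n_ev * ppe, L); B <- matrix(0L, n_ev * ppe, L)
    for (e in seq_len(n_ev)) {
      Ga <- propagate(proc[[fa]], taus[e])$G
      Gb <- propagate(proc[[fb]], taus[e])$G
      idx <- (e - 1L) * ppe + seq_len(ppe)
      for (i in seq_len(L)) {
        c_i <- anc[e, i]
        A[idx, i] <- sample.int(4L, ppe, replace = TRUE,
                                prob = Ga[[i]][c_i, ])
        B[idx, i] <- sample.int(4L, ppe, replace = TRUE,
                                prob = Gb[[i]][c_i, ])
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      factor_a = fa, factor_b = fb, label = "common",
      event = rep(seq_len(n_ev), each = ppe),
      tau = rep(taus, each = ppe),
      seq_a = apply(A, 1, int_to_seq), seq_b = apply(B, 1, int_to_seq),
      stringsAsFactors = FALSE)
    if (config$n_independent > 0) {
      IA <- .sample_from_motif(motifs[[fa]], config$n_independent)
      IB <- .sample_from_motif(motifs[[fb]], config$n_independent)
      rows[[length(rows) + 1L]] <- data.frame(
        factor_a = fa, factor_b = fb, label = "independent",
        event = NA_integer_, tau = NA_real_,
        seq_a = apply(IA, 1, int_to_seq), seq_b = apply(IB, 1, int_to_seq),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(pairs = do.call(rbind, rows), config = config),
            class = "simulated_ensemble")
}

#' @export
print.simulated_ensemble <- function(x, ...) {
  tab <- table(x$pairs$label)
  cat(sprintf(
    "<simulated_ensemble> %d pairs (%s), %d factor pair(s), tau_bar = %g\n",
    nrow(x$pairs),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
    length(x$config$motif_pairs), x$config$tau_bar))
  invisible(x)
}

#' Plant correlated site pairs in Markov background modules
#'
#' Generates background modules from a first-order Markov model and
#' overwrites, at controlled lags, the right member of each planted pair
#' with a (possibly noised) copy of its left member. The ground-truth
#' positions are returned so that detection can be scored against them.
#'
#' @param n_modules number of modules.
#' @param module_length module length in bp; must exceed
#'   `max(pair_distances) + 2 * motif_length`.
#' @param motif_length length of the duplicated segment (bp).
#' @param pair_distances lags (bp, start-to-start) cycled over planted
#'   pairs.
#' @param n_pairs planted pairs per module (0 gives pure background).
#' @param background a [background()] with dinucleotide conditionals.
#' @param seed RNG seed.
#' @param mismatch_prob per-position probability that the right copy is
#'   mutated to a different base (default 0: exact duplicates).
#' @param max_tries placement attempts per pair before declaring the
#'   configuration infeasible.
#' @return list with `modules` (character vector) and `truth` (data.frame:
#'   `module`, `lag`, `left_start`, `right_start`; 1-based starts).
#' @export
plant_correlated_modules <- function(n_modules, module_length,
                                     motif_length, pair_distances,
                                     n_pairs, background, seed = NULL,
                                     mismatch_prob = 0, max_tries = 200) {
  if (n_pairs > 0 &&
      module_length <= max(pair_distances) + 2 * motif_length)
    stop("module_length must exceed max(pair_distances) + 2*motif_length")
  if (any(pair_distances < motif_length))
    stop("lags shorter than the motif make left and right copies overlap")
  if (!is.null(seed)) set.seed(seed)
  seqs <- sample_markov(background, module_length, n_modules)
  truth <- NULL
  l <- motif_length
  for (m in seq_len(n_modules)) {
    s <- seq_to_int(seqs[m])
    occupied <- rep(FALSE, module_length)
    k <- 0L
    for (p in seq_len(n_pairs)) {
      lag <- pair_distances[(p - 1L) %% length(pair_distances) + 1L]
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        x <- sample.int(module_length - lag - l + 1L, 1L)
        span <- x:(x + lag + l - 1L)
        if (any(occupied[span])) next
        copy <- s[x:(x + l - 1L)]
        if (mismatch_prob > 0) {
          mut <- runif(l) < mismatch_prob
          if (any(mut))
            copy[mut] <- vapply(copy[mut], function(a)
              sample(setdiff(1:4, a), 1L), integer(1))
        }
        s[(x + lag):(x + lag + l - 1L)] <- copy
        occupied[span] <- TRUE
        truth <- rbind(truth, data.frame(
          module = m, lag = lag, left_start = x, right_start = x + lag))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("infeasible placement: could not place pair ", p,
             " in module ", m)
    }
    seqs[m] <- int_to_seq(s)
  }
  list(modules = seqs, truth = truth)
}
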