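#' Maximum-similarity set of non-overlapping site pairs at fixed lag
#'
#' Finds, in one sequence, the set of left-site start positions `x` such that
#' (i) the left sites are pairwise non-overlapping (`|x_j - x_k| >= l`),
#' (ii) every pair similarity
#' `k(x) = (1/l) * #\{i < l : s[x+i] == s[x+r+i]\}` is at least `q_c`, and
#' (iii) the total similarity `sum k(x)` is the global maximum over all such
#' sets. The optimum is found by a weighted-interval-scheduling dynamic
#' programming recursion `S_x = max(S_{x-1}, S_{x-l} + k(x)[k(x) >= q_c])`
#' with backtracking; exact ties prefer `S_{x-1}`, giving the leftmost-minimal
#' selection. Similarity is exact nucleotide identity; windows touching an
#' ambiguous symbol (N) are disqualified.
#'
#' @param sequence a DNA string, or an integer-coded sequence (A=1..T=4, NA
#'   for N).
#' @param r lag between paired sites, in bp (distance between left and right
#'   site start positions).
#' @param l site (motif) length in bp.
#' @param q_c similarity threshold in (0, 1].
#' @return object of class `"pair_similarity_set"`: list with `lag`,
#'   `motif_length`, `threshold`, `positions` (1-based left-site starts),
#'   `n`, `total_similarity`, `mean_similarity` and `segment_length`. A
#'   sequence shorter than `r+l` yields an empty set.
#' @examples
#' s <- paste0("TTTTT", "ACGCGTA", "TTTTTTTT", "ACGCGTA", "TTTTT")
#' max_similarity_pairs(s, r = 15, l = 7, q_c = 6 / 7)$positions
#' @export
max_similarity_pairs <- function(sequence, r, l, q_c) {
  stopifnot(r >= 1, l >= 1, q_c > 0, q_c <= 1)
  s <- if (is.character(sequence)) seq_to_int(sequence) else as.integer(sequence)
  res <- dp_max_pairs_cpp(s, as.integer(r), as.integer(l), q_c)
  out <- structure(list(lag = r, motif_length = l, threshold = q_c,
                        positions = res$positions, n = res$n,
                        total_similarity = res$total,
                        mean_similarity = res$qbar,
                        segment_length = length(s)),
                   class = "pair_similarity_set")
  .check_pair_set(out, s)
  out
}

# Defensive check of the DP output contracts: non-overlap and threshold.
.check_pair_set <- function(ps, s) {
  if (ps$n == 0L) return(invisible(TRUE))
  x <- ps$positions
  if (any(diff(x) < ps$motif_length))
    stop("internal error: selected left sites overlap")
  for (xi in x) {
    a <- s[xi:(xi + ps$motif_length - 1L)]
    b <- s[(xi + ps$lag):(xi + ps$lag + ps$motif_length - 1L)]
    k <- sum(!is.na(a) & !is.na(b) & a == b) / ps$motif_length
    if (any(is.na(a)) || any(is.na(b)) || k < ps$threshold - 1e-9)
      stop("internal error: selected pair below threshold")
  }
  invisible(TRUE)
}

#' @export
print.pair_similarity_set <- function(x, ...) {
  cat(sprintf(
    "<pair_similarity_set> r = %d, l = %d, q_c = %.3f: n = %d pairs",
    x$lag, x$motif_length, x$threshold, x$n))
  if (!is.null(x$n0))
    cat(sprintf(", n0 = %.2f, I~ = %.3g nats/bp", x$n0, x$total_information))
  cat("\n")
  invisible(x)
}

#' First-order Markov null ensemble for similarity calibration
#'
#' Fits a first-order Markov chain (single-nucleotide and dinucleotide
#' conditional frequencies) to each input module and samples `n_null`
#' realisations of matching length per module. This is the null model against
#' which observed pair counts are calibrated: it preserves local composition
#' and dinucleotide structure but carries no planted long-range similarity.
#'
#' @param sequences character vector of module sequences.
#' @param n_null number of null realisations per module (default 1000).
#' @param seed optional RNG seed.
#' @return object of class `"markov_null"`: per-module lists of integer-coded
#'   null sequences.
#' @export
markov_null_ensemble <- function(sequences, n_null = 1000, seed = NULL) {
  stopifnot(n_null >= 1)
  if (!is.null(seed)) set.seed(seed)
  sequences <- as.character(sequences)
  per_module <- lapply(sequences, function(sq) {
    bg <- background(sq, dinucleotide = TRUE)
    markov_sample_cpp(bg$p0, bg$dinucleotide, nchar(sq), as.integer(n_null))
  })
  structure(list(per_module = per_module, n_null = as.integer(n_null),
                 lengths = nchar(sequences)),
            class = "markov_null")
}

#' Distance-resolved total similarity information
#'
#' Runs [max_similarity_pairs()] on the data modules and on every realisation
#' of a matched first-order Markov null ensemble, and converts the excess
#' pair count into information units: with `n` observed pairs of mean
#' similarity `qbar`, `n0` the mean null pair count, and `H(qbar; q0)` the
#' per-pair similarity information ([similarity_information()]), the total
#' similarity information per unit length is
#' \deqn{\tilde I(r, l) = \Delta n \cdot H(\bar q; q_0) / N, \qquad
#'       \Delta n = n - n_0,}
#' where `N` is the total module length. The similarity threshold `q_c` is
#' selected by scanning the achievable grid `{ceil(q0*l)/l, ..., 1}` and
#' keeping the value that maximises the total information (a maximum-
#' likelihood choice); a fixed `q_c` may be supplied instead. A negative
#' excess is reported as computed and flagged, never clipped.
#'
#' @param sequences character vector of module sequences (pooled).
#' @param r lag in bp.
#' @param l site length in bp.
#' @param null a [markov_null_ensemble()] built from the same modules.
#' @param q_c optional fixed threshold; default scans the achievable grid.
#' @return a `"pair_similarity_set"` with null-calibrated fields: `n0`,
#'   `n0_sd`, `delta_n`, `z` (excess in null standard deviations),
#'   `pair_information` (H, nats), `total_information` (nats/bp), `q0`,
#'   `null_counts` (per-realisation pooled counts) and `negative_excess`
#'   flag.
#' @export
total_similarity_information <- function(sequences, r, l, null,
                                         q_c = NULL) {
  if (!inherits(null, "markov_null")) stop("null must be a markov_null ensemble")
  if (length(null$per_module) != length(sequences))
    stop("null ensemble does not match the module set")
  sequences <- as.character(sequences)
  enc <- lapply(sequences, seq_to_int)
  N <- sum(lengths(enc))
  bg <- background(sequences, dinucleotide = FALSE)
  q0 <- bg$q0
  grid <- if (is.null(q_c)) seq(min(l, ceiling(q0 * l)), l) / l else q_c
  best <- NULL
  for (qc in grid) {
    n <- 0L; tot <- 0; pos <- vector("list", length(enc))
    for (m in seq_along(enc)) {
      res <- dp_max_pairs_cpp(enc[[m]], as.integer(r), as.integer(l), qc)
      n <- n + res$n; tot <- tot + res$total; pos[[m]] <- res$positions
    }
    n0_j <- numeric(null$n_null)
    for (m in seq_along(enc)) {
      bat <- dp_count_batch_cpp(null$per_module[[m]], as.integer(r),
                                as.integer(l), qc)
      n0_j <- n0_j + bat$n
    }
    qbar <- if (n > 0) tot / n else qc
    H <- similarity_information(qbar, q0, l)
    delta_n <- n - mean(n0_j)
    I_tilde <- delta_n * H / N
    cand <- list(qc = qc, n = n, total = tot, qbar = qbar, H = H,
                 n0_j = n0_j, delta_n = delta_n, I_tilde = I_tilde,
                 positions = pos)
    if (is.null(best) || I_tilde > best$I_tilde) best <- cand
  }
  structure(list(
    lag = r, motif_length = l, threshold = best$qc,
    positions = best$positions, n = best$n,
    total_similarity = best$total, mean_similarity = best$qbar,
    segment_length = N, q0 = q0,
    n0 = mean(best$n0_j), n0_sd = sd(best$n0_j),
    null_counts = best$n0_j,
    delta_n = best$delta_n,
    z = if (sd(best$n0_j) > 0) best$delta_n / sd(best$n0_j) else NA_real_,
    pair_information = best$H,
    total_information = best$I_tilde,
    negative_excess = best$delta_n < 0
  ), class = "pair_similarity_set")
}

#' Similarity-information scan over lags and site lengths
#'
#' Computes [total_similarity_information()] on a grid of lags and site
#' lengths, sums the information over lags for each length,
#' `I_total(l) = sum_r I~(r, l)`, and reports the length `l*` at which the
#' summed information is maximal. On sequence containing duplicated motifs
#' the scan peaks near the true motif length: shorter windows cover motifs
#' only partially, longer windows dilute them with uncorrelated flanks.
#'
#' @param sequences character vector of module sequences.
#' @param r_range integer vector of lags (bp).
#' @param l_range integer vector of site lengths (bp).
#' @param null a [markov_null_ensemble()] for the same modules.
#' @param q_c optional fixed threshold passed through.
#' @return list with `by_length` (data.frame: `l`, `I_total`, `z`, the summed
#'   excess in null standard deviations), `l_star`, and `detail` (data.frame
#'   with one row per (r, l): `r`, `l`, `q_c`, `n`, `n0`, `n0_sd`, `delta_n`,
#'   `z`, `q_bar`, `H`, `I_tilde`).
#' @export
scan_length <- function(sequences, r_range, l_range, null, q_c = NULL) {
  stopifnot(length(r_range) >= 1, length(l_range) >= 1)
  detail <- NULL
  by_length <- data.frame(l = integer(), I_total = numeric(), z = numeric())
  for (l in l_range) {
    Isum <- 0
    null_sum <- numeric(null$n_null)  # per-realisation sum_r H * n0_j / N
    for (r in r_range) {
      ps <- total_similarity_information(sequences, r, l, null, q_c = q_c)
      Isum <- Isum + ps$total_information
      null_sum <- null_sum +
        ps$pair_information * (ps$null_counts - ps$n0) / ps$segment_length
      detail <- rbind(detail, data.frame(
        r = r, l = l, q_c = ps$threshold, n = ps$n, n0 = ps$n0,
        n0_sd = ps$n0_sd, delta_n = ps$delta_n, z = ps$z,
        q_bar = ps$mean_similarity, H = ps$pair_information,
        I_tilde = ps$total_information))
    }
    z <- if (sd(null_sum) > 0) Isum / sd(null_sum) else NA_real_
    by_length <- rbind(by_length,
                       data.frame(l = l, I_total = Isum, z = z))
  }
  list(by_length = by_length,
       l_star = by_length$l[which.max(by_length$I_total)],
       detail = detail)
}
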