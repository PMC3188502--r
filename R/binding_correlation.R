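#' Binding correlation between two transcription factors
#'
#' Quantifies the adaptive potential of a duplicated A-site as a seed for a
#' B-site: the binding correlation is the average information-based fitness
#' of sites drawn from the A-motif under the B-factor's landscape,
#' \deqn{C_{A \to B} = \sum_i \sum_\alpha q^A_i(\alpha)\,
#'       \ln\frac{q^B_i(\alpha)}{p_0(\alpha)},}
#' summed over gaplessly aligned columns (a cross entropy up to a constant).
#' Two exact identities anchor the scale: `C(A->A) = I_A`, the sequence
#' information of the motif, and in general
#' `C(A->B) = I_A - D(Q_A || Q_B) <= I_A` over the aligned columns. It is
#' compared with the average fitness of background sequence under B,
#' `bg_B = -D(P0 || Q_B) <= 0`: an A-motif whose correlation lies well above
#' `bg_B` supplies seeds that selection can upgrade to functional B-sites.
#'
#' @param motif_a,motif_b [motif()] objects.
#' @param background shared [background()].
#' @param sites_b optional character vector of known B-site sequences; their
#'   fitness values under the B-landscape are returned for context.
#' @return object of class `"correlation_record"`: list with `factor_a`,
#'   `factor_b`, `offset`, `aligned_length`, `C_ab` (nats), `C_ab_bits`,
#'   `C_aligned_Ia` (I_A over the aligned columns), `I_a`, `I_b`, `bg_b`
#'   (all full-length, nats) and `site_fitness_values`.
#' @examples
#' bg <- background(p0 = rep(0.25, 4))
#' m <- motif(matrix(c(8, 1, 1, 1), 3, 4, byrow = TRUE), "A")
#' r <- binding_correlation(m, m, bg)
#' all.equal(r$C_ab, r$I_a)
#' @export
binding_correlation <- function(motif_a, motif_b, background,
                                sites_b = NULL) {
  p0 <- background$p0
  La <- motif_a$length; Lb <- motif_b$length
  Lmin <- min(La, Lb)
  best <- NULL
  for (o in 0:abs(La - Lb)) {
    ia <- if (La >= Lb) o + seq_len(Lmin) else seq_len(Lmin)
    ib <- if (La >= Lb) seq_len(Lmin) else o + seq_len(Lmin)
    C <- 0
    for (k in seq_len(Lmin)) {
      qa <- motif_a$freq[ia[k], ]
      qb <- motif_b$freq[ib[k], ]
      C <- C + sum(qa * (log(qb) - log(p0)))
    }
    if (is.null(best) || C > best$C + 1e-12)
      best <- list(C = C, o = o, ia = ia, ib = ib)
  }
  # I_A restricted to the aligned columns (upper bound for C_ab)
  I_a_aligned <- sum(vapply(best$ia, function(i) {
    qa <- motif_a$freq[i, ]
    sum(qa * (log(qa) - log(p0)))
  }, numeric(1)))
  land_b <- build_fitness(motif_b, background)
  bg_b <- sum(p0 * t(land_b$f))
  fit_vals <- if (!is.null(sites_b))
    vapply(sites_b, function(s) site_fitness(land_b, s), numeric(1))
  else NULL
  structure(list(
    factor_a = motif_a$name, factor_b = motif_b$name,
    offset = best$o, aligned_length = Lmin,
    C_ab = best$C, C_ab_bits = best$C / log(2),
    C_aligned_Ia = I_a_aligned,
    I_a = unname(sequence_information(motif_a, background)["nats"]),
    I_b = unname(sequence_information(motif_b, background)["nats"]),
    bg_b = bg_b,
    site_fitness_values = fit_vals), class = "correlation_record")
}

#' @export
print.correlation_record <- function(x, ...) {
  cat(sprintf(
    "<correlation_record> C(%s -> %s) = %.3f nats (%.3f bits), offset %d\n",
    x$factor_a, x$factor_b, x$C_ab, x$C_ab_bits, x$offset))
  cat(sprintf("  I_a = %.3f, I_b = %.3f, background fitness = %.3f nats\n",
              x$I_a, x$I_b, x$bg_b))
  invisible(x)
}

#' Binding correlations for a list of factor pairs
#'
#' @param motifs named list of [motif()] objects.
#' @param pairs two-column data.frame (or matrix) of factor names (A, B).
#' @param background shared [background()].
#' @return data.frame with columns `factor_a`, `factor_b`, `offset`,
#'   `C_ab`, `C_ab_bits`, `I_a`, `I_b`, `bg_b`.
#' @export
binding_correlation_table <- function(motifs, pairs, background) {
  out <- NULL
  for (i in seq_len(nrow(pairs))) {
    a <- as.character(pairs[i, 1]); b <- as.character(pairs[i, 2])
    if (is.null(motifs[[a]]) || is.null(motifs[[b]]))
      stop("unknown factor in pair ", a, ", ", b)
    r <- binding_correlation(motifs[[a]], motifs[[b]], background)
    out <- rbind(out, data.frame(
      factor_a = a, factor_b = b, offset = r$offset, C_ab = r$C_ab,
      C_ab_bits = r$C_ab_bits, I_a = r$I_a, I_b = r$I_b, bg_b = r$bg_b,
      stringsAsFactors = FALSE))
  }
  out
}
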