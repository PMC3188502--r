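#' Position weight matrix (motif) constructor
#'
#' Builds a motif object from a count or frequency matrix. Rows are positions,
#' columns the four nucleotides A, C, G, T. A pseudocount (default 0.5 per
#' position, distributed proportionally to the background composition) is
#' added before row-normalisation so that every entry is strictly positive;
#' zero frequencies would otherwise break the information measures and the
#' substitution rates downstream.
#'
#' @param counts numeric L x 4 matrix of per-position nucleotide counts or
#'   frequencies; columns in order A, C, G, T (a matching `colnames`
#'   permutation is honoured).
#' @param name motif name (the transcription factor it describes).
#' @param background optional [background()] object; its composition weights
#'   the pseudocount. Uniform weights are used when absent.
#' @param pseudocount total pseudocount added to each position (default 0.5).
#' @return an object of class `"motif"`: list with elements `name`, `length`
#'   and `freq` (row-stochastic L x 4 matrix, all entries > 0).
#' @examples
#' m <- motif(matrix(c(10, 0, 0, 0), 1, 4), "toyA")
#' rowSums(m$freq) # 1
#' @export
motif <- function(counts, name = "motif", background = NULL,
                  pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L)
    stop("motif matrix must have 4 columns (A, C, G, T)")
  if (!is.null(colnames(counts))) {
    if (!setequal(colnames(counts), DNA_BASES))
      stop("motif matrix columns must be named A, C, G, T")
    counts <- counts[, DNA_BASES, drop = FALSE]
  }
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("motif matrix entries must be finite and non-negative")
  w <- if (is.null(background)) rep(0.25, 4) else background$p0
  freq <- counts + pseudocount * rep(w, each = nrow(counts))
  freq <- freq / rowSums(freq)
  dimnames(freq) <- list(NULL, DNA_BASES)
  structure(list(name = name, length = nrow(freq), freq = freq),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif> %s  (L = %d)\n", x$name, x$length))
  print(round(x$freq, 3))
  invisible(x)
}

#' Background nucleotide model
#'
#' Single-nucleotide frequencies `p0`, optional first-order (dinucleotide)
#' conditional frequencies, and the random match probability
#' q0 = sum(p0^2), the chance that two independent background letters agree.
#'
#' @param sequences character vector of DNA sequences to estimate from, or
#'   NULL when `p0` is given directly.
#' @param p0 optional 4-vector of frequencies (A, C, G, T order).
#' @param dinucleotide logical; also estimate the 4 x 4 conditional matrix
#'   p(beta | alpha) from adjacent pairs (needed by the Markov null).
#' @param pseudocount total pseudocount, distributed uniformly (default 0.5).
#' @return object of class `"background"`: list with `p0`, `q0` and
#'   (optionally) `dinucleotide`, each strictly positive.
#' @examples
#' bg <- background("ACGTACGTAAAA")
#' bg$q0
#' @export
background <- function(sequences = NULL, p0 = NULL, dinucleotide = TRUE,
                       pseudocount = 0.5) {
  if (is.null(p0)) {
    if (is.null(sequences)) stop("either sequences or p0 required")
    enc <- lapply(as.character(sequences), seq_to_int)
    cnt <- rep(0, 4)
    dint <- matrix(0, 4, 4)
    for (e in enc) {
      tab <- tabulate(e, 4L)
      cnt <- cnt + tab
      if (dinucleotide && length(e) >= 2L) {
        a <- e[-length(e)]; b <- e[-1L]
        keep <- !is.na(a) & !is.na(b)
        if (any(keep))
          dint <- dint + table(factor(a[keep], 1:4), factor(b[keep], 1:4))
      }
    }
    p0 <- (cnt + pseudocount / 4) / sum(cnt + pseudocount / 4)
    dmat <- NULL
    if (dinucleotide) {
      dmat <- (dint + pseudocount / 4) / rowSums(dint + pseudocount / 4)
      dimnames(dmat) <- list(DNA_BASES, DNA_BASES)
    }
  } else {
    if (length(p0) != 4L || any(p0 <= 0))
      stop("p0 must be 4 strictly positive frequencies")
    p0 <- p0 / sum(p0)
    dmat <- if (dinucleotide) matrix(rep(p0, each = 4), 4, 4,
                                     dimnames = list(DNA_BASES, DNA_BASES))
            else NULL
  }
  names(p0) <- DNA_BASES
  structure(list(p0 = p0, dinucleotide = dmat, q0 = sum(p0^2)),
            class = "background")
}

#' @export
print.background <- function(x, ...) {
  cat("<background> p0 =", paste(sprintf("%s:%.3f", DNA_BASES, x$p0),
                                 collapse = " "),
      sprintf(" q0 = %.4f\n", x$q0))
  invisible(x)
}

#' Sequence information of a motif
#'
#' Relative entropy (Kullback-Leibler divergence) between the motif's
#' position-specific nucleotide distribution and the background:
#' \deqn{I = \sum_i \sum_\alpha q_i(\alpha) \ln\frac{q_i(\alpha)}{p_0(\alpha)}.}
#' Under the information-based fitness landscape this also equals the mean
#' scaled fitness of sites drawn from the motif.
#'
#' @param motif a [motif()] object.
#' @param background a [background()] object.
#' @return named numeric vector with elements `nats` and `bits` (I >= 0).
#' @examples
#' bg <- background(p0 = rep(0.25, 4))
#' m <- motif(matrix(1, 3, 4), "flat") # equals background
#' sequence_information(m, bg) # ~ 0
#' @export
sequence_information <- function(motif, background) {
  q <- motif$freq
  p0 <- background$p0
  I <- sum(q * (log(q) - rep(log(p0), each = nrow(q))))
  c(nats = I, bits = I / log(2))
}

#' Similarity information of a pair of matched sites
#'
#' Binary relative entropy between the per-position match probability `q` of
#' two aligned sites and the background match probability `q0`, summed over
#' the `l` aligned positions:
#' \deqn{H = l\,[\, q \ln(q/q_0) + (1-q)\ln((1-q)/(1-q_0)) \,].}
#' `H` is the information (in nats) carried by the observed excess similarity
#' of a site pair over random sequence; it is zero iff `q == q0`.
#'
#' @param q match probability of the pair, in (0, 1); the boundary values 0
#'   and 1 are handled with the 0*log(0) = 0 convention.
#' @param q0 background match probability (see [background()]).
#' @param l number of aligned positions.
#' @return similarity information in nats (vectorised over `q`).
#' @export
similarity_information <- function(q, q0, l) {
  xlx <- function(p, p0) ifelse(p == 0, 0, p * log(p / p0))
  l * (xlx(q, q0) + xlx(1 - q, 1 - q0))
}
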