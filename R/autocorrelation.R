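#' Distance-dependent sequence autocorrelation of regulatory modules
#'
#' For each lag `r` the autocorrelation is the excess probability that two
#' nucleotides `r` bp apart are identical, over the match probability of two
#' random letters of the local composition:
#' \deqn{\Pi(r) = P(r) - \bar p^2,}
#' where `P(r)` is the fraction of identical nucleotide pairs at lag `r`
#' pooled over modules and `pbar^2 = sum_alpha p_alpha^2` is evaluated in a
#' local window (default 500 bp) centred on the midpoint of each pair and
#' truncated at module edges. Changing the window length shifts the baseline
#' of the profile but not its short-distance structure. Pairs touching an
#' ambiguous symbol (N) are dropped from numerator and denominator.
#'
#' @param modules character vector of module sequences (or a `DNAStringSet`).
#' @param r_max maximum lag in bp.
#' @param window local-window length in bp for the composition term
#'   (default 500).
#' @param min_bin_pairs when `bin = TRUE`, the minimum number of nucleotide
#'   pairs per variable-width reporting bin (default 1e4).
#' @param bin also return a variable-width binned summary for display.
#' @return object of class `"autocorrelation_profile"`: list with `profile`
#'   (data.frame: `r`, `pi`, `n_pairs`), `window`, and optionally `bins`
#'   (data.frame: `r_lo`, `r_hi`, `r_mid`, `pi`, `n_pairs`).
#' @examples
#' p <- autocorrelation_profile(strrep("ACGT", 50), r_max = 8, window = 100)
#' subset(p$profile, r %in% c(1, 4)) # pi = -0.25 and 0.75
#' @export
autocorrelation_profile <- function(modules, r_max, window = 500,
                                    min_bin_pairs = 1e4, bin = FALSE) {
  stopifnot(r_max >= 1, window >= 2)
  modules <- as.character(modules)
  match_sum <- numeric(r_max)   # sum over pairs of identity indicator
  p2_sum <- numeric(r_max)      # sum over pairs of local pbar^2
  n_pairs <- numeric(r_max)
  for (sq in modules) {
    s <- seq_to_int(sq)
    n <- length(s)
    if (n < 2L) next
    # prefix counts per nucleotide for O(1) window composition
    pre <- matrix(0L, 4, n + 1L)
    for (a in 1:4) pre[a, -1L] <- cumsum(!is.na(s) & s == a)
    for (r in seq_len(min(r_max, n - 1L))) {
      x <- seq_len(n - r)
      a <- s[x]; b <- s[x + r]
      keep <- !is.na(a) & !is.na(b)
      if (!any(keep)) next
      x <- x[keep]
      mid <- x + r / 2
      lo <- pmax(1, ceiling(mid - window / 2))
      hi <- pmin(n, floor(mid + window / 2))
      cnt <- pre[, hi + 1L, drop = FALSE] - pre[, lo, drop = FALSE]
      width <- colSums(cnt)
      ok <- width > 0
      p2 <- colSums((cnt / rep(pmax(width, 1L), each = 4))^2)
      x <- x[ok]; p2 <- p2[ok]
      match_sum[r] <- match_sum[r] + sum(s[x] == s[x + r])
      p2_sum[r] <- p2_sum[r] + sum(p2)
      n_pairs[r] <- n_pairs[r] + length(x)
    }
  }
  has <- n_pairs > 0
  if (!any(has)) warning("all modules too short: empty profile")
  profile <- data.frame(
    r = seq_len(r_max)[has],
    pi = (match_sum[has] - p2_sum[has]) / n_pairs[has],
    n_pairs = n_pairs[has])
  out <- list(profile = profile, window = window)
  if (bin && nrow(profile) > 0) {
    bins <- NULL
    i <- 1L
    while (i <= nrow(profile)) {
      j <- i
      while (j < nrow(profile) && sum(profile$n_pairs[i:j]) < min_bin_pairs)
        j <- j + 1L
      w <- profile$n_pairs[i:j]
      bins <- rbind(bins, data.frame(
        r_lo = profile$r[i], r_hi = profile$r[j],
        r_mid = sum(profile$r[i:j] * w) / sum(w),
        pi = sum(profile$pi[i:j] * w) / sum(w),
        n_pairs = sum(w)))
      i <- j + 1L
    }
    out$bins <- bins
  }
  structure(out, class = "autocorrelation_profile")
}

#' @export
print.autocorrelation_profile <- function(x, ...) {
  cat(sprintf("<autocorrelation_profile> %d lags, window = %d bp\n",
              nrow(x$profile), x$window))
  print(head(x$profile, 10))
  if (nrow(x$profile) > 10) cat("...\n")
  invisible(x)
}
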