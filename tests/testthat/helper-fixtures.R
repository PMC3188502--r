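# Shared fixtures and independent oracles used across the suite.

uniform_bg <- function() background(p0 = rep(0.25, 4))

skewed_bg <- function() background(p0 = c(0.3, 0.2, 0.2, 0.3))

# strings -> integer codes without touching package internals
seq_to_int_test <- function(x)
  match(strsplit(x, "")[[1]], c("A", "C", "G", "T"))

# all integer-coded sequences of length L (4^L rows)
all_seqs <- function(L) {
  as.matrix(rev(expand.grid(rev(replicate(L, 1:4, simplify = FALSE)))))
}

int2str <- function(v) paste(c("A", "C", "G", "T")[v], collapse = "")

# motif probability of an integer-coded sequence
motif_prob <- function(m, a) prod(m$freq[cbind(seq_along(a), a)])

# Exhaustive oracle for the maximum-similarity pair-set problem: explores
# every admissible set of non-overlapping left-site positions by plain
# recursion (no memoisation, independent of the DP under test) and returns
# the maximal total similarity. `s` is integer-coded.
brute_force_pairs <- function(s, r, l, qc) {
  n <- length(s)
  nx <- n - r - l + 1
  if (nx < 1) return(0)
  k <- vapply(seq_len(nx), function(x) {
    a <- s[x:(x + l - 1)]
    b <- s[(x + r):(x + r + l - 1)]
    if (anyNA(a) || anyNA(b)) return(-1)
    sum(a == b) / l
  }, numeric(1))
  cand <- which(k >= qc - 1e-9 & k >= 0)
  if (!length(cand)) return(0)
  recurse <- function(i) {
    if (i > length(cand)) return(0)
    # skip candidate i
    best <- recurse(i + 1)
    # take candidate i, jump past overlapping candidates
    x <- cand[i]
    j <- i + 1
    while (j <= length(cand) && cand[j] < x + l) j <- j + 1
    best <- max(best, k[x] + recurse(j))
    best
  }
  recurse(1)
}

# A deliberately correlated pair of motifs: B is A with one column shuffled
# towards background. Used for binding-correlation ordering checks.
correlated_motifs <- function(L = 6, seed = 99) {
  set.seed(seed)
  A <- random_motif(L, "corrA", concentration = 0.2)
  fb <- A$freq
  fb[2, ] <- (fb[2, ] + rep(0.25, 4)) / 2
  B <- motif(fb, "corrB")
  list(A = A, B = B)
}

# small standard motif set for simulation-based tests
sim_motifs <- function(L = 8, n = 4, concentration = 0.25, seed = 77) {
  set.seed(seed)
  mots <- lapply(seq_len(n), function(i)
    random_motif(L, LETTERS[i], concentration = concentration))
  names(mots) <- LETTERS[seq_len(n)]
  mots
}

# duplication scores of a pairs data.frame at one fixed evolutionary
# distance (single-point grid; the boundary warning is expected there)
dupscan_score_at <- function(pairs, motifs, bg, t) {
  suppressWarnings(infer_tstar(pairs, motifs, bg, t_grid = t))$scores$S
}

# write a small module/site/motif trio to tempfiles; returns the paths
write_toy_dataset <- function(dir = tempfile("toy")) {
  dir.create(dir)
  set.seed(123)
  bg <- uniform_bg()
  seqs <- sample_markov(bg, 120, 2)
  modules <- data.frame(id = c("mod1", "mod2"),
                        chrom = c("chr2L", "chr2R"),
                        start = c(1000L, 5000L),
                        end = c(1120L, 5120L),
                        sequence = seqs, stringsAsFactors = FALSE)
  fa <- file.path(dir, "modules.fa")
  write_modules(modules, fa)
  ann <- data.frame(
    module_id = c("mod1", "mod1", "mod2"),
    chrom = c("chr2L", "chr2L", "chr2R"),
    start = c(1010L, 1050L, 5020L),
    end = c(1017L, 1057L, 5027L),
    strand = c("+", "-", "+"),
    factor = c("tfA", "tfB", "tfA"), stringsAsFactors = FALSE)
  bed <- file.path(dir, "sites.bed")
  write_sites(ann, bed)
  mots <- list(tfA = random_motif(7, "tfA", seed = 5),
               tfB = random_motif(7, "tfB", seed = 6))
  mot <- file.path(dir, "motifs.txt")
  write_motifs(mots, mot)
  list(dir = dir, fasta = fa, bed = bed, motifs = mot,
       modules = modules, annotations = ann, motif_list = mots)
}
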