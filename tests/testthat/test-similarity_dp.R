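test_that("sequence information matches closed forms and the exhaustive sum", {
  bg <- uniform_bg()
  # motif equal to background carries no information
  flat <- motif(matrix(1, 5, 4), "flat")
  expect_equal(unname(sequence_information(flat, bg)["nats"]), 0,
               tolerance = 1e-12)
  # deterministic 7-mer at uniform background: I = 7 ln 4 nats = 14 bits
  det <- motif(matrix(rep(c(1, 0, 0, 0), 7), 7, 4, byrow = TRUE), "det",
               pseudocount = 0)
  det$freq[det$freq == 0] <- 1e-300  # point mass without pseudocount
  I <- sequence_information(det, bg)
  expect_equal(unname(I["nats"]), 7 * log(4), tolerance = 1e-10)
  expect_equal(unname(I["bits"]), 14, tolerance = 1e-10)
  # random 3-position motif: per-position sum equals the exhaustive sum
  # over all 64 sequences of Q(a) log(Q(a)/P0(a))
  m <- random_motif(3, seed = 51)
  bg2 <- skewed_bg()
  S <- all_seqs(3)
  Q <- apply(S, 1, motif_prob, m = m)
  P0 <- apply(S, 1, function(a) prod(bg2$p0[a]))
  expect_equal(unname(sequence_information(m, bg2)["nats"]),
               sum(Q * log(Q / P0)), tolerance = 1e-12)
})

test_that("similarity information is a proper binary relative entropy", {
  q0 <- 0.25
  expect_equal(similarity_information(q0, q0, 7), 0)
  expect_equal(similarity_information(1, 0.25, 7), 7 * log(4),
               tolerance = 1e-12)
  # H >= 0 with equality only at q = q0
  qs <- seq(0.01, 0.99, by = 0.01)
  H <- similarity_information(qs, q0, 5)
  expect_true(all(H >= 0))
  expect_true(all(H[abs(qs - q0) > 1e-9] > 0))
  # simulation: sites from a peaked motif vs the analytic match probability
  m <- random_motif(6, seed = 52, concentration = 0.15)
  q_analytic <- mean(rowSums(m$freq^2))
  set.seed(53)
  a <- replicate(4000, NULL)
  A <- sapply(1:6, function(i) sample.int(4, 4000, TRUE, prob = m$freq[i, ]))
  B <- sapply(1:6, function(i) sample.int(4, 4000, TRUE, prob = m$freq[i, ]))
  q_emp <- mean(A == B)
  se <- sqrt(q_analytic * (1 - q_analytic) / (4000 * 6))
  expect_lt(abs(q_emp - q_analytic), 4 * se)
  expect_equal(similarity_information(q_emp, 0.25, 6),
               similarity_information(q_analytic, 0.25, 6),
               tolerance = 0.05)
})

test_that("DP recovers a planted pair and respects boundary cases", {
  set.seed(54)
  bgseq <- sample_markov(uniform_bg(), 80, 1)
  word <- "ACGCGTA"
  s <- paste0(substr(bgseq, 1, 20), word, substr(bgseq, 21, 40), word,
              substr(bgseq, 41, 60))
  r <- 7 + 20  # start-to-start lag of the two planted copies
  ps <- max_similarity_pairs(s, r = r, l = 7, q_c = 6 / 7)
  # oracle: DP total equals exhaustive enumeration; planted position found
  expect_equal(ps$total_similarity,
               brute_force_pairs(seq_to_int_test(s), r, 7, 6 / 7),
               tolerance = 1e-9)
  # the planted copy is detected; chance extension of the exact repeat into
  # the background can shift the reported start by a base or two
  expect_true(any(abs(ps$positions - 21) <= 3))
  # sequence of length r + l - 1: no admissible position
  short <- max_similarity_pairs(substr(s, 1, r + 6), r = r, l = 7,
                                q_c = 0.5)
  expect_equal(short$n, 0)
  expect_length(short$positions, 0)
})

test_that("DP optimum equals the exhaustive oracle on random sequences", {
  set.seed(55)
  for (i in 1:60) {
    n <- sample(15:40, 1)
    s <- sample.int(4, n, replace = TRUE)
    r <- sample(1:8, 1)
    l <- sample(3:5, 1)
    qc <- sample(c(1 / 2, 2 / 3, 3 / 4, 1), 1)
    ps <- max_similarity_pairs(s, r, l, qc)
    expect_equal(ps$total_similarity, brute_force_pairs(s, r, l, qc),
                 tolerance = 1e-9,
                 label = sprintf("n=%d r=%d l=%d qc=%.2f", n, r, l, qc))
    # constraints hold (also asserted internally)
    if (ps$n > 1) expect_true(all(diff(ps$positions) >= l))
  }
})

test_that("DP total similarity dominates greedy left-to-right selection", {
  set.seed(56)
  for (i in 1:25) {
    s <- sample.int(4, 60, replace = TRUE)
    r <- 10; l <- 4; qc <- 1 / 2
    k <- vapply(seq_len(60 - r - l + 1), function(x)
      sum(s[x:(x + l - 1)] == s[(x + r):(x + r + l - 1)]) / l, numeric(1))
    greedy <- 0; x <- 1
    while (x <= length(k)) {
      if (k[x] >= qc) { greedy <- greedy + k[x]; x <- x + l } else x <- x + 1
    }
    expect_gte(max_similarity_pairs(s, r, l, qc)$total_similarity + 1e-9,
               greedy)
  }
})

test_that("null-calibrated information is consistent with zero on pure
           background and recovers planted signal", {
  bg <- uniform_bg()
  set.seed(57)
  mods <- sample_markov(bg, 600, 8)
  nul <- markov_null_ensemble(mods, n_null = 150, seed = 58)
  ti <- total_similarity_information(mods, r = 20, l = 7, nul)
  expect_lt(abs(ti$z), 3.5)

  pm <- plant_correlated_modules(8, 600, 7, 30, 3, bg, seed = 59)
  nulp <- markov_null_ensemble(pm$modules, n_null = 150, seed = 60)
  tip <- total_similarity_information(pm$modules, r = 30, l = 7, nulp)
  # 24 planted pairs: excess within sampling noise of the truth, strongly
  # significant, and I~ close to delta_n * H / N
  expect_gt(tip$z, 3)
  expect_gt(tip$delta_n, 24 - 3 * max(tip$n0_sd, sqrt(24)))
  expect_equal(tip$total_information,
               tip$delta_n * tip$pair_information / tip$segment_length)
  # degenerate grid: a single achievable q_c is returned as given
  one <- total_similarity_information(mods, r = 20, l = 7, nul, q_c = 1)
  expect_equal(one$threshold, 1)
})

test_that("length scan peaks at the planted motif length", {
  bg <- uniform_bg()
  pm <- plant_correlated_modules(10, 500, 7, c(20, 35), 4, bg, seed = 61)
  nul <- markov_null_ensemble(pm$modules, n_null = 120, seed = 62)
  sc <- scan_length(pm$modules, r_range = c(20, 35), l_range = 5:9, nul)
  expect_true(sc$l_star %in% 6:8)
  # single length in range is returned trivially
  sc1 <- scan_length(pm$modules, r_range = 20, l_range = 7, nul)
  expect_equal(sc1$l_star, 7)
  expect_equal(nrow(sc1$by_length), 1)
})

test_that("per-pair similarity information stays within the motif
           information rule-of-thumb bound", {
  bg <- uniform_bg()
  m <- random_motif(7, seed = 63, concentration = 0.2)
  I <- unname(sequence_information(m, bg)["nats"])
  q_analytic <- mean(rowSums(m$freq^2))
  H <- similarity_information(q_analytic, bg$q0, 7)
  expect_gt(H, 0)
  expect_lt(H, 2 * I)
})
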