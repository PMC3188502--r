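test_that("the duplication score is a proper log-likelihood ratio", {
  bg <- skewed_bg()
  mA <- random_motif(2, "A", seed = 81, concentration = 0.3)
  mB <- random_motif(2, "B", seed = 82, concentration = 0.3)
  S <- all_seqs(2)
  for (t in c(0.2, 1)) {
    emom <- 0; es_ind <- 0; es_dup <- 0
    for (i in seq_len(nrow(S))) for (j in seq_len(nrow(S))) {
      pr <- site_pair(S[i, ], S[j, ], mA, mB, bg)
      pind <- p_independent(pr)
      s <- as.numeric(duplication_score(pr, t))
      pdup <- pind * exp(s)
      emom <- emom + pind * exp(s)
      es_ind <- es_ind + pind * s
      es_dup <- es_dup + pdup * s
    }
    # exponential-moment identity and the two Gibbs inequalities
    expect_equal(emom, 1, tolerance = 1e-10)
    expect_lte(es_ind, 1e-12)
    expect_gte(es_dup, -1e-12)
  }
  # S -> 0 for any pair as t -> infinity
  pr <- site_pair(c(1, 2), c(1, 2), mA, mB, bg)
  expect_lt(abs(as.numeric(duplication_score(pr, 1e3))), 1e-5)
  # shared consensus of two similar motifs scores positively at finite t
  mots <- correlated_motifs()
  cons <- apply(mots$A$freq, 1, which.max)
  prc <- site_pair(cons, cons, mots$A, mots$B, uniform_bg())
  expect_gt(as.numeric(duplication_score(prc, 0.5)), 0)
})

test_that("t* recovery: interior maximum near the mean divergence time for
           common descent, boundary drift without a signal", {
  bg <- uniform_bg()
  mots <- sim_motifs(L = 8, n = 2, seed = 83)
  tau_bar <- 0.4
  cfg <- simulation_config(list(c("A", "B")), mots, bg, tau_bar = tau_bar,
                           n_events = 60, pairs_per_event = 10,
                           n_independent = 600, seed = 84)
  ens <- simulate_pair_ensemble(cfg)
  common <- ens$pairs[ens$pairs$label == "common", ]
  st <- infer_tstar(common, mots, bg)
  expect_false(st$boundary)
  expect_gte(st$t_star, tau_bar / 2)
  expect_lte(st$t_star, 2 * tau_bar)
  # the curve has an interior maximum
  k <- which.max(st$curve$total_S)
  expect_true(k > 1 && k < nrow(st$curve))

  # independent pairs: expected score <= 0 at every t, -> 0 at large t,
  # so no interior signal comparable to the common-descent one
  indep <- ens$pairs[ens$pairs$label == "independent", ]
  sti <- suppressWarnings(infer_tstar(indep, mots, bg))
  expect_lt(max(sti$curve$total_S) / nrow(indep), 0.05)
  expect_true(sti$boundary || sti$t_star > 2 * tau_bar)

  # single pair: warned, still the argmax of that pair's curve
  expect_warning(st1 <- infer_tstar(common[1, ], mots, bg), "single pair")
  expect_true(st1$t_star %in% st1$t_grid)
  expect_error(infer_tstar(common[0, ], mots, bg), "no pairs")
})

test_that("mixture fitting recovers the planted duplicated fraction", {
  set.seed(85)
  far <- rnorm(600, 0, 1)
  # null: near and far from the same distribution
  near0 <- rnorm(120, 0, 1)
  fit0 <- fit_mixture(near0, far, n_boot = 40, seed = 86)
  expect_lt(fit0$rho, 0.15)
  expect_lt(fit0$Lambda, 0.15 * fit0$n)  # small evidence per pair
  expect_gte(fit0$D, 0)
  expect_equal(fit0$Lambda, fit0$n * fit0$D)

  # planted mixture: rho = 0.5 with a shifted, widened component; the
  # estimator is checked on its mean over replicates (single fits carry
  # sampling noise of ~0.06)
  near5 <- c(rnorm(150, 0, 1), rnorm(150, 3, 1.6))
  fit5 <- fit_mixture(near5, far, n_boot = 40, seed = 87)
  expect_lt(abs(fit5$rho - 0.5), 0.2)
  expect_gt(fit5$mu_dup, mean(far))
  expect_true(fit5$rho_ci[1] <= fit5$rho & fit5$rho <= fit5$rho_ci[2])
  rhos <- replicate(8, {
    nr <- c(rnorm(150, 0, 1), rnorm(150, 3, 1.6))
    fit_mixture(nr, far, n_boot = 0)$rho
  })
  expect_lt(abs(mean(rhos) - 0.5), 0.1)

  # every near score far above the background: rho at its upper bound
  fit1 <- fit_mixture(rnorm(60, 8, 0.5), far, n_boot = 0)
  expect_gt(fit1$rho, 0.95)

  # guard rails
  expect_error(fit_mixture(near0, rep(1, 50)), "degenerate")
  expect_error(fit_mixture(near0[1:5], far), ">= 10")
  expect_error(fit_mixture(near0, far[1:10]), ">= 30")
})

test_that("distance-resolved relative entropy tracks a planted decay", {
  set.seed(88)
  # duplicated fraction decreasing with distance: D(r) should decay
  mk <- function(n, rho) c(rnorm(round(n * (1 - rho))),
                           rnorm(n - round(n * (1 - rho)), 3, 1.5))
  tab <- rbind(
    data.frame(distance = runif(300, 0, 25), S = mk(300, 0.6)),
    data.frame(distance = runif(300, 25, 50), S = mk(300, 0.3)),
    data.frame(distance = runif(300, 50, 75), S = mk(300, 0.1)),
    data.frame(distance = runif(600, 100, 200), S = rnorm(600)))
  prof <- distance_entropy_profile(tab, distance_bins = c(0, 25, 50, 75),
                                   far_threshold = 100)
  expect_equal(nrow(prof), 3)
  expect_true(all(diff(prof$D) < 0))
  expect_true(all(prof$D >= 0))

  # self-comparison: all bins drawn from the background stay near zero
  null_tab <- data.frame(distance = runif(2000, 0, 200), S = rnorm(2000))
  prof0 <- distance_entropy_profile(null_tab,
                                    distance_bins = c(0, 50, 100),
                                    far_threshold = 100)
  expect_true(all(prof0$D < 0.1))
  # single bin gives a one-row table
  prof1 <- distance_entropy_profile(tab, distance_bins = c(0, 50),
                                    far_threshold = 100)
  expect_equal(nrow(prof1), 1)
  # underpopulated bins are skipped with a warning
  expect_warning(
    distance_entropy_profile(tab, distance_bins = c(0, 0.001, 50),
                             far_threshold = 100),
    "skipped")
})

test_that("factor-pair scramble control calibrates and detects", {
  set.seed(89)
  grp <- rep(sprintf("f%d:g%d", 1:6, 1:6), each = 30)
  tab <- data.frame(factor_a = sub(":.*", "", grp),
                    factor_b = sub(".*:", "", grp),
                    S = rnorm(180))
  # exchangeable scores: large p-values dominate
  ps <- replicate(20, {
    tab$S <- rnorm(180)
    factor_pair_scramble_test(tab, n_scrambles = 200)$p_value
  })
  expect_gt(median(ps), 0.1)
  # planted heterogeneity: one factor pair shifted by +3
  tab$S <- rnorm(180) + ifelse(grp == "f1:g1", 3, 0)
  res <- factor_pair_scramble_test(tab, n_scrambles = 500, seed = 90)
  expect_lt(res$p_value, 0.01)
  # fewer than two factor pairs is an error
  expect_error(factor_pair_scramble_test(tab[grp == "f1:g1", ]),
               ">= 2 distinct")
})
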