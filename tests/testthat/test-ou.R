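test_that("OU covariance has the closed form and its BM and independence limits", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  Cbm <- bm_covariance(tr)

  # alpha ~ 0: BM limit within 1e-6 relative
  V0 <- ou_covariance(tr, alpha = 1e-12, sigma2 = 2.5)
  expect_equal(V0, 2.5 * Cbm, tolerance = 1e-6)

  # closed-form entries at alpha = 0.7
  a <- 0.7; s2 <- 1.3
  V <- ou_covariance(tr, a, s2)
  expect_equal(V["A", "A"], s2 / (2 * a) * (1 - exp(-2 * a * 2)))
  expect_equal(V["A", "B"], s2 / (2 * a) * (1 - exp(-2 * a * 1)) *
                 exp(-a * 2)) # shared time 1, distance 2
  expect_equal(V["A", "C"], s2 / (2 * a) * (1 - exp(-2 * a * 0)) *
                 exp(-a * 4)) # no shared history -> 0

  # large alpha: stationary variance on the diagonal, vanishing off-diagonal
  Vbig <- ou_covariance(tr, alpha = 50, sigma2 = 2)
  expect_equal(unname(diag(Vbig)), rep(2 / 100, 3), tolerance = 1e-6)
  expect_lt(max(abs(Vbig[upper.tri(Vbig)])), 1e-12)

  expect_error(ou_covariance(read_newick("(A:1,B:3);"), 1), "ultrametric")
})

test_that("OU log-likelihood matches a dense Gaussian oracle on a 3-tip tree", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  y <- c(0.3, -0.2, 0.9)
  a <- 0.8; s2 <- 0.6; th <- 0.25

  # single regime: mean is theta weighted by (1 - e^{-aT}) plus root e^{-aT}
  # at the same optimum, i.e. exactly theta at every tip
  mu <- rep(th, 3)
  V <- ou_covariance(tr, a, s2)
  expect_equal(ou_loglik(y, tr, a, s2, theta = th),
               dense_mvn_loglik(y, mu, V), tolerance = 1e-10)

  # with a shift on the A-B stem: the shifted regime covers the stem and
  # both tip edges, so its weight at tips A, B is 1 - e^{-2a} (the root
  # state at the base optimum keeps weight e^{-2a}); C stays at the base
  e_ab <- find_clade_edge(tr, c("A", "B"))
  th2 <- c(0.25, 1.4)
  w_shift <- 1 - exp(-a * 2)
  mu2 <- rep(th2[1], 3)
  mu2[1:2] <- th2[1] * (1 - w_shift) + th2[2] * w_shift
  expect_equal(ou_loglik(y, tr, a, s2, theta = th2, shift_edges = e_ab),
               dense_mvn_loglik(y, mu2, V), tolerance = 1e-10)

  # alpha -> 0, no shifts: equals the BM likelihood
  expect_equal(ou_loglik(y, tr, alpha = 0, s2, theta = 0.1),
               dense_mvn_loglik(y, rep(0.1, 3), s2 * bm_covariance(tr)),
               tolerance = 1e-10)

  # adding a shift whose optimum equals the base changes nothing
  expect_equal(ou_loglik(y, tr, a, s2, theta = c(th, th),
                         shift_edges = e_ab),
               ou_loglik(y, tr, a, s2, theta = th), tolerance = 1e-12)
})

test_that("shift search returns no shifts for constant data and never scores worse than zero shifts", {
  tr <- rn_chronogram()
  fit <- detect_shifts(rep(1.5, 20), tr)
  expect_equal(nrow(tidy(fit)), 0)

  for (s in 1:3) {
    y <- simulate_bm(tr, 0.001, seed = 100 + s)
    fit <- detect_shifts(y, tr, max_shifts = 2)
    base <- detect_shifts(y, tr, max_shifts = 0)
    expect_lte(fit$score, base$score + 1e-8)
  }
  expect_error(detect_shifts(1:20, tr, max_shifts = 20), "smaller")
  expect_error(detect_shifts(1:4, read_newick("((A:1,B:1):1,(C:1,D:1):1);")),
               class = "rubrovol_insufficient_data")
})

test_that("shift search is invariant to tip-order permutation of named input", {
  tr <- rn_chronogram()
  hom_edge <- find_clade_edge(tr, hominoid_species())
  y <- simulate_ou(tr, alpha = 0.2, sigma2 = 0.05, theta = c(0, -2),
                   shift_edges = hom_edge, seed = 9)
  f1 <- detect_shifts(y, tr)
  f2 <- detect_shifts(y[sample(names(y))], tr)
  expect_equal(sort(f1$shift_edges), sort(f2$shift_edges))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-9)
})

test_that("bootstrap support is deterministic given the seed and high for a strong shift", {
  tr <- rn_chronogram()
  hom_edge <- find_clade_edge(tr, hominoid_species())
  a <- 1; s2 <- 0.1 # stationary SD ~0.22
  y <- simulate_ou(tr, a, s2, theta = c(0, -10 * sqrt(s2 / (2 * a))),
                   shift_edges = hom_edge, seed = 3)
  fit <- detect_shifts(y, tr, max_shifts = 1)
  expect_equal(fit$shift_edges, hom_edge)

  b1 <- bootstrap_support(fit, n_boot = 20, seed = 7, max_shifts = 1)
  b2 <- bootstrap_support(fit, n_boot = 20, seed = 7, max_shifts = 1)
  expect_equal(b1, b2)
  expect_gt(b1$support[b1$edge == hom_edge], 65)
  expect_error(bootstrap_support(fit, n_boot = 0), ">= 1")
})

test_that("pure Brownian data yield only weakly supported shifts", {
  tr <- rn_chronogram()
  y <- simulate_bm(tr, 0.01, seed = 17)
  fit0 <- detect_shifts(y, tr, max_shifts = 1)
  # force a bootstrap around the best single-shift model on null data
  counts <- bootstrap_support(fit0, n_boot = 30, seed = 5, max_shifts = 1)
  expect_lt(max(counts$support[!counts$in_fit], 0), 30)
})

test_that("signal-to-noise effect size is zero-anchored, linear, and large for strong shifts", {
  tr <- rn_chronogram()
  hom_edge <- find_clade_edge(tr, hominoid_species())
  a <- 1; s2 <- 0.1
  y <- simulate_ou(tr, a, s2, theta = c(0, -10 * sqrt(s2 / (2 * a))),
                   shift_edges = hom_edge, seed = 3)
  fit <- detect_shifts(y, tr, max_shifts = 1)
  es <- snr_effect_size(fit)
  expect_gt(attr(es, "overall"), 1) # strong shift: high effect size

  # linearity in |delta theta| at fixed alpha, sigma^2, tree
  fit2 <- fit
  fit2$shifts$delta_theta <- 2 * fit$shifts$delta_theta
  expect_equal(snr_effect_size(fit2)$snr, 2 * es$snr)
  fit3 <- fit
  fit3$shifts$delta_theta <- 0
  expect_equal(snr_effect_size(fit3)$snr, 0)

  nofit <- detect_shifts(rep(0, 20), tr)
  expect_error(snr_effect_size(nofit), class = "rubrovol_undefined_effect")
})
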