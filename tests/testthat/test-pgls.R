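test_that("pGLS reduces to OLS under identity covariance", {
  x <- c(1, 2, 3, 4, 5)
  fit <- pgls_fit(x, 2 * x + 1, C = diag(5))
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(unname(fit$residuals), rep(0, 5), tolerance = 1e-10)

  # star-tree covariance proportional to identity = OLS with noise
  set.seed(2)
  y <- 0.5 * x + rnorm(5)
  ols <- lm(y ~ x)
  fit2 <- pgls_fit(x, y, C = 7 * diag(5))
  expect_equal(unname(coef(ols)), unname(coef(fit2)), tolerance = 1e-10)
})

test_that("pGLS matches brute-force GLS arithmetic on a 4-taxon tree", {
  tr <- read_newick("((A:1,B:1):2,(C:2,D:2):1);")
  C <- bm_covariance(tr)
  x <- c(A = 1.1, B = 2.3, C = 0.4, D = 3.0)
  y <- c(A = 2.0, B = 3.9, C = 1.1, D = 5.2)
  fit <- pgls_fit(x, y, C)
  oracle <- brute_gls(x, y, C)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
  expect_equal(fit$sigma2, oracle$rss / 2, tolerance = 1e-10)
})

test_that("pGLS agrees with an independent GLS implementation", {
  skip_if_not_installed("nlme")
  tr <- rn_chronogram()
  tab <- load_rn_fixture("table3")
  td <- tab[match(tr$tip.label, tab$species), ]
  x <- log10(td$bv_cm3 * 1000)
  y <- log10(td$rnp_l)
  fit <- pgls_fit(x, y, bm_covariance(tr))
  d <- data.frame(x = x, y = y, sp = tr$tip.label)
  ref <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corBrownian(1, tr, form = ~sp))
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
})

test_that("pGLS estimates are invariant to global tree rescaling", {
  tr <- rn_chronogram()
  tab <- load_rn_fixture("table3")
  td <- tab[match(tr$tip.label, tab$species), ]
  x <- log10(td$bv_cm3 * 1000)
  y <- log10(td$rnm_l)
  f1 <- pgls_fit(x, y, bm_covariance(tr))
  f2 <- pgls_fit(x, y, 1000 * bm_covariance(tr))
  expect_equal(f1$slope, f2$slope, tolerance = 1e-10)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-10)
  # GLS-weighted residual mean is zero
  C <- bm_covariance(tr)
  expect_lt(abs(sum(solve(C, residuals(f1)))), 1e-8)
})

test_that("pGLS recovers a known slope from BM-noise simulations", {
  tr <- simulate_yule_tree(100, seed = 5)
  C <- bm_covariance(tr)
  x <- simulate_bm(tr, sigma2 = 1, seed = 6)
  slopes <- sapply(1:50, function(b) {
    y <- 0.8 * x + simulate_bm(tr, sigma2 = 0.1, seed = 1000 + b)
    pgls_fit(x, y, C)$slope
  })
  expect_lt(abs(mean(slopes) - 0.8), 3 * sd(slopes) / sqrt(50))
})

test_that("prediction intervals collapse, widen monotonically, and flag outliers", {
  x <- c(1, 2, 3, 4, 5)
  fit0 <- pgls_fit(x, 2 * x + 1, C = diag(5))
  pi0 <- prediction_intervals(fit0)
  expect_equal(pi0$lwr, pi0$fitted, tolerance = 1e-8)
  expect_false(any(pi0$outside))
  expect_error(prediction_intervals(fit0, level = 1.2), "probability")

  set.seed(9)
  tr <- simulate_yule_tree(20, seed = 31)
  C <- bm_covariance(tr)
  xx <- simulate_bm(tr, 1, seed = 32)
  yy <- xx + simulate_bm(tr, 0.2, seed = 33)
  fit <- pgls_fit(xx, yy, C)
  flags50 <- sum(prediction_intervals(fit, 0.5)$outside)
  flags95 <- sum(prediction_intervals(fit, 0.95)$outside)
  expect_lte(flags95, flags50)

  # a tip displaced by 5 residual SDs is flagged nearly always
  hit <- 0
  reps <- 200
  for (b in seq_len(reps)) {
    y <- xx + simulate_bm(tr, 0.2, seed = 5000 + b)
    f0 <- pgls_fit(xx, y, C)
    shift_tip <- 1 + (b %% 20)
    y[shift_tip] <- y[shift_tip] + 5 * sqrt(f0$sigma2)
    f1 <- pgls_fit(xx, y, C)
    hit <- hit + prediction_intervals(f1, 0.95)$outside[shift_tip]
  }
  expect_gte(hit / reps, 0.95)
})

test_that("tidy/glance/augment expose the fit as tibbles", {
  x <- 1:6
  set.seed(4)
  fit <- pgls_fit(x, x + rnorm(6), C = diag(6))
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "slope"))
  expect_true(all(c("std.error", "p.value") %in% names(td)))
  expect_equal(glance(fit)$nobs, 6)
  expect_equal(nrow(augment(fit)), 6)
  expect_s3_class(autoplot(fit), "ggplot")
})
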