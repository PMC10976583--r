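test_that("BM simulation is seed-reproducible with the right degenerate limit", {
  tr <- rn_chronogram()
  expect_equal(simulate_bm(tr, sigma2 = 0, root_state = 3, seed = 1),
               setNames(rep(3, 20), tr$tip.label))
  y1 <- simulate_bm(tr, 0.01, seed = 42)
  y2 <- simulate_bm(tr, 0.01, seed = 42)
  y3 <- simulate_bm(tr, 0.01, seed = 43)
  expect_identical(y1, y2)
  expect_false(identical(y1, y3))
})

test_that("BM simulation reproduces sigma2 * C empirically", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  s2 <- 0.7
  draws <- t(sapply(1:10000, function(b) simulate_bm(tr, s2, seed = b)))
  emp <- cov(draws)
  expect_equal(emp, s2 * bm_covariance(tr), tolerance = 0.05)
})

test_that("OU simulation matches its closed-form moments and its BM limit", {
  tr <- rn_chronogram(depth = 1)
  a <- 8; s2 <- 0.5; th <- 2
  draws <- sapply(1:2000, function(b) simulate_ou(tr, a, s2, theta = th,
                                                  seed = 30000 + b)[1])
  # marginal at one tip: mean -> theta, variance -> stationary value
  v_exact <- s2 / (2 * a) * (1 - exp(-2 * a))
  expect_equal(mean(draws), th, tolerance = 0.05)
  expect_equal(var(draws), v_exact, tolerance = 0.1)

  # alpha ~ 0: distribution indistinguishable from BM (KS on one tip)
  bm <- sapply(1:2000, function(b) simulate_bm(tr, s2, seed = 50000 + b)[1])
  ou <- sapply(1:2000, function(b) simulate_ou(tr, 1e-9, s2, theta = 0,
                                               seed = 70000 + b)[1])
  ks <- suppressWarnings(stats::ks.test(bm, ou))
  expect_gt(ks$p.value, 0.01)
})

test_that("OU simulation separates clade means by the optimum shift", {
  tr <- rn_chronogram(depth = 1)
  hom_edge <- find_clade_edge(tr, hominoid_species())
  y <- simulate_ou(tr, alpha = 20, sigma2 = 0.1, theta = c(0, 3),
                   shift_edges = hom_edge, seed = 77)
  inside <- names(y) %in% hominoid_species()
  expect_equal(mean(y[inside]) - mean(y[!inside]), 3, tolerance = 0.3)
})

test_that("synthetic allometric tables are valid, reproducible, and exactly recoverable without noise", {
  tab <- make_allometric_table(seed = 5)
  expect_silent(rn_species_summary(tab))
  expect_identical(tab, make_allometric_table(seed = 5))
  expect_false(identical(tab, make_allometric_table(seed = 6)))

  # zero noise, one grade: pGLS recovers slope and intercept exactly
  tr <- rn_chronogram()
  clean <- make_allometric_table(tr, slope = 0.8, intercept_rnp = -2,
                                 sigma2_resid = 0, asymmetry_sd = 0,
                                 seed = 2)
  td <- clean[match(tr$tip.label, clean$species), ]
  fit <- pgls_fit(log10(td$bv_cm3 * 1000), log10(td$rnp_r + td$rnp_l),
                  bm_covariance(tr))
  expect_equal(fit$slope, 0.8, tolerance = 1e-8)
  expect_equal(fit$intercept, -2, tolerance = 1e-7)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-8)
})

test_that("a simulated hominoid grade shift flows through to detection and testing", {
  tr <- rn_chronogram()
  hom_edge <- find_clade_edge(tr, hominoid_species())
  C <- bm_covariance(tr)
  recovered <- 0
  rejected <- 0
  reps <- 20
  for (b in seq_len(reps)) {
    tab <- make_allometric_table(tr, shift_edges = hom_edge,
                                 shift_delta = -1.5, seed = 300 + b)
    td <- tab[match(tr$tip.label, tab$species), ]
    x <- log10(td$bv_cm3 * 1000)
    y <- setNames(log10(td$rnm_r + td$rnm_l) - x, tr$tip.label)
    fit <- detect_shifts(y, tr, max_shifts = 1)
    hits <- c(hom_edge, adjacent_edges(tr, hom_edge))
    recovered <- recovered + (length(fit$shift_edges) &&
                                fit$shift_edges %in% hits)
    g <- ifelse(td$group %in% c("humans", "non-human apes"), "hom", "rest")
    rejected <- rejected +
      (grade_test(x, log10(td$rnm_r + td$rnm_l), C, g)$p_value < 0.05)
  }
  expect_gte(recovered / reps, 0.8)
  expect_gte(rejected / reps, 0.8)
})

test_that("packaged fixtures are locked against silent edits", {
  tab <- load_rn_fixture("table3")
  expect_equal(nrow(tab), 20)
  expect_equal(as.integer(table(tab$group)[c("prosimians",
                                             "new world monkeys",
                                             "old world monkeys",
                                             "non-human apes", "humans")]),
               c(7L, 3L, 4L, 5L, 1L))
  expect_equal(tab$bv_cm3[tab$species == "Homo_sapiens"], 1235.7)
  expect_equal(tab$n[tab$species == "Homo_sapiens"], 10L)
  expect_equal(sum(tab$bv_cm3), 3284.9) # column checksums
  expect_equal(sum(as.matrix(tab[, c("rnp_r", "rnp_l", "rnm_r", "rnm_l")])),
               2006.6)

  t1 <- load_rn_fixture("table1")
  expect_equal(nrow(t1), 11)
  expect_equal(sum(t1$mapped), 10)
  expect_equal(sum(t1$fresh_weight_g), 14144)

  expect_error(load_rn_fixture("table9"), class = "rubrovol_lookup_error")
})
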