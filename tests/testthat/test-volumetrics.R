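test_that("Cavalieri estimator handles base cases and converges on an ellipsoid", {
  expect_equal(cavalieri_volume(c(0, 0, 0), spacing = 0.3), 0)
  expect_equal(cavalieri_volume(2, spacing = 0.3), 0.6)
  expect_error(cavalieri_volume(2, spacing = 0), "> 0")
  expect_error(cavalieri_volume(numeric(0), spacing = 1), "non-empty")
  expect_error(cavalieri_volume(c(1, -1), spacing = 1), ">= 0")

  truth <- 4 / 3 * pi * 2 * 1 * 1 # ellipsoid semi-axes 2, 1, 1
  secs <- ellipsoid_sections(c(2, 1, 1), spacing = 0.1)
  est <- cavalieri_volume(secs$area, spacing = 0.1)
  expect_lt(abs(est - truth) / truth, 0.02)

  # error decreases monotonically as the sections get denser
  errs <- sapply(c(0.8, 0.4, 0.1), function(sp) {
    s <- ellipsoid_sections(c(2, 1, 1), spacing = sp)
    abs(cavalieri_volume(s$area, spacing = sp) - truth)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("fresh volume and shrinkage conversions are exact ratios", {
  expect_equal(fresh_brain_volume(1032), 1000)
  expect_equal(fresh_brain_volume(100, density = 1), 100)
  expect_error(fresh_brain_volume(-1), "> 0")

  expect_equal(shrinkage_factor(1200, 600), 2)
  expect_equal(shrinkage_factor(1000, 1000), 1)
  expect_error(shrinkage_factor(1, 0), "> 0")

  # shrinkage scales the Cavalieri estimate linearly (algebraic identity)
  areas <- c(1.2, 3.4, 2.2)
  f <- 1350; p <- 820
  expect_equal(
    cavalieri_volume(areas, 0.3, shrinkage_factor(f, p)),
    cavalieri_volume(areas, 0.3) * f / p
  )
})

test_that("species summary reproduces bilateral sums exactly and is row-order invariant", {
  tab <- load_rn_fixture("table3")
  ss <- rn_species_summary(tab)
  expect_equal(ss$rn_total, ss$rnp + ss$rnm) # exact by construction
  homo <- ss[ss$species == "Homo_sapiens", ]
  expect_equal(homo$rn_total, 589.1)
  expect_equal(homo$rnp, 583.0)
  expect_equal(homo$rnm, 6.1)

  shuffled <- tab[rev(seq_len(nrow(tab))), ]
  ss2 <- rn_species_summary(shuffled)
  expect_equal(dplyr::arrange(ss2, species), dplyr::arrange(ss, species))

  bad <- tab
  bad$rnp_r[3] <- NA
  expect_error(rn_species_summary(bad), tab$species[3])
})

test_that("symmetric subdivisions give unit ratio and zero difference", {
  tab <- load_rn_fixture("table3")
  tab$rnm_r <- tab$rnp_r
  tab$rnm_l <- tab$rnp_l
  ss <- rn_species_summary(tab)
  expect_equal(ss$ratio_rnm_rnp, rep(1, nrow(ss)))
  expect_equal(ss$log10_ratio, rep(0, nrow(ss)))
  expect_equal(ss$rel_diff, rep(0, nrow(ss)))
  gs <- rn_group_summary(ss)
  expect_equal(gs$fold_difference, rep(1, nrow(gs)))
})

test_that("group ratio conventions differ as documented", {
  tab <- load_rn_fixture("table3")
  gm <- rn_group_summary(tab, ratio_method = "group_mean")
  sm <- rn_group_summary(tab, ratio_method = "species_mean")
  nwm <- function(d) d$ratio_rnm_rnp[d$group == "new world monkeys"]
  # group-mean convention: ratio of mean bilateral volumes
  ss <- rn_species_summary(tab)
  nw <- ss[ss$group == "new world monkeys", ]
  expect_equal(nwm(gm), mean(nw$rnm) / mean(nw$rnp))
  expect_equal(nwm(sm), mean(nw$rnm / nw$rnp))
})

test_that("asymmetry test gates on normality and handles degenerate ties", {
  expect_warning(res <- asymmetry_test(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_equal(res$p_value, 1)
  expect_equal(res$test, "none")
  expect_error(asymmetry_test(1:4, 1:5), "equal length")
  expect_error(asymmetry_test(1:2, 2:3), "at least 3")

  # normal paired data with n >= 8 goes through Anderson-Darling + t
  set.seed(11)
  l <- rnorm(12); r <- l + rnorm(12, sd = 0.5)
  res <- asymmetry_test(l, r)
  expect_equal(res$test, "paired t")

  # heavily tied/skewed differences push the gate to the signed-rank test
  l2 <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, 10)
  r2 <- l2 + c(rep(0.01, 9), 15)
  res2 <- asymmetry_test(l2, r2)
  expect_equal(res2$test, "wilcoxon signed rank")

  # power: a 2-sigma paired shift at n = 10 is detected nearly always
  hits <- 0
  set.seed(21)
  for (b in 1:300) {
    base <- rnorm(10)
    noise <- rnorm(10)
    p <- asymmetry_test(base + noise + 2, base)$p_value
    hits <- hits + (p < 0.05)
  }
  expect_gt(hits / 300, 0.9)
})
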