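test_that("REML solution matches a direct restricted-likelihood oracle", {
  d <- make_st_data(m = 6, r = 2, s2g = 1, s2e = 0.5, seed = 7)
  f <- fit_st_blup(d, "y")
  oracle <- st_reml_oracle(d, "y")
  expect_lt(abs(f$sigma2_g - oracle["s2g"]), 1e-7)
  expect_lt(abs(f$sigma2_e - oracle["s2e"]), 1e-7)
  # and the likelihood value agrees with the explicit-V formula
  expect_equal(-2 * f$loglik, st_direct_m2ll(d, "y", f$sigma2_g,
                                             f$sigma2_e),
               tolerance = 1e-8)
})

test_that("REML agrees with lme4 on the same model", {
  skip_if_not_installed("lme4")
  d <- make_st_data(m = 12, r = 4, s2g = 0.8, s2e = 0.4, seed = 8)
  f <- fit_st_blup(d, "y")
  lm4 <- lme4::lmer(y ~ 0 + replicate + (1 | genotype), d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lm4))
  expect_equal(f$sigma2_g, vc$vcov[1], tolerance = 1e-5)
  expect_equal(f$sigma2_e, vc$vcov[2], tolerance = 1e-5)
  expect_equal(f$loglik, as.numeric(stats::logLik(lm4)), tolerance = 1e-6)
})

test_that("balanced-design REML equals the ANOVA expected-mean-square solution", {
  d <- make_st_data(m = 10, r = 4, s2g = 1, s2e = 0.5, seed = 9)
  f <- fit_st_blup(d, "y")
  a <- stats::anova(stats::lm(y ~ replicate + genotype, d))
  msg <- a["genotype", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  expect_gt((msg - mse) / 4, 0)  # interior solution for this seed
  expect_equal(f$sigma2_g, (msg - mse) / 4, tolerance = 1e-6)
  expect_equal(f$sigma2_e, mse, tolerance = 1e-6)
})

test_that("EM iterations never decrease the restricted log-likelihood", {
  for (s in 1:5) {
    d <- make_st_data(m = 8, r = 3, s2g = 0.5 * s, s2e = 1, seed = 30 + s)
    f <- fit_st_blup(d, "y", refine = FALSE)
    expect_false(is.unsorted(f$loglik_trace))
  }
})

test_that("BLUPs shrink toward zero or the genotype means with the ratio", {
  d <- make_st_data(m = 8, r = 4, s2g = 1, s2e = 1, seed = 10)
  f <- fit_st_blup(d, "y")
  # balanced design: BLUPs sum to zero
  expect_equal(sum(f$blups), 0, tolerance = 1e-8)
  # shrinkage factor at the estimates: r*lam/(r*lam + 1)
  gmeans <- as.numeric(tapply(d$y, d$genotype, mean)) - mean(d$y)
  lam <- f$sigma2_g / f$sigma2_e
  shrink <- 4 * lam / (4 * lam + 1)
  expect_equal(unname(f$blups), shrink * gmeans, tolerance = 1e-6)
})

test_that("degenerate inputs hit the documented boundaries without crashing", {
  d <- make_st_data(m = 5, r = 3, seed = 11)
  d$y <- 1.25
  f <- fit_st_blup(d, "y")
  expect_equal(f$sigma2_g, 0)
  expect_equal(f$sigma2_e, 0)
  expect_true(f$boundary)
  # pure-noise response keeps sigma2_g near the zero boundary
  d2 <- make_st_data(m = 40, r = 2, s2g = 0, s2e = 1, seed = 101)
  f2 <- fit_st_blup(d2, "y")
  expect_lt(f2$sigma2_g, 0.15)
  # data with the genotype signal stripped lands exactly on the boundary
  d3 <- make_st_data(m = 20, r = 3, s2g = 1, s2e = 1, seed = 102)
  d3$y <- stats::residuals(stats::lm(y ~ genotype, d3))
  f3 <- fit_st_blup(d3, "y")
  expect_lt(f3$sigma2_g, 1e-6)
})

test_that("heritability is the genetic fraction of plot variance", {
  expect_equal(heritability(1, 1), 0.5)
  expect_equal(heritability(0, 2), 0)
  expect_warning(h <- heritability(0, 0), "undefined")
  expect_true(is.na(h))
  d <- make_st_data(m = 10, r = 4, seed = 12)
  f <- fit_st_blup(d, "y")
  expect_equal(heritability(f),
               f$sigma2_g / (f$sigma2_g + f$sigma2_e))
})

test_that("phenotypic correlation uses the flight closest to harvest", {
  des <- trial_design(10, 3, 2, seq(100, 500, length.out = 4), seed = 13)
  tr <- simulate_trial(des, K_g = diag(c(1, 0.5, 0.2, 0.1)),
                       sigma2_e = 0.05)
  tr <- simulate_yield_from_curve(tr, 520)
  # y = 2x: replace each harvest's yield by an affine image of that
  # harvest's last flight
  rec <- tr$records
  for (h in unique(rec$harvest)) {
    last <- rec[!rec$is_yield & rec$harvest == h & rec$gdd == 500, ]
    sel <- rec$is_yield & rec$harvest == h
    rec$vi[sel] <- 2 * last$vi[match(rec$plot[sel], last$plot)]
  }
  pc <- phenotypic_correlation(rec, "vi")
  expect_equal(pc$r, c(1, 1), tolerance = 1e-12)
  rec$vi[rec$is_yield] <- -rec$vi[rec$is_yield] / 2
  expect_equal(phenotypic_correlation(rec, "vi")$r, c(-1, -1),
               tolerance = 1e-12)
})

test_that("permuted pairing destroys the phenotypic correlation", {
  des <- trial_design(200, 2, 1, seq(100, 500, length.out = 3), seed = 14)
  tr <- simulate_trial(des, K_g = diag(c(1, 0.5, 0.2)), sigma2_e = 0.1)
  tr <- simulate_yield_from_curve(tr, 520)
  rec <- tr$records
  set.seed(1)
  yl <- which(rec$is_yield)
  rec$vi[yl] <- rec$vi[sample(yl)]
  r <- phenotypic_correlation(rec, "vi")$r
  expect_lt(abs(r), 3 / sqrt(400))
})
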