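test_that("identical seeds reproduce the trial byte for byte", {
  des <- trial_design(6, 3, 2, seq(100, 500, length.out = 5), seed = 11)
  a <- simulate_trial(des, K_g = diag(c(1, 0.5)), K_p = 0.1 * diag(2),
                      sigma2_e = 0.2)
  b <- simulate_trial(des, K_g = diag(c(1, 0.5)), K_p = 0.1 * diag(2),
                      sigma2_e = 0.2)
  expect_identical(a$records, b$records)
  des2 <- trial_design(6, 3, 2, seq(100, 500, length.out = 5), seed = 12)
  c <- simulate_trial(des2, K_g = diag(c(1, 0.5)), K_p = 0.1 * diag(2),
                      sigma2_e = 0.2)
  expect_false(identical(a$records$vi, c$records$vi))
})

test_that("noise-free trials give identical de-trended replicate trajectories", {
  des <- trial_design(5, 4, 1, seq(100, 500, length.out = 5), seed = 2)
  tr <- simulate_trial(des, K_g = diag(c(1, 0.4, 0.2)), K_p = NULL,
                       sigma2_e = 0)
  rec <- tr$records
  # remove the replicate-within-time fixed effect recorded in truth
  ri <- as.integer(factor(rec$replicate))
  fi <- as.integer(factor(rec$flight))
  rec$detrended <- rec$vi - tr$truth$beta[cbind(ri, fi, 1)]
  spread <- tapply(rec$detrended,
                   list(rec$genotype, rec$flight),
                   function(x) diff(range(x)))
  expect_lt(max(spread), 1e-12)
})

test_that("with no genetic or plot signal the record variance is sigma2_e", {
  des <- trial_design(500, 4, 1, c(100, 300, 500), seed = 3)
  tr <- simulate_trial(des, K_g = matrix(0, 4, 4), K_p = matrix(0, 4, 4),
                       sigma2_e = 0.37)
  one_t <- tr$records[tr$records$gdd == 300, ]
  expect_equal(var(one_t$vi), 0.37, tolerance = 0.1)
})

test_that("genotype coefficients are drawn with covariance K_g", {
  K_g <- matrix(c(1, 0.3, 0.3, 0.5), 2)
  des <- trial_design(5000, 2, 1, c(100, 300, 500), seed = 4)
  tr <- simulate_trial(des, K_g = K_g, sigma2_e = 0.1)
  S <- cov(tr$truth$u_bar)
  expect_lt(max(abs(diag(S) - diag(K_g)) / diag(K_g)), 0.05)
  expect_equal(S[1, 2], K_g[1, 2], tolerance = 0.05)
})

test_that("record variance decomposes as phi'K_g phi + phi'K_p phi + sigma2_e", {
  K_g <- diag(c(0.8, 0.3))
  K_p <- diag(c(0.2, 0.1))
  des <- trial_design(1500, 2, 1, c(100, 300, 500), seed = 5)
  tr <- simulate_trial(des, K_g = K_g, K_p = K_p, sigma2_e = 0.25)
  cf_g <- forageRR:::cov_function(K_g, tr$truth$basis[[1]])
  cf_p <- forageRR:::cov_function(K_p, tr$truth$basis[[1]])
  for (t0 in c(100, 300)) {
    expected <- cf_g$var(t0) + cf_p$var(t0) + 0.25
    observed <- var(tr$records$vi[tr$records$gdd == t0])
    expect_equal(observed, expected, tolerance = 0.08 * expected)
  }
})

test_that("non-PSD covariance specifications are rejected with a diagnostic", {
  des <- trial_design(4, 2, 1, c(100, 300, 500), seed = 1)
  bad <- matrix(c(1, 2, 2, 1), 2)        # eigenvalues 3, -1
  expect_error(simulate_trial(des, K_g = bad), "positive semidefinite")
  expect_error(simulate_trial(des, K_g = matrix(c(1, 0.5, 0, 1), 2)),
               "symmetric")
  expect_error(simulate_trial(des, K_g = diag(2), sigma2_e = -1),
               "non-negative")
})

test_that("trial design invariants are enforced", {
  expect_error(trial_design(1, 4), "n_genotypes >= 2")
  expect_error(trial_design(4, 1), "n_replicates >= 2")
  expect_error(trial_design(4, 2, 1, c(300, 200, 100)), "increasing")
  des <- trial_design(4, 3, 1, c(100, 300), seed = 1)
  tr <- simulate_trial(des, K_g = diag(2), sigma2_e = 0.1)
  # RCBD: every genotype exactly once per replicate per flight
  tab <- table(tr$records$genotype, tr$records$replicate)
  expect_true(all(tab == 2))
})

test_that("terminal yield rows follow the genotype curve at harvest GDD", {
  des <- trial_design(8, 3, 1, seq(100, 500, length.out = 5), seed = 6)
  tr <- simulate_trial(des, K_g = diag(c(1, 0.4, 0.2, 0.1)),
                       sigma2_e = 0.1)
  expect_error(simulate_yield_from_curve(tr, 400), "earlier than")
  # noise-free yield at the last flight time equals the curve there
  tr0 <- simulate_yield_from_curve(tr, 500, mu_yield = 0,
                                   sigma2_yield = 0)
  yl <- tr0$records[tr0$records$is_yield, ]
  Phi <- tr0$truth$basis[[1]]$evaluate(500)
  gval <- drop(tr0$truth$u[[1]] %*% t(Phi))
  expect_equal(yl$vi,
               unname(gval[match(yl$genotype,
                                 rownames(tr0$truth$u[[1]]))]),
               tolerance = 1e-12)
  # determinism
  tr1 <- simulate_yield_from_curve(tr, 560)
  tr2 <- simulate_yield_from_curve(tr, 560)
  expect_identical(tr1$records, tr2$records)
})

test_that("true index-yield genetic correlation is a closed basis form", {
  # with K_g = I the correlation between t* = 0 and t* = 1 is
  # phi(0)'phi(1) / (|phi(0)||phi(1)|) = -0.75 / 3 = -0.25
  b <- legendre_basis(c(0, 100), order = 3)
  cf <- forageRR:::cov_function(diag(4), b)
  expect_equal(drop(cf$cor(50, 100)),
               sum(b$evaluate(50) * b$evaluate(100)) /
                 sqrt(sum(b$evaluate(50)^2) * sum(b$evaluate(100)^2)))
})

test_that("GE yield simulation honors its contracts", {
  expect_error(simulate_ge_yield(5, 3, stability_profile = -1),
               "non-negative")
  a <- simulate_ge_yield(3, 2, seed = 9)
  b <- simulate_ge_yield(3, 2, seed = 9)
  expect_identical(a$ge, b$ge)
  # additive table: environment-centered matrix has rank <= 1
  sim <- simulate_ge_yield(8, 5, stability_profile = 0, seed = 2)
  Yc <- sweep(unclass(sim$ge), 2, colMeans(sim$ge))
  expect_lt(svd(Yc)$d[2], 1e-10)
})

test_that("component streams are independent under one master seed", {
  des <- trial_design(6, 3, 1, c(100, 300, 500), seed = 21)
  with_noise <- simulate_trial(des, K_g = diag(2), sigma2_e = 0.3)
  no_noise <- simulate_trial(des, K_g = diag(2), sigma2_e = 0)
  # toggling the residual leaves the genetic draws untouched
  expect_identical(with_noise$truth$u_bar, no_noise$truth$u_bar)
  expect_identical(with_noise$truth$beta, no_noise$truth$beta)
})

test_that("write_trial emits CSV plus YAML sidecars", {
  dir <- withr::local_tempdir()
  des <- trial_design(4, 2, 1, c(100, 300, 500), seed = 1)
  tr <- simulate_trial(des, K_g = diag(2), sigma2_e = 0.1)
  write_trial(tr, dir)
  expect_true(file.exists(file.path(dir, "records.csv")))
  meta <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(meta$seed, 1)
  back <- utils::read.csv(file.path(dir, "records.csv"))
  expect_equal(nrow(back), nrow(tr$records))
})
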