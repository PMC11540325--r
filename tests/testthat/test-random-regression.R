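test_that("terminal yield scaling matches variances and preserves ranking", {
  y <- c(2, 6, 4, 8)
  vi <- c(0.2, 0.5, 0.3, 0.6)
  sc <- scale_terminal_yield(y, vi)
  expect_equal(var(as.numeric(sc)), var(vi), tolerance = 1e-10)
  expect_equal(order(sc), order(y))
  expect_equal(cor(as.numeric(sc), vi), cor(y, vi))
  # var 4 vs var 1 gives factor 0.5
  expect_equal(attr(scale_terminal_yield(c(0, 4), c(0, 2)),
                    "scale_factor"), 0.5)
  # identity when yield already equals the index
  expect_equal(attr(scale_terminal_yield(vi, vi), "scale_factor"), 1)
  expect_error(scale_terminal_yield(rep(1, 4), vi), "zero variance")
})

test_that("identifiability preconditions are enforced before fitting", {
  des <- trial_design(6, 2, 1, seq(100, 500, length.out = 4), seed = 16)
  tr <- simulate_trial(des, K_g = diag(c(1, 0.5, 0.2, 0.1)),
                       sigma2_e = 0.2)
  expect_error(fit_rr(tr$records, "vi", order = 3), "rank deficient")
  rec <- tr$records
  rec2 <- rec[!(rec$plot == rec$plot[1] & rec$gdd > 100), ]
  expect_error(fit_rr(rec2, "vi", order = 1), ">= 2 time points")
  expect_error(fit_rr(rbind(rec, rec[1, ]), "vi", order = 1),
               "duplicated")
  expect_error(fit_rr(rec, "vi", order = 1, include_yield = TRUE),
               "no yield rows")
})

test_that("REML solution matches direct likelihood maximization on a tiny instance", {
  des <- trial_design(4, 2, 1, seq(100, 500, length.out = 5), seed = 3)
  tr <- simulate_trial(des, K_g = matrix(c(1, 0.3, 0.3, 0.5), 2),
                       K_p = 0.2 * diag(2), sigma2_e = 0.3)
  f <- fit_rr(tr$records, "vi", order = 1, refine = TRUE, tol = 1e-12,
              max_iter = 500)
  oracle <- rr_reml_oracle(tr$records, "vi")
  expect_equal(-2 * f$loglik, oracle$m2ll, tolerance = 1e-6)
  expect_equal(f$K_g, oracle$K_g, tolerance = 1e-5)
  expect_equal(f$K_p, oracle$K_p, tolerance = 1e-5)
  expect_equal(f$sigma2_e, oracle$s2, tolerance = 1e-5)
  # and the reported likelihood agrees with the explicit-V formula
  expect_equal(-2 * f$loglik,
               rr_direct_m2ll(tr$records, "vi", f$K_g, f$K_p,
                              f$sigma2_e),
               tolerance = 1e-7)
})

test_that("EM steps never decrease the restricted log-likelihood", {
  des <- trial_design(10, 3, 1, seq(100, 500, length.out = 6), seed = 17)
  tr <- simulate_trial(des, K_g = diag(c(1, 0.5, 0.2, 0.1)),
                       K_p = 0.1 * diag(4), sigma2_e = 0.3)
  f <- fit_rr(tr$records, "vi", accelerate = FALSE, max_iter = 60)
  expect_false(is.unsorted(f$loglik_trace))
  # the guarded accelerator keeps the recorded trace monotone too
  fa <- fit_rr(tr$records, "vi", accelerate = TRUE, max_iter = 60)
  expect_false(is.unsorted(fa$loglik_trace))
})

test_that("noise-free data is interpolated: BLUPs equal centered truth", {
  des <- trial_design(8, 3, 1, seq(100, 500, length.out = 8), seed = 15)
  tr <- simulate_trial(des, K_g = diag(c(1, 0.5, 0.2, 0.1)), K_p = NULL,
                       sigma2_e = 1e-6)
  f <- fit_rr(tr$records, "vi", max_iter = 300, tol = 1e-11,
              refine = TRUE)
  u_centered <- sweep(tr$truth$u[[1]], 2, colMeans(tr$truth$u[[1]]))
  expect_lt(max(abs(f$u_hat - u_centered)), 1e-3)
  expect_lt(max(diag(f$K_p)), 1e-6)
})

test_that("an intercept-only fit reduces to the repeatability model", {
  des <- trial_design(12, 4, 1, seq(150, 600, length.out = 6), seed = 11)
  tr <- simulate_trial(des, K_g = matrix(0.8), K_p = matrix(0.3),
                       sigma2_e = 0.4)
  f0 <- fit_rr(tr$records, "vi", order = 0, refine = TRUE, tol = 1e-12)
  # plot means follow a one-way genotype model whose components are the
  # basis-weighted coefficients: phi_0^2 = 1/2, residual var / n_flights
  pm <- stats::aggregate(vi ~ plot + genotype + replicate, tr$records,
                         mean)
  fst <- fit_st_blup(pm, "vi")
  expect_equal(f0$K_g[1, 1] / 2, fst$sigma2_g, tolerance = 1e-5)
  expect_equal(f0$K_p[1, 1] / 2 + f0$sigma2_e / 6, fst$sigma2_e,
               tolerance = 1e-5)
})

test_that("per-time-point residual variances are recovered in order", {
  des <- trial_design(30, 4, 1, seq(100, 500, length.out = 6), seed = 18)
  s2_true <- c(0.6, 0.4, 0.3, 0.2, 0.15, 0.1)
  tr <- simulate_trial(des, K_g = diag(c(1, 0.5, 0.2, 0.1)),
                       K_p = 0.1 * diag(4), sigma2_e = s2_true)
  f <- fit_rr(tr$records, "vi", residual = "per_time_point",
              accelerate = FALSE, max_iter = 80)
  expect_false(is.unsorted(f$loglik_trace))
  expect_length(f$sigma2_e, 6)
  # declining trend recovered (rank correlation with the truth)
  expect_gt(cor(f$sigma2_e, s2_true, method = "spearman"), 0.7)
})

test_that("appending scaled yield extends the basis domain to harvest", {
  des <- trial_design(12, 3, 1, seq(100, 500, length.out = 6), seed = 19)
  tr <- simulate_trial(des, K_g = diag(c(1, 0.5, 0.2, 0.1)),
                       K_p = 0.05 * diag(4), sigma2_e = 0.1)
  tr <- simulate_yield_from_curve(tr, 540)
  f <- fit_rr(tr$records, "vi", include_yield = TRUE, max_iter = 120)
  expect_equal(f$basis$domain, c(100, 540))
  expect_true(540 %in% f$times)
  expect_true(is.finite(f$yield_scale) && f$yield_scale > 0)
})

test_that("covariance surfaces are symmetric and Cauchy-Schwarz bounded", {
  des <- trial_design(15, 3, 1, seq(100, 500, length.out = 6), seed = 20)
  tr <- simulate_trial(des, K_g = diag(c(1, 0.5, 0.2, 0.1)),
                       K_p = 0.1 * diag(4), sigma2_e = 0.2)
  f <- fit_rr(tr$records, "vi", max_iter = 400)
  for (src in c("genetic", "permanent")) {
    surf <- covariance_surface(f, src)
    tg <- seq(100, 500, length.out = 25)
    Cv <- surf$cov(tg, tg)
    expect_equal(Cv, t(Cv), tolerance = 1e-12)
    v <- surf$var(tg)
    expect_true(all(v >= 0))
    expect_true(all(abs(Cv) <= sqrt(outer(v, v)) + 1e-10))
  }
})

test_that("correlation curve is one at the reference and NA at zero variance", {
  des <- trial_design(15, 3, 1, seq(100, 500, length.out = 6), seed = 21)
  tr <- simulate_trial(des, K_g = diag(c(1, 0.5, 0.2, 0.1)),
                       sigma2_e = 0.2)
  f <- fit_rr(tr$records, "vi", max_iter = 400)
  gc <- genetic_correlation_curve(f, t_grid = c(200, 350, 500))
  expect_equal(gc$r[3], 1, tolerance = 1e-10)
  expect_true(all(abs(gc$r) <= 1))
  # rank-1 genetic covariance: correlation is +/-1 everywhere
  u <- matrix(rnorm(12), 6, 2,
              dimnames = list(sprintf("g%02d", 1:6), NULL))
  k1 <- tcrossprod(c(1, 0.5))
  fk <- fake_rr_fit(k1, u, domain = c(100, 500))
  gk <- genetic_correlation_curve(fk, t_grid = seq(120, 480, by = 60),
                                  reference = 500)
  expect_true(all(abs(abs(gk$r) - 1) < 1e-10))
})

test_that("growth curves are centered BLUP trajectories with decile flags", {
  u0 <- matrix(0, 5, 4, dimnames = list(sprintf("g%02d", 1:5), NULL))
  f0 <- fake_rr_fit(diag(4), u0)
  gc0 <- growth_curves(f0, t_grid = c(150, 300, 450))
  expect_true(all(gc0$bv == 0))

  des <- trial_design(36, 5, 1, seq(150, 600, length.out = 8), seed = 42)
  tr <- simulate_trial(des, K_g = diag(c(1, 0.5, 0.2, 0.1)),
                       K_p = 0.2 * diag(4), sigma2_e = 0.5)
  f <- fit_rr(tr$records, "vi", max_iter = 400)
  gc <- growth_curves(f)
  bv_by_t <- tapply(gc$bv, gc$gdd, mean)
  expect_lt(max(abs(bv_by_t)), 1e-6)     # balanced BLUPs center at zero
  expect_setequal(unique(gc$decile), c("high", "low", "mid"))
  expect_equal(sum(gc$decile == "high") / length(unique(gc$gdd)), 4)
  # estimated terminal ranking tracks the generating genetic values
  term <- gc[gc$gdd == max(gc$gdd), ]
  Phi_T <- tr$truth$basis[[1]]$evaluate(600)
  truth_T <- drop(tr$truth$u[[1]] %*% t(Phi_T))
  expect_gt(cor(term$bv[match(rownames(tr$truth$u[[1]]), term$genotype)],
                truth_T, method = "spearman"), 0.8)
})

test_that("heritability trajectory stays within [0, 1] on the domain", {
  des <- trial_design(15, 3, 1, seq(100, 500, length.out = 6), seed = 23)
  tr <- simulate_trial(des, K_g = diag(c(1, 0.5, 0.2, 0.1)),
                       K_p = 0.1 * diag(4), sigma2_e = 0.3)
  f <- fit_rr(tr$records, "vi", max_iter = 400)
  hc <- heritability_curve(f)
  expect_true(all(hc$H2 >= 0 & hc$H2 <= 1))
  expect_true(all(hc$var_g >= 0 & hc$var_p >= 0))
})
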