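# small data builders shared across test files

# balanced RCBD single-time-point data with known components
make_st_data <- function(m = 10, r = 4, s2g = 1, s2e = 0.5, seed = 1,
                         rep_effect = 0.3) {
  set.seed(seed)
  d <- expand.grid(genotype = sprintf("g%02d", seq_len(m)),
                   replicate = sprintf("r%d", seq_len(r)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- stats::rnorm(m, 0, sqrt(s2g))
  d$y <- rep_effect * as.integer(factor(d$replicate)) +
    g[as.integer(factor(d$genotype))] +
    stats::rnorm(nrow(d), 0, sqrt(s2e))
  attr(d, "g") <- g
  d
}

# paired two-trait data with known G and R
make_biv_data <- function(m = 36, r = 5, Gm, Rm, seed = 1) {
  set.seed(seed)
  d <- expand.grid(genotype = sprintf("g%02d", seq_len(m)),
                   replicate = sprintf("r%d", seq_len(r)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- matrix(stats::rnorm(m * 2), m) %*% chol(Gm)
  E <- matrix(stats::rnorm(nrow(d) * 2), nrow(d)) %*% chol(Rm)
  gi <- as.integer(factor(d$genotype))
  d$y1 <- g[gi, 1] + E[, 1]
  d$y2 <- g[gi, 2] + E[, 2]
  d
}

# minimal hand-built rr_fit-shaped object for tests of the derived
# operations that only need K, basis and u_hat
fake_rr_fit <- function(K_g, u_hat, domain = c(100, 600),
                        K_p = NULL, sigma2_e = 0.1,
                        times = seq(domain[1], domain[2], length.out = 6)) {
  d <- nrow(K_g)
  if (is.null(K_p)) K_p <- diag(1e-4, d)
  structure(list(K_g = K_g, K_p = K_p, sigma2_e = sigma2_e,
                 u_hat = u_hat,
                 basis = forageRR::legendre_basis(domain, order = d - 1),
                 order = d - 1, times = times, trait = "vi",
                 include_yield = FALSE, residual = "homogeneous",
                 converged = TRUE,
                 genotypes = rownames(u_hat)),
            class = "rr_fit")
}
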