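# Independent oracles used by the equivalence tests.  These deliberately
# take the direct dense-matrix route (explicit V, generic optimizers) so
# they share no code path with the package's mixed-model-equation
# machinery.

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch
# eigenvalue construction
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

# restricted -2 log-likelihood of the single-trait plot model from the
# explicit marginal covariance
st_direct_m2ll <- function(data, response, s2g, s2e) {
  X <- stats::model.matrix(~ 0 + factor(replicate), data)
  Z <- stats::model.matrix(~ 0 + factor(genotype), data)
  n <- nrow(data)
  y <- data[[response]]
  V <- s2g * tcrossprod(Z) + s2e * diag(n)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  as.numeric(determinant(V)$modulus + determinant(XVX)$modulus +
               t(y) %*% P %*% y + (n - ncol(X)) * log(2 * pi))
}

# direct REML maximization for the single-trait model: generic 1-D
# optimizer over the variance ratio with the residual profiled out of the
# explicit-V restricted likelihood
st_reml_oracle <- function(data, response) {
  X <- stats::model.matrix(~ 0 + factor(replicate), data)
  Z <- stats::model.matrix(~ 0 + factor(genotype), data)
  n <- nrow(data)
  p <- ncol(X)
  y <- data[[response]]
  prof <- function(loglam) {
    V <- exp(loglam) * tcrossprod(Z) + diag(n)
    Vi <- solve(V)
    XVX <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
    s2e <- as.numeric(t(y) %*% P %*% y) / (n - p)
    as.numeric(determinant(V)$modulus + determinant(XVX)$modulus) +
      (n - p) * log(s2e)
  }
  opt <- stats::optimize(prof, c(-12, 12), tol = 1e-13)
  lam <- exp(opt$minimum)
  V <- lam * tcrossprod(Z) + diag(n)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  s2e <- as.numeric(t(y) %*% P %*% y) / (n - p)
  c(s2g = lam * s2e, s2e = s2e)
}

# restricted -2 log-likelihood of the random-regression model from the
# explicit marginal covariance (coefficient order: all genotypes for
# coefficient 1, then coefficient 2, ... matching kronecker(K, I))
rr_direct_m2ll <- function(rec, trait, K_g, K_p, s2) {
  d <- nrow(K_g)
  b <- forageRR::legendre_basis(rec$gdd, order = d - 1)
  phi <- b$evaluate(rec$gdd)
  Zg <- stats::model.matrix(~ 0 + factor(genotype), rec)
  Zp <- stats::model.matrix(~ 0 + factor(plot), rec)
  Zgf <- do.call(cbind, lapply(seq_len(d), function(k) Zg * phi[, k]))
  Zpf <- do.call(cbind, lapply(seq_len(d), function(k) Zp * phi[, k]))
  n <- nrow(rec)
  V <- Zgf %*% kronecker(K_g, diag(ncol(Zg))) %*% t(Zgf) +
    Zpf %*% kronecker(K_p, diag(ncol(Zp))) %*% t(Zpf) + s2 * diag(n)
  X <- stats::model.matrix(~ 0 + interaction(replicate, gdd), rec)
  y <- rec[[trait]]
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  as.numeric(determinant(V)$modulus + determinant(XVX)$modulus +
               t(y) %*% P %*% y + (n - ncol(X)) * log(2 * pi))
}

# direct REML maximization of the order-1 random-regression model over
# the Cholesky-parameterized covariance components
rr_reml_oracle <- function(rec, trait, start = c(0, 0, 0, 0, 0, 0,
                                                 log(0.3))) {
  unpackL <- function(v) {
    L <- matrix(c(exp(v[1]), v[2], 0, exp(v[3])), 2, 2)
    tcrossprod(L)
  }
  obj <- function(par) {
    rr_direct_m2ll(rec, trait, unpackL(par[1:3]), unpackL(par[4:6]),
                   exp(par[7]))
  }
  opt <- stats::nlminb(start, obj,
                       control = list(rel.tol = 1e-14, iter.max = 2000))
  list(K_g = unpackL(opt$par[1:3]), K_p = unpackL(opt$par[4:6]),
       s2 = exp(opt$par[7]), m2ll = opt$objective)
}

# restricted -2 log-likelihood of the bivariate model from the explicit
# marginal covariance (trait-major stacking)
biv_direct_m2ll <- function(d, traits, Gm, Rm) {
  X <- stats::model.matrix(~ 0 + factor(replicate), d)
  Z <- stats::model.matrix(~ 0 + factor(genotype), d)
  n <- nrow(d)
  V <- kronecker(Gm, tcrossprod(Z)) + kronecker(Rm, diag(n))
  Xb <- kronecker(diag(2), X)
  y <- c(d[[traits[1]]], d[[traits[2]]])
  Vi <- solve(V)
  XVX <- t(Xb) %*% Vi %*% Xb
  P <- Vi - Vi %*% Xb %*% solve(XVX) %*% t(Xb) %*% Vi
  as.numeric(determinant(V)$modulus + determinant(XVX)$modulus +
               t(y) %*% P %*% y + (2 * n - ncol(Xb)) * log(2 * pi))
}

biv_reml_oracle <- function(d, traits) {
  unpackL <- function(v) {
    L <- matrix(c(exp(v[1]), v[2], 0, exp(v[3])), 2, 2)
    tcrossprod(L)
  }
  obj <- function(par) {
    biv_direct_m2ll(d, traits, unpackL(par[1:3]), unpackL(par[4:6]))
  }
  opt <- stats::nlminb(rep(0, 6), obj,
                       control = list(rel.tol = 1e-14, iter.max = 2000))
  list(G = unpackL(opt$par[1:3]), R = unpackL(opt$par[4:6]),
       m2ll = opt$objective)
}
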