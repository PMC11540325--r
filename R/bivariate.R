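#' Bivariate REML: genetic and residual correlation between two traits
#'
#' Fits the two-trait plot model with unstructured 2x2 genetic (`G`) and
#' residual (`R`) covariance matrices: both traits are observed on the
#' same plots (paired), share the replicate fixed effects and genotype
#' random effects design, genotype effect pairs are `N(0, G)` and plot
#' residual pairs `N(0, R)`.  Estimation is monotone EM-REML on the
#' mixed-model equations of the stacked system, with an optional direct
#' refinement of the restricted log-likelihood over the Cholesky factors
#' of `G` and `R`.  Both matrices are kept positive semidefinite by
#' eigenvalue clipping ("bending") before inversion.
#'
#' The genetic correlation is `r_g = G[1,2] / sqrt(G[1,1] G[2,2])`.  If
#' either genetic variance collapses to the zero boundary, `r_g` is
#' returned as `NA` with an explanatory warning.
#'
#' @param data data frame with both trait columns plus the design factors.
#' @param traits character vector of the two trait column names.
#' @param genotype,replicate design-factor column names.
#' @param tol relative convergence tolerance on the restricted
#'   log-likelihood.
#' @param max_iter EM iteration cap.
#' @param refine polish with `nlminb` over the Cholesky parameterization.
#' @return object of class `bivariate_fit` with `G`, `R`, `r_g`, `r_e`,
#'   per-trait heritabilities, BLUP matrix, log-likelihood trace and
#'   convergence metadata.
#' @export
fit_bivariate <- function(data, traits, genotype = "genotype",
                          replicate = "replicate", tol = 1e-10,
                          max_iter = 1000, refine = TRUE) {
  stopifnot(length(traits) == 2)
  need <- c(traits, genotype, replicate)
  if (!all(need %in% names(data))) {
    stop("missing columns: ", paste(setdiff(need, names(data)),
                                    collapse = ", "))
  }
  data <- data[stats::complete.cases(data[, need]), , drop = FALSE]
  Y <- as.matrix(data[, traits])
  Gf <- factor(data[[genotype]])
  Rf <- factor(data[[replicate]])
  m <- nlevels(Gf)
  p <- nlevels(Rf)
  n <- nrow(Y)
  if (m < 2) stop("need at least 2 genotypes")

  X <- stats::model.matrix(~ Rf - 1)
  Z <- stats::model.matrix(~ Gf - 1)
  WW <- cbind(X, Z)
  S <- crossprod(WW)            # (p+m) square, shared by both traits
  WtY <- crossprod(WW, Y)       # (p+m) x 2
  q <- p + m
  ui <- p + seq_len(m)
  J <- diag(c(rep(0, p), rep(1, m)))

  bend <- function(A, eps = 1e-8) {
    e <- eigen((A + t(A)) / 2, symmetric = TRUE)
    lam <- pmax(e$values, eps * max(e$values, eps))
    e$vectors %*% (lam * t(e$vectors))
  }

  # coefficient matrix of the stacked MME, trait-major ordering
  build_M <- function(Gm, Rm) {
    Ri <- solve(bend(Rm))
    Gi <- solve(bend(Gm))
    M <- rbind(cbind(Ri[1, 1] * S, Ri[1, 2] * S),
               cbind(Ri[2, 1] * S, Ri[2, 2] * S))
    M[1:q, 1:q] <- M[1:q, 1:q] + Gi[1, 1] * J
    M[1:q, q + 1:q] <- M[1:q, q + 1:q] + Gi[1, 2] * J
    M[q + 1:q, 1:q] <- M[q + 1:q, 1:q] + Gi[2, 1] * J
    M[q + 1:q, q + 1:q] <- M[q + 1:q, q + 1:q] + Gi[2, 2] * J
    rhs <- c(Ri[1, 1] * WtY[, 1] + Ri[1, 2] * WtY[, 2],
             Ri[2, 1] * WtY[, 1] + Ri[2, 2] * WtY[, 2])
    list(M = M, rhs = rhs, Ri = Ri)
  }

  yRy <- function(Ri) {
    Ri[1, 1] * sum(Y[, 1]^2) + Ri[2, 2] * sum(Y[, 2]^2) +
      2 * Ri[1, 2] * sum(Y[, 1] * Y[, 2])
  }

  eval_fit <- function(Gm, Rm) {
    bm <- build_M(Gm, Rm)
    ch <- tryCatch(chol(bm$M), error = function(e) NULL)
    if (is.null(ch)) return(list(m2ll = Inf))
    theta <- backsolve(ch, forwardsolve(t(ch), bm$rhs))
    yPy <- yRy(bm$Ri) - sum(theta * bm$rhs)
    m2ll <- n * determinant(bend(Rm))$modulus[1] +
      m * determinant(bend(Gm))$modulus[1] +
      2 * sum(log(diag(ch))) + yPy + (2 * n - 2 * p) * log(2 * pi)
    list(m2ll = m2ll, theta = theta, ch = ch)
  }

  em_step <- function(Gm, Rm) {
    bm <- build_M(Gm, Rm)
    C <- chol2inv(chol(bm$M))
    theta <- drop(C %*% bm$rhs)
    th <- matrix(theta, q, 2)         # columns: trait 1, trait 2
    U <- th[ui, , drop = FALSE]
    # genetic update: BLUP cross-products plus conditional covariances
    C11 <- sum(diag(C)[ui])
    C22 <- sum(diag(C)[q + ui])
    C12 <- sum(C[cbind(ui, q + ui)])
    G_new <- (crossprod(U) + matrix(c(C11, C12, C12, C22), 2)) / m
    # residual update: E'E plus tr(C^{tt'} S)
    E <- Y - WW %*% th
    Tmat <- matrix(0, 2, 2)
    Tmat[1, 1] <- sum(C[1:q, 1:q] * S)
    Tmat[2, 2] <- sum(C[q + 1:q, q + 1:q] * S)
    Tmat[1, 2] <- Tmat[2, 1] <- sum(C[1:q, q + 1:q] * S)
    R_new <- (crossprod(E) + Tmat) / n
    list(G = G_new, R = R_new)
  }

  vy <- apply(Y, 2, stats::var)
  Gm <- diag(vy / 2)
  Rm <- diag(vy / 2)
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    st <- em_step(Gm, Rm)
    Gm <- st$G
    Rm <- st$R
    cur <- eval_fit(Gm, Rm)$m2ll
    trace <- c(trace, cur)
    if (is.finite(prev) && abs(prev - cur) < tol * (1 + abs(cur))) {
      converged <- TRUE
      break
    }
    prev <- cur
  }

  if (refine) {
    pack <- function(A) {
      L <- t(chol(bend(A)))
      c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
    }
    unpack <- function(v) {
      L <- matrix(c(exp(v[1]), v[2], 0, exp(v[3])), 2, 2)
      tcrossprod(L)
    }
    obj <- function(par) {
      eval_fit(unpack(par[1:3]), unpack(par[4:6]))$m2ll
    }
    opt <- stats::nlminb(c(pack(Gm), pack(Rm)), obj,
                         control = list(rel.tol = 1e-13, iter.max = 500))
    Gm <- unpack(opt$par[1:3])
    Rm <- unpack(opt$par[4:6])
    converged <- converged || opt$convergence == 0
  }

  fin <- eval_fit(Gm, Rm)
  th <- matrix(fin$theta, q, 2)
  boundary <- any(diag(Gm) < 1e-8 * max(diag(Rm) + diag(Gm)))
  r_g <- if (boundary) {
    warning("a genetic variance is at the zero boundary: ",
            "genetic correlation undefined")
    NA_real_
  } else Gm[1, 2] / sqrt(Gm[1, 1] * Gm[2, 2])
  r_e <- Rm[1, 2] / sqrt(Rm[1, 1] * Rm[2, 2])
  structure(list(
    G = Gm, R = Rm, r_g = r_g, r_e = r_e,
    H2 = diag(Gm) / (diag(Gm) + diag(Rm)),
    blups = stats::setNames(
      as.data.frame(th[ui, , drop = FALSE]), traits) |>
      (\(d) { rownames(d) <- levels(Gf); d })(),
    fixed_effects = stats::setNames(
      as.data.frame(th[seq_len(p), , drop = FALSE]), traits),
    traits = traits, loglik = -fin$m2ll / 2, loglik_trace = -trace / 2,
    n_iter = iter, converged = converged, boundary = boundary,
    n = n, m = m, p = p),
    class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat(sprintf("Bivariate REML fit: %s vs %s\n", x$traits[1], x$traits[2]))
  cat(sprintf("  r_g = %.3f, r_e = %.3f, H2 = (%.3f, %.3f)\n",
              x$r_g, x$r_e, x$H2[1], x$H2[2]))
  cat(sprintf("  %s after %d EM iterations\n",
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}
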