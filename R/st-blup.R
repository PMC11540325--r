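#' Single-trait plot model: REML variance components and genotype BLUPs
#'
#' Fits `y = Xb + Zg + e` for one trait at one time point, with fixed
#' replicate effects (cell-mean coding, the intercept absorbed into the
#' replicate cells) and i.i.d. random genotype effects
#' `g ~ N(0, I sigma2_g)`, `e ~ N(0, I sigma2_e)`.  Variance components
#' are estimated by REML: monotone EM iterations on the mixed-model
#' equations, followed (by default) by a quasi-Newton refinement of the
#' restricted log-likelihood for tight convergence.  Genotype BLUPs solve
#' the mixed-model equations at the converged estimates.
#'
#' A genetic variance driven to the zero boundary is reported as exactly
#' zero with `boundary = TRUE`; a constant response returns both
#' components as zero without error.
#'
#' @param data data frame holding one time point of one harvest.
#' @param response name of the trait column.
#' @param genotype,replicate names of the design-factor columns.
#' @param tol relative convergence tolerance on the restricted
#'   log-likelihood (parameter change below `sqrt(tol)` also stops).
#' @param max_iter EM iteration cap; non-convergence is flagged, not an
#'   error.
#' @param refine polish the EM solution with `nlminb` on the restricted
#'   log-likelihood (recommended; needed for agreement with direct
#'   likelihood maximization to ~1e-6).
#' @return object of class `st_blup_fit`: variance components, `H2`,
#'   genotype BLUPs, fixed effects, restricted log-likelihood and its EM
#'   trace, convergence metadata.
#' @seealso [heritability()], [fit_bivariate()]
#' @export
fit_st_blup <- function(data, response, genotype = "genotype",
                        replicate = "replicate", tol = 1e-10,
                        max_iter = 500, refine = TRUE) {
  need <- c(response, genotype, replicate)
  if (!all(need %in% names(data))) {
    stop("missing columns: ", paste(setdiff(need, names(data)),
                                    collapse = ", "))
  }
  data <- data[stats::complete.cases(data[, need]), , drop = FALSE]
  y <- as.numeric(data[[response]])
  G <- factor(data[[genotype]])
  R <- factor(data[[replicate]])
  m <- nlevels(G)
  p <- nlevels(R)
  n <- length(y)
  if (m < 2) stop("need at least 2 genotypes")
  if (n < m + 1) stop("need more observations than genotypes")

  vy <- stats::var(y)
  if (vy < 1e-300) {
    return(new_st_fit(0, 0, stats::setNames(rep(0, m), levels(G)),
                      stats::setNames(rep(mean(y), p), levels(R)),
                      loglik = NA_real_, trace = numeric(0), n_iter = 0L,
                      converged = TRUE, boundary = TRUE, n = n, p = p,
                      m = m))
  }

  X <- stats::model.matrix(~ R - 1)
  Z <- stats::model.matrix(~ G - 1)
  alias <- colSums(X) == 0
  if (any(alias)) {
    stop("aliased fixed-effect columns: ",
         paste(colnames(X)[alias], collapse = ", "))
  }
  W <- cbind(X, Z)
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  yty <- sum(y^2)
  ui <- p + seq_len(m)

  # restricted -2 log-likelihood and MME solution at given components
  eval_fit <- function(s2g, s2e) {
    M <- WtW / s2e
    diag(M)[ui] <- diag(M)[ui] + 1 / s2g
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(list(m2ll = Inf))
    theta <- backsolve(ch, forwardsolve(t(ch), Wty / s2e))
    yPy <- yty / s2e - sum(theta * Wty) / s2e
    m2ll <- n * log(s2e) + m * log(s2g) + 2 * sum(log(diag(ch))) + yPy +
      (n - p) * log(2 * pi)
    list(m2ll = m2ll, theta = theta, ch = ch)
  }

  # EM-REML step (monotone in the restricted likelihood)
  em_step <- function(s2g, s2e) {
    M <- WtW / s2e
    diag(M)[ui] <- diag(M)[ui] + 1 / s2g
    C <- chol2inv(chol(M))
    theta <- drop(C %*% (Wty / s2e))
    u <- theta[ui]
    tr_cuu <- sum(diag(C)[ui])
    s2g_new <- (sum(u^2) + tr_cuu) / m
    rss <- yty - 2 * sum(theta * Wty) + drop(t(theta) %*% WtW %*% theta)
    tr_wcw <- s2e * (p + m - tr_cuu / s2g)
    s2e_new <- (rss + tr_wcw) / n
    c(s2g_new, s2e_new)
  }

  s2g <- s2e <- vy / 2
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  boundary <- FALSE
  iter <- 0L
  floor_g <- 1e-10 * vy
  while (iter < max_iter) {
    iter <- iter + 1L
    new <- em_step(s2g, s2e)
    if (new[1] < floor_g) {
      boundary <- TRUE
      s2g <- 0
      s2e <- new[2]
      break
    }
    s2g <- new[1]
    s2e <- new[2]
    cur <- eval_fit(s2g, s2e)$m2ll
    trace <- c(trace, cur)
    if (is.finite(prev) &&
        abs(prev - cur) < tol * (1 + abs(cur))) {
      converged <- TRUE
      break
    }
    prev <- cur
  }

  if (boundary) {
    # sigma2_g on the zero boundary: residual variance is the fixed-model
    # REML estimate
    fe <- stats::lm.fit(X, y)
    s2e <- sum(fe$residuals^2) / (n - p)
    b <- fe$coefficients
    u <- rep(0, m)
    ll <- -0.5 * ((n - p) * (log(2 * pi) + log(s2e)) + (n - p) +
                    determinant(crossprod(X) / s2e)$modulus[1])
    return(new_st_fit(0, s2e, stats::setNames(u, levels(G)),
                      stats::setNames(b, levels(R)), loglik = ll,
                      trace = -trace / 2, n_iter = iter,
                      converged = TRUE, boundary = TRUE, n = n, p = p,
                      m = m))
  }

  if (refine) {
    # profile the residual variance out of the restricted likelihood and
    # optimize the variance ratio lambda = s2g / s2e exactly in 1-D
    prof <- function(loglam) {
      lam <- exp(loglam)
      M <- WtW
      diag(M)[ui] <- diag(M)[ui] + 1 / lam
      ch <- chol(M)
      theta <- backsolve(ch, forwardsolve(t(ch), Wty))
      yPy1 <- yty - sum(theta * Wty)
      s2e_hat <- yPy1 / (n - p)
      (n - p) * log(s2e_hat) + m * log(lam) + 2 * sum(log(diag(ch))) +
        (n - p)
    }
    lo <- log(s2g / s2e) - 6
    hi <- log(s2g / s2e) + 6
    repeat {
      opt <- stats::optimize(prof, c(lo, hi), tol = 1e-12)
      if (opt$minimum > lo + 1e-3 || lo < log(1e-14)) break
      lo <- lo - 8   # optimum pinned at the edge: widen toward zero
    }
    lam <- exp(opt$minimum)
    if (opt$minimum <= log(1e-14) + 1e-3) {
      # variance ratio driven to zero: report the boundary fit
      fe <- stats::lm.fit(X, y)
      s2e <- sum(fe$residuals^2) / (n - p)
      ll <- -0.5 * ((n - p) * (log(2 * pi) + log(s2e)) + (n - p) +
                      determinant(crossprod(X) / s2e)$modulus[1])
      return(new_st_fit(0, s2e,
                        stats::setNames(rep(0, m), levels(G)),
                        stats::setNames(fe$coefficients, levels(R)),
                        loglik = ll, trace = -trace / 2, n_iter = iter,
                        converged = TRUE, boundary = TRUE, n = n, p = p,
                        m = m))
    } else {
      M <- WtW
      diag(M)[ui] <- diag(M)[ui] + 1 / lam
      theta <- solve(M, Wty)
      s2e <- drop(yty - sum(theta * Wty)) / (n - p)
      s2g <- lam * s2e
      if (s2g <= floor_g * 1.01) boundary <- TRUE
    }
    converged <- TRUE
  }

  fin <- eval_fit(s2g, s2e)
  theta <- drop(fin$theta)
  new_st_fit(s2g, s2e,
             blups = stats::setNames(theta[ui], levels(G)),
             fixed = stats::setNames(theta[seq_len(p)], levels(R)),
             loglik = -fin$m2ll / 2, trace = -trace / 2, n_iter = iter,
             converged = converged, boundary = boundary, n = n, p = p,
             m = m)
}

new_st_fit <- function(s2g, s2e, blups, fixed, loglik, trace, n_iter,
                       converged, boundary, n, p, m) {
  structure(list(sigma2_g = s2g, sigma2_e = s2e, blups = blups,
                 fixed_effects = fixed, loglik = loglik,
                 loglik_trace = trace, n_iter = n_iter,
                 converged = converged, boundary = boundary,
                 n = n, p = p, m = m),
            class = "st_blup_fit")
}

#' @export
print.st_blup_fit <- function(x, ...) {
  cat("Single-trait REML plot model\n")
  cat(sprintf("  sigma2_g = %.6g, sigma2_e = %.6g, H2 = %.3f\n",
              x$sigma2_g, x$sigma2_e, heritability(x)))
  cat(sprintf("  %d genotypes, %d obs; %s after %d EM iterations%s\n",
              x$m, x$n, if (x$converged) "converged" else "NOT converged",
              x$n_iter, if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

#' Plot-level broad-sense heritability
#'
#' `H2 = sigma2_g / (sigma2_g + sigma2_e)`, the ratio of genetic variance
#' to total plot variance.  Zero total variance gives `NA` with a warning.
#'
#' @param object an `st_blup_fit`, or the genetic variance as a number.
#' @param sigma2_e residual variance (when `object` is numeric).
#' @return heritability in \[0, 1\], or `NA` if undefined.
#' @examples
#' heritability(1, 1)  # 0.5
#' @export
heritability <- function(object, sigma2_e = NULL) {
  if (is.numeric(object)) {
    s2g <- object
    s2e <- sigma2_e
  } else {
    s2g <- object$sigma2_g
    s2e <- object$sigma2_e
  }
  tot <- s2g + s2e
  out <- s2g / tot
  if (any(tot <= 0, na.rm = TRUE)) {
    warning("zero total variance: heritability undefined")
    out[tot <= 0] <- NA_real_
  }
  out
}

#' Phenotypic correlation of an index with yield, per harvest
#'
#' Plain Pearson correlation between plot-level index values from the
#' flight closest to harvest (the last flight of the cycle) and the
#' plot's harvested yield.
#'
#' @param records long-format table containing index rows
#'   (`is_yield = FALSE`) and terminal yield rows (`is_yield = TRUE`), as
#'   produced by [simulate_yield_from_curve()] or a validated plot table.
#' @param trait index column name.
#' @return data frame `harvest`, `gdd` (of the flight used), `n`, `r`.
#' @export
phenotypic_correlation <- function(records, trait) {
  stopifnot(all(c("plot", "harvest", "gdd", "is_yield", trait) %in%
                  names(records)))
  out <- lapply(split(records, records$harvest), function(h) {
    yld <- h[h$is_yield, c("plot", trait)]
    vi <- h[!h$is_yield, ]
    last <- vi[vi$gdd == max(vi$gdd), c("plot", trait)]
    mm <- merge(last, yld, by = "plot", suffixes = c("_vi", "_y"))
    if (nrow(mm) < 3) stop("need at least 3 paired plots")
    x <- mm[[paste0(trait, "_vi")]]
    y <- mm[[paste0(trait, "_y")]]
    r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero variance: correlation undefined")
      NA_real_
    } else stats::cor(x, y)
    data.frame(harvest = h$harvest[1], gdd = max(vi$gdd), n = nrow(mm),
               r = r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
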