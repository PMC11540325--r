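#' Scale terminal yield to the variance of the last index observation
#'
#' Before appending harvested yield as the final time point of a
#' random-regression fit, yield is rescaled so its sample variance equals
#' that of the index at the preceding (last) flight.  Pure scaling: plot
#' ranking and all correlations with yield are unchanged.
#'
#' @param yield_values plot-level yield.
#' @param last_vi_values plot-level index values at the last flight.
#' @return scaled yield vector, with the multiplier in attribute
#'   `"scale_factor"`.
#' @examples
#' y <- scale_terminal_yield(c(0, 2, 4), c(0, 1, 2))  # factor 0.5
#' @export
scale_terminal_yield <- function(yield_values, last_vi_values) {
  vy <- stats::var(yield_values)
  vv <- stats::var(last_vi_values)
  if (!is.finite(vy) || vy <= 0) stop("yield has zero variance")
  if (!is.finite(vv) || vv <= 0) stop("index has zero variance")
  f <- sqrt(vv / vy)
  structure(yield_values * f, scale_factor = f)
}

# pack/unpack symmetric matrices for the EM parameter vector
vech <- function(A) A[lower.tri(A, diag = TRUE)]
unvech <- function(v, d) {
  A <- matrix(0, d, d)
  A[lower.tri(A, diag = TRUE)] <- v
  A + t(A) - diag(diag(A), d)
}

clip_psd <- function(A, eps = 1e-8) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, eps * max(e$values, eps))
  list(mat = e$vectors %*% (lam * t(e$vectors)),
       clipped = any(e$values < eps * max(e$values, eps)))
}

#' Random-regression growth-curve model by REML
#'
#' Fits the longitudinal plot model
#' `y(t,j,r) = beta_r(t) + phi(t)' u_j + phi(t)' p_jr + eps(t)` for one
#' harvest cycle: replicate-within-time-point fixed cells, genotype
#' random-regression coefficients `u_j ~ N(0, K_g)` on a normalized
#' Legendre basis of standardized time, permanent-environment plot
#' coefficients `p_jr ~ N(0, K_p)`, and residual variance that is either
#' shared across time points or time-point specific.  Estimation is
#' monotone EM-REML on the mixed-model equations with the plot equations
#' absorbed each step; a guarded squared-extrapolation accelerator cuts
#' the iteration count, and `refine = TRUE` finishes with a direct
#' quasi-Newton maximization of the restricted log-likelihood over the
#' Cholesky factors (used for tight-tolerance comparisons).
#'
#' With `include_yield = TRUE`, plot yield (rows flagged `is_yield`) is
#' rescaled by [scale_terminal_yield()] to the variance of the last
#' flight, appended as the final time point at its harvest GDD, and the
#' basis domain re-standardized to include it.
#'
#' @param records long-format table for one harvest cycle with columns
#'   `plot`, `genotype`, `replicate`, `gdd`, `is_yield` (optional if no
#'   yield rows) and the trait column.
#' @param trait trait column name.
#' @param order Legendre degree (default 3, i.e. `order + 1` coefficients
#'   per effect; the same order is used for genetic and
#'   permanent-environment terms).
#' @param include_yield append the scaled terminal yield record.
#' @param residual `"homogeneous"` (one variance) or `"per_time_point"`.
#' @param harvest optional harvest label to subset on (required if
#'   `records` spans several cycles).
#' @param tol relative convergence tolerance on the restricted
#'   log-likelihood.
#' @param max_iter cap on EM-step evaluations.
#' @param accelerate use guarded extrapolation between EM steps.  Turn
#'   off to obtain a textbook monotone EM sequence.
#' @param refine finish with `nlminb` on the restricted log-likelihood.
#' @return object of class `rr_fit`: `K_g`, `K_p`, `sigma2_e`, `beta`,
#'   `u_hat`, `p_hat`, `basis`, log-likelihood and trace, convergence
#'   metadata, and a PSD-clip counter.
#' @seealso [covariance_surface()], [genetic_correlation_curve()],
#'   [growth_curves()], [heritability_curve()]
#' @export
fit_rr <- function(records, trait, order = 3, include_yield = FALSE,
                   residual = c("homogeneous", "per_time_point"),
                   harvest = NULL, tol = 1e-8, max_iter = 300,
                   accelerate = TRUE, refine = FALSE) {
  residual <- match.arg(residual)
  need <- c("plot", "genotype", "replicate", "gdd", trait)
  if (!all(need %in% names(records))) {
    stop("missing columns: ", paste(setdiff(need, names(records)),
                                    collapse = ", "))
  }
  if (!"is_yield" %in% names(records)) records$is_yield <- FALSE
  if ("harvest" %in% names(records)) {
    if (!is.null(harvest)) records <- records[records$harvest == harvest, ]
    if (length(unique(records$harvest)) > 1) {
      stop("records span several harvest cycles; pass `harvest =` or subset")
    }
  }
  vi <- records[!records$is_yield, ]
  if (!nrow(vi)) stop("no index records")

  yield_scale <- NA_real_
  if (include_yield) {
    yld <- records[records$is_yield, ]
    if (!nrow(yld)) stop("include_yield = TRUE but no yield rows present")
    last <- vi[vi$gdd == max(vi$gdd), c("plot", trait)]
    mm <- merge(last, yld[, c("plot", "gdd", trait)], by = "plot",
                suffixes = c("_vi", "_y"))
    sc <- scale_terminal_yield(mm[[paste0(trait, "_y")]],
                               mm[[paste0(trait, "_vi")]])
    yield_scale <- attr(sc, "scale_factor")
    yld <- yld[match(mm$plot, yld$plot), ]
    yld[[trait]] <- as.numeric(sc)
    dat <- rbind(vi[, need], yld[, need])
  } else {
    dat <- vi[, need]
  }

  d <- order + 1
  times <- sort(unique(dat$gdd))
  nt <- length(times)
  if (nt <= d) {
    stop(sprintf(paste0("basis-by-time design is rank deficient: degree %d",
                        " needs more than %d distinct time points, have %d"),
                 order, d, nt))
  }
  if (anyDuplicated(dat[, c("plot", "gdd")])) {
    stop("duplicated plot x time records")
  }
  obs_per_plot <- table(dat$plot)
  if (any(obs_per_plot < 2)) {
    stop("every plot must be observed at >= 2 time points; offending: ",
         paste(utils::head(names(obs_per_plot)[obs_per_plot < 2], 5),
               collapse = ", "))
  }

  basis <- legendre_basis(dat$gdd, order = order)
  y <- as.numeric(dat[[trait]])
  n <- length(y)
  phi <- basis$evaluate(dat$gdd)
  time_id <- match(dat$gdd, times)
  pl <- factor(dat$plot)
  gf <- factor(dat$genotype)
  cellf <- factor(paste(dat$replicate, time_id, sep = "@"))
  P <- nlevels(pl)
  m <- nlevels(gf)
  nF <- nlevels(cellf)
  geno_of_pl <- as.integer(gf[match(levels(pl), as.character(pl))])
  pl_i <- as.integer(pl)
  g_i <- as.integer(gf)
  c_i <- as.integer(cellf)

  if (residual == "per_time_point") {
    thin <- table(time_id) < 2 * d
    if (any(thin)) {
      warning("per-time-point residual weakly identified at time point(s) ",
              paste(times[thin], collapse = ", "),
              " (< 2*(order+1) records)")
    }
  }

  # index scaffolding for vectorized assembly of the reduced MME
  q_s <- nF + m * d
  ucol <- function(j) nF + (j - 1L) * d + seq_len(d)
  pairkey <- (g_i - 1L) * nF + c_i
  upairs <- sort(unique(pairkey))
  pair_of_row <- match(pairkey, upairs)
  pair_cell <- (upairs - 1L) %% nF + 1L
  pair_geno <- (upairs - 1L) %/% nF + 1L
  fu_idx <- cbind(rep(pair_cell, d),
                  rep(nF + (pair_geno - 1L) * d, d) +
                    rep(seq_len(d), each = length(upairs)))
  combo <- which(lower.tri(matrix(0, d, d), diag = TRUE), arr.ind = TRUE)
  n_combo <- nrow(combo)
  uu_idx <- cbind(rep(nF + (seq_len(m) - 1L) * d, n_combo) +
                    rep(combo[, 1], each = m),
                  rep(nF + (seq_len(m) - 1L) * d, n_combo) +
                    rep(combo[, 2], each = m))
  rows_of_pl <- split(seq_len(n), pl_i)

  vy <- stats::var(y)
  n_time_levels <- if (residual == "per_time_point") nt else 1L
  clip_count <- 0L

  # one EM step: returns the updated parameters plus the restricted
  # log-likelihood, BLUPs and residuals evaluated AT the input parameters
  em_step <- function(par, want_effects = FALSE) {
    K_g <- unvech(par$kg, d)
    K_p <- unvech(par$kp, d)
    s2 <- par$s2
    cg <- clip_psd(K_g); cp <- clip_psd(K_p)
    if (cg$clipped || cp$clipped) clip_count <<- clip_count + 1L
    K_g <- cg$mat; K_p <- cp$mat
    Kg_inv <- solve(K_g)
    Kp_inv <- solve(K_p)
    w <- if (residual == "per_time_point") 1 / s2[time_id] else
      rep(1 / s2, n)

    wphi <- phi * w
    wy <- w * y
    rhs_f <- drop(rowsum(wy, c_i))
    rhs_u <- rowsum(wphi * y, g_i)            # m x d
    rhs_p <- rowsum(wphi * y, pl_i)           # P x d
    fu_agg <- rowsum(wphi, pair_of_row)       # npairs x d
    uu_agg <- matrix(0, m, n_combo)
    gram_pl <- matrix(0, P, n_combo)
    for (cc in seq_len(n_combo)) {
      v <- wphi[, combo[cc, 1]] * phi[, combo[cc, 2]]
      uu_agg[, cc] <- rowsum(v, g_i)
      gram_pl[, cc] <- rowsum(v, pl_i)
    }

    M <- matrix(0, q_s, q_s)
    diag(M)[seq_len(nF)] <- drop(rowsum(w, c_i))
    M[fu_idx] <- as.vector(fu_agg)
    M[fu_idx[, 2:1]] <- as.vector(fu_agg)
    M[uu_idx] <- as.vector(uu_agg) +
      rep(Kg_inv[combo], each = m)
    M[uu_idx[, 2:1]] <- M[uu_idx]
    rhs_s <- c(rhs_f, as.vector(t(rhs_u)))

    Dinv_pl <- vector("list", P)
    Bc_pl <- vector("list", P)
    idx_pl <- vector("list", P)
    ldet_D <- 0
    rpDr <- 0
    for (k in seq_len(P)) {
      rows <- rows_of_pl[[k]]
      Gram <- unvech(gram_pl[k, ], d)
      Dk <- Gram + Kp_inv
      chD <- chol(Dk)
      ldet_D <- ldet_D + 2 * sum(log(diag(chD)))
      Dinv <- chol2inv(chD)
      Bc <- rbind(wphi[rows, , drop = FALSE], Gram)
      idx <- c(c_i[rows], ucol(geno_of_pl[k]))
      M[idx, idx] <- M[idx, idx] - Bc %*% Dinv %*% t(Bc)
      rhs_s[idx] <- rhs_s[idx] - Bc %*% (Dinv %*% rhs_p[k, ])
      rpDr <- rpDr + sum(rhs_p[k, ] * (Dinv %*% rhs_p[k, ]))
      Dinv_pl[[k]] <- Dinv
      Bc_pl[[k]] <- Bc
      idx_pl[[k]] <- idx
    }

    ch <- chol(M)
    C_red <- chol2inv(ch)
    theta <- drop(C_red %*% rhs_s)

    u_hat <- matrix(theta[-seq_len(nF)], m, d, byrow = TRUE)
    beta_hat <- theta[seq_len(nF)]
    p_hat <- matrix(0, P, d)
    Kp_acc <- matrix(0, d, d)
    tr_cpp_kpinv <- 0
    for (k in seq_len(P)) {
      idx <- idx_pl[[k]]
      Dinv <- Dinv_pl[[k]]
      Bc <- Bc_pl[[k]]
      p_hat[k, ] <- Dinv %*% (rhs_p[k, ] - crossprod(Bc, theta[idx]))
      DB <- Dinv %*% t(Bc)
      Cpp <- Dinv + DB %*% C_red[idx, idx] %*% t(DB)
      Kp_acc <- Kp_acc + tcrossprod(p_hat[k, ]) + Cpp
      tr_cpp_kpinv <- tr_cpp_kpinv + sum(Cpp * Kp_inv)
    }
    Kg_acc <- matrix(0, d, d)
    tr_cuu_kginv <- 0
    for (j in seq_len(m)) {
      Cu <- C_red[ucol(j), ucol(j)]
      Kg_acc <- Kg_acc + tcrossprod(u_hat[j, ]) + Cu
      tr_cuu_kginv <- tr_cuu_kginv + sum(Cu * Kg_inv)
    }
    K_g_new <- Kg_acc / m
    K_p_new <- Kp_acc / P

    fitted <- beta_hat[c_i] + rowSums(phi * u_hat[g_i, , drop = FALSE]) +
      rowSums(phi * p_hat[pl_i, , drop = FALSE])
    e_hat <- y - fitted
    if (residual == "homogeneous") {
      tr_wcw <- (q_s + P * d - tr_cuu_kginv - tr_cpp_kpinv) * s2
      s2_new <- (sum(e_hat^2) + tr_wcw) / n
    } else {
      wcw <- row_wcw(C_red, Dinv_pl, Bc_pl, idx_pl, rows_of_pl,
                     wphi, phi, c_i, geno_of_pl, ucol, nF, n)
      s2_new <- drop(rowsum(e_hat^2 + wcw, time_id)) /
        tabulate(time_id, nt)
    }

    yPy <- sum(wy * y) - sum(theta * rhs_s) - rpDr
    ldet_R <- if (residual == "per_time_point")
      sum(tabulate(time_id, nt) * log(s2)) else n * log(s2)
    m2ll <- ldet_R + m * determinant(K_g)$modulus[1] +
      P * determinant(K_p)$modulus[1] + ldet_D +
      2 * sum(log(diag(ch))) + yPy + (n - nF) * log(2 * pi)

    out <- list(par = list(kg = vech(K_g_new), kp = vech(K_p_new),
                           s2 = pmax(s2_new, 1e-12 * vy)),
                m2ll = m2ll)
    if (want_effects) {
      out$u_hat <- u_hat
      out$p_hat <- p_hat
      out$beta <- beta_hat
      out$K_g <- K_g
      out$K_p <- K_p
      out$s2 <- s2
    }
    out
  }

  project <- function(par) {
    par$kg <- vech(clip_psd(unvech(par$kg, d))$mat)
    par$kp <- vech(clip_psd(unvech(par$kp, d))$mat)
    par$s2 <- pmax(par$s2, 1e-12 * vy)
    par
  }
  par_vec <- function(par) c(par$kg, par$kp, par$s2)
  vec_par <- function(v) list(kg = v[seq_len(n_combo)],
                              kp = v[n_combo + seq_len(n_combo)],
                              s2 = v[2 * n_combo + seq_len(n_time_levels)])

  # starting values: split the raw variance across the three strata,
  # scaled by the average squared basis norm so Var(t) is the right size
  cbar <- mean(rowSums(phi^2))
  par <- list(kg = vech(diag(vy / (3 * cbar), d)),
              kp = vech(diag(vy / (3 * cbar), d)),
              s2 = rep(vy / 3, n_time_levels))

  trace <- numeric(0)
  n_eval <- 0L
  converged <- FALSE
  prev <- Inf
  note_ll <- function(ll) {
    trace <<- c(trace, -ll / 2)
    n_eval <<- n_eval + 1L
    done <- is.finite(prev) && abs(prev - ll) < tol * (1 + abs(ll))
    prev <<- ll
    done
  }

  while (n_eval < max_iter && !converged) {
    s1 <- em_step(par)
    converged <- note_ll(s1$m2ll)
    if (converged || n_eval >= max_iter) { par <- s1$par; break }
    if (!accelerate) { par <- s1$par; next }
    s2e <- em_step(s1$par)
    converged <- note_ll(s2e$m2ll)
    if (converged || n_eval >= max_iter) { par <- s2e$par; break }
    t0 <- par_vec(par); t1 <- par_vec(s1$par); t2 <- par_vec(s2e$par)
    r <- t1 - t0
    v <- t2 - 2 * t1 + t0
    if (sqrt(sum(v^2)) < 1e-14) { par <- s2e$par; next }
    alpha <- min(-sqrt(sum(r^2)) / sqrt(sum(v^2)), -1)
    cand <- project(vec_par(t0 - 2 * alpha * r + alpha^2 * v))
    s3 <- em_step(cand)
    if (is.finite(s3$m2ll) && s3$m2ll <= prev) {
      converged <- note_ll(s3$m2ll)
      par <- s3$par
    } else {
      par <- s2e$par
    }
  }

  if (refine) {
    pack_chol <- function(K) {
      L <- t(chol(clip_psd(unvech(K, d), 1e-7)$mat))
      v <- L[lower.tri(L, diag = TRUE)]
      di <- cumsum(c(1, rev(seq_len(d - 1) + 1)))  # diagonal positions
      v[di] <- log(diag(L))
      v
    }
    unpack_chol <- function(v) {
      L <- matrix(0, d, d)
      L[lower.tri(L, diag = TRUE)] <- v
      diag(L) <- exp(diag(L))
      vech(tcrossprod(L))
    }
    nv <- n_combo
    obj <- function(x) {
      pp <- list(kg = unpack_chol(x[seq_len(nv)]),
                 kp = unpack_chol(x[nv + seq_len(nv)]),
                 s2 = exp(x[2 * nv + seq_len(n_time_levels)]))
      val <- tryCatch(em_step(pp)$m2ll, error = function(e) Inf)
      if (!is.finite(val)) 1e10 else val
    }
    x0 <- c(pack_chol(par$kg), pack_chol(par$kp), log(par$s2))
    opt <- stats::nlminb(x0, obj, control = list(rel.tol = 1e-13,
                                                 iter.max = 1000))
    par <- list(kg = unpack_chol(opt$par[seq_len(nv)]),
                kp = unpack_chol(opt$par[nv + seq_len(nv)]),
                s2 = exp(opt$par[2 * nv + seq_len(n_time_levels)]))
    converged <- converged || opt$convergence == 0
  }

  fin <- em_step(par, want_effects = TRUE)
  rownames(fin$u_hat) <- levels(gf)
  rownames(fin$p_hat) <- levels(pl)
  s2_out <- fin$s2
  if (residual == "per_time_point") names(s2_out) <- as.character(times)

  structure(list(
    K_g = fin$K_g, K_p = fin$K_p, sigma2_e = s2_out,
    beta = stats::setNames(fin$beta, levels(cellf)),
    u_hat = fin$u_hat, p_hat = fin$p_hat,
    basis = basis, order = order, times = times, trait = trait,
    include_yield = include_yield, yield_scale = yield_scale,
    residual = residual, loglik = -fin$m2ll / 2, loglik_trace = trace,
    n_iter = n_eval, converged = converged, psd_clips = clip_count,
    genotypes = levels(gf), plots = levels(pl), n = n),
    class = "rr_fit")
}

# per-row diagonal of W C W' for the heterogeneous residual EM update
row_wcw <- function(C_red, Dinv_pl, Bc_pl, idx_pl, rows_of_pl, wphi, phi,
                    c_i, geno_of_pl, ucol, nF, n) {
  out <- numeric(n)
  for (k in seq_along(rows_of_pl)) {
    rows <- rows_of_pl[[k]]
    idx <- idx_pl[[k]]
    H <- C_red[idx, idx]
    DB <- Dinv_pl[[k]] %*% t(Bc_pl[[k]])
    Xc <- -H %*% t(DB)                      # cov(touched s, p_k)
    Cpp <- Dinv_pl[[k]] + DB %*% H %*% t(DB)
    nr <- length(rows)
    # touched-coordinate design per row: unit weight on its own cell
    # position (1..nr) plus phi in the genotype block (nr+1 .. nr+d)
    Ph <- phi[rows, , drop = FALSE]
    V <- cbind(diag(nr), Ph)
    out[rows] <- rowSums((V %*% H) * V) + 2 * rowSums((V %*% Xc) * Ph) +
      rowSums((Ph %*% Cpp) * Ph)
  }
  out
}

#' @export
print.rr_fit <- function(x, ...) {
  cat(sprintf("Random-regression REML fit (degree %d) for '%s'\n",
              x$order, x$trait))
  cat(sprintf("  %d genotypes, %d plots, %d time points%s, %d records\n",
              length(x$genotypes), length(x$plots), length(x$times),
              if (x$include_yield) " (incl. terminal yield)" else "", x$n))
  cat("  K_g diagonal:", paste(signif(diag(x$K_g), 4), collapse = ", "),
      "\n")
  cat("  K_p diagonal:", paste(signif(diag(x$K_p), 4), collapse = ", "),
      "\n")
  cat(sprintf("  sigma2_e: %s; logLik %.3f; %s after %d EM evaluations\n",
              paste(signif(x$sigma2_e, 4), collapse = ", "), x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}
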