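#' Covariance function implied by a random-regression fit
#'
#' Evaluates `Cov(t, s) = phi(t*)' K phi(s*)` for the genetic or
#' permanent-environment coefficient covariance of an [fit_rr()] result.
#' Times outside the standardized fitting domain are extrapolated with a
#' warning.
#'
#' @param fit an `rr_fit`.
#' @param source `"genetic"` (K_g) or `"permanent"` (K_p).
#' @return object of class `cov_surface`: evaluators `cov(t, s)`,
#'   `var(t)`, `cor(t, s)` over raw GDD time, plus `K` and `basis`.
#' @export
covariance_surface <- function(fit, source = c("genetic", "permanent")) {
  source <- match.arg(source)
  stopifnot(inherits(fit, "rr_fit"))
  if (!fit$converged) {
    warning("random-regression fit did not converge; ",
            "covariance surface may be unreliable")
  }
  K <- if (source == "genetic") fit$K_g else fit$K_p
  out <- cov_function(K, fit$basis)
  out$source <- source
  class(out) <- "cov_surface"
  out
}

#' @export
print.cov_surface <- function(x, ...) {
  cat(sprintf("%s covariance surface on [%g, %g] GDD (degree %d)\n",
              x$source, x$basis$domain[1], x$basis$domain[2],
              x$basis$order))
  invisible(x)
}

#' Genetic correlation of the index trajectory with a reference time
#'
#' Computes `r(t) = Cov_g(t, T) / sqrt(Var_g(t) Var_g(T))` along a time
#' grid, where the reference `T` is the terminal time point of the fit
#' (the appended yield record, when the model was fitted with
#' `include_yield = TRUE`) or any GDD value supplied directly.  Grid
#' points with zero genetic variance get `NA`.
#'
#' @param fit an `rr_fit`.
#' @param t_grid GDD values; default 50 points across the fitted domain.
#' @param reference `"terminal"` or a GDD value.
#' @return data frame `gdd`, `r`.
#' @export
genetic_correlation_curve <- function(fit, t_grid = NULL,
                                      reference = "terminal") {
  surf <- covariance_surface(fit, "genetic")
  if (is.null(t_grid)) {
    t_grid <- seq(fit$basis$domain[1], fit$basis$domain[2],
                  length.out = 50)
  }
  Tref <- if (identical(reference, "terminal")) max(fit$times) else {
    stopifnot(is.numeric(reference), length(reference) == 1)
    reference
  }
  vT <- surf$var(Tref)
  vt <- surf$var(t_grid)
  r <- drop(surf$cov(t_grid, Tref)) / sqrt(vt * vT)
  bad <- vt <= 0 | vT <= 0
  if (any(bad)) {
    warning("zero genetic variance at some grid points: correlation NA")
    r[bad] <- NA_real_
  }
  data.frame(gdd = t_grid, r = pmin(pmax(r, -1), 1))
}

#' Genotype breeding-value growth curves
#'
#' Evaluates each genotype's fitted genetic trajectory
#' `g_j(t) = phi(t*)' u_j` on a GDD grid and flags the top and bottom
#' deciles by terminal breeding value, mirroring the usual growth-curve
#' display of high- and low-yielding entries.
#'
#' @param fit an `rr_fit`.
#' @param t_grid GDD values; default 50 points across the fitted domain.
#' @return tidy data frame `genotype`, `gdd`, `bv`, `decile`
#'   (`"high"`/`"low"`/`"mid"` by terminal BV).
#' @export
growth_curves <- function(fit, t_grid = NULL) {
  stopifnot(inherits(fit, "rr_fit"))
  if (is.null(t_grid)) {
    t_grid <- seq(fit$basis$domain[1], fit$basis$domain[2],
                  length.out = 50)
  }
  Phi <- fit$basis$evaluate(t_grid)
  bv <- fit$u_hat %*% t(Phi)              # genotypes x grid
  terminal <- bv[, ncol(bv)]
  qs <- stats::quantile(terminal, c(0.1, 0.9))
  decile <- ifelse(terminal <= qs[1], "low",
                   ifelse(terminal >= qs[2], "high", "mid"))
  data.frame(
    genotype = rep(rownames(fit$u_hat), times = length(t_grid)),
    gdd = rep(t_grid, each = nrow(bv)),
    bv = as.vector(bv),
    decile = rep(decile, times = length(t_grid)),
    stringsAsFactors = FALSE)
}

#' Time-resolved plot-level heritability
#'
#' `H2(t) = Var_g(t) / (Var_g(t) + Var_p(t) + sigma2_e(t))` from the
#' fitted covariance functions.  With a per-time-point residual the
#' residual variance of the nearest observed time point is used.
#'
#' @param fit an `rr_fit`.
#' @param t_grid GDD values; default 50 points across the fitted domain.
#' @return data frame `gdd`, `var_g`, `var_p`, `sigma2_e`, `H2`.
#' @export
heritability_curve <- function(fit, t_grid = NULL) {
  stopifnot(inherits(fit, "rr_fit"))
  if (is.null(t_grid)) {
    t_grid <- seq(fit$basis$domain[1], fit$basis$domain[2],
                  length.out = 50)
  }
  vg <- covariance_surface(fit, "genetic")$var(t_grid)
  vp <- covariance_surface(fit, "permanent")$var(t_grid)
  s2 <- if (length(fit$sigma2_e) > 1) {
    fit$sigma2_e[vapply(t_grid,
                        function(t) which.min(abs(fit$times - t)), 1L)]
  } else rep(fit$sigma2_e, length(t_grid))
  data.frame(gdd = t_grid, var_g = vg, var_p = vp, sigma2_e = s2,
             H2 = vg / (vg + vp + s2))
}
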