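#' Relative selection efficiency of indirect selection on an index
#'
#' `RSE = (h_VI / h_FY) * r_g = sqrt(h2_VI / h2_FY) * r_g`, where `h` are
#' the square roots of the plot-level heritabilities of the vegetation
#' index and of forage yield, and `r_g` their genetic correlation.
#' Values near 1 mean selecting on the index loses little response
#' compared to direct selection on yield; the statistic depends on the
#' heritabilities only through their ratio.
#'
#' @param h2_vi plot-level heritability of the index, in (0, 1\].
#' @param h2_fy plot-level heritability of forage yield, in (0, 1\].
#' @param r_g genetic correlation between index and yield, in \[-1, 1\].
#' @return relative selection efficiency.
#' @examples
#' rse(0.22, 0.32, 0.24)  # ~0.20, a weak-flight worked example
#' @export
rse <- function(h2_vi, h2_fy, r_g) {
  if (any(h2_fy == 0)) {
    warning("h2_fy is zero: RSE undefined")
    return(rep(NA_real_, max(length(h2_vi), length(h2_fy), length(r_g))))
  }
  stopifnot(all(h2_vi > 0 & h2_vi <= 1), all(h2_fy > 0 & h2_fy <= 1),
            all(r_g >= -1 & r_g <= 1))
  sqrt(h2_vi / h2_fy) * r_g
}

#' GGE biplot of a genotype-by-environment yield matrix
#'
#' Environment-centers the matrix (`Y_ij - Ybar_j`), takes its singular
#' value decomposition, and forms the rank-2 genotype-focused biplot:
#' singular values are absorbed into the genotype scores
#' (`x'_ik = l_k x_ik`), environments keep unit-scaled scores.  The
#' average-environment axis (AEA) is the direction of the mean
#' environment score in the PC1-PC2 plane; projections on the AEA rank
#' mean performance and the signed perpendicular projection measures
#' instability.  Sign convention: PC1 is oriented so the mean environment
#' score is positive (the AEA arrow points toward higher mean yield);
#' PC2 so the first genotype's score is non-negative.
#'
#' @param ge complete genotype-by-environment matrix (genotypes in rows),
#'   e.g. from [simulate_ge_yield()] or built from per-harvest genotype
#'   means.
#' @return object of class `gge_biplot`: `genotype_scores`
#'   (`PC1`, `PC2`, `aea_mean`, `aea_stability` per genotype),
#'   `environment_scores`, `singular_values`, `explained_fraction`,
#'   `aea` unit vector, and the centered matrix.
#' @export
gge_biplot <- function(ge) {
  Y <- unclass(as.matrix(ge))
  if (anyNA(Y)) stop("genotype x environment matrix has missing cells")
  if (nrow(Y) < 3 || ncol(Y) < 2) {
    stop("need >= 3 genotypes and >= 2 environments")
  }
  if (is.null(rownames(Y))) rownames(Y) <- sprintf("G%02d", seq_len(nrow(Y)))
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("E%d", seq_len(ncol(Y)))
  Yc <- sweep(Y, 2, colMeans(Y))
  sv <- svd(Yc)
  l <- sv$d
  if (sum(l > max(l) * 1e-12) < 2) {
    warning("fewer than 2 positive singular values: ",
            "stability axis undefined")
  }
  U <- sv$u[, 1:2, drop = FALSE]
  V <- sv$v[, 1:2, drop = FALSE]
  # canonical signs: AEA toward higher mean, then first genotype PC2 >= 0
  if (mean(V[, 1]) < 0) { U[, 1] <- -U[, 1]; V[, 1] <- -V[, 1] }
  if (U[1, 2] < 0) { U[, 2] <- -U[, 2]; V[, 2] <- -V[, 2] }
  gsc <- sweep(U, 2, l[1:2], `*`)           # genotype-focused scaling
  aea <- colMeans(V)
  nr <- sqrt(sum(aea^2))
  aea <- if (nr > 0) aea / nr else c(1, 0)
  mean_proj <- drop(gsc %*% aea)
  stab_proj <- drop(gsc %*% c(-aea[2], aea[1]))
  structure(list(
    genotype_scores = data.frame(
      genotype = rownames(Y), PC1 = gsc[, 1], PC2 = gsc[, 2],
      aea_mean = mean_proj, aea_stability = stab_proj,
      stringsAsFactors = FALSE),
    environment_scores = data.frame(
      environment = colnames(Y), PC1 = V[, 1], PC2 = V[, 2],
      stringsAsFactors = FALSE),
    singular_values = l,
    explained_fraction = sum(l[1:2]^2) / sum(l^2),
    aea = aea, centered = Yc),
    class = "gge_biplot")
}

#' @export
print.gge_biplot <- function(x, ...) {
  cat(sprintf(
    "GGE biplot: %d genotypes x %d environments, PC1+PC2 explain %.1f%%\n",
    nrow(x$genotype_scores), nrow(x$environment_scores),
    100 * x$explained_fraction))
  invisible(x)
}

#' @export
plot.gge_biplot <- function(x, main = "GGE biplot (mean vs stability)",
                            ...) {
  g <- x$genotype_scores
  e <- x$environment_scores
  lim <- range(c(g$PC1, g$PC2, 0))
  plot(g$PC1, g$PC2, asp = 1, xlab = "PC1", ylab = "PC2", main = main,
       xlim = lim, ylim = lim, pch = 19, col = "grey30", ...)
  graphics::text(g$PC1, g$PC2, g$genotype, pos = 3, cex = 0.7)
  graphics::points(e$PC1, e$PC2, pch = 17, col = "steelblue")
  graphics::arrows(0, 0, max(abs(g$PC1)) * x$aea[1],
                   max(abs(g$PC1)) * x$aea[2],
                   col = "darkgreen", length = 0.1)
  graphics::abline(0, x$aea[2] / x$aea[1], col = "darkgreen", lty = 3)
  invisible(x)
}

#' Growth-curve stability across cuttings
#'
#' For each genotype, measures how consistent its estimated genetic
#' growth effects are from one cutting to the next.  At each selected
#' time point (standardized GDD), the genetic effects of all genotypes in
#' each cutting are standardized to zero mean and unit variance across
#' genotypes (so cutting-level shifts and raw index units cancel); each
#' genotype's deviations from its own cross-cutting mean then give a
#' per-genotype standard deviation.  The same standardization applied to
#' per-cutting yield BLUPs yields a comparable yield-stability SD.
#'
#' @param fits list of `rr_fit` objects, one per cutting, sharing a
#'   common genotype set (genotypes missing from any cutting are dropped
#'   with a message).
#' @param t_points standardized time points in \[-1, 1\]; default an
#'   evenly spaced 5-point grid.
#' @param yield_blups optional genotype-by-cutting matrix (or data frame)
#'   of yield BLUPs, e.g. collected from [fit_st_blup()] per cutting.
#' @return object of class `stability_profile`: `growth` (data frame
#'   `genotype`, `t_std`, `sd`), `growth_sd` (per-genotype mean SD over
#'   time points), and `yield_sd` (per-genotype, when yield BLUPs were
#'   given).
#' @export
growth_stability <- function(fits, t_points = NULL, yield_blups = NULL) {
  stopifnot(length(fits) >= 2)
  lapply(fits, function(f) stopifnot(inherits(f, "rr_fit")))
  if (is.null(t_points)) t_points <- seq(-0.9, 0.9, length.out = 5)
  genos <- Reduce(intersect, lapply(fits, function(f) f$genotypes))
  dropped <- setdiff(unique(unlist(lapply(fits, function(f) f$genotypes))),
                     genos)
  if (length(dropped)) {
    message("dropping genotype(s) missing from some cutting: ",
            paste(dropped, collapse = ", "))
  }
  if (length(genos) < 3) stop("need >= 3 genotypes common to all cuttings")

  C <- length(fits)
  # z[j, c, t]: standardized genetic effect of genotype j in cutting c
  z <- array(NA_real_, c(length(genos), C, length(t_points)))
  for (ci in seq_len(C)) {
    f <- fits[[ci]]
    Phi <- f$basis$evaluate(t_points, standardized = TRUE)
    g <- (f$u_hat[genos, , drop = FALSE] %*% t(Phi))
    z[, ci, ] <- scale(g)                   # per column: center, unit var
  }
  sds <- apply(z, c(1, 3), stats::sd)
  growth <- data.frame(
    genotype = rep(genos, times = length(t_points)),
    t_std = rep(t_points, each = length(genos)),
    sd = as.vector(sds), stringsAsFactors = FALSE)
  growth_sd <- stats::setNames(rowMeans(sds), genos)

  yield_sd <- NULL
  if (!is.null(yield_blups)) {
    Yb <- as.matrix(yield_blups)
    if (!all(genos %in% rownames(Yb))) {
      stop("yield_blups must cover all common genotypes")
    }
    Zy <- scale(Yb[genos, , drop = FALSE])
    yield_sd <- stats::setNames(apply(Zy, 1, stats::sd), genos)
  }
  structure(list(growth = growth, growth_sd = growth_sd,
                 yield_sd = yield_sd, t_points = t_points,
                 n_cuttings = C),
            class = "stability_profile")
}

#' @export
print.stability_profile <- function(x, ...) {
  cat(sprintf(
    "Growth-stability profile: %d genotypes, %d cuttings, %d time points\n",
    length(x$growth_sd), x$n_cuttings, length(x$t_points)))
  if (!is.null(x$yield_sd)) {
    cat(sprintf("  Spearman(growth SD, yield SD) = %.3f\n",
                stats::cor(x$growth_sd, x$yield_sd, method = "spearman")))
  }
  invisible(x)
}

#' Mean-versus-stability classification table
#'
#' Combines the biplot's average-environment-axis projections with the
#' growth-stability profile into a per-genotype table and classifies each
#' entry into the four mean-by-stability quadrants by median splits
#' (thresholds configurable).  Classification is invariant to environment
#' relabeling because it only uses the AEA projections.
#'
#' @param biplot a [gge_biplot()] result.
#' @param profile optional [growth_stability()] result with matching
#'   genotype labels.
#' @param mean_split,stability_split quantile thresholds for the
#'   high/low-yield and stable/unstable labels (defaults: medians).
#' @return data frame with per-genotype projections, growth/yield SDs
#'   when available, and `yield_class` / `stability_class` labels.
#' @export
mean_vs_stability_report <- function(biplot, profile = NULL,
                                     mean_split = 0.5,
                                     stability_split = 0.5) {
  stopifnot(inherits(biplot, "gge_biplot"))
  g <- biplot$genotype_scores
  out <- data.frame(genotype = g$genotype, aea_mean = g$aea_mean,
                    aea_stability = g$aea_stability,
                    stringsAsFactors = FALSE)
  out$yield_class <- ifelse(
    out$aea_mean >= stats::quantile(out$aea_mean, mean_split),
    "high-yielding", "low-yielding")
  thr <- stats::quantile(abs(out$aea_stability), stability_split)
  # a fully additive table has no interaction signal at all: everything
  # is stable, not split at an (all-zero) median
  out$stability_class <- if (all(abs(out$aea_stability) < 1e-10)) {
    "stable"
  } else ifelse(abs(out$aea_stability) <= thr, "stable", "unstable")
  if (!is.null(profile)) {
    stopifnot(inherits(profile, "stability_profile"))
    idx <- match(out$genotype, names(profile$growth_sd))
    out$growth_sd <- profile$growth_sd[idx]
    if (!is.null(profile$yield_sd)) {
      out$yield_sd <- profile$yield_sd[idx]
    }
  }
  out
}
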