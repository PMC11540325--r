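#' Trial design for synthetic forage experiments
#'
#' Describes a randomized complete block trial with repeated canopy
#' measurements: every genotype appears exactly once per replicate, each
#' harvest cycle carries its own grid of flight times on a cumulative
#' growing-degree-day axis.
#'
#' @param n_genotypes number of entries (>= 2).
#' @param n_replicates number of complete blocks (>= 2).
#' @param n_harvests number of harvest (cutting) cycles.
#' @param gdd_grid numeric vector of flight GDD values, or a list with one
#'   strictly increasing vector per harvest.
#' @param seed master seed; all simulation randomness derives from it.
#' @return object of class `trial_design`.
#' @export
trial_design <- function(n_genotypes, n_replicates, n_harvests = 1,
                         gdd_grid = seq(150, 600, length.out = 6),
                         seed = 1) {
  stopifnot(n_genotypes >= 2, n_replicates >= 2, n_harvests >= 1)
  if (!is.list(gdd_grid)) gdd_grid <- rep(list(gdd_grid), n_harvests)
  if (length(gdd_grid) != n_harvests) {
    stop("gdd_grid must have one vector per harvest")
  }
  for (g in gdd_grid) {
    if (length(g) < 2 || any(diff(g) <= 0)) {
      stop("gdd_grid must be strictly increasing within each harvest")
    }
  }
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_replicates = as.integer(n_replicates),
                 n_harvests = as.integer(n_harvests),
                 design = "RCBD", gdd_grid = gdd_grid,
                 seed = as.integer(seed)),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf(
    "RCBD trial: %d genotypes x %d replicates, %d harvest cycle(s), %s flights/harvest, seed %d\n",
    x$n_genotypes, x$n_replicates, x$n_harvests,
    paste(vapply(x$gdd_grid, length, 1L), collapse = "/"), x$seed))
  invisible(x)
}

check_psd <- function(K, name, tol = 1e-8) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) {
    stop(name, " must be a square matrix")
  }
  if (max(abs(K - t(K))) > tol * max(1, max(abs(K)))) {
    stop(name, " is not symmetric")
  }
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(ev))) {
    stop(sprintf("%s is not positive semidefinite (min eigenvalue %.3g)",
                 name, min(ev)))
  }
  invisible(K)
}

# symmetric PSD square root; tolerates zero and rank-deficient matrices
psd_sqrt <- function(K) {
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(K)) %*% t(e$vectors)
}

# per-component RNG streams derived from one master seed, so toggling one
# simulation component never changes the draws of another
spawn_streams <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 5L)
  names(s) <- c("genetic", "permenv", "residual", "fixed", "yield")
  s
}

default_mean_curve <- function(t_std) 0.2 + 0.6 / (1 + exp(-3 * t_std))

#' Simulate a multi-flight forage trial with known genetic structure
#'
#' Generates plot-level vegetation-index records
#' `VI(t, j, r) = beta_r(t) + phi(t)' u_j + phi(t)' p_jr + eps` on the
#' normalized Legendre basis over standardized time, for a randomized
#' complete block design.  Genotype coefficient vectors `u_j` are drawn
#' with covariance `K_g`, permanent-environment (plot) coefficients with
#' covariance `K_p`, residuals with variance `sigma2_e` (scalar, or one
#' value per flight for a time-heterogeneous residual).  Every drawn
#' effect is returned in `truth`, so downstream estimators can be checked
#' by parameter recovery.  Identical seeds give identical tables.
#'
#' When `genotype_instability` is non-zero, each genotype's coefficients
#' deviate independently around its mean vector from one harvest cycle to
#' the next, with per-genotype deviation scale `tau_j`; this is the
#' generating mechanism for growth-curve (in)stability across cuttings.
#'
#' @param design a [trial_design()].
#' @param K_g genetic coefficient covariance (symmetric PSD, order d).
#' @param K_p permanent-environment coefficient covariance (same order);
#'   default zero.
#' @param sigma2_e residual variance, scalar or per-flight vector.
#' @param beta fixed replicate-within-time effects: matrix
#'   (replicates x flights) or array (replicates x flights x harvests).
#'   Default: a saturating mean growth curve plus small replicate offsets.
#' @param mean_curve function of standardized time giving the default
#'   fixed trajectory (ignored when `beta` is supplied).
#' @param genotype_instability scalar or per-genotype SD multiplier for
#'   cross-harvest deviations of the genetic coefficients (default 0:
#'   genotypes keep the same curve in every cycle).
#' @param trait name of the generated index column (default `"vi"`).
#' @return list with `records` (long-format data frame: `plot`,
#'   `genotype`, `replicate`, `harvest`, `flight`, `gdd`, `is_yield`, and
#'   the trait column) and `truth` (all parameters and drawn effects,
#'   including the per-harvest basis).
#' @export
simulate_trial <- function(design, K_g, K_p = NULL, sigma2_e = 0.25,
                           beta = NULL, mean_curve = default_mean_curve,
                           genotype_instability = 0, trait = "vi") {
  stopifnot(inherits(design, "trial_design"))
  K_g <- as.matrix(K_g)
  d <- nrow(K_g)
  if (is.null(K_p)) K_p <- matrix(0, d, d)
  K_p <- as.matrix(K_p)
  check_psd(K_g, "K_g")
  check_psd(K_p, "K_p")
  if (nrow(K_p) != d) stop("K_g and K_p must have the same order")
  if (any(sigma2_e < 0)) stop("sigma2_e must be non-negative")

  m <- design$n_genotypes
  r <- design$n_replicates
  H <- design$n_harvests
  tau <- rep_len(genotype_instability, m)
  if (any(tau < 0)) stop("genotype_instability must be non-negative")

  geno <- sprintf("g%02d", seq_len(m))
  reps <- sprintf("r%d", seq_len(r))
  harv <- sprintf("h%d", seq_len(H))
  plots <- expand.grid(genotype = geno, replicate = reps,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  plots$plot <- paste(plots$genotype, plots$replicate, sep = "_")
  n_plots <- nrow(plots)

  streams <- spawn_streams(design$seed)
  Lg <- psd_sqrt(K_g)
  Lp <- psd_sqrt(K_p)

  # genetic stream: genotype mean coefficients, then per-harvest deviations
  set.seed(streams[["genetic"]])
  u_bar <- matrix(stats::rnorm(m * d), m, d) %*% Lg
  u <- vector("list", H)
  for (h in seq_len(H)) {
    dev <- matrix(stats::rnorm(m * d), m, d) %*% Lg
    u[[h]] <- u_bar + tau * dev
    rownames(u[[h]]) <- geno
  }

  set.seed(streams[["permenv"]])
  p <- vector("list", H)
  for (h in seq_len(H)) {
    p[[h]] <- matrix(stats::rnorm(n_plots * d), n_plots, d) %*% Lp
    rownames(p[[h]]) <- plots$plot
  }

  n_flights <- vapply(design$gdd_grid, length, 1L)
  basis <- lapply(design$gdd_grid, legendre_basis, order = d - 1)

  set.seed(streams[["fixed"]])
  if (is.null(beta)) {
    beta <- array(0, c(r, max(n_flights), H))
    for (h in seq_len(H)) {
      t_std <- basis[[h]]$standardize(design$gdd_grid[[h]])
      rep_off <- stats::rnorm(r, 0, 0.02)
      beta[, seq_len(n_flights[h]), h] <-
        outer(rep_off, mean_curve(t_std), `+`)
    }
  } else {
    if (is.matrix(beta)) beta <- array(beta, c(dim(beta), H))
    stopifnot(dim(beta)[1] == r, dim(beta)[2] >= max(n_flights))
  }

  set.seed(streams[["residual"]])
  recs <- vector("list", H)
  for (h in seq_len(H)) {
    gg <- design$gdd_grid[[h]]
    nf <- n_flights[h]
    Phi <- basis[[h]]$evaluate(gg)
    s2 <- rep_len(sigma2_e, nf)
    # one row per plot x flight, flights varying fastest
    idx_plot <- rep(seq_len(n_plots), each = nf)
    idx_fl <- rep(seq_len(nf), times = n_plots)
    gmat <- (u[[h]] %*% t(Phi))[match(plots$genotype, geno), , drop = FALSE]
    pmat <- p[[h]] %*% t(Phi)
    eps <- stats::rnorm(n_plots * nf, 0, sqrt(s2)[idx_fl])
    value <- beta[cbind(match(plots$replicate[idx_plot], reps), idx_fl, h)] +
      gmat[cbind(idx_plot, idx_fl)] + pmat[cbind(idx_plot, idx_fl)] + eps
    recs[[h]] <- data.frame(
      plot = plots$plot[idx_plot],
      genotype = plots$genotype[idx_plot],
      replicate = plots$replicate[idx_plot],
      harvest = harv[h],
      flight = sprintf("f%02d", idx_fl),
      gdd = gg[idx_fl],
      is_yield = FALSE,
      value = value,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  names(records)[names(records) == "value"] <- trait

  truth <- list(design = design, trait = trait, K_g = K_g, K_p = K_p,
                sigma2_e = sigma2_e, beta = beta, u_bar = u_bar, u = u,
                p = p, basis = basis, genotype_instability = tau,
                streams = streams)
  list(records = records, truth = truth)
}

#' Append terminal yield records generated from the genetic growth curves
#'
#' Yield for each plot is the genotype's fitted curve value at the harvest
#' GDD plus independent noise, so the true genetic correlation between the
#' index at any time and yield is available in closed form from `K_g` and
#' the basis.  Yield rows are appended to the record table with
#' `is_yield = TRUE` at `gdd = harvest_gdd`.
#'
#' @param trial result of [simulate_trial()].
#' @param harvest_gdd harvest-date GDD, scalar or per-harvest vector; must
#'   not precede the last flight of the corresponding cycle.
#' @param mu_yield baseline yield level added to every plot.
#' @param sigma2_yield residual variance of the yield record; default is
#'   the genetic variance of the curve at `harvest_gdd` (plot-level
#'   heritability 0.5).  Use 0 for noise-free yield.
#' @return the trial with `records` extended and yield parameters recorded
#'   in `truth`.
#' @export
simulate_yield_from_curve <- function(trial, harvest_gdd, mu_yield = 3,
                                      sigma2_yield = NULL) {
  truth <- trial$truth
  design <- truth$design
  H <- design$n_harvests
  harvest_gdd <- rep_len(harvest_gdd, H)
  last_flight <- vapply(design$gdd_grid, max, 1.0)
  if (any(harvest_gdd < last_flight)) {
    stop("harvest_gdd earlier than the last flight of cycle(s) ",
         paste(which(harvest_gdd < last_flight), collapse = ", "))
  }
  plots <- unique(trial$records[trial$records$harvest == "h1" &
                                  !trial$records$is_yield,
                                c("plot", "genotype", "replicate")])
  set.seed(truth$streams[["yield"]])
  out <- vector("list", H)
  s2y <- numeric(H)
  for (h in seq_len(H)) {
    # suppress the extrapolation warning: the harvest point deliberately
    # sits at or beyond the last flight of the standardized flight domain
    Phi_T <- suppressWarnings(truth$basis[[h]]$evaluate(harvest_gdd[h]))
    gvals <- drop(truth$u[[h]] %*% t(Phi_T))
    s2y[h] <- if (is.null(sigma2_yield)) {
      drop(Phi_T %*% truth$K_g %*% t(Phi_T))
    } else rep_len(sigma2_yield, H)[h]
    yld <- mu_yield + gvals[match(plots$genotype, rownames(truth$u[[h]]))] +
      stats::rnorm(nrow(plots), 0, sqrt(s2y[h]))
    out[[h]] <- data.frame(
      plot = plots$plot, genotype = plots$genotype,
      replicate = plots$replicate, harvest = sprintf("h%d", h),
      flight = "yield", gdd = harvest_gdd[h], is_yield = TRUE,
      value = yld, stringsAsFactors = FALSE)
    names(out[[h]])[names(out[[h]]) == "value"] <- truth$trait
  }
  trial$records <- rbind(trial$records, do.call(rbind, out))
  trial$truth$harvest_gdd <- harvest_gdd
  trial$truth$mu_yield <- mu_yield
  trial$truth$sigma2_yield <- s2y
  trial
}

#' Simulate a genotype-by-environment mean-yield matrix
#'
#' Additive genotype and environment effects plus a genotype-specific
#' interaction: `Y_ij = mu + g_i + e_j + eta_ij` with
#' `eta_ij ~ N(0, tau_i^2)`.  Genotypes with larger `tau` are less stable
#' across environments.  All generating effects are recorded.
#'
#' @param n_genotypes,n_envs table dimensions (`n_envs >= 2`).
#' @param stability_profile per-genotype interaction SD `tau_i` (scalar
#'   recycled); must be non-negative.
#' @param seed RNG seed.
#' @param mu,sd_g,sd_e overall mean and SDs of the additive genotype and
#'   environment effects.
#' @return list with `ge` (matrix of class `ge_matrix`, genotypes in rows)
#'   and `truth`.
#' @export
simulate_ge_yield <- function(n_genotypes, n_envs, stability_profile = 0,
                              seed = 1, mu = 5, sd_g = 1, sd_e = 1) {
  stopifnot(n_genotypes >= 2, n_envs >= 2)
  tau <- rep_len(stability_profile, n_genotypes)
  if (any(tau < 0)) stop("stability_profile SDs must be non-negative")
  set.seed(seed)
  g <- stats::rnorm(n_genotypes, 0, sd_g)
  e <- stats::rnorm(n_envs, 0, sd_e)
  eta <- matrix(stats::rnorm(n_genotypes * n_envs), n_genotypes, n_envs) * tau
  Y <- mu + outer(g, rep(0, n_envs), `+`) +
    outer(rep(0, n_genotypes), e, `+`) + eta
  dimnames(Y) <- list(sprintf("G%02d", seq_len(n_genotypes)),
                      sprintf("E%d", seq_len(n_envs)))
  class(Y) <- c("ge_matrix", "matrix")
  list(ge = Y,
       truth = list(mu = mu, g = g, e = e, eta = eta, tau = tau,
                    seed = seed))
}

#' Write a simulated trial to disk
#'
#' The record table goes to `records.csv`; ground-truth scalars to
#' `truth.yaml`; coefficient covariances and drawn effects to CSV
#' sidecars.
#'
#' @param trial result of [simulate_trial()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trial$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  tr <- trial$truth
  yaml::write_yaml(list(
    trait = tr$trait, sigma2_e = tr$sigma2_e, seed = tr$design$seed,
    n_genotypes = tr$design$n_genotypes,
    n_replicates = tr$design$n_replicates,
    n_harvests = tr$design$n_harvests,
    gdd_grid = lapply(tr$design$gdd_grid, as.numeric),
    genotype_instability = as.numeric(tr$genotype_instability)),
    file.path(dir, "truth.yaml"))
  utils::write.csv(tr$K_g, file.path(dir, "K_g.csv"), row.names = FALSE)
  utils::write.csv(tr$K_p, file.path(dir, "K_p.csv"), row.names = FALSE)
  for (h in seq_along(tr$u)) {
    utils::write.csv(tr$u[[h]], file.path(dir, sprintf("u_h%d.csv", h)))
    utils::write.csv(tr$p[[h]], file.path(dir, sprintf("p_h%d.csv", h)))
  }
  invisible(dir)
}
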