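#' Validate a long-format plot table
#'
#' Checks the canonical interchange schema (one row per plot x flight):
#' required columns `plot`, `genotype`, `replicate`, `harvest`, `gdd`
#' plus at least one trait column; duplicated plot x flight rows are an
#' error; a genotype missing from a replicate within a harvest is a
#' warning only (augmented designs with unreplicated entries are
#' tolerated); flights whose GDD is off the harvest's common grid are
#' reported.
#'
#' @param x data frame or path to a CSV file.
#' @param traits trait columns expected; default: any numeric column not
#'   part of the design.
#' @return invisibly, a list with the validated `data` and a `report`
#'   data frame of findings (`severity`, `message`); errors abort.
#' @export
validate_plot_table <- function(x, traits = NULL) {
  data <- if (is.character(x)) utils::read.csv(x) else as.data.frame(x)
  need <- c("plot", "genotype", "replicate", "harvest", "gdd")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("plot table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"is_yield" %in% names(data)) data$is_yield <- FALSE
  if (is.null(traits)) {
    traits <- setdiff(names(data)[vapply(data, is.numeric, TRUE)], "gdd")
  }
  if (!length(traits)) stop("no trait columns found")

  report <- list()
  note <- function(severity, message) {
    report[[length(report) + 1L]] <<- data.frame(
      severity = severity, message = message, stringsAsFactors = FALSE)
  }

  key <- data[, c("plot", "harvest", "gdd", "is_yield")]
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicated plot x flight rows: ",
         paste(utils::head(
           paste(data$plot[dup], data$harvest[dup], data$gdd[dup],
                 sep = "/"), 5), collapse = ", "))
  }

  for (h in unique(data$harvest)) {
    dh <- data[data$harvest == h & !data$is_yield, ]
    tab <- table(dh$genotype, dh$replicate) > 0
    if (any(!tab)) {
      miss <- which(!tab, arr.ind = TRUE)
      msg <- sprintf(
        "harvest %s: genotype(s) %s missing from replicate(s) %s (augmented-design tolerance)",
        h, paste(unique(rownames(tab)[miss[, 1]]), collapse = ","),
        paste(unique(colnames(tab)[miss[, 2]]), collapse = ","))
      warning(msg, call. = FALSE)
      note("warning", msg)
    }
    grid <- sort(unique(dh$gdd))
    per_plot <- tapply(dh$gdd, dh$plot, function(g) all(g %in% grid))
    off <- names(per_plot)[!per_plot]
    if (length(off)) {
      note("warning", sprintf("harvest %s: off-grid GDD for plots %s", h,
                              paste(off, collapse = ",")))
    }
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(severity = character(0), message = character(0))
  invisible(list(data = data, traits = traits, report = report))
}

#' Default pipeline configuration
#'
#' @param output_dir artifact directory.
#' @param input optional path to a plot-table CSV; when `NULL` a
#'   synthetic trial is generated with the design fields below.
#' @param traits trait columns to analyze.
#' @param order Legendre degree for the random-regression stage.
#' @param residual residual structure for [fit_rr()].
#' @param seed master seed (recorded in every output header).
#' @param n_genotypes,n_replicates,n_harvests,gdd_grid,harvest_gdd
#'   synthetic-trial design (used only when `input` is `NULL`).
#' @param genotype_instability per-genotype cross-cutting deviation scale
#'   for the synthetic trial.
#' @param stability_t_points standardized time grid for
#'   [growth_stability()].
#' @param max_iter iteration cap passed to the fitting stages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, input = NULL, traits = "vi",
                            order = 3, residual = "homogeneous",
                            seed = 1, n_genotypes = 24, n_replicates = 4,
                            n_harvests = 3,
                            gdd_grid = seq(150, 600, length.out = 6),
                            harvest_gdd = 650,
                            genotype_instability = NULL,
                            stability_t_points = seq(-0.9, 0.9,
                                                     length.out = 5),
                            max_iter = 300) {
  cfg <- as.list(environment())
  if (!is.null(input) && !file.exists(input)) {
    stop("input file does not exist: ", input)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

config_hash <- function(cfg) {
  # stable content hash without external dependencies: sum over the
  # serialized bytes, folded with a small prime multiplier
  raw <- serialize(cfg[order(names(cfg))], NULL, version = 2)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline on a (possibly synthetic) trial
#'
#' Chains simulation (when no input table is given), validation,
#' per-flight single-trait heritability, phenotypic correlation with
#' yield, random-regression fits per harvest with derived heritability
#' and genetic-correlation curves and growth curves, per-harvest relative
#' selection efficiency, the GGE biplot of the genotype-by-harvest yield
#' matrix, and the growth-stability profile.  Every stage writes tidy
#' CSV; a JSON manifest records the seed, configuration hash and stage
#' status.  A failed stage is recorded in the manifest and the remaining
#' stages still run.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  manifest <- list(package = "forageRR",
                   version = as.character(utils::packageVersion("forageRR")),
                   seed = config$seed, config_hash = hash,
                   stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(list(value = expr, ok = TRUE),
                    error = function(e) list(value = conditionMessage(e),
                                             ok = FALSE))
    manifest$stages[[name]] <<- if (res$ok) "ok" else
      paste("failed:", res$value)
    if (res$ok) res$value else NULL
  }
  emit <- function(df, file) {
    path <- file.path(config$output_dir, file)
    con <- file(path, "w")
    writeLines(sprintf("# forageRR seed=%d config=%s", config$seed, hash),
               con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    path
  }

  # --- input ---------------------------------------------------------
  if (is.null(config$input)) {
    trial <- stage("simulate", {
      des <- trial_design(config$n_genotypes, config$n_replicates,
                          config$n_harvests, config$gdd_grid,
                          seed = config$seed)
      tau <- if (is.null(config$genotype_instability)) {
        seq(0, 1, length.out = config$n_genotypes)
      } else config$genotype_instability
      kdiag <- c(1, 0.5, 0.2, 0.1, rep(0.05, max(0, config$order - 3)))
      tr <- simulate_trial(des,
                           K_g = diag(kdiag[seq_len(config$order + 1)],
                                      config$order + 1),
                           K_p = 0.1 * diag(config$order + 1),
                           sigma2_e = 0.25,
                           genotype_instability = tau,
                           trait = config$traits[1])
      simulate_yield_from_curve(tr, config$harvest_gdd)
    })
    records <- trial$records
  } else {
    records <- utils::read.csv(config$input)
  }
  checked <- stage("validate", validate_plot_table(records,
                                                   config$traits))
  if (is.null(checked)) stop("plot table failed validation")
  records <- checked$data
  harvests <- sort(unique(records$harvest))
  trait <- config$traits[1]

  # surface identifiability problems before any fitting starts
  for (h in harvests) {
    nt <- length(unique(records$gdd[records$harvest == h]))
    if (nt <= config$order + 1) {
      stop(sprintf(paste0("harvest %s has only %d distinct time points; ",
                          "basis degree %d needs more than %d ",
                          "(identifiability)"),
                   h, nt, config$order, config$order + 1))
    }
  }

  # --- per-flight heritability --------------------------------------
  h2_tab <- stage("heritability", {
    out <- list()
    for (h in harvests) {
      dh <- records[records$harvest == h & !records$is_yield, ]
      for (g in sort(unique(dh$gdd))) {
        f <- fit_st_blup(dh[dh$gdd == g, ], trait)
        out[[length(out) + 1L]] <- data.frame(
          harvest = h, gdd = g, trait = trait, sigma2_g = f$sigma2_g,
          sigma2_e = f$sigma2_e, H2 = heritability(f),
          converged = f$converged)
      }
      dy <- records[records$harvest == h & records$is_yield, ]
      if (nrow(dy)) {
        f <- fit_st_blup(dy, trait)
        out[[length(out) + 1L]] <- data.frame(
          harvest = h, gdd = dy$gdd[1], trait = "yield",
          sigma2_g = f$sigma2_g, sigma2_e = f$sigma2_e,
          H2 = heritability(f), converged = f$converged)
      }
    }
    do.call(rbind, out)
  })
  if (!is.null(h2_tab)) emit(h2_tab, "heritability.csv")

  # --- phenotypic correlation ---------------------------------------
  pc <- stage("phenotypic_correlation",
              phenotypic_correlation(records, trait))
  if (!is.null(pc)) emit(pc, "phenotypic_correlation.csv")

  # --- bivariate genetic correlation at the last flight -------------
  gc_tab <- stage("bivariate", {
    out <- list()
    for (h in harvests) {
      dh <- records[records$harvest == h, ]
      vi <- dh[!dh$is_yield & dh$gdd == max(dh$gdd[!dh$is_yield]), ]
      yl <- dh[dh$is_yield, c("plot", trait)]
      names(yl)[2] <- "yield"
      mm <- merge(vi, yl, by = "plot")
      f <- fit_bivariate(mm, c(trait, "yield"))
      out[[length(out) + 1L]] <- data.frame(
        harvest = h, r_g = f$r_g, r_e = f$r_e, H2_vi = f$H2[1],
        H2_fy = f$H2[2], converged = f$converged)
    }
    do.call(rbind, out)
  })
  if (!is.null(gc_tab)) emit(gc_tab, "genetic_correlation.csv")

  # --- RSE per harvest ----------------------------------------------
  if (!is.null(gc_tab)) {
    rse_tab <- stage("rse", {
      ok <- gc_tab$H2_vi > 0 & gc_tab$H2_fy > 0
      data.frame(harvest = gc_tab$harvest[ok],
                 rse = rse(gc_tab$H2_vi[ok], gc_tab$H2_fy[ok],
                           gc_tab$r_g[ok]))
    })
    if (!is.null(rse_tab)) emit(rse_tab, "rse.csv")
  }

  # --- random regression per harvest --------------------------------
  fits <- stage("random_regression", {
    fl <- list()
    for (h in harvests) {
      fl[[h]] <- fit_rr(records, trait, order = config$order,
                        include_yield = any(records$is_yield),
                        residual = config$residual, harvest = h,
                        max_iter = config$max_iter)
    }
    fl
  })
  if (!is.null(fits)) {
    for (h in names(fits)) {
      emit(as.data.frame(fits[[h]]$K_g), sprintf("K_g_%s.csv", h))
      emit(as.data.frame(fits[[h]]$K_p), sprintf("K_p_%s.csv", h))
      emit(genetic_correlation_curve(fits[[h]]),
           sprintf("genetic_correlation_curve_%s.csv", h))
      emit(growth_curves(fits[[h]]), sprintf("growth_curves_%s.csv", h))
      emit(heritability_curve(fits[[h]]),
           sprintf("heritability_curve_%s.csv", h))
    }
  }

  # --- GGE + stability ----------------------------------------------
  ge_and_blups <- stage("ge_matrix", {
    yl <- records[records$is_yield, ]
    if (!nrow(yl)) stop("no yield records for GGE analysis")
    ge <- tapply(yl[[trait]], list(yl$genotype, yl$harvest), mean)
    blups <- sapply(harvests, function(h) {
      f <- fit_st_blup(yl[yl$harvest == h, ], trait)
      f$blups
    })
    list(ge = ge, blups = blups)
  })
  if (!is.null(ge_and_blups)) {
    bp <- stage("gge", gge_biplot(ge_and_blups$ge))
    prof <- if (!is.null(fits) && length(fits) >= 2) {
      stage("stability",
            growth_stability(fits, config$stability_t_points,
                             yield_blups = ge_and_blups$blups))
    } else NULL
    if (!is.null(bp)) {
      emit(bp$genotype_scores, "gge_genotype_scores.csv")
      emit(bp$environment_scores, "gge_environment_scores.csv")
      emit(mean_vs_stability_report(bp, prof), "mean_vs_stability.csv")
    }
    if (!is.null(prof)) emit(prof$growth, "growth_stability.csv")
  }

  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
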