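#' Configure an end-to-end pipeline run
#'
#' @param tree A `phylo` object, Newick string or file path; ignored when
#'   `synthetic` is supplied.
#' @param traits Individual-level trait data frame (or delimited-file path);
#'   ignored when `synthetic` is supplied.
#' @param synthetic Optional [simulation_config()]: generate the study instead
#'   of reading it.
#' @param tip_substitutions Optional named character vector of congener
#'   relabellings applied to the tree before analysis.
#' @param stages Character vector of stages to run, in pipeline order. Any of
#'   `"summarize"`, `"allometry"`, `"signal"`, `"repeatability"`,
#'   `"residuals"`, `"outliers"`, `"regimes"`, `"macroevol"`, `"rjmcmc"`,
#'   `"paths"`.
#' @param min_n Minimum individuals per species (species below are dropped; 0
#'   disables the filter).
#' @param rjmcmc Settings list for the shift sampler
#'   (`iterations`, `thin`, `burn_in`, `chains`, `flavours`).
#' @param n_maps Stochastic maps for the regimes stage.
#' @param path_models Optional named list of [causal_dag()]s for the path
#'   stage (stage skipped when `NULL`).
#' @param pp_threshold Shift-reporting threshold.
#' @param seed Global seed; all stage seeds derive from it.
#' @return A `run_config` list.
#' @export
run_config <- function(tree = NULL, traits = NULL, synthetic = NULL,
                       tip_substitutions = NULL,
                       stages = c("summarize", "allometry", "signal",
                                  "repeatability", "residuals", "outliers",
                                  "regimes", "macroevol", "rjmcmc"),
                       min_n = 0,
                       rjmcmc = list(iterations = 20000, thin = 20,
                                     burn_in = 0.3, chains = 2,
                                     flavours = c("trait", "mass_independent",
                                                  "allometry")),
                       n_maps = 701, path_models = NULL, pp_threshold = 0.2,
                       seed = 1L) {
  if (is.null(synthetic) && (is.null(tree) || is.null(traits))) {
    abort("supply either `synthetic` or both `tree` and `traits`")
  }
  known <- c("summarize", "allometry", "signal", "repeatability", "residuals",
             "outliers", "regimes", "macroevol", "rjmcmc", "paths")
  bad <- setdiff(stages, known)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  if ("paths" %in% stages && is.null(path_models)) {
    abort("the paths stage needs `path_models`")
  }
  structure(list(tree = tree, traits = traits, synthetic = synthetic,
                 tip_substitutions = tip_substitutions, stages = stages,
                 min_n = min_n, rjmcmc = rjmcmc, n_maps = n_maps,
                 path_models = path_models, pp_threshold = pp_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

read_trait_table <- function(x) {
  if (is.data.frame(x)) return(tibble::as_tibble(x))
  utils::read.delim(x, sep = "\t", stringsAsFactors = FALSE) |> tibble::as_tibble()
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full comparative pipeline
#'
#' Executes the study's stage sequence on real or synthetic inputs:
#' species summaries; OLS, profile-lambda PGLS (linear, curvilinear, ANCOVA by
#' suborder and behaviour) and measurement-error PGLS; phylogenetic signal,
#' repeatability and attenuation correction; mass-independent residuals;
#' family outlier scan; Mk fitting with stochastic character maps; the BM/OU
#' maximum-likelihood model table; reversible-jump shift detection on SMR,
#' mass-independent SMR and the allometry; and (optionally) phylogenetic path
#' analysis. Every stochastic stage derives its seed deterministically from
#' the global seed, so reruns with the same config reproduce the report.
#'
#' @param config A [run_config()].
#' @return A `run_report` list of per-stage outputs with provenance.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stages <- config$stages
  report <- list(provenance = list(
    seed = config$seed, config_hash = rlang::hash(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    package_version = as.character(utils::packageVersion("allomacro"))
  ))
  if (!is.null(config$synthetic)) {
    sim <- run_stage("simulate", simulate_allometry_study(config$synthetic))
    tree <- sim$tree
    traits <- sim$data
    report$synthetic_truth <- sim$truth
  } else {
    tree <- if (inherits(config$tree, "phylo")) validate_tree(config$tree) else
      read_newick(config$tree)
    traits <- read_trait_table(config$traits)
  }
  if (!is.null(config$tip_substitutions)) {
    tree <- substitute_tips(tree, config$tip_substitutions)
  }
  if (config$min_n > 0) {
    keep <- names(which(table(traits$species) >= config$min_n))
    traits <- traits[traits$species %in% keep, ]
  }
  report$tree <- list(n_tips = ape::Ntip(tree), height = tree_height(tree),
                      ultrametric = attr(tree, "is_ultrametric"))

  need_summary <- function() {
    if (is.null(report$summary)) {
      abort("this stage needs the 'summarize' stage enabled before it")
    }
    report$summary
  }

  if ("summarize" %in% stages) {
    report$summary <- run_stage("summarize", summarize_species(traits))
  }
  if ("allometry" %in% stages) {
    s <- need_summary()
    report$allometry <- run_stage("allometry", {
      fits <- list(
        ols = fit_ols(s),
        pgls = fit_pgls(s, tree),
        pgls_quadratic = fit_pgls(s, tree, quadratic = TRUE),
        pgls_ives = fit_pgls_ives(s, tree, nboot = 200,
                                  seed = derive_seed(config$seed, 11))
      )
      # an ANCOVA group needs several species for its contrasts to mean much
      groupable <- function(col) {
        col %in% names(s) && length(unique(s[[col]])) > 1 &&
          min(table(s[[col]])) >= 3
      }
      if (groupable("suborder")) {
        fits$ancova_suborder <- fit_pgls(s, tree, grouping = "suborder")
      }
      if (groupable("behaviour")) {
        fits$ancova_behaviour <- fit_pgls(s, tree, grouping = "behaviour")
      }
      fits$table <- dplyr::bind_rows(lapply(fits, glance), .id = NULL)
      fits$table$fit <- names(fits)[seq_len(nrow(fits$table))]
      fits
    })
  }
  if ("residuals" %in% stages) {
    s <- need_summary()
    report$residuals <- run_stage("residuals", mass_independent_residuals(s, tree))
  }
  if ("signal" %in% stages) {
    s <- need_summary()
    report$signal <- run_stage("signal", {
      out <- list(smr = pagel_lambda_signal(s, mean_y, tree))
      if (!is.null(report$residuals)) {
        out$mass_independent <- pagel_lambda_signal(report$residuals, residual, tree)
      }
      out
    })
  }
  if ("repeatability" %in% stages) {
    report$repeatability <- run_stage("repeatability", {
      logit <- "body_mass_g" %in% names(traits)
      mass <- if (logit) repeatability_icc(traits, body_mass_g, species, TRUE) else
        repeatability_icc(traits, log_mass, species, FALSE)
      smr <- if (logit) repeatability_icc(traits, smr, species, TRUE) else
        repeatability_icc(traits, log_smr, species, FALSE)
      res <- dplyr::bind_rows(mass = mass, smr = smr, .id = "trait")
      if (!is.null(report$allometry)) {
        slope <- report$allometry$pgls_ives$coefficients$estimate[2]
        res_att <- attenuation_correct(slope, mass$R)
        attr(res, "corrected_slope") <- res_att
      }
      res
    })
  }
  if ("outliers" %in% stages) {
    s <- need_summary()
    if (!"family" %in% names(s)) abort("outlier scan needs a family column")
    report$outliers <- run_stage("outliers", family_outlier_scan(s, tree))
  }
  if ("regimes" %in% stages) {
    report$regimes <- run_stage("regimes", {
      if (!"behaviour" %in% names(traits)) abort("regimes stage needs a behaviour column")
      tips <- tapply(traits$behaviour, traits$species, function(v) v[1])
      tips <- setNames(as.character(tips), names(tips))
      ms <- fit_mk_models(tree, tips)
      maps <- stochastic_map(tree, tips, ms, n_maps = config$n_maps,
                             seed = derive_seed(config$seed, 21))
      anc <- marginal_ancestral(tree, tips, ms)
      list(models = ms, maps = maps, ancestral = anc)
    })
  }
  if ("macroevol" %in% stages) {
    s <- need_summary()
    report$macroevol <- run_stage("macroevol", {
      y <- setNames(s$mean_y, s$species)
      fits <- list(BM = fit_bm(y, tree), OU1 = fit_ou(y, tree, root = "fixed"))
      if (!is.null(report$regimes)) {
        pb <- report$regimes$maps$summary_painting
        fits$mrBM_behaviour <- fit_bm(y, tree, painting = pb)
        fits$moOU_behaviour <- fit_ou(y, tree, painting = pb, root = "fixed")
      }
      if ("suborder" %in% names(s) && length(unique(s$suborder)) > 1) {
        ps <- painting_from_tip_states(tree, setNames(s$suborder, s$species))
        fits$mrBM_suborder <- fit_bm(y, tree, painting = ps)
        fits$moOU_suborder <- fit_ou(y, tree, painting = ps, root = "fixed")
      }
      list(fits = fits, table = compare_models(fits))
    })
  }
  if ("rjmcmc" %in% stages) {
    s <- need_summary()
    rj <- config$rjmcmc
    report$rjmcmc <- run_stage("rjmcmc", {
      out <- list()
      y <- setNames(s$mean_y, s$species)
      x <- setNames(s$mean_x, s$species)
      if ("trait" %in% rj$flavours) {
        out$smr <- run_rjmcmc_trait(y, tree, iterations = rj$iterations,
                                    thin = rj$thin, burn_in = rj$burn_in,
                                    chains = rj$chains,
                                    seed = derive_seed(config$seed, 31))
      }
      if ("mass_independent" %in% rj$flavours) {
        resid <- mass_independent_residuals(s, tree)
        out$mass_independent <- run_rjmcmc_trait(
          setNames(resid$residual, resid$species), tree,
          iterations = rj$iterations, thin = rj$thin, burn_in = rj$burn_in,
          chains = rj$chains, seed = derive_seed(config$seed, 32))
      }
      if ("allometry" %in% rj$flavours) {
        out$allometry <- run_rjmcmc_allometry(
          y, x, tree, iterations = rj$iterations, thin = rj$thin,
          burn_in = rj$burn_in, chains = rj$chains,
          seed = derive_seed(config$seed, 33))
      }
      out
    })
  }
  if ("paths" %in% stages) {
    s <- need_summary()
    report$paths <- run_stage("paths", {
      df <- tibble::as_tibble(s)
      rank_and_average(config$path_models, df, tree)
    })
  }
  report$config <- config
  structure(report, class = "run_report")
}

#' Write a machine-readable report bundle
#'
#' Serialises the headline numbers of a [run_pipeline()] report to JSON, the
#' main tables to TSV, and optionally a plain-text summary.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @param format Any of `"json"`, `"tsv"`, `"txt"`.
#' @return Invisibly, the paths written.
#' @export
generate_report <- function(report, dir, format = c("json", "tsv", "txt")) {
  stopifnot(inherits(report, "run_report"))
  bad <- setdiff(format, c("json", "tsv", "txt"))
  if (length(bad)) abort(paste0("unknown format(s): ", paste(bad, collapse = ", ")))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  head <- report_headline(report)
  if ("json" %in% format) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(head, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, p)
  }
  if ("tsv" %in% format) {
    tabs <- list()
    if (!is.null(report$allometry)) tabs$allometry_fits <- report$allometry$table
    if (!is.null(report$macroevol)) tabs$macroevol_models <- report$macroevol$table
    if (!is.null(report$rjmcmc$smr)) tabs$rjmcmc_smr_branches <- report$rjmcmc$smr$branch
    if (!is.null(report$summary)) tabs$species_summary <- report$summary
    if (!is.null(report$paths)) tabs$path_models <- report$paths$table
    for (nm in names(tabs)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(as.data.frame(tabs[[nm]]), p, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
  }
  if ("txt" %in% format) {
    p <- file.path(dir, "summary.txt")
    lines <- c(
      sprintf("seed: %d  config: %s", report$provenance$seed,
              report$provenance$config_hash),
      sprintf("tree: %d tips, height %.1f MY", report$tree$n_tips,
              report$tree$height)
    )
    if (!is.null(head$pgls_ives_slope)) {
      lines <- c(lines, sprintf(
        "allometric slope (measurement-error PGLS): %.3f [%.3f, %.3f]",
        head$pgls_ives_slope, head$pgls_ives_ci_low %||% NA,
        head$pgls_ives_ci_high %||% NA))
    }
    if (!is.null(head$lambda_smr)) {
      lines <- c(lines, sprintf("phylogenetic signal lambda(SMR): %.3f",
                                head$lambda_smr))
    }
    if (!is.null(head$rjmcmc_k_median)) {
      lines <- c(lines, sprintf("rjMCMC shifts: k median %.1f (HPD %d-%d)",
                                head$rjmcmc_k_median, head$rjmcmc_k_hpd_low,
                                head$rjmcmc_k_hpd_high))
    }
    if (!is.null(head$ou_half_life)) {
      lines <- c(lines, sprintf("OU phylogenetic half-life: %.1f MY",
                                head$ou_half_life))
    }
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

report_headline <- function(report) {
  out <- list(seed = report$provenance$seed,
              config_hash = report$provenance$config_hash,
              n_tips = report$tree$n_tips, tree_height = report$tree$height)
  if (!is.null(report$allometry)) {
    cf <- report$allometry$pgls_ives$coefficients
    out$ols_slope <- report$allometry$ols$coefficients$estimate[2]
    out$pgls_slope <- report$allometry$pgls$coefficients$estimate[2]
    out$pgls_lambda <- report$allometry$pgls$lambda
    out$pgls_ives_slope <- cf$estimate[2]
    out$pgls_ives_ci_low <- cf$conf_low[2]
    out$pgls_ives_ci_high <- cf$conf_high[2]
  }
  if (!is.null(report$signal)) {
    out$lambda_smr <- report$signal$smr$lambda
    if (!is.null(report$signal$mass_independent)) {
      out$lambda_mass_independent <- report$signal$mass_independent$lambda
    }
  }
  if (!is.null(report$repeatability)) {
    out$repeatability_mass <- report$repeatability$R[report$repeatability$trait == "mass"]
    out$repeatability_smr <- report$repeatability$R[report$repeatability$trait == "smr"]
    cs <- attr(report$repeatability, "corrected_slope")
    if (!is.null(cs)) out$corrected_slope <- cs
  }
  if (!is.null(report$macroevol)) {
    best <- report$macroevol$table$model[1]
    out$best_macroevol_model <- best
    f <- report$macroevol$fits[[best]]
    if (inherits(f, "ou_fit")) out$ou_half_life <- f$half_life
  }
  if (!is.null(report$rjmcmc$smr)) {
    out$rjmcmc_k_median <- report$rjmcmc$smr$k_median
    out$rjmcmc_k_hpd_low <- report$rjmcmc$smr$k_hpd[1]
    out$rjmcmc_k_hpd_high <- report$rjmcmc$smr$k_hpd[2]
  }
  if (!is.null(report$paths)) {
    out$path_best_model <- report$paths$table$model[1]
    out$path_n_supported <- length(report$paths$supported)
  }
  out
}
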