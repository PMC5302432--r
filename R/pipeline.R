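#' Run a pipeline stage and write its result tables
#'
#' Orchestrates the analysis stages over a plot-level CSV (or the
#' simulator) and writes delimited result tables plus a JSON run manifest
#' (config echo, seed, package/R versions, files written) into `out_dir`.
#'
#' Stages:
#' \describe{
#'   \item{simulate}{draw a dataset from [generate_met()] and write it
#'     (with its generating truth) to CSV; deterministic given `seed`.}
#'   \item{nutyield}{plot-level nutritional yields, genotype summary and
#'     population summary.}
#'   \item{ammi}{per trait (yield and each mineral nutritional yield):
#'     ANOVA table, biplot scores (TSV) and stability ranking.}
#'   \item{blup}{per trait: variance components, genotypic values and the
#'     HMGV/RPGV/HMRPGV ranking.}
#'   \item{index}{Elston and desired-gains indexes on the genotype mean
#'     nutritional yields.}
#'   \item{report}{all of the above plus the combined balanced ranking
#'     (mean rank over AMMI stability, HMRPGV, EMI and BDGI components).}
#' }
#'
#' @param command one of `"simulate"`, `"nutyield"`, `"ammi"`, `"blup"`,
#'   `"index"`, `"report"`.
#' @param input path to a plot-level CSV (ignored by `simulate`); a
#'   [met_dataset()] is accepted too.
#' @param out_dir output directory, created if absent.
#' @param config an [analysis_config()].
#' @param sim_cfg a [sim_config()] for `simulate`.
#' @param seed optional integer; overrides `sim_cfg$seed`.
#' @return invisibly, a list with the computed objects and the manifest.
#' @export
run_pipeline <- function(command = c("simulate", "nutyield", "ammi", "blup",
                                     "index", "report"),
                         input = NULL, out_dir = ".",
                         config = analysis_config(),
                         sim_cfg = sim_config(), seed = NULL) {
  command <- match.arg(command)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name, sep = ",") {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
    written <<- c(written, path)
  }
  results <- list()

  if (command == "simulate") {
    if (!is.null(seed)) sim_cfg$seed <- as.integer(seed)
    sim <- generate_met(sim_cfg)
    write_met(sim$data, file.path(out_dir, "met_data.csv"))
    written <- c(written, file.path(out_dir, "met_data.csv"))
    emit(data.frame(genotype = names(sim$truth$genotype_effects),
                    effect = sprintf("%.17g", sim$truth$genotype_effects)),
         "truth_genotype_effects.csv")
    emit(data.frame(environment = names(sim$truth$environment_effects),
                    effect = sprintf("%.17g", sim$truth$environment_effects)),
         "truth_environment_effects.csv")
    results$sim <- sim
  } else {
    data <- if (inherits(input, "met_dataset")) input
            else read_met(input, quiet = TRUE)
    data <- add_nutritional_yield(data, config)   # errors if minerals missing
    ny_traits <- paste0("ny_", names(config$dri))
    # stability/BLUP analyses run on the dehull-adjusted yield basis
    traits <- c("yield_adj_kg_ha", ny_traits)
    results$data <- data

    if (command %in% c("nutyield", "report")) {
      plot_cols <- c("genotype", "group", "environment", "replicate",
                     "yield_kg_ha", "yield_adj_kg_ha", ny_traits)
      emit(data$records[plot_cols], "nutritional_yield_plots.csv")
      gs <- genotype_summary(data, traits)
      report_gs <- gs
      for (cl in grep("^(mean|sd)_", names(report_gs), value = TRUE))
        report_gs[[cl]] <- round_half_away(report_gs[[cl]])
      emit(report_gs, "genotype_summary.csv")
      pop <- population_summary(gs)
      emit(data.frame(trait = names(pop), mean = pop,
                      mean_rounded = round_half_away(pop)),
           "population_summary.csv")
      conc_summary <- genotype_summary(data, names(config$dri))
      dens <- data.frame(genotype = conc_summary$genotype,
                         stringsAsFactors = FALSE)
      for (m in names(config$dri))
        dens[[paste0("g_", m)]] <- round_half_away(
          amount_for_dri(conc_summary[[paste0("mean_", m)]], config$dri[[m]]))
      emit(dens, "nutrient_density.csv")
      results$genotype_summary <- gs
      results$population_summary <- pop
    }

    if (command %in% c("ammi", "report")) {
      ammi_ranks <- list()
      for (tr in traits) {
        tm <- cell_means(data, tr)
        fit <- fit_ammi(tm, data = data, trait = tr)
        rk <- stability_ranking(fit)
        ammi_ranks[[paste0("ammi_", tr)]] <- rk
        emit(cbind(term = rownames(fit$anova), as.data.frame(fit$anova)),
             paste0("ammi_anova_", tr, ".csv"))
        emit(biplot_data(fit), paste0("ammi_scores_", tr, ".tsv"), sep = "\t")
        emit(rk, paste0("ammi_ranking_", tr, ".csv"))
      }
      results$ammi_ranks <- ammi_ranks
    }

    if (command %in% c("blup", "report")) {
      blup_ranks <- list(); vrows <- list()
      for (tr in traits) {
        bs <- blup_stability(data, tr)
        blup_ranks[[paste0("blup_", tr)]] <- bs$stats
        vrows[[tr]] <- data.frame(trait = tr, method = bs$varcomp$method,
                                  sigma2_g = bs$varcomp$sigma2_g,
                                  sigma2_ge = bs$varcomp$sigma2_ge,
                                  sigma2_eps = bs$varcomp$sigma2_eps)
        gvdf <- data.frame(genotype = rownames(bs$gv$gv), bs$gv$gv,
                           check.names = FALSE)
        emit(gvdf, paste0("blup_gv_", tr, ".csv"))
        emit(bs$stats, paste0("blup_ranking_", tr, ".csv"))
      }
      emit(do.call(rbind, vrows), "blup_varcomp.csv")
      results$blup_ranks <- blup_ranks
    }

    if (command %in% c("index", "report")) {
      bad <- setdiff(names(config$lal), names(config$dri))
      bad <- c(bad, setdiff(names(config$desired_gains), names(config$dri)))
      if (length(bad) > 0)
        stop("LAL/desired-gains mineral(s) not in analysis: ",
             paste(unique(bad), collapse = ", "))
      gs <- genotype_summary(data, ny_traits)
      X <- as.matrix(gs[paste0("mean_ny_", names(config$dri))])
      colnames(X) <- names(config$dri)
      rownames(X) <- gs$genotype
      emi <- elston_index(X, config$lal)
      Gcov <- genotypic_covariance(data, ny_traits)
      dimnames(Gcov) <- list(names(config$dri), names(config$dri))
      bdgi <- baker_index(X, Gcov, config$desired_gains,
                          ridge = config$ridge)
      emit(emi, "elston_index.csv")
      emit(bdgi, "baker_index.csv")
      emit(data.frame(trait = names(config$dri),
                      coefficient = attr(bdgi, "coefficients"),
                      expected_gain = attr(bdgi, "expected_gain")),
           "baker_coefficients.csv")
      results$emi <- emi
      results$bdgi <- bdgi
    }

    if (command == "report") {
      comps <- c(results$ammi_ranks, results$blup_ranks,
                 list(emi = results$emi, bdgi = results$bdgi))
      combined <- balanced_ranking(comps)
      emit(combined, "balanced_ranking.csv")
      results$balanced <- combined
    }
  }

  manifest <- list(command = command,
                   seed = if (command == "simulate") sim_cfg$seed else seed,
                   config = unclass(config),
                   package = "nutristab",
                   package_version = as.character(
                     utils::packageVersion("nutristab")),
                   r_version = R.version.string,
                   files = basename(written))
  manifest_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
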