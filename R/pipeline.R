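#' Convert a trait table to path-analysis variables
#'
#' Restricts to complete cases over ASR, GSD, and the three bias metrics,
#' codes the sex-determination system as a standardized 0/1 indicator (XY =
#' 0, ZW = 1), and z-scores the continuous metrics on the subset. Column
#' names follow the path-model vertices (`GSD`, `JMB`, `AMB`, `MAT`,
#' `ASR`).
#'
#' @param table TraitTable data.frame (`species`, `gsd`, `asr`, `jmb`,
#'   `amb`, `mat`).
#' @return A data.frame with columns `species`, `GSD`, `JMB`, `AMB`, `MAT`,
#'   `ASR`.
#' @export
as_path_data <- function(table) {
  need <- c("species", "gsd", "asr", "jmb", "amb", "mat")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(table[need])
  tab <- table[keep, , drop = FALSE]
  data.frame(species = tab$species,
             GSD = standardize(as.numeric(tab$gsd == "ZW")),
             JMB = standardize(tab$jmb),
             AMB = standardize(tab$amb),
             MAT = standardize(tab$mat),
             ASR = standardize(tab$asr),
             stringsAsFactors = FALSE)
}

#' Read a pipeline configuration file
#'
#' Flat YAML key-value schema: `traits` and `tree` (input paths), `out_dir`,
#' `seed`, `n_boot`, `n_maps`, `power_reps`, and logical toggles
#' `bivariate`, `interactions`, `quadratic`, `outliers`, `simmap`, `power`,
#' plus `path_styles` (list of `santos` / `hardenberg`). Missing keys take
#' defaults. The configuration round-trips through [yaml::write_yaml()].
#'
#' @param path YAML file path.
#' @return A named list of class `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg A named list of configuration values.
#' @export
as_pipeline_config <- function(cfg) {
  defaults <- list(out_dir = "asrpath_out", seed = 1, n_boot = 500,
                   n_maps = 100, power_reps = 500,
                   bivariate = TRUE, interactions = TRUE, quadratic = TRUE,
                   outliers = TRUE, simmap = TRUE, power = TRUE,
                   path_styles = c("santos", "hardenberg"))
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  structure(cfg, class = "pipeline_config")
}

#' Run the full comparative analysis pipeline
#'
#' Orchestrates every stage on one trait table and tree: bivariate PGLS
#' models (sex-determination differences in each demographic trait, and
#' demographic predictors of adult sex ratio), interaction models with
#' marginal tests and per-group slopes, quadratic-term comparisons, power
#' simulations on the phylogenetically transformed predictors, the
#' d-separation path-model comparison in both flavours with bootstrap path
#' coefficients for the best model, and Mk-model fitting with stochastic
#' character maps. Results are written as plain-text files into
#' `config$out_dir`:
#' `table1_bivariate.tsv`, `table1_interactions.tsv`, `table2_dsep.tsv`,
#' `fig3_coefficients.json`, `simmap_summary.json`, `power.tsv`, and
#' `run.log`.
#'
#' @param config A `"pipeline_config"` list (see [read_pipeline_config()]);
#'   `traits`/`tree` may be file paths or in-memory objects.
#' @return Invisibly, a list of the in-memory results.
#' @export
run_full_analysis <- function(config) {
  config <- as_pipeline_config(unclass(config))
  tab <- if (is.character(config$traits)) read_trait_csv(config$traits) else config$traits
  tree <- if (is.character(config$tree)) read_newick(config$tree) else config$tree
  # tip-name normalization: underscores and spaces treated as equivalent
  norm <- function(x) gsub(" ", "_", x)
  tree$tip.label <- norm(tree$tip.label)
  tab$species <- norm(tab$species)
  unmatched <- setdiff(tab$species, tree$tip.label)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                               sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("asrpath %s | R %s | seed %d",
          as.character(utils::packageVersion("asrpath")),
          paste(R.version$major, R.version$minor, sep = "."), config$seed)
  if (length(unmatched))
    logline("species not in tree (%d): %s", length(unmatched),
            paste(utils::head(unmatched, 20), collapse = ", "))
  results <- list()

  traits_b <- intersect(c("asr", "bsr", "jmb", "amb", "mat"), names(tab))
  traits_pred <- setdiff(traits_b, "asr")
  if (isTRUE(config$bivariate)) {
    rows <- list()
    has_gsd <- "gsd" %in% names(tab) && any(!is.na(tab$gsd))
    for (v in traits_b) {
      if (!has_gsd) break
      ms <- model_subset(tab, c(v, "gsd"), tree)
      ms$table$gsd <- factor(ms$table$gsd, levels = c("XY", "ZW"))
      fit <- fit_pgls(stats::reformulate("gsd", paste0(v, "_z")),
                      ms$table, tree = ms$tree)
      rows[[paste0(v, "~gsd")]] <- data.frame(
        response = v, predictor = "gsd", b = fit$coefficients[2],
        se = fit$se[2], t = fit$tstat[2], p = fit$pvalue[2],
        lambda = fit$lambda, R2 = fit$R2, n = fit$n)
      logline("bivariate %s ~ gsd: fit_pgls n=%d", v, fit$n)
    }
    for (v in traits_pred) {
      ms <- model_subset(tab, c("asr", v), tree)
      fit <- fit_pgls(stats::reformulate(paste0(v, "_z"), "asr_z"),
                      ms$table, tree = ms$tree)
      rows[[paste0("asr~", v)]] <- data.frame(
        response = "asr", predictor = v, b = fit$coefficients[2],
        se = fit$se[2], t = fit$tstat[2], p = fit$pvalue[2],
        lambda = fit$lambda, R2 = fit$R2, n = fit$n)
      logline("bivariate asr ~ %s: fit_pgls n=%d", v, fit$n)
    }
    results$bivariate <- do.call(rbind, rows)
    utils::write.table(results$bivariate,
                       file.path(config$out_dir, "table1_bivariate.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  if (isTRUE(config$interactions) && "gsd" %in% names(tab)) {
    rows <- list()
    for (v in traits_pred) {
      ms <- model_subset(tab, c("asr", v, "gsd"), tree)
      ms$table$gsd <- factor(ms$table$gsd, levels = c("XY", "ZW"))
      vz <- paste0(v, "_z")
      fit <- fit_pgls(stats::as.formula(paste0("asr_z ~ ", vz, " * gsd")),
                      ms$table, tree = ms$tree)
      am <- anova_marginal(fit)
      inter <- am[nrow(am), ]
      gs <- group_slopes(fit, vz, "gsd")
      rows[[v]] <- data.frame(
        predictor = v, F_interaction = inter$F, df_num = inter$df_num,
        df_den = inter$df_den, p_interaction = inter$p,
        slope_XY = gs$slope[1], lo_XY = gs$lower[1], hi_XY = gs$upper[1],
        slope_ZW = gs$slope[2], lo_ZW = gs$lower[2], hi_ZW = gs$upper[2],
        lambda = fit$lambda, n = fit$n)
      logline("interaction asr ~ %s * gsd: F=%.3g (df %d;%d)", v,
              inter$F, inter$df_num, inter$df_den)
    }
    results$interactions <- do.call(rbind, rows)
    utils::write.table(results$interactions,
                       file.path(config$out_dir, "table1_interactions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  if (isTRUE(config$quadratic)) {
    rows <- list()
    for (v in traits_pred) {
      ms <- model_subset(tab, c("asr", v), tree)
      cq <- compare_quadratic("asr_z", paste0(v, "_z"), ms$table, tree = ms$tree)
      rows[[v]] <- data.frame(predictor = v, dAIC = cq$dAIC,
                              chisq = cq$chisq, p = cq$p)
      logline("quadratic check asr ~ %s: dAIC=%.3g", v, cq$dAIC)
    }
    results$quadratic <- do.call(rbind, rows)
  }

  if (isTRUE(config$power)) {
    rows <- list()
    for (v in traits_pred) {
      ms <- model_subset(tab, c("asr", v), tree)
      f0 <- fit_pgls(stats::reformulate("1", paste0(v, "_z")), ms$table,
                     tree = ms$tree)
      tr_l <- lambda_rescale_tree(ms$tree, f0$lambda)
      xs <- independent_contrasts(
        tr_l, stats::setNames(ms$table[[paste0(v, "_z")]], ms$table$species))
      for (eff in c(0.1, 0.3, 0.5)) {
        pw <- power_simulation(xs$contrasts, eff, n_reps = config$power_reps,
                               seed = config$seed, type = "correlation")
        rows[[paste(v, eff)]] <- data.frame(predictor = v, effect = eff,
                                            power = pw$power, se = pw$se,
                                            n = ms$n)
      }
      logline("power asr ~ %s: %d reps", v, config$power_reps)
    }
    results$power <- do.call(rbind, rows)
    utils::write.table(results$power, file.path(config$out_dir, "power.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  if (length(config$path_styles) && all(c("gsd", "jmb", "amb", "mat") %in% names(tab))) {
    pd <- as_path_data(tab)
    ptree <- prune_to(tree, pd$species)
    pd <- pd[pd$species %in% ptree$tip.label, ]
    models <- build_model_set()
    dtabs <- list()
    for (st in config$path_styles) {
      rep_ <- dsep(models, pd, ptree, style = st)
      d <- as.data.frame(rep_)
      d$style <- st
      dtabs[[st]] <- d
      logline("dsep %s flavour: best model %s", st, d$model[1])
    }
    results$dsep <- do.call(rbind, dtabs)
    utils::write.table(results$dsep,
                       file.path(config$out_dir, "table2_dsep.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    best <- results$dsep$model[1]
    coefs <- fit_path_coefficients(models[[best]], pd, ptree,
                                   style = config$path_styles[1],
                                   n_boot = config$n_boot, seed = config$seed)
    results$path_coefficients <- coefs
    jsonlite::write_json(coefs, file.path(config$out_dir, "fig3_coefficients.json"),
                         dataframe = "rows", digits = NA)
    logline("path coefficients for %s: %d edges, %d bootstrap reps",
            best, nrow(coefs), config$n_boot)
  }

  if (isTRUE(config$simmap) && "gsd" %in% names(tab)) {
    ok <- !is.na(tab$gsd)
    states <- stats::setNames(tab$gsd[ok], tab$species[ok])
    states <- states[names(states) %in% tree$tip.label]
    stree <- prune_to(tree, names(states))
    fits <- list(ER = fit_mk(stree, states, "ER"),
                 ARD = fit_mk(stree, states, "ARD"))
    maps <- stochastic_maps(fits$ARD, n_maps = config$n_maps,
                            seed = config$seed)
    sm <- list(dAIC_ER_minus_ARD = fits$ER$AIC - fits$ARD$AIC,
               AIC = c(ER = fits$ER$AIC, ARD = fits$ARD$AIC),
               logLik = c(ER = fits$ER$logLik, ARD = fits$ARD$logLik),
               rates_ARD = as.list(fits$ARD$rates),
               n_maps = maps$n_maps, mean_total = maps$mean_total,
               mean_by_direction = stats::setNames(
                 list(maps$mean_12, maps$mean_21), maps$directions))
    results$simmap <- sm
    utils::write.csv(as.data.frame(maps$counts),
                     file.path(config$out_dir, "simmap_counts.csv"),
                     row.names = FALSE)
    jsonlite::write_json(sm, file.path(config$out_dir, "simmap_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    logline("simmap: %d maps, mean transitions %.3f", maps$n_maps,
            maps$mean_total)
  }

  logline("pipeline complete")
  invisible(results)
}
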