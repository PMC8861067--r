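# End-to-end pipeline: filters -> chord transform -> beta partition ->
# abundance models -> permutation tests -> RDA -> species response ->
# wing-shape PGLS, writing one CSV per stage plus a filter log.

#' Pipeline configuration
#'
#' Collects paths, thresholds and reproducibility settings for
#' [run_pipeline()]. When `records` is `NULL` the packaged synthetic
#' generator supplies the data (the default, since the study's ringing
#' database is not public).
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed used for the generator and all permutation
#'   tests.
#' @param n_perm permutation count for all permutation tests (>= 99).
#' @param min_years,min_islands species eligibility thresholds.
#' @param window,min_days season window and per-fortnight effort threshold.
#' @param exclude_islands islands excluded from capture-rate models.
#' @param records,effort,descriptors,traits,tree optional inputs (file
#'   paths or objects); `NULL` means simulate / use packaged defaults.
#' @param sim_config `synthetic_config` used when simulating.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, n_perm = 999,
                            min_years = 5, min_islands = 5,
                            window = c("04-16", "05-15"), min_days = 7,
                            exclude_islands = "Columbrets",
                            records = NULL, effort = NULL,
                            descriptors = NULL, traits = NULL, tree = NULL,
                            sim_config = synthetic_config()) {
  if (n_perm < 99) stop("pipeline_config: n_perm must be >= 99")
  if (length(seed) != 1 || is.na(seed)) stop("pipeline_config: seed required")
  structure(as.list(environment()), class = "pipeline_config")
}

write_stage <- function(x, out_dir, name) {
  write.csv(x, file.path(out_dir, paste0(name, ".csv")), row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes every stage with a fixed seed and writes result tables to
#' `config$out_dir`: `beta_partition.csv`, `lcbd.csv`, `scbd.csv`,
#' `abundance_models.csv`, `abundance_fit.csv`, `permanova.csv`,
#' `dispersion.csv`, `pairwise_adjusted.csv`, `rda_axes.csv`,
#' `species_corr.csv`, `variable_corr.csv`, `varpart.csv`,
#' `response_models.csv`, `response_summary.csv`, `pgls_results.csv`, and
#' `pipeline_log.txt` recording every filter decision. Re-running with the
#' same config and seed reproduces all outputs exactly.
#'
#' @param config a `pipeline_config`.
#' @return (invisibly) a list with the main stage objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  desc <- config$descriptors
  if (is.null(desc)) desc <- island_descriptors()
  else if (is.character(desc)) desc <- read_island_descriptors(desc)

  if (is.null(config$records)) {
    sim <- stage("simulate", simulate_ringing(config$sim_config,
                                              seed = config$seed))
    records <- sim$records; effort <- sim$effort
    truth <- sim$truth
    traits <- stage("simulate", simulate_traits(config$sim_config, truth,
                                                seed = config$seed + 1))
    tree <- stage("simulate", simulate_tree(nrow(truth),
                                            seed = config$seed + 2))
    continental <- setNames(truth$C, truth$species)
    say("simulated inputs with seed ", config$seed)
  } else {
    records <- if (is.character(config$records))
      read_capture_records(config$records) else config$records
    effort <- if (is.character(config$effort))
      read_effort_records(config$effort) else config$effort
    traits <- if (is.character(config$traits))
      read_trait_table(config$traits) else config$traits
    tree <- if (is.character(config$tree))
      read_newick(config$tree) else config$tree
    continental <- NULL
    truth <- NULL
  }

  # eligibility filters
  if (!is.null(effort)) {
    elig <- stage("filter", filter_years(effort, config$window,
                                         config$min_days))
    key <- paste(records$island, records$year)
    ok <- key %in% paste(elig$island, elig$year)
    say("filter_years: dropped ", sum(!ok), " of ", length(ok),
        " records (ineligible island-years)")
    records <- records[ok, , drop = FALSE]
    class(records) <- c("capture_records", "data.frame")
  }
  fs <- stage("filter", filter_species(records, config$min_years,
                                       config$min_islands))
  say("filter_species: dropped ", length(fs$dropped), " species (",
      paste(fs$dropped, collapse = ", "), ")")
  records <- fs$records

  cm <- stage("pivot", pivot_records(records))
  tm <- stage("transform", chord_transform(cm))
  say("community matrix: ", nrow(cm), " island-years x ", ncol(cm),
      " species")

  # beta diversity
  bp <- stage("beta", beta_partition(tm))
  glob <- data.frame(island = "(all)", Y_i = bp$N, BD = bp$BD_IT,
                     component = "BD_I,T")
  isl_tab <- data.frame(island = bp$islands$island, Y_i = bp$islands$Y_i,
                        BD = bp$islands$BD_Ti, component = "BD_Ti",
                        mean_LCBD = bp$islands$mean_LCBD)
  glob2 <- data.frame(island = c("(between islands)", "(within islands)"),
                      Y_i = c(bp$n, bp$N - bp$n),
                      BD = c(bp$BD_I, bp$BD_T),
                      component = c("BD_I", "BD_T"))
  bt <- rbind(cbind(glob, mean_LCBD = NA), cbind(glob2, mean_LCBD = NA),
              isl_tab)
  write_stage(bt, config$out_dir, "beta_partition")
  write_stage(data.frame(sample = names(bp$LCBD), LCBD = bp$LCBD),
              config$out_dir, "lcbd")
  write_stage(data.frame(species = names(bp$SCBD), SCBD = bp$SCBD),
              config$out_dir, "scbd")

  # continental abundance models
  if (!is.null(continental)) {
    mr <- mean_ringed_table(records)
    comp <- stage("abundance", fit_loglog_models(mr, continental))
    write_stage(as.data.frame(comp), config$out_dir, "abundance_models")
    totals <- tapply(records$count, records$species, sum)
    fin <- stage("abundance",
                 fit_final_regression(totals, continental))
    write_stage(data.frame(slope = fin$slope, intercept = fin$intercept,
                           F = fin$F, df1 = fin$df[1], df2 = fin$df[2],
                           p = fin$p, r = fin$r),
                config$out_dir, "abundance_fit")
  } else comp <- fin <- NULL

  # permutation tests
  pm <- stage("permtest", permanova(tm, n_perm = config$n_perm,
                                    seed = config$seed))
  dt <- stage("permtest", dispersion_test(tm, n_perm = config$n_perm,
                                          seed = config$seed))
  pw <- stage("permtest", pairwise_permanova(tm, n_perm = config$n_perm,
                                             seed = config$seed))
  write_stage(data.frame(test = c("PERMANOVA", "dispersion"),
                         F = c(pm$statistic, dt$statistic),
                         df1 = c(pm$df[1], dt$df[1]),
                         df2 = c(pm$df[2], dt$df[2]),
                         p = c(pm$p, dt$p)),
              config$out_dir, "permanova")
  write_stage(data.frame(island = names(dt$group_means),
                         mean_dist = as.vector(dt$group_means)),
              config$out_dir, "dispersion")
  utils::write.csv(pw$p_adjusted,
                   file.path(config$out_dir, "pairwise_adjusted.csv"))

  # ordination
  meta <- sample_meta(tm)
  geo_vars <- c("Latitude", "LongKm", "MinDistAfrica", "StrDistAfrica",
                "MinDistLand", "MinDSouthLand")
  hab_vars <- c("Area", "MaxAlt", "NDVI")
  ldesc <- log_descriptors(desc, c(geo_vars, hab_vars))
  geo_keep <- stage("rda", vif_filter(ldesc[geo_vars], 10))$retained
  hab_keep <- stage("rda", vif_filter(ldesc[hab_vars], 10))$retained
  say("vif_filter geographic: kept ", paste(geo_keep, collapse = ", "))
  say("vif_filter habitat: kept ", paste(hab_keep, collapse = ", "))
  Xs <- ldesc[meta$island, c(geo_keep, hab_keep), drop = FALSE]
  rownames(Xs) <- rownames(tm)
  # few islands can support fewer predictors than survive the VIF screen
  qx <- qr(scale(as.matrix(Xs)))
  if (qx$rank < ncol(Xs)) {
    keep_ix <- sort(qx$pivot[seq_len(qx$rank)])
    say("rda: dropped aliased predictor(s): ",
        paste(setdiff(colnames(Xs), colnames(Xs)[keep_ix]), collapse = ", "))
    Xs <- Xs[, keep_ix, drop = FALSE]
    geo_keep <- intersect(geo_keep, colnames(Xs))
    hab_keep <- intersect(hab_keep, colnames(Xs))
  }
  rd <- stage("rda", rda_fit(tm, Xs, n_perm = config$n_perm,
                             seed = config$seed))
  vp <- if (length(geo_keep) && length(hab_keep))
    stage("rda", varpart2(tm, Xs[geo_keep], Xs[hab_keep]))
  else NULL
  write_stage(data.frame(axis = colnames(rd$site_scores),
                         eigenvalue = rd$eig, pct_total = rd$pct_total,
                         pct_constrained = rd$pct_constrained,
                         p = rd$axis_p),
              config$out_dir, "rda_axes")
  write_stage(species_axis_correlations(rd, tm),
              config$out_dir, "species_corr")
  write_stage(axis_variable_association(rd, Xs),
              config$out_dir, "variable_corr")
  if (!is.null(vp))
    write_stage(data.frame(fraction = c("a_geo_unique", "b_shared",
                                        "c_hab_unique", "residual"),
                           R2_adj = c(vp$a, vp$b, vp$c, vp$residual)),
                config$out_dir, "varpart")

  # species response models (capture-rate mode, excluding flagged islands)
  off <- stage("respond", build_offsets(cm, effort, mode = "rate",
                                        exclude = config$exclude_islands))
  say("rate-mode offsets: ", sum(is.na(off)), " island-year(s) excluded")
  pred <- ldesc[meta$island, c(geo_keep, hab_keep), drop = FALSE]
  sr <- stage("respond", select_models(cm, pred, offset = off))
  write_stage(as.data.frame(sr), config$out_dir, "response_models")
  write_stage(summarize_response(sr), config$out_dir, "response_summary")

  # wing-shape PGLS on response groups
  pg <- NULL
  if (!is.null(traits) && !is.null(tree)) {
    area_var <- intersect(c("Area"), unique(sr$predictor))
    ds_var <- intersect(c("MinDSouthLand"), unique(sr$predictor))
    if (length(area_var) && length(ds_var)) {
      rel <- function(v) {
        s <- sr[sr$predictor == v, , drop = FALSE]
        setNames(s$shape != "none" & s$sign %in% c("+", "intermediate"),
                 s$species)
      }
      ga <- rel(area_var); gd <- rel(ds_var)
      groups <- data.frame(species = names(ga), area_related = ga,
                           dsouth_related = gd[names(ga)])
      pg <- tryCatch(
        stage("pgls", group_tests(traits, groups, tree)),
        error = function(e) { say("pgls skipped: ", conditionMessage(e)); NULL })
      if (!is.null(pg)) write_stage(pg, config$out_dir, "pgls_results")
    }
  }

  writeLines(log_lines, file.path(config$out_dir, "pipeline_log.txt"))
  invisible(list(beta = bp, permanova = pm, dispersion = dt,
                 pairwise = pw, rda = rd, varpart = vp,
                 response = sr, pgls = pg, abundance = comp,
                 abundance_fit = fin, community = cm, chord = tm,
                 truth = truth))
}
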