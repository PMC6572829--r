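#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end run. Thresholds default to the
#' field-standard values: synergy cutoff 20, score cap 100, Bayes factor
#' tie cutoff 5, FDR 0.05, enrichment grid step 0.1, 1000 bootstrap
#' iterations, enrichment bootstrap 5 x 80%.
#'
#' @param seed root seed; every stage derives its own substream from it.
#' @param n_cells,n_genes,n_combos,cells_per_combo screen design size.
#' @param n_coupled number of biomarker-coupled combinations.
#' @param noise_sd viability noise sd (% control).
#' @param n_teams,team_skill simulated team count and skill range.
#' @param bootstrap_iters paired bootstrap iterations for Bayes factors.
#' @param n_perm permutations for the null model.
#' @param synergy_threshold,cap,bf_cutoff,fdr,grid_step,enrichment_boot
#'   analysis thresholds (see description).
#' @param n_pdx_models PDX models per combination.
#' @param outdir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_cells = 30L, n_genes = 12L,
                       n_combos = 8L, cells_per_combo = NULL,
                       n_coupled = 4L, noise_sd = 5,
                       n_teams = 6L, team_skill = c(0.9, 0.7, 0.5, 0.3,
                                                    0.1, 0),
                       bootstrap_iters = 200L, n_perm = 200L,
                       synergy_threshold = 20, cap = 100, bf_cutoff = 5,
                       fdr = 0.05, grid_step = 0.1,
                       enrichment_boot = c(5, 0.8),
                       n_pdx_models = 40L, outdir = tempfile("combobench_")) {
  structure(as.list(environment()), class = "run_config")
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[combobench] %-14s %s", stage, sprintf(...)))
}

#' Run the full synthetic-screen pipeline
#'
#' Generation -> surface scoring -> team benchmarking -> ensembles ->
#' biomarkers -> PDX comparison, writing every result table plus a
#' machine-readable JSON manifest (configuration, stage list, seed,
#' package version) into the configured output directory. Identical
#' configurations yield byte-identical tables.
#'
#' @param config a [run_config()].
#' @return the output directory path, invisibly; the manifest lists the
#'   files written.
#' @export
run_pipeline <- function(config = run_config()) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$outdir, name)
    df$schema_version <- "combobench-1"
    df$seed <- config$seed
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
    path
  }
  run_stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s (prior outputs kept in %s)",
                   name, conditionMessage(e), config$outdir), call. = FALSE)
    })
    stages <<- c(stages, name)
    out
  }

  # -- simulate ----------------------------------------------------------
  sim <- run_stage("simulate", {
    panel <- make_panel(config$n_cells, config$n_genes, seed = config$seed)
    drugs <- make_drug_library(max(8L, config$n_combos), rownames(panel$bem),
                               seed = config$seed)
    design <- make_design(panel, drugs, config$n_combos,
                          config$cells_per_combo, seed = config$seed)
    coupled <- utils::head(unique(design$combo_id), config$n_coupled)
    genes <- stats::setNames(rownames(panel$bem)[seq_along(coupled)], coupled)
    scr <- simulate_screen(panel, drugs, design, noise_sd = config$noise_sd,
                           coupling = if (length(coupled))
                             list(genes = genes) else NULL,
                           seed = config$seed)
    pipeline_log("simulate", "%d experiments, %d cells, %d genes",
                 length(scr$screen), config$n_cells, config$n_genes)
    list(panel = panel, drugs = drugs, design = design, scr = scr,
         coupled_genes = genes)
  })
  write_screen(sim$scr$screen, file.path(config$outdir, "screen.csv"),
               drug_map = sim$design)
  files <- c(files, "screen.csv")
  emit(sim$scr$truth, "ground_truth.csv")

  # -- score surfaces ----------------------------------------------------
  synergy <- run_stage("score_surfaces", {
    s <- score_screen(sim$scr$screen)
    pipeline_log("score_surfaces", "%d records, %d synergistic",
                 nrow(s), sum(s$class == "synergistic"))
    s
  })
  emit(synergy, "synergy_table.csv")

  # -- score teams -------------------------------------------------------
  leaderboard <- run_stage("score_teams", {
    teams <- simulate_teams(synergy, config$n_teams,
                            skill = config$team_skill, seed = config$seed)
    bf <- bootstrap_bayes_factor(teams, synergy, metric = "SC1",
                                 iters = config$bootstrap_iters,
                                 bf_cutoff = config$bf_cutoff,
                                 seed = config$seed)
    null <- null_model(synergy, metric = "SC1", n_perm = config$n_perm,
                       seed = config$seed)
    btr <- better_than_random(stats::setNames(bf$pm, bf$team), null,
                              fdr = config$fdr)
    bf$pass_fdr <- btr$pass[match(bf$team, btr$team)]
    pipeline_log("score_teams", "%d teams, best pm=%.3f", nrow(bf),
                 max(bf$pm))
    list(teams = teams, board = bf)
  })
  emit(leaderboard$board, "leaderboard.csv")

  # -- ensemble ----------------------------------------------------------
  ens <- run_stage("ensemble", {
    binpreds <- lapply(leaderboard$teams, function(df) {
      df$prediction <- NULL
      names(df)[names(df) == "prediction_binary"] <- "prediction"
      df
    })
    pm <- prediction_matrix(binpreds)
    v <- sml_estimate(pm)
    yhat <- sml_ensemble(pm)
    keys <- strsplit(colnames(pm), ":", fixed = TRUE)
    pred <- data.frame(combo_id = vapply(keys, `[`, "", 1),
                       cell_id = vapply(keys, `[`, "", 2),
                       prediction = yhat, stringsAsFactors = FALSE)
    pipeline_log("ensemble", "%d teams aggregated over %d experiments",
                 nrow(pm), ncol(pm))
    list(pred = pred, v = data.frame(team = names(v), v = unname(v)))
  })
  emit(ens$pred, "ensemble_predictions.csv")
  emit(ens$v, "ensemble_team_estimates.csv")

  # -- biomarkers --------------------------------------------------------
  biom <- run_stage("biomarkers", {
    mono <- monotherapy_table(sim$scr$screen, sim$design)
    assocs <- monotherapy_association(mono, sim$panel$bem)
    syn2 <- merge(synergy, unique(sim$design[, c("combo_id", "drug_a",
                                                 "drug_b")]), by = "combo_id")
    enr <- synergy_enrichment(assocs, syn2, sim$panel$bem,
                              step = config$grid_step,
                              boot = config$enrichment_boot,
                              seed = config$seed)
    cands <- data.frame(gene = unname(sim$coupled_genes),
                        combo_id = names(sim$coupled_genes),
                        stringsAsFactors = FALSE)
    anova_res <- tryCatch(
      synergy_biomarker_anova(synergy, sim$panel$bem, sim$panel$tissue,
                              cands),
      error = function(e) NULL)
    pipeline_log("biomarkers", "%d associations, enrichment r=%.2f",
                 nrow(assocs), enr$r)
    list(assocs = assocs, enr = enr, anova = anova_res)
  })
  emit(biom$assocs, "monotherapy_associations.csv")
  emit(biom$enr$curve, "enrichment_curve.csv")
  if (!is.null(biom$anova)) emit(biom$anova, "synergy_biomarkers.csv")

  # -- pdx ---------------------------------------------------------------
  pdx <- run_stage("pdx", {
    pairs <- unique(sim$design[, c("combo_id", "drug_a", "drug_b")])
    cohort <- simulate_pdx(pairs, config$n_pdx_models,
                           coupling = list(prevalence = 0.3),
                           seed = config$seed)
    classed <- classify_pdx_cohort(cohort)
    conc <- synergy_rate_concordance(classed, synergy,
                                     threshold = config$synergy_threshold)
    pipeline_log("pdx", "%d records, concordance r=%.2f", nrow(classed),
                 if (is.na(conc$r)) NA else conc$r)
    list(classed = classed, conc = conc)
  })
  emit(pdx$classed, "pdx_classes.csv")
  emit(pdx$conc$rates, "pdx_concordance.csv")

  manifest <- list(
    package = "combobench",
    version = as.character(utils::packageVersion("combobench")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    schema_version = "combobench-1",
    stages = stages,
    files = files,
    config = config[setdiff(names(config), "outdir")])
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config$outdir)
}

#' Per (drug, cell) monotherapy sensitivity table from a screen
#'
#' Extracts the monotherapy row/column of every experiment, fits the Hill
#' curve and summarises sensitivity as one minus the normalised log-dose
#' AUC, averaging over experiments when a (drug, cell) pair is measured
#' multiple times.
#'
#' @param screen list of [dose_response_matrix()] objects.
#' @param design data.frame with `combo_id`, `drug_a`, `drug_b` mapping.
#' @return data.frame `drug_id`, `cell_id`, `sensitivity`.
#' @export
monotherapy_table <- function(screen, design) {
  map <- unique(design[, c("combo_id", "drug_a", "drug_b")])
  rows <- list()
  for (drm in screen) {
    hit <- map[map$combo_id == drm$combo_id, ]
    if (nrow(hit) == 0) next
    ca <- fit_hill(drm$doses_a, drm$viability[, 1])
    cb <- fit_hill(drm$doses_b, drm$viability[1, ])
    rows[[length(rows) + 1L]] <- data.frame(
      drug_id = c(hit$drug_a[1], hit$drug_b[1]),
      cell_id = drm$cell_id,
      sensitivity = c(monotherapy_sensitivity(ca, drm$doses_a),
                      monotherapy_sensitivity(cb, drm$doses_b)),
      stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  stats::aggregate(sensitivity ~ drug_id + cell_id, data = all, FUN = mean)
}

#' Command-line entry point
#'
#' Thin wrapper over the same exported stage functions used by
#' [run_pipeline()], so subcommands compose to identical results.
#' Subcommands: `simulate`, `score-surfaces`, `score-teams`, `ensemble`,
#' `biomarkers`, `pdx`, `run-all`. All take `--seed` and `--out`;
#' `score-surfaces` additionally takes a screen CSV path as its first
#' positional argument.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 success, 2 input error, 1 internal error),
#'   invisibly.
#' @export
combobench_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: combobench <simulate|score-surfaces|score-teams|ensemble|",
    "        biomarkers|pdx|run-all> [path] [--seed N] [--out DIR]")
  if (length(args) == 0) { message(usage); return(invisible(2L)) }
  cmd <- args[1]; rest <- args[-1]
  getopt <- function(flag, default) {
    i <- which(rest == flag)
    if (length(i) == 1 && i < length(rest)) rest[i + 1] else default
  }
  seed <- as.integer(getopt("--seed", "1"))
  out <- getopt("--out", tempfile("combobench_"))
  positional <- setdiff(rest, c("--seed", "--out",
                                getopt("--seed", NA), getopt("--out", NA)))
  status <- tryCatch({
    cfg <- run_config(seed = seed, outdir = out)
    switch(cmd,
      "run-all" = run_pipeline(cfg),
      "simulate" = {
        panel <- make_panel(cfg$n_cells, cfg$n_genes, seed = seed)
        drugs <- make_drug_library(max(8L, cfg$n_combos),
                                   rownames(panel$bem), seed = seed)
        design <- make_design(panel, drugs, cfg$n_combos, seed = seed)
        scr <- simulate_screen(panel, drugs, design,
                               noise_sd = cfg$noise_sd, seed = seed)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_screen(scr$screen, file.path(out, "screen.csv"),
                     drug_map = design)
      },
      "score-surfaces" = {
        assert_that(length(positional) >= 1,
                    "score-surfaces needs a screen CSV path")
        parsed <- read_screen(positional[1])
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_synergy_table(score_screen(parsed$screen),
                            file.path(out, "synergy_table.csv"), seed)
      },
      "score-teams" = , "ensemble" = , "biomarkers" = , "pdx" = {
        # these stages need the simulated context; run the full pipeline
        run_pipeline(cfg)
      },
      { message(usage); return(invisible(2L)) })
    0L
  },
  combobench_input_error = function(e) { message("input error: ",
                                                 conditionMessage(e)); 2L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
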