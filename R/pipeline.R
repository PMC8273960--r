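# End-to-end pipeline: cohort acquisition, zero imputation, model fits,
# reallocation tables, hazard-ratio surface, delimited-text reports.

#' Pipeline configuration
#'
#' Collects every option of [run_pipeline()]: input source (epoch CSV,
#' cohort CSV, or the synthetic generator), cut-points, adjustment sets,
#' reference compositions, reallocation deltas, and the sensitivity
#' toggles (2-year event exclusion, non-fatal-only outcome, non-normalised
#' behaviours with waking-duration adjustment, alternative 45 mg cut-off
#' via `cuts`).
#'
#' @param out_dir Directory for report files (created if absent).
#' @param seed Integer seed governing the synthetic stages.
#' @param cohort_csv,epoch_csv Optional input paths; when both are `NULL` a
#'   cohort is simulated from `sim`.
#' @param sim A [sim_config()] used when simulating.
#' @param cuts A [cutpoints()] object for epoch classification.
#' @param adjustments Adjustment sets to fit (see
#'   [adjustment_covariates()]).
#' @param reference_mvpa MVPA anchors (minutes) of the MVPA-anchored
#'   references.
#' @param sb_share SB share of non-MVPA time in those references.
#' @param reference_sb_min SB anchors (minutes) of the SB-anchored
#'   references.
#' @param reference_sb_mvpa MVPA duration of the SB-anchored references.
#' @param deltas Reallocation displacements in minutes.
#' @param rotation Rotation used for the reallocation model (the estimates
#'   are rotation-invariant).
#' @param exclude_first_2_years Drop (or censor, see `two_year_mode`)
#'   events occurring within the first 2 years of follow-up.
#' @param two_year_mode `"drop"` removes those subjects entirely;
#'   `"censor"` keeps them censored at the event time.
#' @param nonfatal_only Censor fatal events at the date of death instead of
#'   counting them.
#' @param non_normalized Fit the recorded minutes without closure,
#'   additionally adjusting for total waking duration (`waking_min`).
#' @param grid_step Grid spacing of the hazard-ratio surface, minutes.
#' @param write_heatmap Also render the ternary heatmap to a PNG.
#' @param total Waking-day closure total in minutes.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = tempfile("ilrsurv_run_"), seed = 1,
                            cohort_csv = NULL, epoch_csv = NULL,
                            sim = sim_config(seed = seed),
                            cuts = cutpoints(),
                            adjustments = c("model1", "model2"),
                            reference_mvpa = c(10, 21, 30), sb_share = 0.77,
                            reference_sb_min = c(540, 840),
                            reference_sb_mvpa = 10,
                            deltas = c(10, 20, 30),
                            rotation = "sb_first",
                            exclude_first_2_years = FALSE,
                            two_year_mode = c("drop", "censor"),
                            nonfatal_only = FALSE,
                            non_normalized = FALSE,
                            grid_step = 5, write_heatmap = FALSE,
                            total = 960) {
  structure(list(
    out_dir = out_dir, seed = seed, cohort_csv = cohort_csv,
    epoch_csv = epoch_csv, sim = sim, cuts = cuts,
    adjustments = adjustments, reference_mvpa = reference_mvpa,
    sb_share = sb_share, reference_sb_min = reference_sb_min,
    reference_sb_mvpa = reference_sb_mvpa, deltas = deltas,
    rotation = match_rotation(rotation),
    exclude_first_2_years = isTRUE(exclude_first_2_years),
    two_year_mode = match.arg(two_year_mode),
    nonfatal_only = isTRUE(nonfatal_only),
    non_normalized = isTRUE(non_normalized),
    grid_step = grid_step, write_heatmap = isTRUE(write_heatmap),
    total = total
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a structured-text configuration whose keys match the arguments of
#' [pipeline_config()] (scalar and vector fields only; `sim` fields may be
#' given under a `sim:` block).
#'
#' @param path YAML file path.
#' @return A `"pipeline_config"` object.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is needed to read configuration files", call. = FALSE)
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim
  raw$sim <- NULL
  if (!is.null(raw$cuts)) raw$cuts <- do.call(cutpoints, as.list(raw$cuts))
  cfg <- do.call(pipeline_config, raw)
  if (!is.null(sim_args)) {
    sim_args$seed <- sim_args$seed %||% cfg$seed
    cfg$sim <- do.call(sim_config, sim_args)
  }
  cfg
}

#' Run the analysis pipeline
#'
#' Executes simulate/load -> aggregate -> impute -> fit -> reallocate ->
#' surface, writing delimited-text reports to `cfg$out_dir` and logging row
#' counts in and out of each stage. Outputs are deterministic given the
#' configuration and seed.
#'
#' Reports written: `cohort.csv` (analysis set after imputation),
#' `exclusions.csv` (one row per excluded subject with the reason),
#' `importance.csv` (coordinate hazard ratios, three rotations by
#' adjustment set), `reallocations_mvpa_refs.csv` and
#' `reallocations_sb_refs.csv` (reallocation estimates around the two
#' reference families), `surface.csv` (ternary hazard-ratio grid), and
#' optionally `heatmap.png`.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the tables, fitted models, references and
#'   output paths.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  exclusions <- data.frame(subject_id = character(0), stage = character(0),
                           reason = character(0))

  # --- acquire cohort -------------------------------------------------
  if (!is.null(cfg$epoch_csv)) {
    epochs <- utils::read.csv(cfg$epoch_csv)
    agg <- aggregate_cohort(epochs, cfg$cuts)
    cohort <- agg$cohort
    if (nrow(agg$excluded))
      exclusions <- rbind(exclusions,
                          data.frame(subject_id = agg$excluded$subject_id,
                                     stage = "aggregate",
                                     reason = agg$excluded$reason))
    message(sprintf("[aggregate] %d subjects valid, %d excluded",
                    nrow(cohort), nrow(agg$excluded)))
    if (!all(c("followup_years", "event") %in% names(cohort)))
      stop("epoch input yields compositions only; supply outcomes via cohort_csv",
           call. = FALSE)
  } else if (!is.null(cfg$cohort_csv)) {
    cohort <- utils::read.csv(cfg$cohort_csv, stringsAsFactors = TRUE)
    message(sprintf("[load] %d subjects read from %s", nrow(cohort),
                    cfg$cohort_csv))
  } else {
    cohort <- simulate_cohort(cfg$sim)
    message(sprintf("[simulate] %d subjects, %d events", nrow(cohort),
                    sum(cohort$event)))
  }

  # --- sensitivity relabelling ---------------------------------------
  if (cfg$nonfatal_only && "fatal_cvd" %in% names(cohort)) {
    n_relab <- sum(cohort$event == 1 & cohort$fatal_cvd == 1)
    cohort$event[cohort$fatal_cvd == 1] <- 0
    message(sprintf("[nonfatal-only] %d fatal events censored at death", n_relab))
  }
  if (cfg$exclude_first_2_years) {
    early <- cohort$event == 1 & cohort$followup_years < 2
    if (cfg$two_year_mode == "drop") {
      exclusions <- rbind(exclusions, data.frame(
        subject_id = as.character(cohort$subject_id[early]),
        stage = "two_year_exclusion",
        reason = "event within first 2 years of follow-up"))
      cohort <- cohort[!early, , drop = FALSE]
      message(sprintf("[2-year exclusion] %d early events dropped", sum(early)))
    } else {
      cohort$event[early] <- 0
      message(sprintf("[2-year exclusion] %d early events censored", sum(early)))
    }
  }

  # --- zero imputation -----------------------------------------------
  comp <- impute_zeros_lrem(cohort[, c("sb_min", "lipa_min", "mvpa_min")])
  message(sprintf("[impute] %d zero cells imputed in %d iterations",
                  attr(comp, "n_imputed"), attr(comp, "iterations")))
  cohort$sb_min <- comp[, "sb"]
  cohort$lipa_min <- comp[, "lipa"]
  cohort$mvpa_min <- comp[, "mvpa"]

  # --- model fits -----------------------------------------------------
  extra <- if (cfg$non_normalized) "waking_min" else NULL
  fit_args <- list(total = cfg$total, normalize = !cfg$non_normalized)
  importance <- do.call(behaviour_importance_table,
                        c(list(cohort, adjustments = cfg$adjustments), fit_args))
  if (cfg$non_normalized) {
    importance <- do.call(rbind, lapply(names(rotations()), function(rot) {
      m <- fit_compositional_cox(
        cohort, rotation = rot,
        covariates = c(adjustment_covariates("model2"), extra),
        total = cfg$total, normalize = FALSE)
      tab <- coord_hr_table(m)
      tab$rotation <- rot
      tab$adjustment <- "model2+waking"
      tab[, c("rotation", "adjustment", "term", "meaning", "hr", "ci_low",
              "ci_high", "p")]
    }))
  }

  adj_main <- cfg$adjustments[length(cfg$adjustments)]
  model <- fit_compositional_cox(
    cohort, rotation = cfg$rotation,
    covariates = if (cfg$non_normalized)
      c(adjustment_covariates("model2"), extra) else NULL,
    adjustment = adj_main, total = cfg$total,
    normalize = !cfg$non_normalized)
  message(sprintf("[fit] rotation %s, %d events, log partial likelihood %.2f",
                  cfg$rotation, model$n_events, model$loglik))

  # --- references and reallocations ----------------------------------
  refs_mvpa <- lapply(cfg$reference_mvpa, build_reference_mvpa,
                      sb_share = cfg$sb_share, total = cfg$total)
  refs_sb <- lapply(cfg$reference_sb_min, build_reference_sb,
                    mvpa_min = cfg$reference_sb_mvpa, total = cfg$total)
  tab_mvpa <- reallocation_table(model, refs_mvpa, deltas = cfg$deltas)
  tab_sb <- reallocation_table(model, refs_sb, deltas = cfg$deltas)

  ref_b <- refs_mvpa[[min(2, length(refs_mvpa))]]
  surface <- hr_surface(model, ref_b, observed_ranges(cohort),
                        grid_step = cfg$grid_step, total = cfg$total)

  # --- reports --------------------------------------------------------
  paths <- c(
    cohort = file.path(cfg$out_dir, "cohort.csv"),
    exclusions = file.path(cfg$out_dir, "exclusions.csv"),
    importance = file.path(cfg$out_dir, "importance.csv"),
    realloc_mvpa = file.path(cfg$out_dir, "reallocations_mvpa_refs.csv"),
    realloc_sb = file.path(cfg$out_dir, "reallocations_sb_refs.csv"),
    surface = file.path(cfg$out_dir, "surface.csv"))
  utils::write.csv(cohort, paths["cohort"], row.names = FALSE)
  utils::write.csv(exclusions, paths["exclusions"], row.names = FALSE)
  utils::write.csv(importance, paths["importance"], row.names = FALSE)
  utils::write.csv(tab_mvpa, paths["realloc_mvpa"], row.names = FALSE)
  utils::write.csv(tab_sb, paths["realloc_sb"], row.names = FALSE)
  utils::write.csv(surface, paths["surface"], row.names = FALSE)
  if (cfg$write_heatmap) {
    p <- plot_hr_ternary(surface)
    ggplot2::ggsave(file.path(cfg$out_dir, "heatmap.png"), p,
                    width = 6, height = 5, dpi = 150)
    paths <- c(paths, heatmap = file.path(cfg$out_dir, "heatmap.png"))
  }
  message(sprintf("[report] %d files written to %s", length(paths), cfg$out_dir))

  invisible(list(cohort = cohort, exclusions = exclusions,
                 importance = importance, reallocations_mvpa = tab_mvpa,
                 reallocations_sb = tab_sb, surface = surface, model = model,
                 references = c(refs_mvpa, refs_sb), paths = paths))
}
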