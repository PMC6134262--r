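# End-to-end orchestration: simulate or load dual-polarity tables, trim,
# fuse, compute diversity and distances, test, ordinate, classify shifts,
# and fit the richness mixed model -- from one config, with a deterministic
# machine-readable report.

.default_config <- function() {
  list(
    schema_version = "1.0",
    rt_window = c(1, 21),
    match = list(mass_offset = 2.014552, mass_tol = 0.005, rt_tol = 0.10,
                 paper_mode = FALSE),
    presence_threshold = 0,
    threshold_pct = 75,
    n_perm = 999,
    n_boot = 1000,
    nmds_restarts = 10,
    seeds = list(permanova = 101, permdisp = 102, nmds = 103,
                 bootstrap = 104)
  )
}

#' Validate and normalize a pipeline configuration
#'
#' A config is a named list (or path to a YAML file) with either a
#' `simulation` block (`design`, `truth`, optional `species`/`year`) or an
#' `inputs` block (`positive`/`negative`, each the three file paths of the
#' table contract), a `reference` condition label, and optional stage
#' parameters (`rt_window`, `match`, `presence_threshold`, `threshold_pct`,
#' `n_perm`, `n_boot`, `nmds_restarts`, `seeds`). Every stochastic stage has
#' an explicit seed; unspecified parameters take documented defaults which
#' are echoed into the run report.
#'
#' @param config named list or path to a YAML file.
#' @return normalized config list.
#' @export
load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  cfg <- utils::modifyList(.default_config(), config)
  if (is.null(cfg$simulation) && is.null(cfg$inputs))
    stop("config needs either a 'simulation' or an 'inputs' block")
  if (is.null(cfg$reference))
    stop("config must name the reference condition ('reference')")
  for (s in c("permanova", "permdisp", "nmds", "bootstrap"))
    if (is.null(cfg$seeds[[s]])) stop("missing seed for stage: ", s)
  cfg
}

.pipeline_tables <- function(cfg) {
  if (!is.null(cfg$simulation)) {
    sim_cfg <- cfg$simulation
    ds <- design_spec(
      factors = sim_cfg$design$factors,
      replicates_per_cell = sim_cfg$design$replicates_per_cell,
      blocks = if (is.null(sim_cfg$design$blocks)) 1 else sim_cfg$design$blocks,
      plants_per_plot = if (is.null(sim_cfg$design$plants_per_plot)) 1
                        else sim_cfg$design$plants_per_plot
    )
    design <- make_design(
      ds,
      species = if (is.null(sim_cfg$species)) "species1" else sim_cfg$species,
      year = if (is.null(sim_cfg$year)) "Y1" else sim_cfg$year
    )
    truth <- do.call(ground_truth, sim_cfg$truth)
    sim <- simulate_tables(design, truth)
    list(positive = sim$positive, negative = sim$negative, truth = sim$truth)
  } else {
    rd <- function(b) read_feature_table(b$intensity, b$features, b$samples)
    list(positive = rd(cfg$inputs$positive), negative = rd(cfg$inputs$negative),
         truth = NULL)
  }
}

.analyze_group <- function(tbl, cfg) {
  conds <- tbl$samples$condition
  blocks <- tbl$samples$block
  rich <- richness(tbl, cfg$presence_threshold)

  can <- canberra_matrix(tbl)
  bin <- binarize(tbl, cfg$presence_threshold)
  jac <- jaccard_matrix(bin)

  pm_profile <- permanova(can, conds, strata = blocks, n_perm = cfg$n_perm,
                          seed = cfg$seeds$permanova)
  pm_turnover <- permanova(jac, conds, strata = blocks, n_perm = cfg$n_perm,
                           seed = cfg$seeds$permanova)
  disp <- tryCatch(
    permdisp(can, conds, n_perm = cfg$n_perm, seed = cfg$seeds$permdisp),
    error = function(e) NULL)
  md <- meandist_groups(can, conds)
  ord <- nmds(can, k = 2, n_restarts = cfg$nmds_restarts,
              seed = cfg$seeds$nmds)
  ells <- suppressWarnings(group_ellipses(ord, conds))
  shifts <- shift_report(tbl, cfg$reference, cfg$threshold_pct)
  lme_rich <- tryCatch(
    fit_lme(rich, conds, blocks, cfg$reference, response = "richness"),
    error = function(e) NULL)

  list(
    n_samples = nrow(tbl$intensities),
    n_features = ncol(tbl$intensities),
    group_sizes = as.list(table(conds)),
    permanova_profile = list(F = pm_profile$F, r2 = pm_profile$r2,
                             p = pm_profile$p, method = pm_profile$method),
    permanova_turnover = list(F = pm_turnover$F, r2 = pm_turnover$r2,
                              p = pm_turnover$p, method = pm_turnover$method),
    dispersion = if (is.null(disp)) NULL else
      list(F = disp$F, p = disp$p, center_type = disp$center_type),
    mean_dissimilarity = list(
      groups = md$groups, matrix = md$m,
      centroid_separation = md$centroid_separation),
    nmds = list(stress = ord$stress, converged = ord$converged,
                best_restart = ord$best_restart),
    ellipse_groups = names(ells),
    richness = as.list(stats::setNames(rich, tbl$samples$sample_id)),
    lme_richness = if (is.null(lme_rich)) NULL else list(
      fixed_effects = lme_rich$fixed_effects,
      random_intercept_sd = lme_rich$random_intercept_sd,
      residual_sd = lme_rich$residual_sd,
      boundary = lme_rich$boundary),
    shifts = list(
      reference = shifts$reference,
      up_counts = lapply(shifts$up_sets, length),
      down_counts = lapply(shifts$down_sets, length),
      venn_up = if (!is.null(shifts$venn_up)) as.list(shifts$venn_up$counts),
      venn_down = if (!is.null(shifts$venn_down))
        as.list(shifts$venn_down$counts),
      n_undetected = length(shifts$undetected)),
    results = list(canberra = can, jaccard = jac, nmds = ord,
                   shift_report = shifts, permanova_profile = pm_profile,
                   permanova_turnover = pm_turnover, dispersion = disp,
                   meandist = md, lme_richness = lme_rich)
  )
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes, in order: simulation (or table loading), retention-time
#' trimming per polarity, cross-polarity matching and merging, presence/
#' absence binarization and richness, Canberra and Jaccard distance
#' matrices, perMANOVA (profiles and turnover, strata = blocks), dispersion
#' and mean-dissimilarity diagnostics, NMDS with confidence ellipses, the
#' reference-condition shift report, and the richness mixed model. Samples
#' from different years (or species) are analyzed independently of one
#' another — per species-by-year group.
#'
#' All seeds and parameter decisions are echoed into the report, and the
#' report contains nothing time- or machine-dependent: identical config and
#' seeds give a byte-identical report file.
#'
#' @param config config list or YAML path; see [load_config()].
#' @param outdir optional output directory; when given, the merged table,
#'   distance matrices, richness table, NMDS scores and `report.json` are
#'   written there with deterministic filenames.
#' @return the run report (list), invisibly carrying the full result objects
#'   in `groups[[...]]$results`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- load_config(config)
  tabs <- .pipeline_tables(cfg)

  n_pos_in <- ncol(tabs$positive$intensities)
  n_neg_in <- ncol(tabs$negative$intensities)
  pos <- suppressWarnings(
    trim_rt_window(tabs$positive, cfg$rt_window[1], cfg$rt_window[2]))
  neg <- suppressWarnings(
    trim_rt_window(tabs$negative, cfg$rt_window[1], cfg$rt_window[2]))

  mcfg <- match_config(
    mass_offset = cfg$match$mass_offset, mass_tol = cfg$match$mass_tol,
    rt_tol = cfg$match$rt_tol, paper_mode = isTRUE(cfg$match$paper_mode))
  mres <- match_features(pos, neg, mcfg)
  merged <- merge_tables(pos, neg, mres)

  groups <- split(seq_len(nrow(merged$intensities)),
                  paste(merged$samples$species, merged$samples$year, sep = "/"))
  analyses <- lapply(groups, function(idx)
    .analyze_group(subset_features(merged, samples = idx), cfg))

  report <- list(
    schema_version = cfg$schema_version,
    config = cfg[setdiff(names(cfg), "simulation")],
    simulation_seed = if (!is.null(tabs$truth)) tabs$truth$seed,
    counts = list(
      features_positive_in = n_pos_in,
      features_negative_in = n_neg_in,
      features_positive_after_rt_trim = ncol(pos$intensities),
      features_negative_after_rt_trim = ncol(neg$intensities),
      cross_polarity_pairs = nrow(mres$pairs),
      features_after_fusion = ncol(merged$intensities)
    ),
    groups = lapply(analyses, function(a) a[setdiff(names(a), "results")])
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(merged,
                        file.path(outdir, "merged_intensities.csv"),
                        file.path(outdir, "merged_features.csv"),
                        file.path(outdir, "merged_samples.csv"))
    .write_delim(data.frame(pos_id = mres$pairs$pos_id,
                            neg_id = mres$pairs$neg_id,
                            mass_delta = mres$pairs$mass_delta,
                            rt_delta = mres$pairs$rt_delta),
                 file.path(outdir, "match_report.tsv"))
    for (gname in names(analyses)) {
      tag <- gsub("[^A-Za-z0-9]+", "_", gname)
      res <- analyses[[gname]]$results
      utils::write.csv(res$canberra$d,
                       file.path(outdir, paste0(tag, "_canberra.csv")))
      utils::write.csv(res$jaccard$d,
                       file.path(outdir, paste0(tag, "_jaccard.csv")))
      utils::write.table(res$nmds$scores,
                         file.path(outdir, paste0(tag, "_nmds_scores.tsv")),
                         sep = "\t", col.names = NA)
    }
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }

  full <- report
  full$groups <- analyses
  class(full) <- "pipeline_report"
  invisible(full)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report (schema", x$schema_version, ")\n")
  cat("  features after fusion:", x$counts$features_after_fusion,
      "(", x$counts$cross_polarity_pairs, "cross-polarity pairs )\n")
  for (g in names(x$groups)) {
    a <- x$groups[[g]]
    cat(sprintf(
      "  %s: n = %d, features = %d | profile F = %.3g (p = %.3g) | turnover F = %.3g (p = %.3g) | stress = %.3g\n",
      g, a$n_samples, a$n_features,
      a$permanova_profile$F, a$permanova_profile$p,
      a$permanova_turnover$F, a$permanova_turnover$p, a$nmds$stress))
  }
  invisible(x)
}
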