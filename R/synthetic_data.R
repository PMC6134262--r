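#' Describe a blocked factorial (or observational) sampling design
#'
#' @param factors named list; each element is the character vector of levels
#'   of one design factor, e.g.
#'   `list(overstory = c("open", "closed"), warming = c("ambient", "mod", "high"))`.
#' @param replicates_per_cell plots per factor-level combination.
#' @param blocks number of strata; plots are assigned to blocks round-robin
#'   within each factor cell, so blocks are balanced across treatments.
#' @param plants_per_plot plants sampled per plot; each plant yields one
#'   sample.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(factors, replicates_per_cell, blocks = 1,
                        plants_per_plot = 1) {
  if (!is.list(factors) || length(factors) == 0 || is.null(names(factors)) ||
      any(names(factors) == ""))
    stop("factors must be a non-empty named list of level vectors")
  nlev <- vapply(factors, length, integer(1))
  if (any(nlev == 0))
    stop("factor(s) with zero levels: ",
         paste(names(factors)[nlev == 0], collapse = ", "))
  stopifnot(replicates_per_cell >= 1, blocks >= 1, plants_per_plot >= 0)
  structure(
    list(factors = factors,
         replicates_per_cell = as.integer(replicates_per_cell),
         blocks = as.integer(blocks),
         plants_per_plot = as.integer(plants_per_plot)),
    class = "design_spec"
  )
}

#' Expand a design into sample metadata
#'
#' Generates one sample record per plot x plant. The condition label is the
#' concatenation of the factor levels of the plot's cell (joined with `+`),
#' and plots are assigned to blocks round-robin within each cell. The number
#' of plots always equals `replicates_per_cell` times the product of the
#' factor level counts: the default experimental template (2 overstory x 3
#' warming x 2 precipitation levels, 6 replicates) gives 72 plots, and the
#' observational template (2 x 2, 3 replicates) gives 12.
#'
#' @param spec a [design_spec()].
#' @param species species label stamped on every sample.
#' @param year year label (e.g. `"Y1"`).
#' @return data.frame with columns `sample_id`, `species`, `condition`,
#'   `block`, `year`, `plot` — one row per sample, `replicates_per_cell *
#'   prod(levels) * plants_per_plot` rows in total.
#' @export
make_design <- function(spec, species = "species1", year = "Y1") {
  stopifnot(inherits(spec, "design_spec"))
  cells <- expand.grid(spec$factors, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  cond <- apply(cells, 1, paste, collapse = "+")
  reps <- spec$replicates_per_cell

  plot_cond <- rep(cond, each = reps)
  plot_rep <- rep(seq_len(reps), times = length(cond))
  plot_block <- ((plot_rep - 1) %% spec$blocks) + 1
  n_plots <- length(plot_cond)
  plot_id <- sprintf("plot%03d", seq_len(n_plots))

  ppp <- max(spec$plants_per_plot, 1L)
  idx <- rep(seq_len(n_plots), each = ppp)
  plant <- rep(seq_len(ppp), times = n_plots)
  data.frame(
    sample_id = sprintf("%s_pl%d", plot_id[idx], plant),
    species = species,
    condition = plot_cond[idx],
    block = sprintf("block%02d", plot_block[idx]),
    year = year,
    plot = plot_id[idx],
    stringsAsFactors = FALSE
  )
}

#' Ground-truth parameters for the synthetic dual-polarity generator
#'
#' Encodes the statistical structure the downstream analyses assume: a
#' log-normal intensity baseline, multiplicative block and sample noise,
#' condition-specific multiplicative effects on a subset of features
#' (centroid shifts), presence/absence toggles (turnover), and a
#' partially-overlapping positive/negative ionization feature universe
#' offset by roughly the mass of two protons.
#'
#' Defaults emulate a Year-1-scale species group: about 1,900 features and
#' intensities on the 1e5-1e7 scale typical of Orbitrap peak areas.
#'
#' @param seed integer RNG seed; identical seeds give byte-identical tables.
#' @param n_features_total size of the feature universe.
#' @param shared_fraction proportion of features detectable in both
#'   polarities (in `[0, 1]`).
#' @param polarity_offset Daltons between a feature's positive-mode and
#'   negative-mode mass; default the physical \[M+H\]+ vs \[M-H\]- difference
#'   2.014552 Da. See [match_config()] for the paper-replication preset.
#' @param effects named list: condition label -> `list(n_features =, delta =)`
#'   giving the number of features receiving a multiplicative intensity
#'   effect `delta` (> 0) in that condition.
#' @param turnover named list: condition label -> `list(n_features =)` giving
#'   the number of features toggled present/absent in that condition (half
#'   forced absent there, half present only there).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline parameters for
#'   per-feature mean intensity.
#' @param noise_cv coefficient of variation of the multiplicative per-cell
#'   sample noise.
#' @param block_sd standard deviation of the block random effect on log
#'   intensity (shared by all samples of a block).
#' @param dropout_rate baseline probability that a present feature reads 0.
#' @param rt_range retention-time range (minutes) features are drawn from.
#' @param rt_jitter SD (minutes) of cross-polarity retention-time jitter for
#'   shared features; keep below the matching `rt_tol`.
#' @param mass_min_sep minimum spacing (Daltons) between distinct features in
#'   offset-adjusted mass space, so that matching at the default tolerance is
#'   unambiguous.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(seed = 1L,
                         n_features_total = 1900,
                         shared_fraction = 0.3,
                         polarity_offset = 2.014552,
                         effects = list(),
                         turnover = list(),
                         baseline_meanlog = 13,
                         baseline_sdlog = 1.5,
                         noise_cv = 0.25,
                         block_sd = 0.25,
                         dropout_rate = 0.02,
                         rt_range = c(1, 21),
                         rt_jitter = 0.01,
                         mass_min_sep = 0.05) {
  stopifnot(shared_fraction >= 0, shared_fraction <= 1,
            n_features_total >= 1, polarity_offset > 0,
            noise_cv >= 0, block_sd >= 0,
            dropout_rate >= 0, dropout_rate < 1,
            length(rt_range) == 2, rt_range[1] < rt_range[2],
            rt_jitter >= 0, mass_min_sep > 0)
  for (e in effects) {
    stopifnot(is.list(e), !is.null(e$n_features), !is.null(e$delta))
    if (e$delta <= 0) stop("effect delta must be > 0")
  }
  structure(
    list(seed = as.integer(seed), n_features_total = as.integer(n_features_total),
         shared_fraction = shared_fraction, polarity_offset = polarity_offset,
         effects = effects, turnover = turnover,
         baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
         noise_cv = noise_cv, block_sd = block_sd, dropout_rate = dropout_rate,
         rt_range = rt_range, rt_jitter = rt_jitter,
         mass_min_sep = mass_min_sep),
    class = "ground_truth"
  )
}

#' Simulate a pair of polarity-specific feature tables with known truth
#'
#' Draws a feature universe in which a `shared_fraction` of features is
#' detectable in both ionization modes (negative-mode mass = positive-mode
#' mass minus `polarity_offset`, identical retention time up to a jitter
#' below the matching tolerance), then generates intensities as
#' `exp(N(meanlog, sdlog^2)) * block_effect * noise`, multiplied by `delta`
#' for (condition, feature) pairs in the effect sets, and forced absent /
#' present-only-there for turnover features. Present cells additionally drop
#' to 0 with probability `dropout_rate`.
#'
#' @param design sample metadata from [make_design()] (or any data.frame
#'   with `sample_id`, `condition`, `block` columns).
#' @param truth a [ground_truth()].
#' @return list with components `positive` and `negative` (two
#'   [feature_table()]s over the same samples), and `truth`: the input
#'   parameters augmented with the realized memberships —
#'   `shared_pairs` (data.frame `pos_id`, `neg_id`), `effect_features` and
#'   `turnover_features` (per condition, universe feature IDs; turnover split
#'   into `loss`/`gain`), and `presence` bookkeeping matrices per polarity.
#' @export
simulate_tables <- function(design, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  req <- c("sample_id", "condition", "block")
  if (!all(req %in% names(design)))
    stop("design must have columns: ", paste(req, collapse = ", "))
  if (!("species" %in% names(design))) design$species <- "species1"
  if (!("year" %in% names(design))) design$year <- "Y1"

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(truth$seed)

  n <- truth$n_features_total
  uid <- sprintf("met%05d", seq_len(n))

  # detectability classes
  n_shared <- round(truth$shared_fraction * n)
  cls <- rep("pos", n)
  if (n_shared > 0) cls[seq_len(n_shared)] <- "shared"
  rest <- which(cls == "pos")
  if (length(rest) > 1) {
    half <- length(rest) %/% 2
    cls[rest[seq_len(length(rest) - half)]] <- "pos"
    cls[rest[seq.int(length(rest) - half + 1, length(rest))]] <- "neg"
  }
  if (n > 1) cls <- sample(cls) # shuffle class assignment over the universe

  # offset-adjusted ("match-space") masses with guaranteed minimum spacing,
  # so fusion at the default tolerance has no spurious candidates
  span <- 100 + n * truth$mass_min_sep * 4
  gaps <- truth$mass_min_sep +
    stats::rexp(n, rate = n / span)
  mass_adj <- 100 + cumsum(gaps)
  if (n > 1) mass_adj <- sample(mass_adj)
  mass_pos <- mass_adj + truth$polarity_offset
  mass_neg <- mass_adj

  rt <- stats::runif(n, truth$rt_range[1], truth$rt_range[2])
  rt_neg <- rt + if (truth$rt_jitter > 0)
    stats::rnorm(n, 0, truth$rt_jitter) else 0
  rt_neg <- pmax(rt_neg, 1e-3)

  baseline <- stats::rlnorm(n, truth$baseline_meanlog, truth$baseline_sdlog)
  # polarity response: shared molecules ionize with different efficiency per mode
  pol_factor_neg <- stats::rlnorm(n, 0, 0.5)

  conds <- design$condition
  blocks <- design$block
  ns <- nrow(design)
  ublock <- unique(blocks)
  block_eff <- stats::rnorm(length(ublock), 0, truth$block_sd)
  names(block_eff) <- ublock

  # realized effect / turnover memberships (disjoint within a condition)
  effect_features <- list()
  effect_delta <- list()
  turnover_features <- list()
  for (cond in union(names(truth$effects), names(truth$turnover))) {
    if (!(cond %in% conds))
      stop("effect/turnover condition not present in design: ", cond)
    avail <- uid
    ef <- truth$effects[[cond]]
    if (!is.null(ef)) {
      picked <- sample(avail, ef$n_features)
      effect_features[[cond]] <- sort(picked)
      effect_delta[[cond]] <- ef$delta
      avail <- setdiff(avail, picked)
    }
    tv <- truth$turnover[[cond]]
    if (!is.null(tv)) {
      picked <- sample(avail, tv$n_features)
      n_loss <- length(picked) %/% 2
      turnover_features[[cond]] <- list(
        loss = sort(picked[seq_len(n_loss)]),
        gain = sort(picked[seq.int(n_loss + 1, length(picked))])
      )
    }
  }

  sdlog_noise <- sqrt(log(1 + truth$noise_cv^2))

  # presence design: logical ns x n, before dropout
  present <- matrix(TRUE, ns, n)
  for (cond in names(turnover_features)) {
    in_cond <- conds == cond
    loss <- match(turnover_features[[cond]]$loss, uid)
    gain <- match(turnover_features[[cond]]$gain, uid)
    if (length(loss)) present[in_cond, loss] <- FALSE
    if (length(gain)) present[!in_cond, gain] <- FALSE
  }

  mult <- matrix(1, ns, n) # condition effects
  for (cond in names(effect_features)) {
    fi <- match(effect_features[[cond]], uid)
    mult[conds == cond, fi] <- effect_delta[[cond]]
  }

  make_half <- function(which_pol) {
    keep <- if (which_pol == "positive") cls %in% c("shared", "pos")
            else cls %in% c("shared", "neg")
    fi <- which(keep)
    nf <- length(fi)
    noise <- matrix(
      stats::rlnorm(ns * nf, -sdlog_noise^2 / 2, sdlog_noise), ns, nf)
    base <- baseline[fi]
    if (which_pol == "negative") base <- base * pol_factor_neg[fi]
    X <- noise * mult[, fi, drop = FALSE] *
      rep(base, each = ns) * exp(block_eff[blocks])
    X[!present[, fi, drop = FALSE]] <- 0
    if (truth$dropout_rate > 0) {
      drop <- matrix(stats::runif(ns * nf) < truth$dropout_rate, ns, nf)
      X[drop] <- 0
    }
    suffix <- if (which_pol == "positive") "_P" else "_N"
    fm <- data.frame(
      feature_id = paste0(uid[fi], suffix),
      mass = if (which_pol == "positive") mass_pos[fi] else mass_neg[fi],
      rt = if (which_pol == "positive") rt[fi] else rt_neg[fi],
      polarity = which_pol,
      provenance = if (which_pol == "positive") "pos_only" else "neg_only",
      stringsAsFactors = FALSE
    )
    list(tbl = feature_table(X, fm, design[, c("sample_id", "species",
                                               "condition", "block", "year")]),
         fi = fi, presence = X > 0)
  }

  pos <- make_half("positive")
  neg <- make_half("negative")

  shared_idx <- which(cls == "shared")
  shared_pairs <- data.frame(
    pos_id = paste0(uid[shared_idx], "_P"),
    neg_id = paste0(uid[shared_idx], "_N"),
    stringsAsFactors = FALSE
  )

  truth_out <- truth
  truth_out$universe <- data.frame(uid = uid, class = cls,
                                   mass_adjusted = mass_adj, rt = rt,
                                   stringsAsFactors = FALSE)
  truth_out$shared_pairs <- shared_pairs
  truth_out$effect_features <- effect_features
  truth_out$effect_delta <- effect_delta
  truth_out$turnover_features <- turnover_features
  truth_out$presence_positive <- pos$presence
  truth_out$presence_negative <- neg$presence

  list(positive = pos$tbl, negative = neg$tbl, truth = truth_out)
}

#' Write a simulated dataset to a directory
#'
#' Writes the three-file table contract per polarity
#' (`<pol>_intensities.csv`, `<pol>_features.csv`, `<pol>_samples.csv`) plus
#' `ground_truth.json` with the realized effect/turnover memberships and
#' shared pairs. Output is deterministic: identical seeds give byte-identical
#' files.
#'
#' @param sim result of [simulate_tables()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (pol in c("positive", "negative")) {
    write_feature_table(
      sim[[pol]],
      file.path(outdir, paste0(pol, "_intensities.csv")),
      file.path(outdir, paste0(pol, "_features.csv")),
      file.path(outdir, paste0(pol, "_samples.csv"))
    )
  }
  tr <- sim$truth
  gt <- list(
    seed = tr$seed,
    n_features_total = tr$n_features_total,
    shared_fraction = tr$shared_fraction,
    polarity_offset = tr$polarity_offset,
    effect_features = tr$effect_features,
    effect_delta = tr$effect_delta,
    turnover_features = tr$turnover_features,
    shared_pairs = tr$shared_pairs
  )
  jsonlite::write_json(gt, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
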