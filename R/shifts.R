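# Reference-condition contrasts: per-feature relative abundance change,
# >= threshold% shift classification with Venn-set intersections, and
# bootstrap confidence intervals for individual compounds.

#' Venn regions of a collection of sets
#'
#' Enumerates all `2^k - 1` membership signatures over `k` named sets and
#' counts the elements falling in each exclusive region (in all sets of the
#' signature and in no other). Region counts sum to the size of the union.
#'
#' @param sets named list of character vectors.
#' @return list with `counts` (named integer vector, names are
#'   `&`-joined set names) and `members` (list of character vectors).
#' @export
venn_regions <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  k <- length(sets)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, 1, k)
  if (length(universe) == 0) membership <- matrix(FALSE, 0, k)
  counts <- integer(0)
  members <- list()
  for (m in seq_len(2^k - 1)) {
    sig <- as.logical(bitwAnd(m, 2^(seq_len(k) - 1)))
    name <- paste(names(sets)[sig], collapse = "&")
    inside <- if (length(universe) == 0) logical(0)
      else apply(membership, 1, function(row) all(row == sig))
    counts[name] <- sum(inside)
    members[[name]] <- universe[inside]
  }
  list(counts = counts, members = members)
}

#' Classify per-feature abundance shifts relative to a reference condition
#'
#' For every non-reference condition, computes the percent change of each
#' feature's condition-mean intensity relative to the reference-condition
#' mean, `100 * (mean_cond - mean_ref) / mean_ref` (arithmetic means over
#' samples, zeros included), and classifies features whose change is at least
#' `+threshold_pct` (up) or at most `-threshold_pct` (down), both bounds
#' inclusive. Features undetected in the reference (`mean_ref = 0`) are
#' routed to `undetected` and excluded from the percent-change sets. The up
#' and down sets are intersected Venn-style across conditions.
#'
#' @param tbl a [feature_table()].
#' @param reference reference condition label (must exist in the table).
#' @param threshold_pct classification threshold in percent (default 75).
#' @param normalize if `TRUE`, divide each sample by its total intensity
#'   before computing means (off by default; raw intensities are the
#'   conventional "relative abundance" for background-subtracted tables).
#' @return An object of class `shift_report`: `reference`, `conditions`,
#'   `relative_change` (features x conditions matrix, percent; NA rows for
#'   undetected features), `up_sets`, `down_sets` (per condition),
#'   `venn_up`, `venn_down` ([venn_regions()] output), `undetected`,
#'   `threshold_pct`, `normalized`.
#' @export
shift_report <- function(tbl, reference, threshold_pct = 75,
                         normalize = FALSE) {
  stopifnot(inherits(tbl, "feature_table"), threshold_pct > 0)
  conds <- tbl$samples$condition
  if (!(reference %in% conds))
    stop("unknown reference condition: ", reference)
  X <- tbl$intensities
  if (normalize) {
    tot <- rowSums(X)
    tot[tot == 0] <- 1
    X <- X / tot
  }
  lev <- unique(conds)
  means <- do.call(rbind, lapply(lev, function(cc)
    colMeans(X[conds == cc, , drop = FALSE])))
  rownames(means) <- lev

  mean_ref <- means[reference, ]
  undetected <- colnames(X)[mean_ref == 0]
  others <- setdiff(lev, reference)

  rc <- matrix(NA_real_, ncol(X), length(others),
               dimnames = list(colnames(X), others))
  ok <- mean_ref > 0
  for (cc in others)
    rc[ok, cc] <- 100 * (means[cc, ok] - mean_ref[ok]) / mean_ref[ok]

  up_sets <- lapply(others, function(cc)
    rownames(rc)[!is.na(rc[, cc]) & rc[, cc] >= threshold_pct])
  down_sets <- lapply(others, function(cc)
    rownames(rc)[!is.na(rc[, cc]) & rc[, cc] <= -threshold_pct])
  names(up_sets) <- names(down_sets) <- others

  structure(
    list(reference = reference, conditions = others,
         relative_change = rc, up_sets = up_sets, down_sets = down_sets,
         venn_up = if (length(others) > 0) venn_regions(up_sets) else NULL,
         venn_down = if (length(others) > 0) venn_regions(down_sets) else NULL,
         undetected = undetected, threshold_pct = threshold_pct,
         normalized = isTRUE(normalize)),
    class = "shift_report"
  )
}

#' @export
print.shift_report <- function(x, ...) {
  cat("shift_report vs reference '", x$reference, "' (threshold ",
      x$threshold_pct, "%):\n", sep = "")
  for (cc in x$conditions)
    cat(sprintf("  %s: %d up, %d down\n", cc,
                length(x$up_sets[[cc]]), length(x$down_sets[[cc]])))
  if (length(x$undetected) > 0)
    cat("  ", length(x$undetected), "features undetected in reference\n")
  invisible(x)
}

#' Bootstrap confidence interval for one compound's relative abundance change
#'
#' Resamples samples with replacement independently within the condition and
#' the reference group, recomputes the percent change of the group means per
#' replicate, and reports the percentile confidence interval. Replicates
#' whose resampled reference mean is 0 are dropped and counted. A condition
#' group that is all zeros is reported as absent (`absent_flag = TRUE`,
#' relative change -100%, degenerate CI) — the "undetected in all samples"
#' case.
#'
#' @param tbl a [feature_table()].
#' @param feature feature ID.
#' @param condition,reference condition labels; both groups need >= 2
#'   samples.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return An object of class `compound_contrast`: `feature_id`,
#'   `condition`, `reference`, `relative_change` (percent), `ci_low`,
#'   `ci_high`, `n_boot`, `n_dropped` (replicates with zero resampled
#'   reference mean), `seed`, `level`, `significant` (CI excludes 0),
#'   `absent_flag`.
#' @export
bootstrap_contrast <- function(tbl, feature, condition, reference,
                               n_boot = 2000, seed = 1L, level = 0.95) {
  stopifnot(inherits(tbl, "feature_table"))
  fi <- match(feature, tbl$features$feature_id)
  if (is.na(fi)) stop("feature not found in table: ", feature)
  conds <- tbl$samples$condition
  x_cond <- tbl$intensities[conds == condition, fi]
  x_ref <- tbl$intensities[conds == reference, fi]
  if (length(x_cond) < 2 || length(x_ref) < 2)
    stop("both groups need >= 2 samples")
  if (mean(x_ref) == 0)
    stop("feature undetected in the reference group; relative change undefined")

  rel <- function(mc, mr) 100 * (mc - mr) / mr

  if (all(x_cond == 0)) {
    return(structure(
      list(feature_id = feature, condition = condition, reference = reference,
           relative_change = -100, ci_low = -100, ci_high = -100,
           n_boot = n_boot, n_dropped = 0L, seed = seed, level = level,
           significant = TRUE, absent_flag = TRUE),
      class = "compound_contrast"
    ))
  }

  point <- rel(mean(x_cond), mean(x_ref))

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  nc <- length(x_cond)
  nr <- length(x_ref)
  mc <- rowMeans(matrix(x_cond[sample.int(nc, nc * n_boot, replace = TRUE)],
                        n_boot, nc))
  mr <- rowMeans(matrix(x_ref[sample.int(nr, nr * n_boot, replace = TRUE)],
                        n_boot, nr))
  keep <- mr > 0
  n_dropped <- sum(!keep)
  reps <- rel(mc[keep], mr[keep])
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha)))

  structure(
    list(feature_id = feature, condition = condition, reference = reference,
         relative_change = point, ci_low = ci[1], ci_high = ci[2],
         n_boot = n_boot, n_dropped = n_dropped, seed = seed, level = level,
         significant = ci[1] > 0 || ci[2] < 0, absent_flag = FALSE),
    class = "compound_contrast"
  )
}

#' @export
print.compound_contrast <- function(x, ...) {
  cat(sprintf(
    "%s, %s vs %s: %+.1f%% [%.1f, %.1f] (%d boot%s)%s\n",
    x$feature_id, x$condition, x$reference, x$relative_change,
    x$ci_low, x$ci_high, x$n_boot,
    if (x$n_dropped > 0) paste0(", ", x$n_dropped, " dropped") else "",
    if (x$absent_flag) " [absent in condition]"
    else if (x$significant) " *" else ""))
  invisible(x)
}
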