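# Random-intercept linear mixed models for phytochemical richness and
# compound abundance, with treatment contrasts against a reference condition.

#' Fit a random-intercept mixed model with contrasts against a reference
#'
#' Fits `y = intercept + condition + (1 | grouping) + residual` by restricted
#' maximum likelihood (via [nlme::lme()]) with the condition factor releveled
#' so that every fixed-effect estimate is the contrast of a condition against
#' the `reference` level. P-values are Wald-type tests from the model's
#' coefficient table (residual-df approximation). The grouping unit is the
#' experimental block or observational site.
#'
#' A fit whose random-intercept variance collapses to (near) zero is valid
#' and flagged with `boundary = TRUE`; in balanced data it reduces to
#' ordinary least squares on group means. A constant response is handled
#' without calling the optimizer and flagged `degenerate = TRUE`.
#'
#' @param y numeric response per sample (richness or compound abundance).
#' @param condition per-sample condition labels (>= 2 levels).
#' @param grouping per-sample block/site labels (>= 2 units).
#' @param reference condition level used as the contrast baseline.
#' @param response label recorded in the result (`"richness"` or
#'   `"abundance"`).
#' @return An object of class `lme_result`: `fixed_effects` (data.frame with
#'   `level`, `estimate` — 0 for the reference by construction —, `se`,
#'   `df`, `p`), `random_intercept_sd`, `residual_sd`, `n_obs`, `n_groups`,
#'   `fit_method = "REML"`, `boundary`, `degenerate`, `reference`,
#'   `response`.
#' @export
fit_lme <- function(y, condition, grouping, reference,
                    response = c("richness", "abundance")) {
  response <- match.arg(response)
  condition <- droplevels(factor(condition))
  grouping <- droplevels(factor(grouping))
  stopifnot(length(y) == length(condition), length(y) == length(grouping))
  if (nlevels(condition) < 2) stop("need >= 2 condition levels")
  if (nlevels(grouping) < 2) stop("need >= 2 grouping units")
  if (!(reference %in% levels(condition)))
    stop("reference level not found: ", reference)
  condition <- stats::relevel(condition, ref = reference)
  others <- levels(condition)[-1]

  fe_frame <- function(est, se, df, p) {
    data.frame(level = c(reference, others),
               estimate = c(0, est), se = c(NA, se),
               df = c(NA, df), p = c(NA, p),
               stringsAsFactors = FALSE)
  }

  if (stats::sd(y) == 0) {
    k <- length(others)
    return(structure(
      list(fixed_effects = fe_frame(rep(0, k), rep(0, k), rep(NA, k),
                                    rep(NA, k)),
           random_intercept_sd = 0, residual_sd = 0,
           n_obs = length(y), n_groups = nlevels(grouping),
           fit_method = "REML", boundary = TRUE, degenerate = TRUE,
           reference = reference, response = response),
      class = "lme_result"
    ))
  }

  dat <- data.frame(y = y, condition = condition, grouping = grouping)
  fit <- tryCatch(
    nlme::lme(y ~ condition, random = ~ 1 | grouping, data = dat,
              method = "REML"),
    error = function(e)
      nlme::lme(y ~ condition, random = ~ 1 | grouping, data = dat,
                method = "REML",
                control = nlme::lmeControl(opt = "optim"))
  )

  tt <- summary(fit)$tTable
  rows <- paste0("condition", others)
  est <- tt[rows, "Value"]
  se <- tt[rows, "Std.Error"]
  df <- tt[rows, "DF"]
  p <- tt[rows, "p-value"]

  vc <- nlme::VarCorr(fit)
  ri_sd <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
  res_sd <- fit$sigma

  structure(
    list(fixed_effects = fe_frame(unname(est), unname(se), unname(df),
                                  unname(p)),
         random_intercept_sd = ri_sd, residual_sd = res_sd,
         n_obs = nrow(dat), n_groups = nlevels(grouping),
         fit_method = "REML",
         boundary = is.finite(ri_sd) && ri_sd < 1e-6 * max(res_sd, 1e-12),
         degenerate = FALSE,
         reference = reference, response = response),
    class = "lme_result"
  )
}

#' @export
print.lme_result <- function(x, ...) {
  cat(sprintf("LME (%s, REML): %d obs, %d groups; random-intercept sd %.4g, residual sd %.4g\n",
              x$response, x$n_obs, x$n_groups, x$random_intercept_sd,
              x$residual_sd))
  fe <- x$fixed_effects
  for (i in seq_len(nrow(fe))) {
    if (fe$level[i] == x$reference) next
    cat(sprintf("  %s vs %s: delta = %.4g (se %.3g), p = %.4g\n",
                fe$level[i], x$reference, fe$estimate[i], fe$se[i], fe$p[i]))
  }
  if (x$boundary) cat("  note: random-intercept variance at boundary\n")
  invisible(x)
}
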