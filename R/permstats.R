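# Permutational MANOVA, multivariate dispersion, and mean-dissimilarity
# decomposition on distance matrices, with strata-restricted permutations.

.coerce_dist <- function(D) {
  if (inherits(D, "distance_matrix")) return(D$d)
  if (inherits(D, "dist")) return(as.matrix(D))
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("D must be a square distance matrix")
  D
}

# one random permutation of 1..n that shuffles only within strata
.perm_within_strata <- function(n, strata_idx) {
  if (is.null(strata_idx)) return(sample.int(n))
  p <- seq_len(n)
  for (s in strata_idx) p[s] <- s[sample.int(length(s))]
  p
}

# all permutations of 1..n as a (n! x n) matrix
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

# all within-strata permutations of 1..n (rows); count = prod(size_i!)
.all_perms_strata <- function(n, strata_idx) {
  if (is.null(strata_idx)) return(.all_perms(n))
  per <- lapply(strata_idx, function(s) {
    ap <- .all_perms(length(s))
    matrix(s[ap], nrow(ap), ncol(ap))
  })
  grid <- do.call(expand.grid, lapply(per, function(m) seq_len(nrow(m))))
  out <- matrix(rep(seq_len(n), each = nrow(grid)), nrow(grid), n)
  for (k in seq_along(per))
    out[, strata_idx[[k]]] <- per[[k]][grid[[k]], , drop = FALSE]
  out
}

.n_exact_perms <- function(n, strata_idx) {
  if (is.null(strata_idx)) return(factorial(n))
  prod(vapply(strata_idx, function(s) factorial(length(s)), numeric(1)))
}

# within/total squared-distance partition for a label assignment
.permanova_stat <- function(W, g_idx, nper, N, a, SS_T) {
  ssw <- 0
  for (k in seq_along(g_idx)) {
    idx <- g_idx[[k]]
    ssw <- ssw + sum(W[idx, idx]) / (2 * nper[[k]])
  }
  ssa <- SS_T - ssw
  if (ssw <= 0) return(c(F = Inf, r2 = ssa / SS_T, ssw = ssw))
  c(F = (ssa / (a - 1)) / (ssw / (N - a)), r2 = ssa / SS_T, ssw = ssw)
}

#' Permutational MANOVA on a distance matrix
#'
#' Partitions the total sum of squared dissimilarities into between- and
#' within-group components: `SS_T = (1/N) sum_{i<j} d_ij^2`,
#' `SS_W = sum_g (1/n_g) sum_{i<j in g} d_ij^2`, `SS_A = SS_T - SS_W`,
#' `pseudo-F = (SS_A/(a-1)) / (SS_W/(N-a))`, `r2 = SS_A/SS_T`. The null
#' distribution comes from permutations of the group labels; when `strata`
#' is given, labels are shuffled only within strata, so the test respects a
#' blocked sampling design.
#'
#' When the number of distinct within-strata permutations does not exceed
#' `n_perm` (and `method = "auto"`), the test enumerates all of them and the
#' p-value is exact: `p = #(F_perm >= F_obs) / n_total`, the identity
#' permutation included. Otherwise `n_perm` random permutations are drawn and
#' `p = (#(F_perm >= F_obs) + 1) / (n_perm + 1)`, so p is never 0.
#'
#' @param D a [distance_matrix()], `dist`, or square symmetric matrix.
#' @param groups per-sample group labels (>= 2 groups).
#' @param strata optional per-sample stratum labels restricting permutations.
#' @param n_perm number of random permutations (default 9999, small enough
#'   p-resolution for permutation p-values down to 1e-4).
#' @param seed integer seed for the permutation stream; results are
#'   reproducible bit-for-bit given `(seed, n_perm)`.
#' @param method `"auto"` (exact enumeration when cheaper than `n_perm`
#'   draws), `"exact"`, or `"monte_carlo"`.
#' @return An object of class `permanova_result`: `F`, `r2`, `p`, `n_perm`
#'   (permutations actually evaluated, identity excluded in Monte-Carlo
#'   mode), `df_between`, `df_within`, `observed_ge_count`, `method`,
#'   `degenerate` (TRUE when all within-group distances are zero, in which
#'   case `F` is `Inf`), and the SS decomposition.
#' @export
permanova <- function(D, groups, strata = NULL, n_perm = 9999, seed = 1L,
                      method = c("auto", "exact", "monte_carlo")) {
  method <- match.arg(method)
  d <- .coerce_dist(D)
  N <- nrow(d)
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (length(groups) != N) stop("groups length must match D")
  a <- nlevels(groups)
  if (a < 2) stop("permanova needs at least 2 groups")
  strata_idx <- NULL
  if (!is.null(strata)) {
    if (length(strata) != N) stop("strata length must match D")
    strata_idx <- split(seq_len(N), strata)
  }

  W <- d^2
  SS_T <- sum(W[upper.tri(W)]) / N
  g_idx <- split(seq_len(N), groups)
  nper <- vapply(g_idx, length, integer(1))
  obs <- .permanova_stat(W, g_idx, nper, N, a, SS_T)
  F_obs <- obs["F"]
  degenerate <- !is.finite(F_obs)

  n_exact <- .n_exact_perms(N, strata_idx)
  use_exact <- switch(method,
    exact = TRUE,
    monte_carlo = FALSE,
    auto = n_exact <= n_perm
  )
  if (use_exact && n_exact > 1e6)
    stop("exact enumeration infeasible: ", n_exact, " permutations")

  stat_for <- function(perm) {
    gp <- groups[perm]
    gi <- split(seq_len(N), gp)
    .permanova_stat(W, gi, vapply(gi, length, integer(1)), N, a, SS_T)["F"]
  }

  eps <- 1e-12 * max(1, abs(F_obs[is.finite(F_obs)]), na.rm = TRUE)
  if (length(eps) == 0 || is.na(eps)) eps <- 1e-12
  if (use_exact) {
    P <- .all_perms_strata(N, strata_idx)
    Fp <- apply(P, 1, stat_for)
    cnt <- sum(Fp >= F_obs - eps) # Inf >= Inf covers the degenerate case
    p <- cnt / nrow(P)
    n_used <- nrow(P)
  } else {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      Fp <- stat_for(.perm_within_strata(N, strata_idx))
      if (Fp >= F_obs - eps) cnt <- cnt + 1L
    }
    p <- (cnt + 1) / (n_perm + 1)
    n_used <- n_perm
  }

  structure(
    list(F = unname(F_obs), r2 = unname(obs["r2"]), p = p, n_perm = n_used,
         df_between = a - 1L, df_within = N - a,
         observed_ge_count = cnt,
         method = if (use_exact) "exact" else "monte_carlo",
         degenerate = degenerate,
         SS_total = SS_T, SS_between = SS_T - unname(obs["ssw"]),
         SS_within = unname(obs["ssw"]), seed = seed),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "perMANOVA: pseudo-F = %.4g (df %d, %d), r2 = %.4g, p = %.4g [%s, %d perms]\n",
    x$F, x$df_between, x$df_within, x$r2, x$p, x$method, x$n_perm))
  if (x$degenerate) cat("  note: all within-group distances zero (degenerate)\n")
  invisible(x)
}

#' Multivariate homogeneity of dispersion (distance to group center)
#'
#' Embeds the distance matrix by principal-coordinates analysis
#' (eigendecomposition of the Gower-centered matrix), retaining both
#' positive- and negative-eigenvalue axes. Each sample's distance to its
#' group center is `z = sqrt(max(0, dr^2 - di^2))` where `dr`/`di` are
#' distances along the real (positive-eigenvalue) and imaginary
#' (negative-eigenvalue) axes. Group differences in dispersion are tested by
#' a classical one-way ANOVA F on `z` with a permutation p-value (labels of
#' `z` permuted).
#'
#' @param D a [distance_matrix()], `dist`, or square symmetric matrix.
#' @param groups per-sample labels; at least 2 groups with >= 2 samples each.
#' @param center_type `"spatial_median"` (iteratively reweighted; default) or
#'   `"centroid"` (group mean in PCoA space).
#' @param n_perm number of label permutations for the p-value.
#' @param seed integer seed for the permutation stream.
#' @return An object of class `dispersion_result`: `distances_to_center`
#'   (per sample), `group_centers` (real-axis coordinates), `F`, `p`,
#'   `center_type`, `eigenvalues`.
#' @export
permdisp <- function(D, groups, center_type = c("spatial_median", "centroid"),
                     n_perm = 999, seed = 1L) {
  center_type <- match.arg(center_type)
  d <- .coerce_dist(D)
  N <- nrow(d)
  groups <- droplevels(factor(groups))
  if (length(groups) != N) stop("groups length must match D")
  sizes <- table(groups)
  if (nlevels(groups) < 2 || any(sizes < 2))
    stop("permdisp needs >= 2 groups with >= 2 samples each")

  # principal coordinates, keeping real and imaginary axes
  A <- -0.5 * d^2
  G <- sweep(A, 1, rowMeans(A))
  G <- sweep(G, 2, colMeans(G))
  G <- (G + t(G)) / 2
  eg <- eigen(G, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-8
  if (max(abs(eg$values)) < 1e-12) stop("degenerate geometry: all eigenvalues ~ 0")
  pos <- eg$values > tol
  neg <- eg$values < -tol
  Vr <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(eg$values[pos]), sum(pos))
  Vi <- eg$vectors[, neg, drop = FALSE] %*% diag(sqrt(-eg$values[neg]), sum(neg))

  center_of <- function(M) {
    if (ncol(M) == 0) return(numeric(0))
    if (center_type == "centroid") colMeans(M) else .spatial_median(M)
  }

  z <- numeric(N)
  centers_r <- matrix(NA_real_, nlevels(groups), ncol(Vr),
                      dimnames = list(levels(groups), NULL))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    cr <- center_of(Vr[idx, , drop = FALSE])
    ci <- center_of(Vi[idx, , drop = FALSE])
    centers_r[g, ] <- cr
    dr2 <- rowSums(sweep(Vr[idx, , drop = FALSE], 2, cr)^2)
    di2 <- if (ncol(Vi) > 0)
      rowSums(sweep(Vi[idx, , drop = FALSE], 2, ci)^2) else 0
    z[idx] <- sqrt(pmax(0, dr2 - di2))
  }

  anova_F <- function(y, g) {
    gm <- tapply(y, g, mean)
    ssb <- sum(table(g) * (gm - mean(y))^2)
    ssw <- sum((y - gm[g])^2)
    a <- nlevels(g)
    if (ssb < 1e-14 * max(1, ssw)) return(0)
    if (ssw <= 0) return(Inf)
    (ssb / (a - 1)) / (ssw / (length(y) - a))
  }
  F_obs <- anova_F(z, groups)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    Fp <- anova_F(z, groups[sample.int(N)])
    if (Fp >= F_obs - 1e-12) cnt <- cnt + 1L
  }

  structure(
    list(distances_to_center = stats::setNames(z, rownames(d)),
         group_centers = centers_r,
         F = F_obs, p = (cnt + 1) / (n_perm + 1), n_perm = n_perm,
         center_type = center_type, eigenvalues = eg$values, seed = seed),
    class = "dispersion_result"
  )
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("permdisp (%s): F = %.4g, p = %.4g [%d perms]\n",
              x$center_type, x$F, x$p, x$n_perm))
  invisible(x)
}

# geometric (spatial) median by damped Weiszfeld iteration
.spatial_median <- function(X, max_iter = 200, tol = 1e-10) {
  if (nrow(X) == 1) return(X[1, ])
  m <- colMeans(X)
  for (it in seq_len(max_iter)) {
    dd <- sqrt(rowSums(sweep(X, 2, m)^2))
    dd <- pmax(dd, 1e-12)
    w <- 1 / dd
    m_new <- colSums(X * w) / sum(w)
    if (sqrt(sum((m_new - m)^2)) < tol * (1 + sqrt(sum(m^2)))) {
      m <- m_new
      break
    }
    m <- m_new
  }
  m
}

#' Mean within- and between-group dissimilarities
#'
#' Averages the entries of a distance matrix within and between groups: the
#' diagonal of the result holds mean within-group dissimilarity (NA and
#' flagged for singleton groups, which have no within pairs), off-diagonals
#' the mean between-group dissimilarity. A between-group mean exceeding both
#' within-group means indicates centroid separation rather than a dispersion
#' difference.
#'
#' @param D a [distance_matrix()], `dist`, or square symmetric matrix.
#' @param groups per-sample group labels.
#' @return An object of class `mean_dissimilarity`: `groups`, `m` (g x g
#'   matrix), `centroid_separation` (logical g x g, TRUE where between >
#'   both withins), `singleton` (logical per group).
#' @export
meandist_groups <- function(D, groups) {
  d <- .coerce_dist(D)
  groups <- droplevels(factor(groups))
  if (length(groups) != nrow(d)) stop("groups length must match D")
  lev <- levels(groups)
  g <- length(lev)
  m <- matrix(NA_real_, g, g, dimnames = list(lev, lev))
  for (i in seq_len(g)) {
    ii <- which(groups == lev[i])
    if (length(ii) > 1) {
      sub <- d[ii, ii]
      m[i, i] <- mean(sub[upper.tri(sub)])
    }
    for (j in seq_len(g)) {
      if (j <= i) next
      jj <- which(groups == lev[j])
      m[i, j] <- m[j, i] <- mean(d[ii, jj])
    }
  }
  sep <- matrix(FALSE, g, g, dimnames = list(lev, lev))
  for (i in seq_len(g)) for (j in seq_len(g)) {
    if (i != j && !is.na(m[i, i]) && !is.na(m[j, j]))
      sep[i, j] <- m[i, j] > m[i, i] && m[i, j] > m[j, j]
  }
  structure(
    list(groups = lev, m = m, centroid_separation = sep,
         singleton = stats::setNames(tabulate(groups, g) == 1, lev)),
    class = "mean_dissimilarity"
  )
}

#' @export
print.mean_dissimilarity <- function(x, ...) {
  cat("mean dissimilarity matrix (diagonal = within-group):\n")
  print(round(x$m, 4))
  invisible(x)
}
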