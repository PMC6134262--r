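# Non-metric multidimensional scaling (Kruskal stress-1) by iterative
# majorization alternated with isotonic regression, and standard-error
# confidence ellipses for sample groups.

.config_dist <- function(X) as.matrix(stats::dist(X))

# Kruskal stress-1 of configuration X against dissimilarities dvec,
# with the isotonic fit dhat of config distances on the rank order of dvec.
# Primary treatment of ties: within tied dissimilarities, pairs are ordered
# by current configuration distance, so ties impose no constraint.
.stress1 <- function(dvec, cvec) {
  ord <- order(dvec, cvec)
  dhat <- numeric(length(cvec))
  dhat[ord] <- stats::isoreg(cvec[ord])$yf
  denom <- sum(cvec^2)
  if (denom <= 0) return(list(stress = Inf, dhat = dhat))
  list(stress = sqrt(sum((cvec - dhat)^2) / denom), dhat = dhat)
}

# one majorization (Guttman transform) step toward target disparities dhat
.guttman <- function(X, dmat, dhat_mat) {
  n <- nrow(X)
  ratio <- matrix(0, n, n)
  nz <- dmat > 0
  ratio[nz] <- dhat_mat[nz] / dmat[nz]
  B <- -ratio
  diag(B) <- 0
  diag(B) <- -rowSums(B)
  (B %*% X) / n
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Finds a k-dimensional configuration minimizing Kruskal stress-1,
#' `sqrt(sum((dhat - d_config)^2) / sum(d_config^2))`, where `dhat` is the
#' isotonic (monotone non-decreasing) regression of configuration distances
#' on the rank order of the input dissimilarities. Optimization alternates
#' isotonic regression with iterative majorization (Guttman transform),
#' accepting a step only if stress does not increase (with step halving as a
#' fallback), so the recorded stress sequence is non-increasing on every
#' restart. Restarts are one principal-coordinates start plus
#' `n_restarts - 1` random starts; the lowest-stress solution is returned,
#' centered and rotated to its principal axes.
#'
#' @param D a [distance_matrix()], `dist`, or square symmetric matrix.
#' @param k target dimensionality (default 2, the conventional choice for
#'   visualizing metabolite profiles); requires `n >= k + 1`.
#' @param n_restarts total number of starts (default 20).
#' @param max_iter maximum majorization iterations per restart.
#' @param tol convergence tolerance on the stress decrease per iteration.
#' @param seed integer seed for the random starts.
#' @return An object of class `nmds_result`: `scores` (n x k, centered,
#'   principal-axis rotated), `stress`, `converged`, `n_restarts`,
#'   `best_restart`, `stress_trace` (per-iteration stress of the best
#'   restart), `seed`.
#' @export
nmds <- function(D, k = 2, n_restarts = 20, max_iter = 300, tol = 1e-7,
                 seed = 1L) {
  d <- .coerce_dist(D)
  n <- nrow(d)
  if (k >= n) stop("nmds needs n >= k + 1")
  lower <- lower.tri(d)
  dvec <- d[lower]

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  pcoa_start <- function() {
    A <- -0.5 * d^2
    G <- sweep(A, 1, rowMeans(A))
    G <- sweep(G, 2, colMeans(G))
    G <- (G + t(G)) / 2
    eg <- eigen(G, symmetric = TRUE)
    ax <- seq_len(k)
    X <- eg$vectors[, ax, drop = FALSE] %*%
      diag(sqrt(pmax(eg$values[ax], 1e-12)), k)
    X
  }

  run_restart <- function(X) {
    trace <- numeric(0)
    cmat <- .config_dist(X)
    st <- .stress1(dvec, cmat[lower])
    trace <- st$stress
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      dhat_mat <- matrix(0, n, n)
      dhat_mat[lower] <- st$dhat
      dhat_mat <- dhat_mat + t(dhat_mat)
      Xc <- .guttman(X, cmat, dhat_mat)
      accepted <- FALSE
      step <- 1
      for (try in 1:6) {
        Xn <- X + step * (Xc - X)
        cn <- .config_dist(Xn)
        sn <- .stress1(dvec, cn[lower])
        if (is.finite(sn$stress) && sn$stress <= st$stress + 1e-14) {
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted) { # no descent direction left: local optimum
        converged <- TRUE
        break
      }
      improve <- st$stress - sn$stress
      X <- Xn; cmat <- cn; st <- sn
      trace <- c(trace, st$stress)
      if (!is.finite(improve) || improve < tol) {
        converged <- TRUE
        break
      }
      if (st$stress < 1e-12) { # exact embedding reached
        converged <- TRUE
        break
      }
    }
    list(X = X, stress = st$stress, trace = trace, converged = converged)
  }

  best <- NULL
  best_i <- 0L
  scl <- stats::sd(dvec)
  if (!is.finite(scl) || scl <= 0) scl <- max(mean(dvec), 1)
  for (r in seq_len(n_restarts)) {
    X0 <- if (r == 1) pcoa_start()
          else matrix(stats::rnorm(n * k), n, k) * scl
    res <- run_restart(X0)
    if (is.null(best) || res$stress < best$stress) {
      best <- res
      best_i <- r
    }
  }

  # center and rotate to principal axes
  X <- scale(best$X, center = TRUE, scale = FALSE)
  sv <- svd(X)
  X <- X %*% sv$v
  dimnames(X) <- list(rownames(d), paste0("NMDS", seq_len(k)))

  structure(
    list(scores = X, stress = best$stress, converged = best$converged,
         n_restarts = n_restarts, best_restart = best_i,
         stress_trace = best$trace, k = k, seed = seed),
    class = "nmds_result"
  )
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS (k = %d): stress = %.6g, %s after %d restarts (best: #%d)\n",
              x$k, x$stress, if (x$converged) "converged" else "not converged",
              x$n_restarts, x$best_restart))
  invisible(x)
}

#' Standard-error confidence ellipses for ordination groups
#'
#' For each group with at least 3 samples, the ellipse
#' `{x : (x - c)' (Cov/n_g)^{-1} (x - c) <= q}` with `c` the group mean
#' score, `Cov` the group score covariance, and `q` the `level` quantile of
#' the chi-squared distribution with `k` degrees of freedom — a confidence
#' region for the group centroid (standard-error ellipse), so its area
#' shrinks as 1/n_g for fixed covariance. Groups with fewer than 3 samples
#' are skipped with a warning; a singular covariance produces a degenerate
#' ellipse flag.
#'
#' @param res an [nmds_result()] (or any list with a `scores` matrix).
#' @param groups per-sample labels aligned with the score rows.
#' @param level confidence level (default 0.95).
#' @return list of per-group ellipse parameter lists: `group`, `center`,
#'   `covariance` (the SE covariance `Cov/n_g`), `radius_scale`
#'   (`sqrt(q)`), `level`, `n`, `degenerate`.
#' @export
group_ellipses <- function(res, groups, level = 0.95) {
  scores <- if (is.list(res)) res$scores else res
  scores <- as.matrix(scores)
  groups <- droplevels(factor(groups))
  if (length(groups) != nrow(scores))
    stop("groups length must match score rows")
  k <- ncol(scores)
  q <- stats::qchisq(level, df = k)
  out <- list()
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 3) {
      warning("group '", g, "' has fewer than 3 samples; ellipse skipped")
      next
    }
    S <- scores[idx, , drop = FALSE]
    ctr <- colMeans(S)
    Cov <- stats::cov(S) / length(idx)
    degenerate <- FALSE
    if (!all(is.finite(Cov)) || det(Cov) <= 1e-30) {
      warning("group '", g, "' has a singular score covariance; ",
              "degenerate ellipse (major axis only)")
      degenerate <- TRUE
    }
    out[[g]] <- list(group = g, center = ctr, covariance = Cov,
                     radius_scale = sqrt(q), level = level,
                     n = length(idx), degenerate = degenerate)
  }
  out
}

#' Boundary polygon of a confidence ellipse
#'
#' @param ell one element of the [group_ellipses()] result (k = 2 only).
#' @param n_points number of polygon vertices.
#' @return `n_points` x 2 matrix tracing the ellipse boundary.
#' @export
ellipse_points <- function(ell, n_points = 100) {
  stopifnot(length(ell$center) == 2)
  theta <- seq(0, 2 * pi, length.out = n_points)
  circle <- cbind(cos(theta), sin(theta))
  ev <- eigen(ell$covariance, symmetric = TRUE)
  half <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
  sweep(circle %*% (ell$radius_scale * half), 2, ell$center, "+")
}

#' Area of a 2-D confidence ellipse
#'
#' @param ell one element of the [group_ellipses()] result (k = 2 only).
#' @return ellipse area (`pi * q * sqrt(det(Cov/n))` for k = 2).
#' @export
ellipse_area <- function(ell) {
  stopifnot(length(ell$center) == 2)
  pi * ell$radius_scale^2 * sqrt(max(det(ell$covariance), 0))
}
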