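#' Construct a distance-matrix object
#'
#' @param d symmetric numeric matrix with zero diagonal.
#' @param sample_ids sample identifiers (default: rownames of `d`).
#' @param metric one of `"canberra"`, `"jaccard"`, `"euclidean"`.
#' @return An object of class `distance_matrix`.
#' @export
distance_matrix <- function(d, sample_ids = rownames(d),
                            metric = c("canberra", "jaccard", "euclidean")) {
  metric <- match.arg(metric)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-10) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  if (any(d < 0)) stop("distances must be nonnegative")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(d)))
  dimnames(d) <- list(sample_ids, sample_ids)
  structure(list(sample_ids = as.character(sample_ids), d = d, metric = metric),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("distance_matrix (", x$metric, "): ", length(x$sample_ids),
      " samples\n", sep = "")
  invisible(x)
}

#' Coerce to a plain `dist` object
#' @param dm a [distance_matrix()].
#' @return a [stats::dist] object.
#' @export
as_dist <- function(dm) {
  stopifnot(inherits(dm, "distance_matrix"))
  stats::as.dist(dm$d)
}

#' Binarize a feature table to presence/absence
#'
#' Entry is 1 iff intensity is strictly greater than `threshold`. The default
#' threshold 0 means any positive intensity counts as presence, appropriate
#' for background-subtracted peak tables; it is exposed as a first-class
#' parameter for sensitivity analysis.
#'
#' @param tbl a [feature_table()] or a numeric samples x features matrix.
#' @param threshold nonnegative intensity cutoff.
#' @return binary (0/1) samples x features matrix.
#' @export
binarize <- function(tbl, threshold = 0) {
  stopifnot(threshold >= 0)
  X <- if (inherits(tbl, "feature_table")) tbl$intensities else as.matrix(tbl)
  B <- (X > threshold) + 0
  dimnames(B) <- dimnames(X)
  B
}

#' Phytochemical richness per sample
#'
#' Number of features present in each sample (presence = intensity above
#' `threshold`).
#'
#' @inheritParams binarize
#' @return named integer vector, one count per sample.
#' @export
richness <- function(tbl, threshold = 0) {
  rowSums(binarize(tbl, threshold))
}

#' Canberra dissimilarity matrix of metabolite profiles
#'
#' For samples x and y, `d(x, y) = (1/NZ) * sum_i |x_i - y_i| / (x_i + y_i)`
#' where the sum and the count NZ run only over features with
#' `x_i + y_i > 0` (double zeros excluded). With this per-pair normalization
#' the distance lies in `[0, 1]`; `raw = TRUE` returns the unnormalized
#' Canberra sum instead. A pair of all-zero samples has no comparable
#' components; its distance is defined as 0 with a warning.
#'
#' @param tbl a [feature_table()] or nonnegative samples x features matrix.
#' @param raw if `TRUE`, skip the division by NZ.
#' @return a [distance_matrix()] with metric `"canberra"`.
#' @export
canberra_matrix <- function(tbl, raw = FALSE) {
  X <- if (inherits(tbl, "feature_table")) tbl$intensities else as.matrix(tbl)
  if (any(X < 0)) stop("Canberra requires nonnegative intensities")
  n <- nrow(X)
  d <- matrix(0, n, n)
  warned <- FALSE
  for (i in seq_len(max(n - 1, 0))) {
    xi <- X[i, ]
    for (j in seq.int(i + 1, n)) {
      yj <- X[j, ]
      s <- xi + yj
      nz <- s > 0
      NZ <- sum(nz)
      if (NZ == 0) {
        if (!warned) {
          warning("sample pair(s) with no nonzero features; distance set to 0")
          warned <- TRUE
        }
        val <- 0
      } else {
        val <- sum(abs(xi[nz] - yj[nz]) / s[nz])
        if (!raw) val <- val / NZ
      }
      d[i, j] <- d[j, i] <- val
    }
  }
  distance_matrix(d, rownames(X), "canberra")
}

#' Jaccard dissimilarity matrix of presence/absence profiles
#'
#' For presence sets A and B, `d(A, B) = 1 - |A intersect B| / |A union B|`.
#' Quantifies phytochemical turnover: which features are present, ignoring
#' abundance. A pair of all-absent samples has an empty union; its distance
#' is defined as 0 with a warning.
#'
#' @param b binary samples x features matrix (e.g. from [binarize()]), or a
#'   [feature_table()] which is binarized at threshold 0 first.
#' @return a [distance_matrix()] with metric `"jaccard"`.
#' @export
jaccard_matrix <- function(b) {
  if (inherits(b, "feature_table")) b <- binarize(b)
  b <- as.matrix(b)
  if (!all(b %in% c(0, 1))) stop("Jaccard requires a binary matrix")
  n <- nrow(b)
  inter <- tcrossprod(b)          # |A intersect B|
  sizes <- rowSums(b)
  uni <- outer(sizes, sizes, "+") - inter
  d <- matrix(0, n, n)
  pos <- uni > 0
  d[pos] <- 1 - inter[pos] / uni[pos]
  off <- !pos
  diag(off) <- FALSE
  if (any(off)) warning("sample pair(s) with empty union; distance set to 0")
  diag(d) <- 0
  distance_matrix(d, rownames(b), "jaccard")
}
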