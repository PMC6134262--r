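# shared fixture builders and independent oracle helpers

tiny_table <- function() {
  X <- matrix(c(0, 5.2, 0, 1.1,
                2.5, 0, 3.3, 0,
                1, 1, 1, 1), nrow = 3, byrow = TRUE)
  feature_table(
    X,
    data.frame(feature_id = paste0("f", 1:4),
               mass = c(150.1, 220.2, 310.3, 440.4),
               rt = c(1.5, 5.0, 12.0, 20.5),
               polarity = "positive", provenance = "pos_only",
               stringsAsFactors = FALSE),
    data.frame(sample_id = paste0("s", 1:3), species = "sp",
               condition = c("ref", "trt", "trt"),
               block = c("b1", "b1", "b2"), year = "Y1",
               stringsAsFactors = FALSE)
  )
}

# feature table straight from an intensity matrix and a condition vector
make_table <- function(X, conds, blocks = NULL, rt = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(blocks)) blocks <- rep("b1", n)
  if (is.null(rt)) rt <- seq(2, 20, length.out = p)
  feature_table(
    X,
    data.frame(feature_id = sprintf("f%03d", seq_len(p)),
               mass = 100 + seq_len(p), rt = rt,
               polarity = "positive", provenance = "pos_only",
               stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("s%03d", seq_len(n)), species = "sp",
               condition = conds, block = blocks, year = "Y1",
               stringsAsFactors = FALSE)
  )
}

# least-squares similarity transform of Y onto X; RMSE of residuals
procrustes_rmse <- function(X, Y) {
  Xc <- scale(as.matrix(X), scale = FALSE)
  Yc <- scale(as.matrix(Y), scale = FALSE)
  s <- svd(t(Yc) %*% Xc)
  R <- s$u %*% t(s$v)
  cc <- sum(s$d) / sum(Yc^2)
  E <- Xc - cc * Yc %*% R
  sqrt(mean(rowSums(E^2)))
}

# brute-force pool-adjacent-violators isotonic regression, unit weights
pava_oracle <- function(y) {
  blocks <- lapply(y, function(v) list(sum = v, n = 1))
  i <- 2
  while (i <= length(blocks)) {
    if (blocks[[i - 1]]$sum / blocks[[i - 1]]$n >
        blocks[[i]]$sum / blocks[[i]]$n) {
      blocks[[i - 1]] <- list(sum = blocks[[i - 1]]$sum + blocks[[i]]$sum,
                              n = blocks[[i - 1]]$n + blocks[[i]]$n)
      blocks[[i]] <- NULL
      if (i > 2) i <- i - 1
    } else i <- i + 1
  }
  unlist(lapply(blocks, function(b) rep(b$sum / b$n, b$n)))
}

# brute-force pseudo-F over all label assignments of a small instance
bruteforce_permanova <- function(d, groups) {
  d <- as.matrix(d)
  N <- nrow(d)
  groups <- factor(groups)
  a <- nlevels(groups)
  W <- d^2
  SS_T <- sum(W[upper.tri(W)]) / N
  f_of <- function(g) {
    ssw <- 0
    for (lv in levels(groups)) {
      idx <- which(g == lv)
      ssw <- ssw + sum(W[idx, idx]) / (2 * length(idx))
    }
    ((SS_T - ssw) / (a - 1)) / (ssw / (N - a))
  }
  F_obs <- f_of(groups)
  # all distinct label assignments = distinct orderings of the label multiset
  perms <- unique(combinat_perms(as.character(groups)))
  Fs <- vapply(perms, function(g) f_of(factor(g, levels = levels(groups))),
               numeric(1))
  list(F = F_obs, p = mean(Fs >= F_obs - 1e-12), n_assignments = length(perms))
}

# all orderings of a character vector (small n only)
combinat_perms <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(combinat_perms(x[-i]), function(r) c(x[i], r)))
  out
}
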