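#' Construct a dual-polarity LC-MS feature table
#'
#' A `feature_table` is the in-memory form of an untargeted LC-MS peak table:
#' a samples x features intensity matrix together with per-feature annotations
#' (mass, retention time, ionization polarity, provenance) and per-sample
#' metadata (species, condition, block, year). Intensity 0 is the canonical
#' encoding of "feature absent in this sample".
#'
#' @param intensities numeric matrix, samples in rows, features in columns,
#'   all entries nonnegative. Missing values are coerced to 0 (with a message
#'   reporting the count), because presence/absence analyses require a
#'   complete matrix.
#' @param features data.frame with columns `feature_id`, `mass` (Daltons,
#'   > 0), `rt` (minutes, > 0), `polarity` (one of `"positive"`,
#'   `"negative"`, `"both"`) and `provenance` (one of `"pos_only"`,
#'   `"neg_only"`, `"merged"`). For merged features `polarity` records which
#'   mode's intensities were retained.
#' @param samples data.frame with columns `sample_id`, `species`,
#'   `condition`, `block`, `year`; extra columns are preserved untouched.
#'
#' @return An object of class `feature_table`.
#' @seealso [read_feature_table()], [write_feature_table()],
#'   [trim_rt_window()]
#' @export
feature_table <- function(intensities, features, samples) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)

  n_na <- sum(is.na(intensities))
  if (n_na > 0) {
    message("feature_table: coerced ", n_na, " missing intensity cells to 0")
    intensities[is.na(intensities)] <- 0
  }

  tbl <- structure(
    list(intensities = intensities, features = features, samples = samples),
    class = "feature_table"
  )
  validate_feature_table(tbl)
}

#' Validate a feature table's structural invariants
#'
#' Checks dimension agreement between the intensity matrix and the metadata
#' tables, uniqueness of feature and sample identifiers, nonnegativity of
#' intensities, and the domain constraints on feature annotations
#' (mass > 0, rt > 0, polarity and provenance levels).
#'
#' @param tbl a [feature_table()].
#' @return `tbl`, invisibly unchanged, if valid; otherwise an error naming
#'   the offending axis or entries.
#' @export
validate_feature_table <- function(tbl) {
  stopifnot(inherits(tbl, "feature_table"))
  X <- tbl$intensities
  fm <- tbl$features
  sm <- tbl$samples

  req_f <- c("feature_id", "mass", "rt", "polarity", "provenance")
  req_s <- c("sample_id", "species", "condition", "block", "year")
  miss_f <- setdiff(req_f, names(fm))
  if (length(miss_f) > 0)
    stop("feature metadata is missing column(s): ", paste(miss_f, collapse = ", "))
  miss_s <- setdiff(req_s, names(sm))
  if (length(miss_s) > 0)
    stop("sample metadata is missing column(s): ", paste(miss_s, collapse = ", "))

  if (ncol(X) != nrow(fm))
    stop("dimension mismatch on the feature axis: intensity matrix has ",
         ncol(X), " feature columns but feature metadata has ", nrow(fm), " rows")
  if (nrow(X) != nrow(sm))
    stop("dimension mismatch on the sample axis: intensity matrix has ",
         nrow(X), " sample rows but sample metadata has ", nrow(sm), " rows")

  dup_f <- unique(fm$feature_id[duplicated(fm$feature_id)])
  if (length(dup_f) > 0)
    stop("duplicate feature_id(s): ", paste(dup_f, collapse = ", "))
  dup_s <- unique(sm$sample_id[duplicated(sm$sample_id)])
  if (length(dup_s) > 0)
    stop("duplicate sample_id(s): ", paste(dup_s, collapse = ", "))

  if (any(X < 0))
    stop("negative intensity value(s) found; intensities must be nonnegative")
  if (any(!is.finite(X)))
    stop("non-finite intensity value(s) found")

  if (any(!is.finite(fm$mass)) || any(fm$mass <= 0))
    stop("feature masses must be positive reals")
  if (any(!is.finite(fm$rt)) || any(fm$rt <= 0))
    stop("feature retention times must be positive reals")
  bad_pol <- setdiff(unique(fm$polarity), c("positive", "negative", "both"))
  if (length(bad_pol) > 0)
    stop("invalid polarity value(s): ", paste(bad_pol, collapse = ", "))
  bad_prov <- setdiff(unique(fm$provenance), c("pos_only", "neg_only", "merged"))
  if (length(bad_prov) > 0)
    stop("invalid provenance value(s): ", paste(bad_prov, collapse = ", "))

  dimnames(tbl$intensities) <- list(sm$sample_id, fm$feature_id)
  invisible(tbl)
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$intensities), "samples x",
      ncol(x$intensities), "features\n")
  prov <- table(x$features$provenance)
  cat("  provenance:", paste(names(prov), prov, sep = "=", collapse = ", "), "\n")
  cat("  conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Read a feature table from its three-file CSV/TSV contract
#'
#' The on-disk contract is three delimited files: an intensity file whose
#' first column is `sample_id` and remaining columns are feature IDs; a
#' feature metadata file with columns `feature_id`, `mass`, `rt`,
#' `polarity`, `provenance`; and a sample metadata file with columns
#' `sample_id`, `species`, `condition`, `block`, `year` (extra columns are
#' preserved). The delimiter is inferred from the file extension
#' (`.tsv` = tab, otherwise comma). Blank or NA intensity cells are coerced
#' to 0 with a reported count.
#'
#' @param intensity_path,feature_meta_path,sample_meta_path file paths.
#' @return A validated [feature_table()].
#' @export
read_feature_table <- function(intensity_path, feature_meta_path,
                               sample_meta_path) {
  for (p in c(intensity_path, feature_meta_path, sample_meta_path))
    if (!file.exists(p)) stop("file not found: ", p)

  ints <- .read_delim(intensity_path)
  fm <- .read_delim(feature_meta_path)
  sm <- .read_delim(sample_meta_path)

  if (names(ints)[1] != "sample_id")
    stop("intensity file: first column must be 'sample_id', found '",
         names(ints)[1], "'")
  X <- as.matrix(ints[, -1, drop = FALSE])
  rownames(X) <- ints$sample_id
  if (!identical(colnames(X), as.character(fm$feature_id))) {
    if (!setequal(colnames(X), fm$feature_id))
      stop("dimension mismatch on the feature axis: intensity columns and ",
           "feature metadata feature_ids differ")
    fm <- fm[match(colnames(X), fm$feature_id), , drop = FALSE]
  }
  if (!identical(rownames(X), as.character(sm$sample_id))) {
    if (!setequal(rownames(X), sm$sample_id))
      stop("dimension mismatch on the sample axis: intensity rows and ",
           "sample metadata sample_ids differ")
    sm <- sm[match(rownames(X), sm$sample_id), , drop = FALSE]
  }
  rownames(fm) <- NULL
  rownames(sm) <- NULL
  feature_table(X, fm, sm)
}

#' Write a feature table to the three-file CSV/TSV contract
#'
#' Inverse of [read_feature_table()]; the round trip is lossless to full
#' double precision (values are written with 15 significant digits).
#'
#' @param tbl a [feature_table()].
#' @param intensity_path,feature_meta_path,sample_meta_path output paths;
#'   a `.tsv` extension selects tab delimiting, anything else comma.
#' @return The three paths, invisibly.
#' @export
write_feature_table <- function(tbl, intensity_path, feature_meta_path,
                                sample_meta_path) {
  stopifnot(inherits(tbl, "feature_table"))
  ints <- data.frame(sample_id = tbl$samples$sample_id,
                     tbl$intensities, check.names = FALSE,
                     stringsAsFactors = FALSE)
  .write_delim(ints, intensity_path)
  .write_delim(tbl$features, feature_meta_path)
  .write_delim(tbl$samples, sample_meta_path)
  invisible(c(intensity_path, feature_meta_path, sample_meta_path))
}

.read_delim <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "")
}

.write_delim <- function(df, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    # full-precision text so the round trip is lossless
    ifelse(is.na(x), NA_character_, formatC(x, digits = 15, format = "g"))
  })
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Subset a feature table by feature or sample index
#'
#' @param tbl a [feature_table()].
#' @param features,samples integer or logical index vectors (default: keep
#'   all).
#' @return A [feature_table()] restricted to the selected axes.
#' @export
subset_features <- function(tbl, features = NULL, samples = NULL) {
  stopifnot(inherits(tbl, "feature_table"))
  fi <- if (is.null(features)) seq_len(ncol(tbl$intensities)) else features
  si <- if (is.null(samples)) seq_len(nrow(tbl$intensities)) else samples
  fm <- tbl$features[fi, , drop = FALSE]
  sm <- tbl$samples[si, , drop = FALSE]
  rownames(fm) <- NULL
  rownames(sm) <- NULL
  feature_table(tbl$intensities[si, fi, drop = FALSE], fm, sm)
}

#' Trim a feature table to a retention-time window
#'
#' Keeps exactly the features whose retention time lies inside the window,
#' both bounds inclusive, so boundary peaks are never silently dropped. The
#' sample list is unchanged. The conventional analysis window for these data
#' is 1 to 21 minutes.
#'
#' @param tbl a [feature_table()].
#' @param rt_min,rt_max window bounds in minutes, `rt_min < rt_max`.
#' @return A [feature_table()] with the retained features. An empty result
#'   is valid and raises a warning, not an error.
#' @export
trim_rt_window <- function(tbl, rt_min = 1, rt_max = 21) {
  stopifnot(inherits(tbl, "feature_table"))
  if (!(rt_min < rt_max)) stop("rt_min must be < rt_max")
  keep <- tbl$features$rt >= rt_min & tbl$features$rt <= rt_max
  if (!any(keep))
    warning("trim_rt_window: no features inside [", rt_min, ", ", rt_max, "]")
  subset_features(tbl, features = which(keep))
}
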