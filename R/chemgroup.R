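#' Define an RT x m/z bucketing grid
#'
#' Fixed grid for discretising LC-MS feature lists: linear bins of
#' \code{rt_width_s} seconds on retention time and multiplicative
#' (constant-ppm) bins on m/z anchored at the range minimum. The study
#' defaults are 30-1080 s, 100-1600 m/z, 12 s x 5 ppm.
#'
#' @param rt_range Numeric length-2, half-open RT window [min, max) in
#'   seconds.
#' @param rt_width_s RT bin width in seconds (> 0).
#' @param mz_range Numeric length-2, half-open m/z window [min, max).
#' @param mz_ppm Multiplicative m/z bin width in ppm (> 0).
#' @return An object of class \code{"bucket_grid"}.
#' @export
bucket_grid <- function(rt_range = c(30, 1080), rt_width_s = 12,
                        mz_range = c(100, 1600), mz_ppm = 5) {
  stopifnot(length(rt_range) == 2L, length(mz_range) == 2L,
            rt_range[1] < rt_range[2], mz_range[1] < mz_range[2],
            mz_range[1] > 0, rt_width_s > 0, mz_ppm > 0)
  structure(list(rt_range = as.numeric(rt_range),
                 rt_width_s = as.numeric(rt_width_s),
                 mz_range = as.numeric(mz_range),
                 mz_ppm = as.numeric(mz_ppm)),
            class = "bucket_grid")
}

#' Bucket one feature list onto a grid
#'
#' Maps each feature (rt_s, mz, intensity) to a bucket: RT bin index
#' floor((rt - rt_min) / rt_width), m/z bin index
#' floor(log(mz / mz_min) / log(1 + ppm * 1e-6)). Intensities of
#' features sharing a bucket are summed, untransformed. Features
#' outside either range are dropped and counted, not an error.
#'
#' @param features data.frame with columns \code{rt_s}, \code{mz},
#'   \code{intensity}.
#' @param grid A \code{\link{bucket_grid}}.
#' @return List with \code{buckets} (named numeric vector, names
#'   "rtbin_mzbin" of zero-based bin indices) and \code{n_dropped}.
#' @examples
#' g <- bucket_grid()
#' bucketize(data.frame(rt_s = 35, mz = 500, intensity = 1), g)
#' @export
bucketize <- function(features, grid) {
  stopifnot(inherits(grid, "bucket_grid"))
  features <- .as_feature_df(features)
  in_rt <- features$rt_s >= grid$rt_range[1] & features$rt_s < grid$rt_range[2]
  in_mz <- features$mz >= grid$mz_range[1] & features$mz < grid$mz_range[2]
  keep <- in_rt & in_mz
  f <- features[keep, , drop = FALSE]
  rt_bin <- floor((f$rt_s - grid$rt_range[1]) / grid$rt_width_s)
  mz_bin <- floor(log(f$mz / grid$mz_range[1]) / log1p(grid$mz_ppm * 1e-6))
  key <- paste(rt_bin, mz_bin, sep = "_")
  vals <- tapply(f$intensity, key, sum)
  buckets <- as.numeric(vals)
  names(buckets) <- names(vals)
  list(buckets = buckets, n_dropped = sum(!keep))
}

#' Exclude samples with too few detected features
#'
#' Samples whose feature list holds strictly fewer than
#' \code{min_features} rows are set aside before similarity analysis
#' (study rule: fewer than 50 features).
#'
#' @param feature_lists Named list of feature data.frames.
#' @param min_features Minimum feature count to retain (default 50).
#' @return List with \code{retained} and \code{excluded} (both named
#'   lists of feature data.frames).
#' @export
feature_count_filter <- function(feature_lists, min_features = 50L) {
  stopifnot(is.list(feature_lists), min_features >= 0)
  n <- vapply(feature_lists, nrow, integer(1))
  list(retained = feature_lists[n >= min_features],
       excluded = feature_lists[n < min_features])
}

#' Build the sample x bucket intensity table
#'
#' Buckets every retained feature list onto a common grid and assembles
#' the sample x bucket matrix; bucket columns that are zero across all
#' samples are dropped.
#'
#' @param feature_lists Named list of feature data.frames (one per
#'   sample).
#' @param grid A \code{\link{bucket_grid}}.
#' @return An object of class \code{"bucket_table"}: list with
#'   \code{intensities} (matrix samples x buckets), \code{grid},
#'   \code{n_dropped} (per-sample out-of-range feature counts).
#' @export
bucket_table <- function(feature_lists, grid = bucket_grid()) {
  stopifnot(is.list(feature_lists), length(feature_lists) >= 1L)
  if (is.null(names(feature_lists)))
    names(feature_lists) <- paste0("S", seq_along(feature_lists))
  bl <- lapply(feature_lists, bucketize, grid = grid)
  keys <- sort(unique(unlist(lapply(bl, function(b) names(b$buckets)))))
  m <- matrix(0, nrow = length(bl), ncol = length(keys),
              dimnames = list(names(feature_lists), keys))
  for (i in seq_along(bl))
    m[i, names(bl[[i]]$buckets)] <- bl[[i]]$buckets
  m <- m[, colSums(m) > 0, drop = FALSE]
  structure(list(intensities = m, grid = grid,
                 n_dropped = vapply(bl, `[[`, numeric(1), "n_dropped")),
            class = "bucket_table")
}

#' Pairwise cosine similarity between samples
#'
#' S(i, j) = x_i . x_j / (|x_i| |x_j|) over bucket vectors; the
#' diagonal is exactly 1. Rows with zero norm are rejected by name --
#' they should have been removed by \code{\link{feature_count_filter}}.
#'
#' @param x A \code{\link{bucket_table}} or a numeric matrix with
#'   samples in rows.
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
cosine_matrix <- function(x) {
  m <- if (inherits(x, "bucket_table")) x$intensities else as.matrix(x)
  stopifnot(is.numeric(m), nrow(m) >= 2L)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0))
    stop("zero-intensity sample(s): ",
         paste(rownames(m)[nrm == 0], collapse = ", "))
  s <- (m %*% t(m)) / outer(nrm, nrm)
  s[s > 1] <- 1
  diag(s) <- 1
  s
}

#' Order samples by hierarchical clustering
#'
#' Agglomerative clustering on distance 1 - S and extraction of the
#' dendrogram leaf order. Samples are pre-sorted by label so that the
#' leaf order (and hence downstream group assignment) is invariant to
#' the input ordering.
#'
#' @param S Symmetric similarity matrix with unit diagonal.
#' @param linkage Linkage method for \code{\link[stats]{hclust}};
#'   default \code{"average"}.
#' @return Character vector: sample labels in dendrogram leaf order.
#' @export
order_samples <- function(S, linkage = "average") {
  .check_similarity(S)
  if (is.null(rownames(S)))
    rownames(S) <- colnames(S) <- paste0("S", seq_len(nrow(S)))
  lab <- sort(rownames(S))
  S <- S[lab, lab]
  if (nrow(S) == 2L) return(lab)
  hc <- stats::hclust(stats::as.dist(1 - S), method = linkage)
  lab[hc$order]
}

#' Assign metabolic groups along the clustering order
#'
#' Walks the leaf order and starts a new group whenever the cosine
#' similarity between two subsequent samples drops below the threshold;
#' adjacent pairs at or above the threshold share a group (the rule is
#' "0.9 or higher", so ties group together).
#'
#' @param ordered_samples Character vector of sample labels in leaf
#'   order.
#' @param consecutive_sims Numeric vector of length
#'   \code{length(ordered_samples) - 1}: similarity between each
#'   adjacent ordered pair.
#' @param threshold Similarity cut (default 0.9).
#' @return An object of class \code{"metabolic_grouping"}: list with
#'   \code{ordered_samples}, \code{consecutive_sims}, \code{groups}
#'   (named integer vector, ids contiguous from 1), \code{threshold}.
#' @examples
#' assign_groups(paste0("s", 1:4), c(0.95, 0.85, 0.92))$groups
#' @export
assign_groups <- function(ordered_samples, consecutive_sims,
                          threshold = 0.9) {
  n <- length(ordered_samples)
  if (length(consecutive_sims) != n - 1L)
    stop("'consecutive_sims' must have length ", n - 1L)
  grp <- integer(n)
  grp[1] <- 1L
  for (i in seq_len(n - 1L))
    grp[i + 1L] <- if (consecutive_sims[i] >= threshold) grp[i]
                   else grp[i] + 1L
  names(grp) <- ordered_samples
  structure(list(ordered_samples = ordered_samples,
                 consecutive_sims = consecutive_sims,
                 groups = grp, threshold = threshold),
            class = "metabolic_grouping")
}

#' @export
print.metabolic_grouping <- function(x, ...) {
  cat(sprintf("Metabolic grouping: %d samples in %d groups (threshold %g)\n",
              length(x$groups), max(x$groups), x$threshold))
  invisible(x)
}

#' Full metabolic redundancy grouping of extracts
#'
#' End-to-end convenience wrapper: feature-count filter, bucketing,
#' cosine similarity, clustering order and sequential group assignment.
#'
#' @param feature_lists Named list of feature data.frames.
#' @param grid A \code{\link{bucket_grid}}.
#' @param min_features Feature-count exclusion threshold (default 50).
#' @param threshold Grouping similarity cut (default 0.9).
#' @param linkage Clustering linkage (default \code{"average"}).
#' @return A \code{"metabolic_grouping"} with extra elements
#'   \code{similarity} (full cosine matrix) and \code{excluded}
#'   (labels of samples removed by the feature filter).
#' @export
metabolic_grouping <- function(feature_lists, grid = bucket_grid(),
                               min_features = 50L, threshold = 0.9,
                               linkage = "average") {
  flt <- feature_count_filter(feature_lists, min_features)
  if (length(flt$retained) < 2L)
    stop("fewer than 2 samples survive the feature-count filter")
  bt <- bucket_table(flt$retained, grid)
  S <- cosine_matrix(bt)
  ord <- order_samples(S, linkage)
  sims <- S[cbind(ord[-length(ord)], ord[-1])]
  g <- assign_groups(ord, sims, threshold)
  g$similarity <- S
  g$excluded <- names(flt$excluded)
  g
}

#' Read per-sample LC-MS feature lists
#'
#' Reads either one CSV per sample (columns \code{rt_s,mz,intensity};
#' sample ids from file names) or a single long-format CSV with an
#' additional \code{sample} column.
#'
#' @param paths Character vector of CSV paths (length 1 for the
#'   long format when the file has a \code{sample} column).
#' @return Named list of feature data.frames.
#' @export
read_feature_lists <- function(paths) {
  stopifnot(length(paths) >= 1L)
  first <- utils::read.csv(paths[1], stringsAsFactors = FALSE)
  if ("sample" %in% names(first) && length(paths) == 1L) {
    return(split(first[, c("rt_s", "mz", "intensity")], first$sample))
  }
  out <- lapply(paths, function(p)
    .as_feature_df(utils::read.csv(p, stringsAsFactors = FALSE)))
  names(out) <- sub("\\.csv$", "", basename(paths))
  out
}

.as_feature_df <- function(features) {
  if (!is.data.frame(features) ||
      !all(c("rt_s", "mz", "intensity") %in% names(features)))
    stop("features must be a data.frame with rt_s, mz, intensity")
  if (any(!is.finite(features$rt_s)) || any(!is.finite(features$mz)) ||
      any(features$mz <= 0) || any(features$intensity < 0))
    stop("invalid feature values: rt_s/mz must be finite, mz > 0, intensity >= 0")
  features
}

.check_similarity <- function(S, tol = 1e-8) {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop("similarity matrix must be square")
  if (max(abs(S - t(S))) > tol) stop("similarity matrix must be symmetric")
  if (max(abs(diag(S) - 1)) > tol) stop("similarity matrix must have unit diagonal")
  if (is.null(rownames(S)))
    rownames(S) <- colnames(S) <- paste0("S", seq_len(nrow(S)))
  invisible(TRUE)
}
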