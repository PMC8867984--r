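#' Register electrophoretic band sizes onto a shared registry
#'
#' Fragment sizes measured on different lanes never agree exactly, so
#' before set comparison the raw per-strain size lists are merged into a
#' shared band registry by single linkage: two sizes belong to the same
#' registry band if they are within \code{tolerance} (relative) of each
#' other, chained transitively. Each strain's bands are then expressed
#' as registry ids.
#'
#' @param raw_sizes Named list; one numeric vector of fragment sizes
#'   (base pairs, > 0) per strain.
#' @param tolerance Relative size tolerance for merging (default 0.02,
#'   i.e. 2 percent).
#' @return An object of class \code{"fingerprint_set"}: list with
#'   \code{bands} (named list of integer registry-id vectors per
#'   strain) and \code{registry} (numeric vector of representative
#'   sizes, one per registry band).
#' @examples
#' register_bands(list(a = c(1000, 2000), b = c(1015, 2000)))
#' @export
register_bands <- function(raw_sizes, tolerance = 0.02) {
  stopifnot(is.list(raw_sizes), length(raw_sizes) >= 1L, tolerance >= 0)
  if (is.null(names(raw_sizes)))
    names(raw_sizes) <- paste0("strain", seq_along(raw_sizes))
  all_sizes <- unlist(raw_sizes, use.names = FALSE)
  if (any(!is.finite(all_sizes)) || any(all_sizes <= 0))
    stop("band sizes must be finite and > 0")
  u <- sort(unique(all_sizes))
  # single-linkage chain: break where the gap to the previous size
  # exceeds the relative tolerance
  band_id <- integer(length(u))
  band_id[1] <- 1L
  if (length(u) > 1L) {
    for (i in 2:length(u)) {
      gap_ok <- (u[i] - u[i - 1]) / u[i - 1] <= tolerance
      band_id[i] <- if (gap_ok) band_id[i - 1] else band_id[i - 1] + 1L
    }
  }
  registry <- as.numeric(tapply(u, band_id, stats::median))
  lookup <- stats::setNames(band_id, as.character(u))
  bands <- lapply(raw_sizes, function(s)
    sort(unique(unname(lookup[as.character(sort(unique(s)))]))))
  structure(list(bands = bands, registry = registry),
            class = "fingerprint_set")
}

#' Dice similarity between two band sets
#'
#' 2 |A intersect B| / (|A| + |B|) on registered band-id sets; 1 iff the
#' sets are identical, 0 iff disjoint.
#'
#' @param a,b Vectors of band identifiers (nonempty).
#' @return Similarity in [0, 1].
#' @examples
#' dice_similarity(c(1, 2, 3), c(2, 3, 4))  # 0.667
#' @export
dice_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("empty fingerprint: Dice similarity undefined")
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Pairwise Dice similarity matrix for a fingerprint set
#'
#' @param fps A \code{"fingerprint_set"} from
#'   \code{\link{register_bands}}, or a named list of band-id vectors.
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
dice_matrix <- function(fps) {
  bands <- if (inherits(fps, "fingerprint_set")) fps$bands else fps
  stopifnot(is.list(bands), length(bands) >= 2L)
  n <- length(bands)
  S <- diag(1, n)
  dimnames(S) <- list(names(bands), names(bands))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    S[i, j] <- S[j, i] <- dice_similarity(bands[[i]], bands[[j]])
  }
  S
}

#' Ward clustering of a similarity matrix
#'
#' Agglomerative clustering with the Ward objective applied to the
#' dissimilarities 1 - S via the Lance-Williams update (method
#' \code{"ward.D"}). Applying Ward to a non-Euclidean 1 - Dice matrix is
#' mathematically informal but is the standard practice in fingerprint
#' analysis; merge heights remain monotone non-decreasing.
#'
#' @param S Symmetric similarity matrix with unit diagonal (e.g. from
#'   \code{\link{dice_matrix}}).
#' @return An \code{\link[stats]{hclust}} object.
#' @export
ward_cluster <- function(S) {
  .check_similarity(S)
  if (is.null(rownames(S)))
    rownames(S) <- colnames(S) <- paste0("S", seq_len(nrow(S)))
  stats::hclust(stats::as.dist(1 - S), method = "ward.D")
}

#' Superimpose genotype clusters and metabolic groups
#'
#' Cuts the genotype dendrogram at \code{cut} (distance) and crosses
#' the resulting clusters with the metabolic groups of each strain's
#' extracts. Strains sharing both a genotype cluster and a metabolic
#' group are declared redundant ("equal"); one representative per
#' redundancy class is nominated deterministically (lexicographically
#' smallest strain id). Strains alone in their (cluster x group) cell
#' are "unique". Strains missing from the metabolic grouping are
#' flagged and treated as their own group.
#'
#' @param dendrogram An \code{hclust} over strains (from
#'   \code{\link{ward_cluster}}).
#' @param cut Cut height on the 1 - Dice scale (default 0.15).
#' @param metabolic_groups Named vector/list mapping strain id to
#'   metabolic group id (e.g. from \code{\link{metabolic_grouping}},
#'   reduced to one group per strain).
#' @return An object of class \code{"redundancy_report"}: list with
#'   \code{genotype_clusters} (named integer), \code{cells}
#'   (data.frame strain / genotype cluster / metabolic group / status /
#'   representative), \code{unique_strains} (nominated representatives,
#'   sorted), \code{missing} (strains without a metabolic group).
#' @export
curate <- function(dendrogram, cut = 0.15, metabolic_groups) {
  stopifnot(inherits(dendrogram, "hclust"))
  if (missing(metabolic_groups) || length(metabolic_groups) == 0L)
    stop("empty metabolic grouping")
  mg <- unlist(metabolic_groups)
  cl <- stats::cutree(dendrogram, h = cut)
  strains <- names(cl)
  missing <- setdiff(strains, names(mg))
  grp <- mg[strains]
  names(grp) <- strains
  # strains without an extract get a sentinel group of their own
  grp[missing] <- paste0(".none.", missing)
  cell <- paste(cl, grp, sep = "|")
  rep_of <- tapply(strains, cell, function(s) min(s))
  counts <- table(cell)
  status <- ifelse(counts[cell] > 1L, "redundant", "unique")
  status[strains %in% rep_of & status == "redundant"] <- "representative"
  cells <- data.frame(strain = strains,
                      genotype_cluster = unname(cl),
                      metabolic_group = unname(grp),
                      status = unname(status),
                      representative = unname(rep_of[cell]),
                      stringsAsFactors = FALSE)
  cells <- cells[order(cells$strain), ]
  rownames(cells) <- NULL
  structure(list(genotype_clusters = cl, cells = cells,
                 unique_strains = sort(unname(rep_of)),
                 missing = missing, cut = cut),
            class = "redundancy_report")
}

#' @export
print.redundancy_report <- function(x, ...) {
  cat(sprintf(
    "Redundancy report: %d strains, %d genotype clusters (cut %g), %d nominated\n",
    nrow(x$cells), length(unique(x$genotype_clusters)), x$cut,
    length(x$unique_strains)))
  print(x$cells)
  invisible(x)
}

#' Read a long-format band table
#'
#' CSV with columns \code{strain} and \code{band_size_bp}; one row per
#' observed band.
#'
#' @param path CSV path.
#' @return Named list of numeric size vectors, ready for
#'   \code{\link{register_bands}}.
#' @export
read_band_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("strain", "band_size_bp") %in% names(df)))
    stop("band table needs columns 'strain' and 'band_size_bp'")
  split(df$band_size_bp, df$strain)
}
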