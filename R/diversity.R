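#' Read a taxon abundance table
#'
#' Reads a TSV table of read counts with taxa in rows and samples in
#' columns; the first column holds taxon labels. This is the finished
#' classification output of an amplicon pipeline (e.g. a SILVAngs-style
#' export) -- no sequence processing happens here.
#'
#' @param path Path to a tab-separated file.
#' @return Integer matrix, rows = taxa (rownames), cols = samples.
#' @export
read_taxon_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("taxon table needs a label column plus >= 1 sample")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0))
    stop("taxon table counts must be finite and >= 0")
  rownames(m) <- as.character(df[[1]])
  m
}

#' Remove taxa below a pooled relative-abundance threshold
#'
#' Drops taxa whose abundance pooled over all samples is strictly below
#' \code{min_rel_abundance} of the grand total of classified reads.
#' Taxa exactly at the threshold are retained. The filter is applied
#' table-wide, so the same taxa disappear from every sample.
#'
#' @param counts Numeric matrix, rows = taxa, cols = samples.
#' @param min_rel_abundance Fraction in [0, 1); the study default is
#'   1e-5 (0.001 percent of total).
#' @return List with \code{counts} (filtered matrix) and \code{removed}
#'   (character vector of dropped taxon labels).
#' @export
filter_rare <- function(counts, min_rel_abundance = 1e-5) {
  counts <- .as_count_matrix(counts)
  if (nrow(counts) == 0L || sum(counts) <= 0)
    stop("empty taxon table")
  stopifnot(is.numeric(min_rel_abundance), length(min_rel_abundance) == 1L)
  if (min_rel_abundance < 0 || min_rel_abundance >= 1)
    stop("'min_rel_abundance' must be in [0, 1)")
  pooled <- rowSums(counts) / sum(counts)
  keep <- pooled >= min_rel_abundance
  list(counts = counts[keep, , drop = FALSE],
       removed = rownames(counts)[!keep])
}

#' Shannon diversity and richness
#'
#' Shannon index H = -sum p_i log p_i over taxa with nonzero abundance,
#' with p_i the relative abundance within the sample. Natural log
#' (nats) by default, matching common community-ecology practice;
#' \code{base} switches the logarithm.
#'
#' @param counts Named numeric vector of taxon counts for one sample, or
#'   a matrix (rows = taxa, cols = samples) for per-sample results.
#' @param base Logarithm base (default \code{exp(1)} for nats).
#' @return For a vector: data.frame with \code{shannon} and
#'   \code{richness}. For a matrix: one row per sample.
#' @examples
#' shannon_index(c(a = 50, b = 25, c = 25))
#' @export
shannon_index <- function(counts, base = exp(1)) {
  if (is.matrix(counts)) {
    res <- do.call(rbind, lapply(seq_len(ncol(counts)), function(j)
      shannon_index(counts[, j], base = base)))
    res$sample_id <- colnames(counts)
    return(res[, c("sample_id", "shannon", "richness")])
  }
  stopifnot(is.numeric(counts), all(is.finite(counts)), all(counts >= 0))
  total <- sum(counts)
  if (total <= 0) stop("all-zero profile: Shannon index undefined")
  p <- counts[counts > 0] / total
  data.frame(shannon = -sum(p * log(p, base = base)),
             richness = sum(counts > 0))
}

#' Kruskal-Wallis rank test across sample groups
#'
#' Several-sample one-way ANOVA on ranks: the H statistic is computed on
#' midranks with the standard tie correction and referred to a
#' chi-squared distribution with (number of groups - 1) degrees of
#' freedom.
#'
#' @param groups List of >= 2 nonempty numeric vectors.
#' @return List with \code{statistic} (H, tie-corrected), \code{df},
#'   \code{p_value}.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' @export
kruskal_wallis <- function(groups) {
  .check_groups(groups)
  # fully tied data: every observation has the same midrank, H = 0
  if (length(unique(unlist(groups))) == 1L)
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1))
  k <- stats::kruskal.test(groups)
  list(statistic = unname(k$statistic), df = unname(k$parameter),
       p_value = k$p.value)
}

#' Dunn's post hoc test on pooled midranks
#'
#' Pairwise z statistics following a Kruskal-Wallis test: for groups i
#' and j, z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))
#' with tie correction T = sum(t^3 - t) / (12 (N - 1)) over tie groups.
#' Two-sided p-values come from the standard normal and are adjusted for
#' multiplicity. Significance stars follow the convention
#' *** P < 0.001, ** P < 0.01, * P < 0.1, else ns.
#'
#' @param groups Named list of >= 2 nonempty numeric vectors.
#' @param adjust Multiplicity adjustment passed to
#'   \code{\link[stats]{p.adjust}}; default \code{"bonferroni"}.
#' @param comparisons \code{"control"} compares every group to the
#'   first (the reference/starting-material column); \code{"all"} runs
#'   all pairs.
#' @return data.frame with columns \code{group1}, \code{group2},
#'   \code{z}, \code{p_raw}, \code{p_adj}, \code{stars}.
#' @export
dunn_posthoc <- function(groups, adjust = "bonferroni",
                         comparisons = c("control", "all")) {
  .check_groups(groups)
  comparisons <- match.arg(comparisons)
  g <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(g))
  x <- unlist(groups, use.names = FALSE)
  grp <- rep(seq_len(g), lengths(groups))
  N <- length(x)
  r <- rank(x)  # midranks
  rbar <- tapply(r, grp, mean)
  n <- lengths(groups)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_corr

  pairs <- if (comparisons == "control") {
    cbind(1L, seq_len(g)[-1])
  } else {
    t(utils::combn(g, 2))
  }
  z <- p_raw <- numeric(nrow(pairs))
  for (idx in seq_len(nrow(pairs))) {
    i <- pairs[idx, 1]; j <- pairs[idx, 2]
    se <- sqrt(v0 * (1 / n[i] + 1 / n[j]))
    z[idx] <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
    p_raw[idx] <- 2 * stats::pnorm(-abs(z[idx]))
  }
  p_adj <- stats::p.adjust(p_raw, method = adjust)
  data.frame(group1 = names(groups)[pairs[, 1]],
             group2 = names(groups)[pairs[, 2]],
             z = z, p_raw = p_raw, p_adj = p_adj,
             stars = significance_stars(p_adj),
             stringsAsFactors = FALSE)
}

#' Map p-values to significance stars
#'
#' \code{***} for P < 0.001, \code{**} for P < 0.01, \code{*} for
#' P < 0.1, \code{ns} otherwise. Note the deliberately wide single-star
#' band (P < 0.1 rather than the usual 0.05).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of the same length.
#' @export
significance_stars <- function(p) {
  stopifnot(is.numeric(p))
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.1, "*", "ns")))
}

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups")
  if (any(lengths(groups) == 0L))
    stop("every group must contain at least one observation")
  if (!all(vapply(groups, is.numeric, logical(1))))
    stop("groups must be numeric vectors")
  invisible(TRUE)
}

.as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix (taxa x samples)")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and >= 0")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("taxon", seq_len(nrow(counts)))
  counts
}
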