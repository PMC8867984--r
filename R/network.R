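#' Construct an MS/MS spectrum
#'
#' Centroided fragment peak list plus precursor m/z. Peaks are stored
#' sorted by m/z ascending; zero- or negative-intensity peaks are
#' rejected.
#'
#' @param spectrum_id Label.
#' @param precursor_mz Precursor (parent ion) m/z.
#' @param mz Numeric vector of fragment m/z values.
#' @param intensity Matching numeric vector of intensities (> 0).
#' @return An object of class \code{"msms_spectrum"}.
#' @export
msms_spectrum <- function(spectrum_id, precursor_mz, mz, intensity) {
  stopifnot(length(mz) == length(intensity),
            is.numeric(mz), is.numeric(intensity))
  if (any(intensity <= 0)) stop("peak intensities must be > 0")
  o <- order(mz)
  structure(list(spectrum_id = as.character(spectrum_id),
                 precursor_mz = as.numeric(precursor_mz),
                 mz = mz[o], intensity = intensity[o]),
            class = "msms_spectrum")
}

#' @export
print.msms_spectrum <- function(x, ...) {
  cat(sprintf("MS/MS spectrum '%s': precursor m/z %.4f, %d peaks\n",
              x$spectrum_id, x$precursor_mz, length(x$mz)))
  invisible(x)
}

#' Read MGF spectra
#'
#' Parses a Mascot generic format file (BEGIN IONS / END IONS blocks
#' with PEPMASS, optional TITLE/NAME, and mass-intensity peak lines).
#' Peaks strictly below the absolute-intensity floor are removed at
#' read time (default 1000, mirroring a typical raw-conversion
#' threshold filter); spectra left empty are dropped with a warning.
#'
#' @param path MGF file path.
#' @param intensity_floor Absolute intensity floor; peaks with
#'   intensity < floor are removed (default 1000). Use 0 to keep all.
#' @return List of \code{\link{msms_spectrum}} objects; any NAME/TITLE
#'   is kept as the spectrum id.
#' @export
read_mgf <- function(path, intensity_floor = 1000) {
  lines <- readLines(path)
  spectra <- list()
  i <- 1L; n <- length(lines); block <- 0L
  while (i <= n) {
    ln <- trimws(lines[i])
    if (ln == "BEGIN IONS") {
      block <- block + 1L
      pep <- NA_real_; id <- NULL
      mz <- numeric(0); inten <- numeric(0)
      i <- i + 1L
      repeat {
        if (i > n) stop("unterminated BEGIN IONS block at line ", i - 1L)
        ln <- trimws(lines[i])
        if (ln == "END IONS") break
        if (grepl("^PEPMASS=", ln)) {
          pep <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "[ \t]")[[1]][1])
        } else if (grepl("^(NAME|TITLE)=", ln)) {
          id <- sub("^(NAME|TITLE)=", "", ln)
        } else if (grepl("^[A-Z]+=", ln) || ln == "") {
          # other headers ignored
        } else {
          parts <- strsplit(ln, "[ \t]+")[[1]]
          if (length(parts) < 2L || anyNA(suppressWarnings(as.numeric(parts[1:2]))))
            stop("malformed peak line ", i, ": '", lines[i], "'")
          mz <- c(mz, as.numeric(parts[1]))
          inten <- c(inten, as.numeric(parts[2]))
        }
        i <- i + 1L
      }
      if (is.na(pep)) stop("spectrum block ", block, " has no PEPMASS")
      keep <- inten >= intensity_floor
      if (!any(keep)) {
        warning("spectrum ", if (is.null(id)) block else id,
                " empty after intensity floor; dropped")
      } else {
        spectra[[length(spectra) + 1L]] <- msms_spectrum(
          if (is.null(id)) paste0("spectrum_", block) else id,
          pep, mz[keep], inten[keep])
      }
    }
    i <- i + 1L
  }
  spectra
}

#' Write spectra to MGF
#'
#' @param spectra List of \code{\link{msms_spectrum}} objects.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("NAME=", s$spectrum_id),
                 sprintf("PEPMASS=%.6f", s$precursor_mz),
                 sprintf("%.6f %.6f", s$mz, s$intensity),
                 "END IONS", ""), con)
  }
  invisible(path)
}

#' Greedy one-to-one fragment matching between two spectra
#'
#' Candidate peak pairs within the mass tolerance are sorted by
#' intensity product (descending) and accepted greedily if neither
#' peak is already used, yielding a one-to-one pairing.
#'
#' @param a,b \code{\link{msms_spectrum}} objects (nonempty).
#' @param tol_da Absolute fragment tolerance in Da (default 0.05).
#' @return List with \code{pairs} (2-column index matrix into a and b)
#'   and \code{n_matched}.
#' @export
match_fragments <- function(a, b, tol_da = 0.05) {
  stopifnot(inherits(a, "msms_spectrum"), inherits(b, "msms_spectrum"))
  if (length(a$mz) == 0L || length(b$mz) == 0L)
    return(list(pairs = matrix(integer(0), ncol = 2), n_matched = 0L))
  d <- abs(outer(a$mz, b$mz, "-"))
  cand <- which(d <= tol_da, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(list(pairs = matrix(integer(0), ncol = 2), n_matched = 0L))
  prod <- a$intensity[cand[, 1]] * b$intensity[cand[, 2]]
  cand <- cand[order(-prod, d[cand]), , drop = FALSE]
  used_a <- logical(length(a$mz)); used_b <- logical(length(b$mz))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ia <- cand[i, 1]; ib <- cand[i, 2]
    if (!used_a[ia] && !used_b[ib]) {
      keep[i] <- TRUE; used_a[ia] <- TRUE; used_b[ib] <- TRUE
    }
  }
  pairs <- cand[keep, , drop = FALSE]
  list(pairs = pairs, n_matched = nrow(pairs))
}

#' Spectral cosine similarity with fragment matching
#'
#' Peak intensities are (optionally square-root) transformed and
#' normalized to unit vector norm over the full spectrum; the cosine is
#' the sum over matched peak pairs of the products of the normalized
#' intensities, so unmatched peaks dilute the score. With
#' \code{modified = TRUE}, fragments are additionally allowed to match
#' after shifting by the precursor mass difference (modified cosine),
#' useful for homologous series differing by a neutral loss.
#'
#' @param a,b \code{\link{msms_spectrum}} objects.
#' @param tol_da Fragment tolerance in Da (default 0.05).
#' @param sqrt_intensity Use square-root intensity weighting (default
#'   TRUE, standard networking practice).
#' @param modified Also allow precursor-shifted matches (default
#'   FALSE; plain cosine).
#' @return List with \code{cosine} in [0, 1] and \code{n_matched}.
#' @export
spectral_cosine <- function(a, b, tol_da = 0.05, sqrt_intensity = TRUE,
                            modified = FALSE) {
  stopifnot(inherits(a, "msms_spectrum"), inherits(b, "msms_spectrum"))
  if (length(a$mz) == 0L || length(b$mz) == 0L)
    stop("empty spectrum: cosine undefined")
  wa <- if (sqrt_intensity) sqrt(a$intensity) else a$intensity
  wb <- if (sqrt_intensity) sqrt(b$intensity) else b$intensity
  wa <- wa / sqrt(sum(wa^2)); wb <- wb / sqrt(sum(wb^2))
  mf <- match_fragments(a, b, tol_da)
  if (modified) {
    shift <- b$precursor_mz - a$precursor_mz
    if (abs(shift) > tol_da) {
      a2 <- a; a2$mz <- a$mz + shift
      mf2 <- match_fragments(a2, b, tol_da)
      # merge: direct pairs take precedence, shifted pairs fill in
      # peaks unused on both sides
      used_a <- logical(length(a$mz)); used_b <- logical(length(b$mz))
      used_a[mf$pairs[, 1]] <- TRUE; used_b[mf$pairs[, 2]] <- TRUE
      extra <- mf2$pairs[!used_a[mf2$pairs[, 1]] &
                         !used_b[mf2$pairs[, 2]], , drop = FALSE]
      mf$pairs <- rbind(mf$pairs, extra)
      mf$n_matched <- nrow(mf$pairs)
    }
  }
  cosine <- if (mf$n_matched == 0L) 0 else
    sum(wa[mf$pairs[, 1]] * wb[mf$pairs[, 2]])
  list(cosine = min(cosine, 1), n_matched = mf$n_matched)
}

#' Build an MS/MS molecular network
#'
#' Computes all pairwise spectral cosines and keeps an undirected edge
#' between two spectra iff cosine > \code{cosine_cut} (strict) AND the
#' number of one-to-one matched fragments is at least
#' \code{min_matched}. Isolated nodes are retained and flagged.
#'
#' @param spectra List of \code{\link{msms_spectrum}} objects.
#' @param cosine_cut Edge cosine cut-off, strict (default 0.7).
#' @param min_matched Minimum shared fragments, inclusive (default 6).
#' @param tol_da Fragment tolerance in Da (default 0.05).
#' @param sqrt_intensity,modified Passed to
#'   \code{\link{spectral_cosine}}.
#' @return An object of class \code{"spectral_network"}: list with
#'   \code{nodes} (data.frame id / precursor_mz / isolated /
#'   annotation) and \code{edges} (data.frame from / to / cosine /
#'   matched).
#' @export
build_network <- function(spectra, cosine_cut = 0.7, min_matched = 6L,
                          tol_da = 0.05, sqrt_intensity = TRUE,
                          modified = FALSE) {
  stopifnot(is.list(spectra), length(spectra) >= 1L)
  ids <- vapply(spectra, `[[`, character(1), "spectrum_id")
  if (anyDuplicated(ids)) stop("duplicate spectrum ids")
  n <- length(spectra)
  from <- to <- character(0); cosv <- numeric(0); mv <- integer(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      sc <- spectral_cosine(spectra[[i]], spectra[[j]], tol_da,
                            sqrt_intensity, modified)
      if (sc$cosine > cosine_cut && sc$n_matched >= min_matched) {
        from <- c(from, ids[i]); to <- c(to, ids[j])
        cosv <- c(cosv, sc$cosine); mv <- c(mv, sc$n_matched)
      }
    }
  }
  edges <- data.frame(from = from, to = to, cosine = cosv,
                      matched = mv, stringsAsFactors = FALSE)
  nodes <- data.frame(
    id = ids,
    precursor_mz = vapply(spectra, `[[`, numeric(1), "precursor_mz"),
    isolated = !(ids %in% c(from, to)),
    annotation = NA_character_,
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 params = list(cosine_cut = cosine_cut,
                               min_matched = as.integer(min_matched),
                               tol_da = tol_da,
                               sqrt_intensity = sqrt_intensity,
                               modified = modified)),
            class = "spectral_network")
}

#' @export
print.spectral_network <- function(x, ...) {
  cat(sprintf(
    "Molecular network: %d nodes (%d isolated), %d edges (cosine > %g, >= %d fragments)\n",
    nrow(x$nodes), sum(x$nodes$isolated), nrow(x$edges),
    x$params$cosine_cut, x$params$min_matched))
  invisible(x)
}

#' Connected components of a spectral network
#'
#' @param network A \code{"spectral_network"}.
#' @return Named integer vector: component membership per node id.
#' @export
network_components <- function(network) {
  stopifnot(inherits(network, "spectral_network"))
  g <- .as_igraph(network)
  igraph::components(g)$membership
}

#' Annotate network nodes against a spectral library
#'
#' Each node is compared to every library spectrum under the network's
#' own edge rule (cosine cut and minimum matched fragments); the best
#' passing library name is written to the node's annotation, with ties
#' on cosine reported jointly (separated by \code{" | "}).
#'
#' @param network A \code{"spectral_network"}.
#' @param library_spectra List of \code{\link{msms_spectrum}} objects
#'   whose ids are compound names.
#' @param spectra The network's node spectra (same order/ids as used
#'   in \code{\link{build_network}}).
#' @return The network with filled \code{annotation} fields.
#' @export
annotate_network <- function(network, library_spectra, spectra) {
  stopifnot(inherits(network, "spectral_network"))
  if (length(library_spectra) == 0L) return(network)
  ids <- vapply(spectra, `[[`, character(1), "spectrum_id")
  p <- network$params
  for (k in seq_len(nrow(network$nodes))) {
    s <- spectra[[match(network$nodes$id[k], ids)]]
    best_cos <- -Inf; best <- character(0)
    for (ls in library_spectra) {
      sc <- spectral_cosine(s, ls, p$tol_da, p$sqrt_intensity, p$modified)
      if (sc$cosine > p$cosine_cut && sc$n_matched >= p$min_matched) {
        if (sc$cosine > best_cos + 1e-12) {
          best_cos <- sc$cosine; best <- ls$spectrum_id
        } else if (abs(sc$cosine - best_cos) <= 1e-12) {
          best <- c(best, ls$spectrum_id)
        }
      }
    }
    if (length(best))
      network$nodes$annotation[k] <- paste(best, collapse = " | ")
  }
  network
}

#' Export a spectral network to GraphML or an edge list
#'
#' GraphML output (via igraph) carries precursor m/z and annotation as
#' node attributes and cosine / matched-fragment count as edge
#' attributes; the TSV edge list holds the edge table only.
#'
#' @param network A \code{"spectral_network"}.
#' @param path Output file path.
#' @param format \code{"graphml"} or \code{"edgelist"}.
#' @return \code{path}, invisibly.
#' @export
export_graph <- function(network, path, format = c("graphml", "edgelist")) {
  stopifnot(inherits(network, "spectral_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    g <- .as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(network$edges, path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

.as_igraph <- function(network) {
  vertices <- network$nodes
  vertices$annotation[is.na(vertices$annotation)] <- ""
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = vertices)
}
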