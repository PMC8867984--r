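# Seeded synthetic-data generators. Every generator plants a known
# structure and returns it as machine-readable ground truth next to the
# data, so each downstream stage can be tested against a recovery
# target. All generators are deterministic for a fixed seed and leave
# the caller's RNG state untouched.

#' Generate a synthetic community profile
#'
#' Taxon relative abundances are drawn from a symmetric Dirichlet with
#' concentration \code{concentration} (large values give even
#' communities, small values skewed ones) and reads from a multinomial.
#' The generating distribution's true Shannon index is returned for
#' recovery checks.
#'
#' @param n_taxa Number of taxa (>= 1).
#' @param total_reads Number of reads (>= 1).
#' @param concentration Dirichlet concentration parameter (> 0);
#'   \code{Inf} gives an exactly uniform community.
#' @param seed Integer RNG seed.
#' @return List with \code{counts} (named integer vector),
#'   \code{true_p} (generating probabilities), \code{true_shannon}.
#' @export
gen_community <- function(n_taxa, total_reads, concentration = 1,
                          seed = 1L) {
  stopifnot(n_taxa >= 1L, total_reads >= 1L, concentration > 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  p <- if (is.infinite(concentration)) rep(1 / n_taxa, n_taxa) else {
    g <- stats::rgamma(n_taxa, shape = concentration, rate = 1)
    g / sum(g)
  }
  counts <- as.integer(stats::rmultinom(1, total_reads, p))
  names(counts) <- paste0("taxon", seq_len(n_taxa))
  true_shannon <- -sum(p[p > 0] * log(p[p > 0]))
  list(counts = counts, true_p = p, true_shannon = true_shannon)
}

#' Generate LC-MS feature tables with planted metabolic groups
#'
#' Each group owns a template set of bucket positions (a fraction
#' \code{between_share} of which is drawn from a pool common to all
#' groups); each sample inherits a fraction \code{within_share} of its
#' group template plus private noise positions, with log-normal
#' intensity jitter. Positions are placed at RT-bin centres of the
#' standard grid with well-separated m/z values, so every planted
#' position maps to its own bucket.
#'
#' @param n_groups Number of planted groups.
#' @param samples_per_group Integer vector (recycled) of samples per
#'   group.
#' @param n_features Template size: features per sample (default 120,
#'   comfortably above the 50-feature exclusion rule).
#' @param within_share Fraction of the group template present in every
#'   sample (default 0.95).
#' @param between_share Fraction of each template shared across groups
#'   (default 0.05); must be < \code{within_share}.
#' @param noise_cv Coefficient of variation of the log-normal
#'   intensity jitter (default 0.1).
#' @param grid A \code{\link{bucket_grid}} defining where features may
#'   fall.
#' @param seed Integer RNG seed.
#' @return List with \code{feature_lists} (named list of data.frames
#'   \code{rt_s,mz,intensity}) and \code{true_groups} (named integer
#'   vector).
#' @export
gen_feature_tables <- function(n_groups, samples_per_group,
                               n_features = 120L, within_share = 0.95,
                               between_share = 0.05, noise_cv = 0.1,
                               grid = bucket_grid(), seed = 1L) {
  stopifnot(n_groups >= 1L, within_share > 0, within_share <= 1,
            between_share >= 0, between_share < 1, noise_cv >= 0)
  if (within_share <= between_share)
    stop("within_share must exceed between_share: planted structure ",
         "would be unrecoverable by design")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  nspg <- rep_len(as.integer(samples_per_group), n_groups)

  rt_bins <- floor(diff(grid$rt_range) / grid$rt_width_s)
  pos <- function(k) {
    # random bucket positions: RT at bin centres, log-uniform m/z
    data.frame(
      rt_s = grid$rt_range[1] +
        (sample.int(rt_bins, k, replace = TRUE) - 0.5) * grid$rt_width_s,
      mz = exp(stats::runif(k, log(grid$mz_range[1]),
                            log(grid$mz_range[2] * 0.999))))
  }
  n_shared <- round(between_share * n_features)
  shared <- pos(n_shared)
  templates <- lapply(seq_len(n_groups), function(g)
    rbind(shared, pos(n_features - n_shared)))
  base_int <- lapply(templates, function(t)
    stats::rlnorm(nrow(t), meanlog = log(1e5), sdlog = 1))

  feature_lists <- list(); true_groups <- integer(0)
  sdlog <- sqrt(log1p(noise_cv^2))
  for (g in seq_len(n_groups)) for (s in seq_len(nspg[g])) {
    id <- sprintf("G%02d_S%02d", g, s)
    n_keep <- round(within_share * n_features)
    # dropout hits low-abundance features: detection near the limit is
    # what varies between technical runs, not the dominant peaks
    keep <- sort(sample.int(n_features, n_keep, prob = base_int[[g]]))
    tpl <- templates[[g]][keep, , drop = FALSE]
    tpl$intensity <- base_int[[g]][keep] *
      stats::rlnorm(n_keep, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    n_noise <- n_features - n_keep
    if (n_noise > 0) {
      noise <- pos(n_noise)
      noise$intensity <- stats::rlnorm(n_noise, meanlog = log(1e4),
                                       sdlog = 1)
      tpl <- rbind(tpl, noise)
    }
    rownames(tpl) <- NULL
    feature_lists[[id]] <- tpl
    true_groups[id] <- g
  }
  list(feature_lists = feature_lists, true_groups = true_groups)
}

#' Generate clonal fingerprint band tables
#'
#' Clone templates are random subsets of a registry of well-separated
#' band sizes; each copy of a clone flips every band's presence with
#' probability \code{flip_prob} (Bernoulli noise).
#'
#' @param n_clones Number of distinct clones.
#' @param copies_per_clone Copies (strains) per clone.
#' @param n_registry_bands Size of the band registry (default 30).
#' @param flip_prob Per-band flip probability in [0, 0.5).
#' @param seed Integer RNG seed.
#' @return List with \code{raw_sizes} (named list of band-size vectors
#'   per strain, in bp) and \code{true_clones} (named integer vector).
#' @export
gen_fingerprints <- function(n_clones, copies_per_clone,
                             n_registry_bands = 30L, flip_prob = 0.05,
                             seed = 1L) {
  stopifnot(n_clones >= 1L, copies_per_clone >= 1L,
            n_registry_bands >= 4L)
  if (flip_prob < 0 || flip_prob >= 0.5)
    stop("flip_prob must be in [0, 0.5)")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  # geometric size ladder: adjacent registry bands differ by 8%,
  # far beyond the 2% registration tolerance
  registry <- round(100 * 1.08^(seq_len(n_registry_bands) - 1))
  templates <- lapply(seq_len(n_clones), function(i) {
    repeat {
      b <- stats::runif(n_registry_bands) < 0.5
      if (sum(b) >= 3L) return(b)
    }
  })
  raw_sizes <- list(); true_clones <- integer(0)
  for (cl in seq_len(n_clones)) for (cp in seq_len(copies_per_clone)) {
    id <- sprintf("C%02d_R%02d", cl, cp)
    present <- xor(templates[[cl]],
                   stats::runif(n_registry_bands) < flip_prob)
    if (!any(present)) present[sample.int(n_registry_bands, 1)] <- TRUE
    raw_sizes[[id]] <- registry[present]
    true_clones[id] <- cl
  }
  list(raw_sizes = raw_sizes, true_clones = true_clones)
}

#' Generate an MS/MS compound family
#'
#' Derivatives of a compound family share a scaffold of fragment peaks
#' and differ by cumulative neutral-loss steps on the precursor (e.g.
#' CH2 homologues at 14.01565 Da); each derivative adds a few private
#' fragments. Intensities sit well above the standard read floor.
#'
#' @param family_id Label prefix for the spectra.
#' @param n_derivatives Number of family members.
#' @param scaffold_peaks Number of shared scaffold fragments (>= 6 for
#'   families to be detectable at the default network parameters; a
#'   warning is raised below that).
#' @param base_precursor_mz Precursor m/z of the first derivative.
#' @param loss_step Neutral-loss step between successive derivatives
#'   in Da (default 14.01565, a CH2 unit).
#' @param n_private Private fragments per derivative (default 3).
#' @param seed Integer RNG seed.
#' @return List with \code{spectra} (list of
#'   \code{\link{msms_spectrum}}) and \code{family} (named character
#'   vector: spectrum id -> family id).
#' @export
gen_compound_family <- function(family_id = "fam", n_derivatives = 7L,
                                scaffold_peaks = 10L,
                                base_precursor_mz = 515.33,
                                loss_step = 14.01565, n_private = 3L,
                                seed = 1L) {
  stopifnot(n_derivatives >= 1L, scaffold_peaks >= 1L, n_private >= 0L)
  if (scaffold_peaks < 6L)
    warning("fewer than 6 scaffold peaks: family undetectable at the ",
            "default >= 6 shared-fragment rule")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  scaffold_mz <- sort(stats::runif(scaffold_peaks, 120,
                                   base_precursor_mz - 30))
  scaffold_int <- stats::runif(scaffold_peaks, 5e4, 5e5)
  spectra <- list(); family <- character(0)
  for (i in seq_len(n_derivatives)) {
    id <- sprintf("%s_%02d", family_id, i)
    pmz <- base_precursor_mz + (i - 1) * loss_step
    priv_mz <- stats::runif(n_private, 120, pmz - 30)
    priv_int <- stats::runif(n_private, 2e4, 2e5)
    spectra[[id]] <- msms_spectrum(
      id, pmz,
      c(scaffold_mz, priv_mz),
      c(scaffold_int * stats::runif(scaffold_peaks, 0.8, 1.2), priv_int))
    family[id] <- family_id
  }
  list(spectra = spectra, family = family)
}

#' Generate a microfractionation bioassay plate
#'
#' Simulates OD readouts for a fraction plate: growth-control wells at
#' a nominal OD, medium-control wells at the blank OD, and one sample
#' well per fraction whose inhibition is zero except inside the spiked
#' windows, plus Gaussian noise.
#'
#' @param scheme A \code{\link{fraction_scheme}}.
#' @param spiked_windows List of \code{list(fractions =, inhibition =)}
#'   entries; windows must not overlap.
#' @param noise_sd Gaussian noise on the inhibition scale, in percent
#'   points (default 2).
#' @param growth_od,medium_od Nominal control readouts (defaults 1.0
#'   and 0.08).
#' @param n_control_wells Wells per control column (default 8).
#' @param seed Integer RNG seed.
#' @return List with \code{plate} (data.frame well / role / fraction /
#'   readout, ready for \code{\link{call_active}}) and
#'   \code{true_active} (sorted spiked fraction indices).
#' @export
gen_fraction_plate <- function(scheme = fraction_scheme(),
                               spiked_windows = list(),
                               noise_sd = 2, growth_od = 1.0,
                               medium_od = 0.08, n_control_wells = 8L,
                               seed = 1L) {
  stopifnot(inherits(scheme, "fraction_scheme"), noise_sd >= 0,
            growth_od > medium_od)
  spiked <- unlist(lapply(spiked_windows, `[[`, "fractions"))
  if (anyDuplicated(spiked)) stop("overlapping spiked windows")
  if (length(spiked) && (min(spiked) < 1L || max(spiked) > scheme$n_fractions))
    stop("spiked fractions outside 1..", scheme$n_fractions)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  inh <- numeric(scheme$n_fractions)
  for (w in spiked_windows) inh[w$fractions] <- w$inhibition
  inh_noisy <- inh + stats::rnorm(scheme$n_fractions, 0, noise_sd)
  span <- growth_od - medium_od
  readout <- growth_od - inh_noisy / 100 * span
  plate <- rbind(
    data.frame(well = sprintf("M%02d", seq_len(n_control_wells)),
               role = "medium-control", fraction = NA_integer_,
               readout = medium_od +
                 stats::rnorm(n_control_wells, 0, noise_sd / 100 * span)),
    data.frame(well = sprintf("G%02d", seq_len(n_control_wells)),
               role = "growth-control", fraction = NA_integer_,
               readout = growth_od +
                 stats::rnorm(n_control_wells, 0, noise_sd / 100 * span)),
    data.frame(well = sprintf("F%03d", seq_len(scheme$n_fractions)),
               role = "sample", fraction = seq_len(scheme$n_fractions),
               readout = readout))
  plate$readout <- pmax(plate$readout, 0)
  list(plate = plate, true_active = sort(unique(spiked)))
}

#' Paper-scale synthetic scenario
#'
#' One call reproducing a study-sized fixture with known ground truth:
#' a 60-extract / 8-group metabolic grouping problem, a 3-clone x 3-copy
#' genotype set, a 7-member spectral family plus unrelated singleton
#' spectra, a 159-fraction plate with one active window (fractions
#' 84-87), and a diverse community profile. Used as the end-to-end
#' smoke test of the pipeline.
#'
#' @param seed Integer RNG seed; sub-generators derive distinct seeds
#'   from it.
#' @param dir Optional directory: when given, the standard text files
#'   (taxon TSV, long-format feature CSV, band CSV, plate CSV, MGF)
#'   are written there.
#' @return List with elements \code{community}, \code{features},
#'   \code{fingerprints}, \code{spectra} (family + unrelated, with
#'   \code{family} truth), \code{plate}; each carries its own ground
#'   truth.
#' @export
gen_paper_scale <- function(seed = 1L, dir = NULL) {
  seed <- as.integer(seed)
  community <- gen_community(n_taxa = 60, total_reads = 1e5,
                             concentration = Inf, seed = seed + 11L)
  features <- gen_feature_tables(
    n_groups = 8, samples_per_group = c(20, 10, 8, 6, 5, 4, 4, 3),
    within_share = 0.95, between_share = 0.05, noise_cv = 0.1,
    seed = seed + 23L)
  fingerprints <- gen_fingerprints(n_clones = 3, copies_per_clone = 3,
                                   flip_prob = 0.05, seed = seed + 37L)
  fam <- gen_compound_family("serrata_like", n_derivatives = 7,
                             scaffold_peaks = 10, seed = seed + 41L)
  singles <- lapply(1:5, function(i)
    gen_compound_family(paste0("single", i), n_derivatives = 1,
                        scaffold_peaks = 8,
                        base_precursor_mz = 300 + 60 * i,
                        seed = seed + 50L + i))
  spectra <- c(fam$spectra, unlist(lapply(singles, `[[`, "spectra"),
                                   recursive = FALSE))
  family <- c(fam$family, unlist(lapply(singles, `[[`, "family")))
  plate <- gen_fraction_plate(
    spiked_windows = list(list(fractions = 84:87, inhibition = 95)),
    noise_sd = 2, seed = seed + 61L)
  out <- list(community = community, features = features,
              fingerprints = fingerprints,
              spectra = list(spectra = spectra, family = family),
              plate = plate)
  if (!is.null(dir)) .write_scenario(out, dir)
  out
}

.write_scenario <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(taxon = names(x$community$counts),
               sample1 = x$community$counts),
    file.path(dir, "taxa.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  feats <- do.call(rbind, lapply(names(x$features$feature_lists),
    function(id) cbind(sample = id, x$features$feature_lists[[id]])))
  utils::write.csv(feats, file.path(dir, "features.csv"),
                   row.names = FALSE)
  bands <- do.call(rbind, lapply(names(x$fingerprints$raw_sizes),
    function(id) data.frame(strain = id,
                            band_size_bp = x$fingerprints$raw_sizes[[id]])))
  utils::write.csv(bands, file.path(dir, "bands.csv"), row.names = FALSE)
  utils::write.csv(x$plate$plate, file.path(dir, "plate.csv"),
                   row.names = FALSE)
  write_mgf(x$spectra$spectra, file.path(dir, "spectra.mgf"))
  invisible(dir)
}
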