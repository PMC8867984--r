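# Monoisotopic masses of the most abundant isotope (CODATA/AME),
# in Da. Electron and proton masses kept separately so that adduct
# arithmetic is explicit about charge bookkeeping.
.monoisotopic <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268,
  F  = 18.99840322,
  Br = 78.9183371,
  I  = 126.904473,
  Se = 79.9165213,
  Si = 27.9769265325
)

.electron_mass <- 0.00054857990907
.proton_mass <- 1.00782503207 - 0.00054857990907  # H atom minus electron

#' Parse a molecular formula
#'
#' Parses a Hill-style elemental formula string (e.g.
#' \code{"C26H46N2O8"}) into an element -> count map. Only elements
#' with embedded monoisotopic masses are accepted.
#'
#' @param formula Formula string.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  f <- gsub("[[:space:]_]", "", formula)
  if (f == "") return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
  if (sum(attr(m, "match.length")) != nchar(f))
    stop("cannot parse formula: ", formula)
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(ifelse(grepl("[0-9]+$", toks),
                         sub("^[A-Za-z]+", "", toks), "1"))
  unknown <- setdiff(el, names(.monoisotopic))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  counts <- tapply(n, el, sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' Neutral monoisotopic mass of a molecular formula
#'
#' Sum over elements of count times the mass of the most abundant
#' isotope. \code{formula} may be a string or a parsed count vector.
#'
#' @param formula Formula string or named count vector.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")         # 18.0106
#' monoisotopic_mass("C26H46N2O8")  # 514.3254
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (length(counts) == 0L) return(0)
  if (any(counts < 0)) stop("element counts must be >= 0")
  unknown <- setdiff(names(counts), names(.monoisotopic))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  sum(.monoisotopic[names(counts)] * counts)
}

#' Theoretical adduct m/z for a molecular formula
#'
#' m/z = (M + n * m_proton) / n for the protonated adducts, with the
#' proton mass taken as hydrogen-atom mass minus electron mass
#' (1.00727646 Da). Full precision is returned; display values in the
#' field are conventionally rounded to 4 decimals.
#'
#' @param formula Formula string or parsed count vector (neutral
#'   molecule).
#' @param adduct One of \code{"[M+H]+"}, \code{"[M+2H]2+"},
#'   \code{"[M+Na]+"}, \code{"[M-H]-"}.
#' @return Theoretical m/z (full precision).
#' @examples
#' round(adduct_mz("C53H93N9O16", "[M+H]+"), 4)  # 1112.6813
#' @export
adduct_mz <- function(formula, adduct = "[M+H]+") {
  M <- monoisotopic_mass(formula)
  switch(adduct,
    "[M+H]+"   = M + .proton_mass,
    "[M+2H]2+" = (M + 2 * .proton_mass) / 2,
    "[M+Na]+"  = M + .monoisotopic[["Na"]] - .electron_mass,
    "[M-H]-"   = M - .proton_mass,
    stop("unsupported adduct '", adduct,
         "'; supported: [M+H]+, [M+2H]2+, [M+Na]+, [M-H]-")
  )
}

#' Signed ppm mass error
#'
#' 1e6 * (observed - theoretical) / theoretical.
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z (> 0).
#' @return Signed error in parts per million.
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(is.numeric(observed), is.numeric(theoretical))
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0")
  1e6 * (observed - theoretical) / theoretical
}

#' Percent growth inhibition from raw readouts
#'
#' 100 * (growth - raw) / (growth - medium), where \code{medium} is the
#' sterile-medium control mean (full inhibition) and \code{growth} the
#' untreated growth-control mean (no inhibition). Identical for OD and
#' luminescence readouts. Values are clipped to [-10, 110] and clipping
#' is flagged; mildly negative values (growth promotion) are reported,
#' not hidden.
#'
#' @param raw Numeric vector of well readouts.
#' @param medium_ctrl Mean medium-control readout.
#' @param growth_ctrl Mean growth-control readout (must exceed
#'   \code{medium_ctrl}).
#' @return Numeric vector of percentages with attribute
#'   \code{"clipped"} (logical vector).
#' @export
percent_inhibition <- function(raw, medium_ctrl, growth_ctrl) {
  stopifnot(is.numeric(raw), is.numeric(medium_ctrl),
            is.numeric(growth_ctrl))
  if (growth_ctrl <= medium_ctrl)
    stop("assay failure: growth control does not exceed medium control")
  p <- 100 * (growth_ctrl - raw) / (growth_ctrl - medium_ctrl)
  clipped <- p < -10 | p > 110
  p <- pmin(pmax(p, -10), 110)
  attr(p, "clipped") <- clipped
  p
}

#' Microfractionation scheme
#'
#' Describes how an LC run was split into time-sliced fractions: the
#' study collected 159 fractions of ~ 7 s each, with the crude extract
#' applied as fraction 160 (a plate control, not a chromatographic
#' fraction).
#'
#' @param n_fractions Number of chromatographic fractions (default
#'   159).
#' @param fraction_seconds Seconds per fraction (default 7).
#' @param start_offset_s Chromatographic time of fraction 1's left
#'   edge in seconds (default 30).
#' @param crude_control_index Plate index of the unfractionated crude
#'   control (default \code{n_fractions + 1}).
#' @return An object of class \code{"fraction_scheme"}.
#' @export
fraction_scheme <- function(n_fractions = 159L, fraction_seconds = 7,
                            start_offset_s = 30,
                            crude_control_index = n_fractions + 1L) {
  stopifnot(n_fractions >= 1L, fraction_seconds > 0)
  structure(list(n_fractions = as.integer(n_fractions),
                 fraction_seconds = fraction_seconds,
                 start_offset_s = start_offset_s,
                 crude_control_index = as.integer(crude_control_index)),
            class = "fraction_scheme")
}

#' Retention-time window of a fraction
#'
#' Half-open window [offset + (idx - 1) * dur, offset + idx * dur) in
#' seconds for 1-based fraction index \code{idx}.
#'
#' @param idx Fraction index (1-based).
#' @param scheme A \code{\link{fraction_scheme}}.
#' @return Numeric length-2: window start and end (seconds).
#' @examples
#' fraction_rt_window(1, fraction_scheme())    # 30 37
#' fraction_rt_window(159, fraction_scheme())  # 1136 1143
#' @export
fraction_rt_window <- function(idx, scheme = fraction_scheme()) {
  stopifnot(inherits(scheme, "fraction_scheme"))
  idx <- as.integer(idx)
  if (is.na(idx)) stop("invalid fraction index")
  if (idx == scheme$crude_control_index)
    stop("fraction ", idx, " is the crude-extract control, ",
         "not a chromatographic fraction")
  if (idx < 1L || idx > scheme$n_fractions)
    stop("fraction index must be in 1..", scheme$n_fractions)
  start <- scheme$start_offset_s + (idx - 1L) * scheme$fraction_seconds
  c(start, start + scheme$fraction_seconds)
}

#' Call bioactive fractions on a microplate
#'
#' Normalizes every sample well by the plate's control means and calls
#' fractions whose percent inhibition is at least \code{threshold}
#' (inclusive -- the study rule is "at least 70 percent"). Contiguous
#' runs of active fractions are reported as activity windows.
#'
#' @param plate data.frame with columns \code{well}, \code{role} (one
#'   of \code{sample}, \code{medium-control}, \code{growth-control},
#'   \code{positive-control}), \code{fraction} (index, NA for
#'   controls), \code{readout} (>= 0).
#' @param threshold Percent inhibition cut (default 70).
#' @return List with \code{inhibition} (data.frame fraction /
#'   percent), \code{active} (sorted active fraction indices),
#'   \code{windows} (data.frame start / end of contiguous runs).
#' @export
call_active <- function(plate, threshold = 70) {
  req <- c("well", "role", "fraction", "readout")
  if (!is.data.frame(plate) || !all(req %in% names(plate)))
    stop("plate needs columns: ", paste(req, collapse = ", "))
  med <- plate$readout[plate$role == "medium-control"]
  gro <- plate$readout[plate$role == "growth-control"]
  if (length(med) == 0L || length(gro) == 0L)
    stop("plate must contain medium-control and growth-control wells")
  samp <- plate[plate$role == "sample", , drop = FALSE]
  p <- percent_inhibition(samp$readout, mean(med), mean(gro))
  inhibition <- data.frame(fraction = samp$fraction,
                           percent = as.numeric(p))
  agg <- tapply(inhibition$percent, inhibition$fraction, mean)
  frac <- as.integer(names(agg))
  active <- sort(frac[agg >= threshold])
  windows <- if (length(active)) {
    brk <- c(0, which(diff(active) > 1), length(active))
    data.frame(start = active[brk[-length(brk)] + 1],
               end = active[brk[-1]])
  } else {
    data.frame(start = integer(0), end = integer(0))
  }
  list(inhibition = inhibition, active = active, windows = windows)
}

#' Read a reference compound table
#'
#' CSV with columns \code{name}, \code{formula} and optionally
#' \code{adducts} (semicolon-separated; default \code{[M+H]+}).
#'
#' @param path CSV path.
#' @return data.frame with columns \code{name}, \code{formula},
#'   \code{adducts} (list column).
#' @export
read_compound_db <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "formula") %in% names(df)))
    stop("compound table needs columns 'name' and 'formula'")
  df$adducts <- if ("adducts" %in% names(df)) {
    lapply(strsplit(df$adducts, ";"), trimws)
  } else {
    rep(list("[M+H]+"), nrow(df))
  }
  df[, c("name", "formula", "adducts")]
}

#' Dereplicate features in active RT windows against a compound table
#'
#' For every feature whose retention time falls inside an active
#' fraction window, all (compound, adduct) pairs whose theoretical m/z
#' lies within \code{tol_ppm} (inclusive) of the observed m/z are
#' returned, sorted by absolute ppm error. Features with no match are
#' flagged as unknowns -- candidate novel compounds.
#'
#' @param features data.frame with columns \code{rt_s}, \code{mz} (and
#'   optionally \code{intensity}).
#' @param db Compound table as from \code{\link{read_compound_db}}.
#' @param active_fractions Integer vector of active fraction indices;
#'   if NULL, all features are searched.
#' @param scheme A \code{\link{fraction_scheme}} mapping fractions to
#'   RT windows.
#' @param tol_ppm Mass tolerance in ppm, inclusive (default 2).
#' @return List with \code{hits} (data.frame compound / adduct /
#'   theoretical_mz / observed_mz / ppm_error / rt_s / fraction) and
#'   \code{unknowns} (features in active windows with no hit).
#' @export
dereplicate <- function(features, db, active_fractions = NULL,
                        scheme = fraction_scheme(), tol_ppm = 2) {
  stopifnot(is.data.frame(features),
            all(c("rt_s", "mz") %in% names(features)))
  if (!is.data.frame(db))
    stop("compound table must be a data.frame")
  if (is.null(db$adducts)) db$adducts <- rep(list("[M+H]+"), nrow(db))

  frac_of <- function(rt) {
    idx <- floor((rt - scheme$start_offset_s) / scheme$fraction_seconds) + 1
    idx[idx < 1 | idx > scheme$n_fractions] <- NA_integer_
    as.integer(idx)
  }
  features$fraction <- frac_of(features$rt_s)
  in_scope <- if (is.null(active_fractions)) rep(TRUE, nrow(features))
              else features$fraction %in% active_fractions
  feat <- features[in_scope, , drop = FALSE]

  # theoretical m/z per (compound, adduct)
  theo <- data.frame(compound = character(0), adduct = character(0),
                     theoretical_mz = numeric(0))
  if (nrow(db)) theo <- do.call(rbind, lapply(seq_len(nrow(db)), function(i) {
    ad <- db$adducts[[i]]
    data.frame(compound = db$name[i], adduct = ad,
               theoretical_mz = vapply(ad, function(a)
                 adduct_mz(db$formula[i], a), numeric(1)),
               stringsAsFactors = FALSE)
  }))

  hits <- list()
  unknown <- logical(nrow(feat))
  for (i in seq_len(nrow(feat))) {
    err <- ppm_error(feat$mz[i], theo$theoretical_mz)
    ok <- abs(err) <= tol_ppm
    if (any(ok)) {
      hits[[length(hits) + 1L]] <- data.frame(
        compound = theo$compound[ok], adduct = theo$adduct[ok],
        theoretical_mz = theo$theoretical_mz[ok],
        observed_mz = feat$mz[i], ppm_error = err[ok],
        rt_s = feat$rt_s[i], fraction = feat$fraction[i],
        stringsAsFactors = FALSE)
    } else {
      unknown[i] <- TRUE
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(compound = character(0), adduct = character(0),
               theoretical_mz = numeric(0), observed_mz = numeric(0),
               ppm_error = numeric(0), rt_s = numeric(0),
               fraction = integer(0))
  hits <- hits[order(abs(hits$ppm_error)), , drop = FALSE]
  rownames(hits) <- NULL
  unknowns <- feat[unknown, , drop = FALSE]
  if (nrow(unknowns)) unknowns$status <- "unknown - candidate novel"
  list(hits = hits, unknowns = unknowns)
}
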