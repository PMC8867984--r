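#' Droplet encapsulation design
#'
#' Bundles the three knobs of a droplet single-cell encapsulation run:
#' the Poisson loading density lambda (mean cells per droplet), the
#' droplet generation rate, and the droplet diameter.
#'
#' @param lambda Mean number of cells per droplet (dimensionless, >= 0).
#'   A loading of 0.1 means on average one cell per ten droplets.
#' @param rate_hz Droplets generated per second (>= 0).
#' @param diameter_um Droplet diameter in micrometres (>= 0).
#'
#' @return An object of class \code{"droplet_design"}: a list with
#'   elements \code{lambda}, \code{rate_hz}, \code{diameter_um}.
#'
#' @examples
#' d <- droplet_design(lambda = 0.1, rate_hz = 1300, diameter_um = 40)
#' throughput_cells_per_hour(d)
#' @export
droplet_design <- function(lambda, rate_hz = 0, diameter_um = 0) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            is.numeric(rate_hz), length(rate_hz) == 1L, is.finite(rate_hz),
            is.numeric(diameter_um), length(diameter_um) == 1L,
            is.finite(diameter_um))
  if (lambda < 0) stop("'lambda' must be >= 0")
  if (rate_hz < 0) stop("'rate_hz' must be >= 0")
  if (diameter_um < 0) stop("'diameter_um' must be >= 0")
  structure(list(lambda = lambda, rate_hz = rate_hz,
                 diameter_um = diameter_um),
            class = "droplet_design")
}

#' @export
print.droplet_design <- function(x, ...) {
  cat("Droplet encapsulation design\n")
  cat(sprintf("  lambda (cells/droplet): %g\n", x$lambda))
  cat(sprintf("  generation rate:        %g Hz\n", x$rate_hz))
  cat(sprintf("  diameter:               %g um (volume %.2f pl)\n",
              x$diameter_um, droplet_volume_pl(x$diameter_um)))
  cat(sprintf("  co-encapsulation P(k>=2): %.4g\n",
              coculture_probability(x$lambda)))
  cat(sprintf("  throughput: %.0f cells/h\n", throughput_cells_per_hour(x)))
  invisible(x)
}

#' Poisson occupancy distribution of cells per droplet
#'
#' Probability of finding k = 0, 1, ..., \code{k_max} cells in a droplet
#' under Poisson loading with mean \code{lambda}, plus the explicit tail
#' mass P(k > k_max). The tail is reported rather than silently
#' truncated so the distribution always accounts for total mass 1.
#'
#' @param lambda Mean cells per droplet (>= 0).
#' @param k_max Largest occupancy reported individually (default 10).
#' @return An object of class \code{"occupancy_distribution"}: list with
#'   \code{probs} (named numeric, P(k) for k = 0..k_max), \code{tail}
#'   (P(k > k_max)) and \code{lambda}.
#' @examples
#' occupancy(0.1)$probs[1:3]
#' @export
occupancy <- function(lambda, k_max = 10L) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda))
  if (lambda < 0) stop("'lambda' must be >= 0")
  k_max <- as.integer(k_max)
  if (is.na(k_max) || k_max < 0L) stop("'k_max' must be a nonnegative integer")
  k <- 0:k_max
  probs <- stats::dpois(k, lambda)
  names(probs) <- as.character(k)
  tail <- stats::ppois(k_max, lambda, lower.tail = FALSE)
  structure(list(probs = probs, tail = tail, lambda = lambda),
            class = "occupancy_distribution")
}

#' @export
print.occupancy_distribution <- function(x, ...) {
  cat(sprintf("Poisson droplet occupancy, lambda = %g\n", x$lambda))
  print(signif(x$probs, 4))
  cat(sprintf("P(k > %s) = %.4g\n", names(x$probs)[length(x$probs)], x$tail))
  invisible(x)
}

#' Probability that a droplet starts a co-culture
#'
#' Unconditional probability that a droplet contains two or more founder
#' cells under Poisson loading: P(k >= 2) = 1 - exp(-lambda) (1 + lambda).
#' At the loading used for axenic isolation (lambda = 0.1) this is
#' 0.00468, i.e. below 0.5 percent.
#'
#' @param lambda Mean cells per droplet (>= 0).
#' @return Probability in [0, 1].
#' @examples
#' coculture_probability(0.1)  # 0.004679
#' @export
coculture_probability <- function(lambda) {
  stopifnot(is.numeric(lambda), all(is.finite(lambda)))
  if (any(lambda < 0)) stop("'lambda' must be >= 0")
  stats::ppois(1, lambda, lower.tail = FALSE)
}

#' Droplet volume from diameter
#'
#' Sphere volume (4/3) pi (d/2)^3 in cubic micrometres, converted to
#' picolitres (1 um^3 = 1 fl, so volume_pl = um^3 / 1000). A 40 um
#' droplet holds 33.51 pl (~ 33 pl floored).
#'
#' @param diameter_um Droplet diameter in micrometres (>= 0).
#' @param floor_pl If TRUE, floor the result to an integer picolitre
#'   count for report-style presentation. Default FALSE.
#' @return Volume in picolitres.
#' @examples
#' droplet_volume_pl(40)               # 33.51
#' droplet_volume_pl(40, floor_pl = TRUE)  # 33
#' @export
droplet_volume_pl <- function(diameter_um, floor_pl = FALSE) {
  stopifnot(is.numeric(diameter_um), all(is.finite(diameter_um)))
  if (any(diameter_um < 0)) stop("'diameter_um' must be >= 0")
  v <- (4 / 3) * pi * (diameter_um / 2)^3 / 1000
  if (floor_pl) floor(v) else v
}

#' Expected encapsulated cells per hour
#'
#' Expected number of cells encapsulated per hour: generation rate (Hz)
#' times 3600 times lambda. At 1.3 kHz and lambda 0.1 this is 468 000
#' cells per hour.
#'
#' @param design A \code{\link{droplet_design}}.
#' @return Expected cells per hour.
#' @export
throughput_cells_per_hour <- function(design) {
  stopifnot(inherits(design, "droplet_design"))
  design$rate_hz * 3600 * design$lambda
}

#' Simulate per-droplet cell counts
#'
#' Monte-Carlo twin of the analytic occupancy model: i.i.d. Poisson
#' draws of the number of cells per droplet, reproducible for a fixed
#' seed.
#'
#' @param design A \code{\link{droplet_design}}.
#' @param n_droplets Number of droplets to simulate (> 0).
#' @param seed Integer RNG seed.
#' @return Integer vector of length \code{n_droplets}.
#' @export
simulate_droplets <- function(design, n_droplets, seed = 1L) {
  stopifnot(inherits(design, "droplet_design"))
  n_droplets <- as.integer(n_droplets)
  if (is.na(n_droplets) || n_droplets <= 0L)
    stop("'n_droplets' must be a positive integer")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  stats::rpois(n_droplets, design$lambda)
}

# Save/restore .Random.seed so seeded helpers do not disturb the
# caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
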