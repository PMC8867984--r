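# Shared test helpers: independent oracles and small utilities.

# Two labelled partitions describe the same grouping?
partitions_equal <- function(a, b) {
  a <- unlist(a); b <- unlist(b)
  ta <- unname(lapply(split(names(a), a), sort))
  tb <- unname(lapply(split(names(b), b), sort))
  setequal(ta, tb)
}

# Brute-force Kruskal-Wallis H on midranks with tie correction,
# straight from the textbook formula (independent of kruskal.test).
kw_oracle <- function(groups) {
  x <- unlist(groups)
  grp <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, grp, mean)
  n <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(n * rbar^2) - 3 * (N + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr == 0) 0 else H / corr
}

# Dunn z for one pair, by direct rank arithmetic.
dunn_oracle_z <- function(groups, i, j) {
  x <- unlist(groups)
  grp <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, grp, mean)
  n <- lengths(groups)
  ties <- table(x)
  v0 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  (rbar[i] - rbar[j]) / sqrt(v0 * (1 / n[i] + 1 / n[j]))
}

# Exhaustive maximum one-to-one fragment pairing between two peak
# lists within a tolerance; returns the best achievable matched count
# (recursion over candidate pairs; fine for <= 10 peaks).
max_matching_oracle <- function(mza, mzb, tol) {
  cand <- which(abs(outer(mza, mzb, "-")) <= tol, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(0L)
  best <- 0L
  recurse <- function(k, used_a, used_b, count) {
    if (count + (nrow(cand) - k + 1L) <= best) return()
    if (k > nrow(cand)) {
      best <<- max(best, count)
      return()
    }
    ia <- cand[k, 1]; ib <- cand[k, 2]
    if (!used_a[ia] && !used_b[ib]) {
      used_a[ia] <- TRUE; used_b[ib] <- TRUE
      recurse(k + 1L, used_a, used_b, count + 1L)
      used_a[ia] <- FALSE; used_b[ib] <- FALSE
    }
    recurse(k + 1L, used_a, used_b, count)
  }
  recurse(1L, logical(length(mza)), logical(length(mzb)), 0L)
  best
}

# Minimal spectrum constructor for tests.
spec_of <- function(id, pmz, mz, intensity = rep(1e4, length(mz))) {
  msms_spectrum(id, pmz, mz, intensity)
}
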