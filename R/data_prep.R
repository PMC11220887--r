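#' Anomalous differences from Bijvoet pairs
#'
#' Turns merged Bijvoet-pair measurements into anomalous difference
#' magnitudes `|dF| = ||F+| - |F-||` with propagated sigmas,
#' `sig = sqrt(sigF+^2 + sigF-^2)`, the standard approximation to the
#' substructure amplitude |F_A|.  Records are dropped when either mate is
#' unobserved (NA), when a sigma is non-positive, when `|dF|` exceeds
#' `k_reject * sig` (off by default), and when the reflection is centric
#' (phase-restricted, hence carrying no Bijvoet signal) or systematically
#' absent.  Indices are mapped to their Laue-unique representative.
#'
#' @param pairs data frame with columns h, k, l, Fplus, sigFplus, Fminus,
#'   sigFminus (NA marks an unobserved mate)
#' @param cell a [unit_cell()]
#' @param sg a [space_group()]
#' @param k_reject optional outlier cutoff in sigma units (default `Inf`)
#' @return a reflection-set data frame (columns h, k, l, dF, sig_dF, E,
#'   phase, d and the flag columns observed/weak/strong/centric/absent/
#'   beyond_limit) with a `filter_log` attribute of drop counts
#' @export
compute_anomalous_differences <- function(pairs, cell, sg, k_reject = Inf) {
  need <- c("h", "k", "l", "Fplus", "sigFplus", "Fminus", "sigFminus")
  stopifnot(all(need %in% names(pairs)))
  m <- as.matrix(pairs[, c("h", "k", "l")])
  n0 <- nrow(pairs)
  unpaired <- is.na(pairs$Fplus) | is.na(pairs$Fminus)
  badsig <- !unpaired & (is.na(pairs$sigFplus) | is.na(pairs$sigFminus) |
                           pairs$sigFplus <= 0 | pairs$sigFminus <= 0)
  keep <- !unpaired & !badsig
  dF <- abs(pairs$Fplus - pairs$Fminus)
  sig <- sqrt(pairs$sigFplus^2 + pairs$sigFminus^2)
  outlier <- keep & dF > k_reject * sig
  keep <- keep & !outlier
  centric <- is_centric(m, sg)
  absent <- is_systematically_absent(m, sg)
  n_centric <- sum(keep & centric)
  n_absent <- sum(keep & !centric & absent)
  keep <- keep & !centric & !absent
  if (!any(keep))
    stop("no reflections survive filtering; relax k_reject or check input")
  rep_hkl <- asu_representative(m[keep, , drop = FALSE], sg)$hkl
  out <- reflection_set(rep_hkl, dF = dF[keep], sig_dF = sig[keep],
                        cell = cell)
  attr(out, "filter_log") <- c(input = n0, unpaired = sum(unpaired),
                               bad_sigma = sum(badsig),
                               outlier = sum(outlier), centric = n_centric,
                               absent = n_absent, kept = nrow(out))
  out
}

#' Construct a reflection-set data frame
#'
#' @param hkl n x 3 matrix of (Laue-unique) Miller indices
#' @param dF anomalous difference magnitudes (>= 0)
#' @param sig_dF their standard deviations
#' @param cell a [unit_cell()] used to fill the resolution column
#' @param E optional normalized magnitudes
#' @param phase optional phases in radians
#' @return data frame of class `reflection_set`
#' @export
reflection_set <- function(hkl, dF, sig_dF, cell, E = NA_real_,
                           phase = 0) {
  m <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3, byrow = TRUE)
  stopifnot(all(dF >= 0))
  df <- data.frame(h = as.integer(m[, 1]), k = as.integer(m[, 2]),
                   l = as.integer(m[, 3]),
                   dF = dF, sig_dF = sig_dF, E = E, phase = phase,
                   d = d_spacing(cell, m),
                   observed = TRUE, weak = FALSE, strong = FALSE,
                   centric = FALSE, absent = FALSE, beyond_limit = FALSE)
  class(df) <- c("reflection_set", "data.frame")
  df
}

# equal-volume shell boundaries in (1/d)^3 over the kept reflections;
# returns vector of boundaries in 1/d^2 of length n_shells + 1
.shell_bounds <- function(d, n_shells) {
  s3 <- (1 / d)^3
  lo <- min(s3); hi <- max(s3) * (1 + 1e-12)
  b3 <- seq(lo, hi, length.out = n_shells + 1)
  b3^(2 / 3)
}

#' Resolution-shell statistics
#'
#' Bins reflections into `n_shells` equal-volume shells (uniform in 1/d^3)
#' and tabulates the per-shell mean `|dF|/sigma`, mean `|dF|^2` and count.
#'
#' @param refl a reflection-set data frame
#' @param n_shells number of shells (default 10)
#' @return object of class `shell_table`: data frame with columns
#'   s2_lo, s2_hi (shell boundaries in 1/d^2), n, mean_ratio, mean_dF2
#' @export
shell_table <- function(refl, n_shells = 10) {
  use <- refl$observed & !refl$beyond_limit
  d <- refl$d[use]
  if (length(d) < n_shells) stop("too few reflections for ", n_shells, " shells")
  b2 <- .shell_bounds(d, n_shells)
  s2 <- (1 / d)^2
  idx <- findInterval(s2, b2, rightmost.closed = TRUE)
  idx[idx < 1] <- 1; idx[idx > n_shells] <- n_shells
  ratio <- refl$dF[use] / refl$sig_dF[use]
  tab <- data.frame(
    s2_lo = b2[-length(b2)], s2_hi = b2[-1],
    n = as.vector(tabulate(idx, n_shells)),
    mean_ratio = as.vector(tapply(ratio, factor(idx, levels = 1:n_shells),
                                  mean)),
    mean_dF2 = as.vector(tapply(refl$dF[use]^2,
                                factor(idx, levels = 1:n_shells), mean)))
  class(tab) <- c("shell_table", "data.frame")
  tab
}

#' Anomalous-signal resolution cutoff
#'
#' Scans shells from low to high resolution and truncates at the first
#' shell whose mean `|dF|/sigma(dF)` falls below `ratio` (default 1.2, the
#' standard anomalous-resolution criterion): `d_cut` is the low-resolution
#' edge of that shell.  If no shell falls below the criterion the data are
#' kept in full.  Reflections with `d < d_cut` get the `beyond_limit` flag.
#'
#' @param refl a reflection-set data frame
#' @param shells a [shell_table()]; computed from `refl` when missing
#' @param ratio criterion on the shell mean `|dF|/sigma` (default 1.2)
#' @return `refl` with updated `beyond_limit` flags and attribute `d_cut`
#'   (NA when no truncation occurred)
#' @export
estimate_resolution_cutoff <- function(refl, shells = NULL, ratio = 1.2) {
  if (is.null(shells)) shells <- shell_table(refl)
  pop <- shells$n > 0
  if (sum(pop) < 3) stop("need at least 3 populated shells")
  sh <- shells[pop, , drop = FALSE] # ordered low res (small s2) -> high res
  fail <- which(sh$mean_ratio < ratio)
  if (length(fail) == 0) {
    attr(refl, "d_cut") <- NA_real_
    return(refl)
  }
  d_cut <- 1 / sqrt(sh$s2_lo[fail[1]])
  refl$beyond_limit <- refl$d < d_cut
  if (!any(refl$observed & !refl$beyond_limit))
    stop("resolution cutoff removed all reflections")
  attr(refl, "d_cut") <- d_cut
  refl
}

#' Normalize anomalous differences to E values
#'
#' Computes `E = dF / sqrt(<dF^2>)` with the mean-square amplitude taken
#' per resolution shell and smoothed by linear interpolation in 1/d^2
#' between shell centres, so that `<E^2>` is ~1 in every shell.  Optionally
#' corrects for symmetry enhancement (epsilon factors, the Laue-orbit
#' stabilizer order) before normalization, as E-value practice requires.
#' Empty shells are merged into their populated neighbours.
#'
#' @param refl a reflection-set data frame (cutoff applied)
#' @param n_shells number of shells (default 10)
#' @param sg a [space_group()]; needed when `use_epsilon = TRUE`
#' @param use_epsilon apply epsilon-factor correction (default TRUE when
#'   `sg` is given)
#' @return `refl` with the E column filled for kept reflections
#' @export
normalize_to_E <- function(refl, n_shells = 10, sg = NULL,
                           use_epsilon = !is.null(sg)) {
  use <- refl$observed & !refl$beyond_limit
  x <- refl$dF[use]
  if (use_epsilon) {
    if (is.null(sg)) stop("epsilon correction requires sg")
    eps <- epsilon_factor(as.matrix(refl[use, c("h", "k", "l")]), sg)
    x <- x / sqrt(eps)
  }
  d <- refl$d[use]
  s2 <- (1 / d)^2
  b2 <- .shell_bounds(d, n_shells)
  idx <- findInterval(s2, b2, rightmost.closed = TRUE)
  idx[idx < 1] <- 1; idx[idx > n_shells] <- n_shells
  cnt <- tabulate(idx, n_shells)
  msq <- as.vector(tapply(x^2, factor(idx, levels = 1:n_shells), mean))
  ctr <- as.vector(tapply(s2, factor(idx, levels = 1:n_shells), mean))
  ok <- cnt > 0
  if (!all(ok)) message(sum(!ok), " empty shell(s) merged with neighbours")
  interp <- .interp_linear(ctr[ok], msq[ok], s2)
  E <- x / sqrt(interp)
  E <- E / sqrt(mean(E^2)) # exact global <E^2> = 1
  refl$E <- NA_real_
  refl$E[use] <- E
  refl
}

# piecewise-linear interpolation with linear (not constant) extrapolation
# past the end knots; positive floor keeps sqrt() safe for steep falloffs
.interp_linear <- function(x, y, xout) {
  if (length(x) == 1) return(rep(y, length(xout)))
  out <- approx(x, y, xout = xout, rule = 2)$y
  n <- length(x)
  lo <- xout < x[1]
  if (any(lo))
    out[lo] <- y[1] + (y[2] - y[1]) / (x[2] - x[1]) * (xout[lo] - x[1])
  hi <- xout > x[n]
  if (any(hi))
    out[hi] <- y[n] + (y[n] - y[n - 1]) / (x[n] - x[n - 1]) *
      (xout[hi] - x[n])
  pmax(out, min(y[y > 0]) * 1e-3)
}

#' One-call preparation: differences, cutoff, normalization
#'
#' @inheritParams compute_anomalous_differences
#' @param n_shells shells for cutoff scan and normalization
#' @param ratio cutoff criterion on mean `|dF|/sigma`
#' @return normalized reflection set with attributes `d_cut`, `filter_log`
#' @export
prep_anomalous <- function(pairs, cell, sg, n_shells = 10, ratio = 1.2,
                           k_reject = Inf) {
  refl <- compute_anomalous_differences(pairs, cell, sg, k_reject = k_reject)
  flog <- attr(refl, "filter_log")
  refl <- estimate_resolution_cutoff(refl, shell_table(refl, n_shells),
                                     ratio = ratio)
  dcut <- attr(refl, "d_cut")
  refl <- normalize_to_E(refl, n_shells = n_shells, sg = sg)
  attr(refl, "filter_log") <- flog
  attr(refl, "d_cut") <- dcut
  refl
}
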