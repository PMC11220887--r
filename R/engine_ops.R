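# Reference (R-level) implementations of the individual reciprocal- and
# real-space constraint operations.  The C++ trial loop applies the same
# operations; these versions are the documented, testable surface and the
# oracles for the compiled path.

#' Replace calculated moduli by observed moduli
#'
#' Observed reflections get amplitude `E_obs` with the calculated phase
#' kept; unobserved reflections inside the resolution sphere stay free;
#' beyond-limit and systematically absent reflections are forced to zero,
#' as is F(000).
#'
#' @param calc data frame h, k, l, amp, phase of calculated structure
#'   factors
#' @param obs reflection-set data frame carrying E and the flag columns
#' @return `calc` with amplitudes projected
#' @export
amplitude_projection <- function(calc, obs) {
  key <- function(d) paste(d$h, d$k, d$l)
  pos <- match(key(calc), key(obs))
  out <- calc
  hit <- !is.na(pos)
  usable <- hit & obs$observed[pos] & !obs$beyond_limit[pos] &
    !obs$absent[pos]
  out$amp[usable] <- obs$E[pos[usable]]
  kill <- (hit & (obs$beyond_limit[pos] | obs$absent[pos])) |
    (calc$h == 0 & calc$k == 0 & calc$l == 0)
  out$amp[kill] <- 0
  out
}

#' Shift the phases of the weakest observed reflections by pi/2
#'
#' The weak set is the `floor(w_best * n_obs)` observed reflections with
#' smallest `E_obs`, fixed for a whole run.
#'
#' @param refl reflection-set data frame with E and phase columns
#' @param w_best weak fraction in [0, 1]
#' @param sign +1 (default) or -1: direction of the 90 degree shift
#' @return `refl` with shifted phases and the weak flag set
#' @export
pi_half_perturb <- function(refl, w_best, sign = 1) {
  stopifnot(w_best >= 0, w_best <= 1)
  obs_i <- which(refl$observed)
  n_weak <- floor(w_best * length(obs_i))
  refl$weak <- FALSE
  if (n_weak > 0) {
    weak_i <- obs_i[order(refl$E[obs_i])][seq_len(n_weak)]
    refl$weak[weak_i] <- TRUE
    refl$phase[weak_i] <- refl$phase[weak_i] + sign * pi / 2
  }
  refl
}

#' Strong-reflection count rule
#'
#' @param n_obs number of observed reflections
#' @return 1000 for n_obs < 5000; 1300 for 5000 <= n_obs < 8000; 1500 for
#'   n_obs >= 8000; never more than n_obs
#' @export
n_tf_rule <- function(n_obs) {
  stopifnot(n_obs >= 1)
  n <- if (n_obs < 5000) 1000L else if (n_obs < 8000) 1300L else 1500L
  min(n, as.integer(n_obs))
}

#' Tangent-formula phase refinement of the strong set
#'
#' For each strong reflection h the triplet sum
#' `G(h) = sum_k E(k) E(h-k)` runs over pairs with both k and h-k in the
#' strong set (the set is closed under Friedel inversion here, matching
#' the engine's symmetry-expanded convolution).  With `T = Im G`,
#' `B = Re G`, the tangent phase is `atan2(T, B)`; the reliability weight
#' is `alpha = M / max(M)` with `M = E_h |G(h)|`, and the new phase is the
#' argument of `(1-alpha) exp(i phi_c) + alpha exp(i phi_tf)`.
#'
#' @param refl data frame h, k, l, E, phase describing a full (Friedel
#'   complete) reflection list; only observed rows are considered when an
#'   `observed` column is present
#' @param n_tf number of strongest reflections to refine
#' @param method "fft" (convolution of the strong-set E-map) or "brute"
#'   (double loop; the independent oracle)
#' @return `refl` with refined phases on the strong set and the strong
#'   flag set
#' @export
tangent_refine <- function(refl, n_tf, method = c("fft", "brute")) {
  method <- match.arg(method)
  obs <- if ("observed" %in% names(refl)) refl$observed else
    rep(TRUE, nrow(refl))
  cand <- which(obs)
  n_tf <- min(n_tf, length(cand))
  strong <- cand[order(-refl$E[cand])][seq_len(n_tf)]
  sh <- as.matrix(refl[strong, c("h", "k", "l")])
  Es <- complex(modulus = refl$E[strong], argument = refl$phase[strong])
  G <- if (method == "brute") .triplet_brute(sh, Es) else .triplet_fft(sh, Es)
  G[Mod(G) < 1e-9 * sum(refl$E[strong]^2)] <- 0 # FFT roundoff is not signal
  M <- refl$E[strong] * Mod(G)
  mmax <- max(M)
  if ("strong" %in% names(refl)) {
    refl$strong <- FALSE
    refl$strong[strong] <- TRUE
  }
  if (mmax <= 0) return(refl)
  alpha <- M / mmax
  phi_tf <- Arg(G)
  upd <- Mod(G) > 0
  blend <- (1 - alpha) * complex(argument = refl$phase[strong]) +
    alpha * complex(argument = phi_tf)
  refl$phase[strong][upd] <- Arg(blend)[upd]
  refl
}

# brute-force triplet sums: G(h) = sum over k in the set with h-k in the set
.triplet_brute <- function(hkl, E) {
  n <- nrow(hkl)
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  lut <- setNames(seq_len(n), key)
  G <- complex(real = numeric(n))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      rem <- hkl[i, ] - hkl[j, ]
      k <- lut[paste(rem[1], rem[2], rem[3])]
      if (!is.na(k)) G[i] <- G[i] + E[j] * E[k]
    }
  }
  G
}

# same sums via FFT: coefficients of the squared strong-set E-map
.triplet_fft <- function(hkl, E) {
  hspan <- apply(abs(hkl), 2, max)
  dims <- vapply(4 * hspan + 4, .good_dim, integer(1))
  N <- prod(dims)
  idx <- (hkl[, 1] %% dims[1]) + dims[1] * (hkl[, 2] %% dims[2]) +
    dims[1] * dims[2] * (hkl[, 3] %% dims[3]) + 1
  grid <- complex(real = numeric(N))
  grid[idx] <- E
  emap <- fft3_cpp(grid, as.integer(dims), -1L)
  sq <- as.vector(emap)^2
  conv <- fft3_cpp(sq, as.integer(dims), 1L) / N
  as.vector(conv)[idx]
}

#' RAAR real-space constraint
#'
#' Works on the absolute density `|rho_tilde|`: values at or above the
#' threshold `delta` pass through; below it the relaxed update
#' `beta * rho_last + (1 - 2 beta) * |rho_tilde|` applies; the result is
#' made non-negative by a final absolute value.  `delta` is chosen so that
#' exactly `floor(perturb_fraction * N)` grid points fall in the perturbed
#' branch (`delta_mode = "perturbed"`), or the complementary reading
#' (`"pass"`).
#'
#' @param rho_tilde fresh synthesis (3D array)
#' @param rho_last previous constrained map (same dims)
#' @param beta relaxation coefficient in (0, 1); 0.82 is the working value
#' @param perturb_fraction fraction defining the threshold (default 0.13)
#' @param delta optional explicit threshold overriding the quantile
#' @param delta_mode "perturbed" (default) or "pass"
#' @return constrained density array, min >= 0
#' @export
raar_real_space <- function(rho_tilde, rho_last, beta, perturb_fraction,
                            delta = NULL, delta_mode = c("perturbed", "pass")) {
  delta_mode <- match.arg(delta_mode)
  if (!all(dim(rho_tilde) == dim(rho_last))) stop("grid shape mismatch")
  a <- abs(rho_tilde)
  if (is.null(delta))
    delta <- .density_threshold(a, perturb_fraction, delta_mode)
  out <- ifelse(a >= delta, a, beta * rho_last + (1 - 2 * beta) * a)
  abs(out)
}

#' Charge-flipping real-space constraint (baseline)
#'
#' Densities below the threshold are sign-flipped, others kept; no
#' positivity enforcement.
#'
#' @inheritParams raar_real_space
#' @return flipped density array
#' @export
cf_real_space <- function(rho_tilde, perturb_fraction, delta = NULL,
                          delta_mode = c("perturbed", "pass")) {
  delta_mode <- match.arg(delta_mode)
  if (is.null(delta))
    delta <- .density_threshold(abs(rho_tilde), perturb_fraction, delta_mode)
  ifelse(rho_tilde >= delta, rho_tilde, -rho_tilde)
}

.density_threshold <- function(a, frac, delta_mode = "perturbed") {
  N <- length(a)
  k <- floor(frac * N)
  if (delta_mode == "pass") k <- N - k
  if (k <= 0) return(-Inf)
  if (k >= N) return(Inf)
  sort(as.vector(a), partial = k + 1)[k + 1]
}

#' Pearson correlation between observed and calculated E values
#'
#' Zero variance in either argument yields 0 (flat maps correlate with
#' nothing).
#'
#' @param E_obs,E_calc equal-length numeric vectors
#' @return correlation coefficient
#' @export
cc_pearson <- function(E_obs, E_calc) {
  stopifnot(length(E_obs) == length(E_calc), length(E_obs) >= 2)
  if (sd(E_obs) == 0 || sd(E_calc) == 0) return(0)
  x <- E_obs - mean(E_obs); y <- E_calc - mean(E_calc)
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

#' Figures of merit for a map against observed data
#'
#' The classical R factor (with least-squares scale k), the skewness of
#' the density histogram (third standardized moment), and the Pearson CC.
#'
#' @param rho density array
#' @param E_obs,E_calc observed and calculated amplitudes over the
#'   observed set
#' @return list with r_factor, skewness, cc
#' @export
monitor_fom <- function(rho, E_obs, E_calc) {
  k <- sum(E_obs * E_calc) / sum(E_calc^2)
  r <- sum(abs(E_obs - k * E_calc)) / sum(E_obs)
  v <- as.vector(rho)
  z <- v - mean(v)
  skew <- mean(z^3) / (sqrt(mean(z^2))^3)
  list(r_factor = r, skewness = skew, cc = cc_pearson(E_obs, E_calc))
}
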