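#' Specification for a synthetic SAD dataset
#'
#' Describes a point-atom anomalous substructure in a given cell and space
#' group, an optional light-atom background (for Bijvoet-pair simulation),
#' and the measurement-noise model.  Defaults mirror a small Se-substructure
#' experiment: moderate B factors, full occupancies, a 2.0 A anomalous
#' resolution limit and a few-percent amplitude noise.
#'
#' @param cell a [unit_cell()]
#' @param sg a [space_group()]
#' @param n_atoms number of anomalous (heavy) atoms in the asymmetric unit
#' @param f0 normal scattering magnitude of the heavy atom (electrons;
#'   Se ~ 34)
#' @param fp,fpp anomalous corrections f' and f'' (Se K edge ~ -8, 4)
#' @param B isotropic temperature factor(s), A^2 (recycled over atoms)
#' @param occ occupancies (recycled)
#' @param d_min resolution limit in angstrom
#' @param noise_frac relative Gaussian noise on amplitudes (sigma =
#'   noise_frac x shell-mean amplitude)
#' @param n_background number of light background atoms for Bijvoet mode
#' @param f0_light scattering magnitude of a light atom (carbon ~ 6)
#' @param B_light temperature factor of light atoms
#' @param min_sep minimum inter-site separation in angstrom (across all
#'   symmetry images)
#' @param seed RNG seed driving every random choice
#' @return list of class `synthetic_spec`
#' @export
synthetic_spec <- function(cell, sg, n_atoms = 8, f0 = 34, fp = -8, fpp = 4,
                           B = 20, occ = 1, d_min = 2.0, noise_frac = 0.02,
                           n_background = 300, f0_light = 6, B_light = 15,
                           min_sep = 3.5, seed = 1) {
  stopifnot(n_atoms >= 1, d_min > 0, noise_frac >= 0, min_sep >= 0)
  spec <- list(cell = cell, sg = sg, n_atoms = n_atoms, f0 = f0, fp = fp,
               fpp = fpp, B = rep_len(B, n_atoms),
               occ = rep_len(occ, n_atoms), d_min = d_min,
               noise_frac = noise_frac, n_background = n_background,
               f0_light = f0_light, B_light = B_light, min_sep = min_sep,
               seed = seed)
  class(spec) <- "synthetic_spec"
  spec
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Place a random substructure respecting symmetry and minimum separation
#'
#' Rejection-samples uniform fractional positions; a candidate is accepted
#' only if all its symmetry images stay at least `min_sep` angstrom (minimum
#' image convention) from every previously placed site, their images, and
#' its own non-identity images.
#'
#' @param spec a [synthetic_spec()]
#' @param max_tries attempts per atom before giving up
#' @return a site-list data frame (x, y, z fractional; height = occupancy;
#'   rank)
#' @export
place_substructure <- function(spec, max_tries = 2000) {
  cell <- spec$cell; sg <- spec$sg
  expand_images <- function(x) {
    im <- lapply(sg$ops, function(op)
      (as.vector(op$rot %*% x) + op$trans) %% 1)
    do.call(rbind, im)
  }
  with_seed(spec$seed, {
    placed <- NULL       # accepted sites, one row per asymmetric-unit atom
    images <- NULL       # all symmetry images of accepted sites
    for (i in seq_len(spec$n_atoms)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        x <- runif(3)
        im <- expand_images(x)
        # self-clash: non-identity images of x against x itself
        if (nrow(im) > 1) {
          dself <- min_image_dist(cell, im[-1, , drop = FALSE],
                                  matrix(x, nrow(im) - 1, 3, byrow = TRUE))
          if (min(dself) < spec$min_sep) next
        }
        if (!is.null(images)) {
          dd <- outer(seq_len(nrow(im)), seq_len(nrow(images)),
                      function(a, b) min_image_dist(cell, im[a, , drop = FALSE],
                                                    images[b, , drop = FALSE]))
          if (min(dd) < spec$min_sep) next
        }
        placed <- rbind(placed, x)
        images <- rbind(images, im)
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place atom ", i, " with min_sep = ",
                    spec$min_sep, " A; cell too crowded")
    }
    site_list(placed %% 1, height = spec$occ)
  })
}

#' Structure factors of a point-atom model
#'
#' `F(h) = sum_j occ_j f_j exp(-B_j s^2 / 4) sum_ops exp(2 pi i h.(R x_j + t))`
#' with `s = 1/d(h)`.  `f` may be complex (anomalous scattering), in which
#' case Friedel's law is intentionally broken.
#'
#' @param sites site-list data frame (fractional x, y, z)
#' @param cell a [unit_cell()]
#' @param sg a [space_group()]
#' @param hkl n x 3 matrix of indices
#' @param f scattering factor(s), numeric or complex, recycled over sites
#' @param B temperature factor(s), recycled
#' @param occ occupancies, recycled
#' @return complex vector of structure factors, one per row of `hkl`
#' @export
structure_factors <- function(sites, cell, sg, hkl, f = 1, B = 0, occ = 1) {
  m <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3, byrow = TRUE)
  ns <- nrow(sites)
  f <- rep_len(f, ns); B <- rep_len(B, ns); occ <- rep_len(occ, ns)
  s2 <- 1 / d_spacing(cell, m)^2
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  F <- complex(real = numeric(nrow(m)), imaginary = numeric(nrow(m)))
  for (op in sg$ops) {
    hr <- m %*% op$rot                     # h.R x_j  as (hR).x_j
    ht <- as.vector(m %*% op$trans)
    for (j in seq_len(ns)) {
      ph <- 2 * pi * (as.vector(hr %*% xyz[j, ]) + ht)
      F <- F + occ[j] * f[j] * exp(-B[j] * s2 / 4) *
        complex(modulus = 1, argument = ph)
    }
  }
  F
}

# Laue-unique indices inside the resolution sphere (excluding 000)
unique_hkl <- function(cell, sg, d_min) {
  astar <- sqrt(diag(cell$metric_star))
  hmax <- floor(1 / (d_min * astar)) + 1
  g <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                   l = -hmax[3]:hmax[3])
  m <- as.matrix(g)
  m <- m[rowSums(abs(m)) > 0, , drop = FALSE]
  m <- m[d_spacing(cell, m) >= d_min, , drop = FALSE]
  rep_hkl <- asu_representative(m, sg)$hkl
  is_rep <- rowSums(abs(rep_hkl - m)) == 0
  m[is_rep, , drop = FALSE]
}

#' Generate a synthetic SAD dataset with ground truth
#'
#' Two modes.  `direct_fa`: the anomalous difference amplitudes are taken
#' as |F_A| of the substructure itself plus Gaussian noise -- the idealized
#' input to the phase-retrieval engine.  `bijvoet`: a light-atom background
#' structure is added, heavy atoms scatter with complex `f0 + f' + i f''`,
#' and noisy |F+|, |F-| Bijvoet pairs are produced, so that the full
#' preparation pipeline (differences, cutoff, normalization) can be
#' exercised; the uncorrelated background phase makes ||F+|-|F-|| only an
#' approximation to |F_A|.
#'
#' @param spec a [synthetic_spec()]
#' @param mode "direct_fa" or "bijvoet"
#' @return list with elements `sites` (ground truth), `refl` (direct_fa: a
#'   reflection-set), `pairs` (bijvoet: a Bijvoet-pair data frame),
#'   `truth` (data frame h, k, l, F_A modulus and phase of the
#'   normal-scattering substructure factor)
#' @export
make_dataset <- function(spec, mode = c("direct_fa", "bijvoet")) {
  mode <- match.arg(mode)
  cell <- spec$cell; sg <- spec$sg
  sites <- place_substructure(spec)
  hkl <- unique_hkl(cell, sg, spec$d_min)
  fA <- spec$f0 + spec$fp
  FA <- structure_factors(sites, cell, sg, hkl, f = fA, B = spec$B,
                          occ = spec$occ)
  truth <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                      amp = Mod(FA), phase = Arg(FA))
  shell_mean <- function(amp, d, n_shells = 10) {
    b2 <- .shell_bounds(d, n_shells)
    idx <- findInterval((1 / d)^2, b2, rightmost.closed = TRUE)
    idx[idx < 1] <- 1; idx[idx > n_shells] <- n_shells
    mu <- tapply(amp, factor(idx, levels = seq_len(n_shells)), mean)
    mu <- as.vector(mu)
    mu[is.na(mu)] <- mean(amp)
    mu[idx]
  }
  d <- d_spacing(cell, hkl)
  if (mode == "direct_fa") {
    keep <- !is_centric(hkl, sg) & !is_systematically_absent(hkl, sg)
    hklk <- hkl[keep, , drop = FALSE]
    amp <- Mod(FA)[keep]
    mu <- shell_mean(amp, d[keep])
    sig <- pmax(spec$noise_frac, 1e-4) * mu
    dF <- with_seed(spec$seed + 1L,
                    abs(amp + rnorm(length(amp),
                                    sd = spec$noise_frac * mu)))
    refl <- reflection_set(hklk, dF = dF, sig_dF = sig, cell = cell)
    list(mode = mode, sites = sites, refl = refl, truth = truth, spec = spec)
  } else {
    light <- with_seed(spec$seed + 2L,
                       site_list(matrix(runif(3 * spec$n_background),
                                        ncol = 3), height = 1))
    f_heavy <- complex(real = spec$f0 + spec$fp, imaginary = spec$fpp)
    Fp <- structure_factors(light, cell, sg, hkl, f = spec$f0_light,
                            B = spec$B_light) +
      structure_factors(sites, cell, sg, hkl, f = f_heavy, B = spec$B,
                        occ = spec$occ)
    Fm <- structure_factors(light, cell, sg, -hkl, f = spec$f0_light,
                            B = spec$B_light) +
      structure_factors(sites, cell, sg, -hkl, f = f_heavy, B = spec$B,
                        occ = spec$occ)
    mu <- shell_mean(Mod(Fp), d)
    sig <- pmax(spec$noise_frac, 1e-4) * mu
    noisy <- with_seed(spec$seed + 3L, {
      n <- length(mu)
      cbind(Mod(Fp) + rnorm(n, sd = spec$noise_frac * mu),
            Mod(Fm) + rnorm(n, sd = spec$noise_frac * mu))
    })
    pairs <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                        Fplus = pmax(noisy[, 1], 0), sigFplus = sig,
                        Fminus = pmax(noisy[, 2], 0), sigFminus = sig)
    list(mode = mode, sites = sites, pairs = pairs, truth = truth,
         spec = spec)
  }
}
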