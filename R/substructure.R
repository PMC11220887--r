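#' Site list
#'
#' Fractional heavy-atom coordinates with peak heights, sorted by
#' descending height, coordinates wrapped into [0, 1).
#'
#' @param xyz n x 3 matrix of fractional coordinates
#' @param height peak heights (map-sigma units for search results)
#' @return data frame of class `site_list` with columns x, y, z, height,
#'   rank
#' @export
site_list <- function(xyz, height = 1) {
  m <- if (is.matrix(xyz)) xyz else matrix(xyz, ncol = 3, byrow = TRUE)
  height <- rep_len(height, nrow(m))
  ord <- order(-height)
  df <- data.frame(x = m[ord, 1] %% 1, y = m[ord, 2] %% 1,
                   z = m[ord, 3] %% 1, height = height[ord],
                   rank = seq_len(nrow(m)))
  class(df) <- c("site_list", "data.frame")
  df
}

# circularly shifted copy of a 3D array
.shift3 <- function(a, d) {
  dm <- dim(a)
  a[(seq_len(dm[1]) - 1 + d[1]) %% dm[1] + 1,
    (seq_len(dm[2]) - 1 + d[2]) %% dm[2] + 1,
    (seq_len(dm[3]) - 1 + d[3]) %% dm[3] + 1, drop = FALSE]
}

#' Peak search on a density map
#'
#' Finds local maxima over the periodic 26-neighbourhood, refines each to
#' sub-grid precision with separable 3-point parabolic interpolation,
#' suppresses peaks closer than `min_sep` angstrom to a higher peak
#' (symmetry images included when `sg` is given), and returns the top
#' `n_peaks` with heights in map-sigma units.  The conventional cutoff for
#' substructure work is `n_expected + 2` peaks.
#'
#' @param rho 3D density array over the unit cell
#' @param cell a [unit_cell()]
#' @param n_peaks number of peaks to return
#' @param min_sep suppression radius in angstrom (default 1.0)
#' @param sg optional [space_group()] for symmetry-aware suppression
#' @return a [site_list()] (empty for a flat map)
#' @export
find_peaks <- function(rho, cell, n_peaks, min_sep = 1.0, sg = NULL) {
  stopifnot(n_peaks >= 1, length(dim(rho)) == 3)
  dm <- dim(rho)
  mu0 <- mean(rho)
  sdv <- sd(as.vector(rho))
  if (sdv == 0) return(site_list(matrix(numeric(0), 0, 3), numeric(0)))
  # candidate points first (anything prominent), then the exact periodic
  # 26-neighbourhood maximum test on just those; the threshold relaxes
  # until enough maxima turn up
  idx <- integer(0)
  for (level in c(1.5, 0, -Inf)) {
    cand <- which(rho > mu0 + level * sdv)
    if (length(cand) == 0) next
    ijk0 <- arrayInd(cand, dm) - 1L
    keep_max <- rep(TRUE, length(cand))
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ni <- (ijk0[, 1] + di) %% dm[1]
      nj <- (ijk0[, 2] + dj) %% dm[2]
      nk <- (ijk0[, 3] + dk) %% dm[3]
      keep_max <- keep_max & (rho[cand] > rho[1 + ni + dm[1] * nj +
                                                dm[1] * dm[2] * nk])
    }
    idx <- cand[keep_max]
    if (length(idx) >= n_peaks) break
  }
  if (length(idx) == 0) return(site_list(matrix(numeric(0), 0, 3), numeric(0)))
  ord <- order(rho[idx], decreasing = TRUE)
  idx <- idx[ord][seq_len(min(length(idx), 5 * n_peaks + 30))]
  ijk <- arrayInd(idx, dm) - 1L
  # separable parabolic refinement
  frac <- matrix(0, length(idx), 3)
  hts <- rho[idx]
  for (p in seq_along(idx)) {
    pos <- ijk[p, ]
    off <- numeric(3)
    for (ax in 1:3) {
      lo <- pos; hi <- pos
      lo[ax] <- (pos[ax] - 1) %% dm[ax]; hi[ax] <- (pos[ax] + 1) %% dm[ax]
      f0 <- rho[pos[1] + 1, pos[2] + 1, pos[3] + 1]
      fm <- rho[lo[1] + 1, lo[2] + 1, lo[3] + 1]
      fp <- rho[hi[1] + 1, hi[2] + 1, hi[3] + 1]
      den <- fm - 2 * f0 + fp
      if (den < 0) off[ax] <- 0.5 * (fm - fp) / den
      hts[p] <- hts[p] - 0.125 * (fm - fp) * off[ax]
    }
    frac[p, ] <- ((pos + off) / dm) %% 1
  }
  # greedy suppression, symmetry mates included
  keep <- integer(0)
  for (p in seq_along(idx)) {
    cand <- frac[p, , drop = FALSE]
    images <- cand
    if (!is.null(sg) && sg$n_ops > 1)
      images <- do.call(rbind, lapply(sg$ops, function(op)
        (as.vector(op$rot %*% cand[1, ]) + op$trans) %% 1))
    clash <- FALSE
    for (q in keep) {
      dmin <- min(min_image_dist(cell, images,
                                 matrix(frac[q, ], nrow(images), 3,
                                        byrow = TRUE)))
      if (dmin < min_sep) { clash <- TRUE; break }
    }
    if (!clash) keep <- c(keep, p)
    if (length(keep) >= n_peaks) break
  }
  mu <- mean(as.vector(rho))
  site_list(frac[keep, , drop = FALSE], height = (hts[keep] - mu) / sdv)
}

# n_a x n_b distances minimized over all symmetry images of the a sites
.orbit_dist_matrix <- function(cell, sg, a, b) {
  D <- NULL
  for (op in sg$ops) {
    im <- (a %*% t(op$rot) + matrix(op$trans, nrow(a), 3, byrow = TRUE)) %% 1
    Dop <- pair_dist_matrix(cell, im, b)
    D <- if (is.null(D)) Dop else pmin(D, Dop)
  }
  D
}

# greedy nearest-pair matching under a distance matrix; returns pairs
.greedy_match <- function(D, tol) {
  pairs <- NULL
  if (length(D) == 0) return(pairs)
  repeat {
    i <- which.min(D)
    if (!length(i) || !is.finite(D[i]) || D[i] > tol) break
    rc <- arrayInd(i, dim(D))
    pairs <- rbind(pairs, c(rc[1], rc[2], D[i]))
    D[rc[1], ] <- Inf
    D[, rc[2]] <- Inf
  }
  pairs
}

#' Compare two substructure site lists
#'
#' Searches the ambiguity group of phase retrieval -- space-group rotations
#' x permissible origin shifts x enantiomorph inversion -- for the
#' transform of `calc` that best matches `ref`, with continuous
#' optimization of shift components along polar axes.  Matching is greedy
#' nearest-neighbour under periodic minimum-image Cartesian distance with
#' threshold `tol`; site-to-site distances are minimized over symmetry
#' images.  Success follows the >50%-of-reference-sites-matched rule.
#'
#' @param calc calculated (found) site list
#' @param ref reference (true) site list
#' @param sg a [space_group()]
#' @param cell a [unit_cell()]
#' @param tol match distance threshold in angstrom (default 1.5)
#' @return list of class `match_report`: n_ref, n_calc, n_matched,
#'   fraction_matched, mean_dist, rmsd_dist, distances, transform
#'   (rotation index, shift, inverted flag), success
#' @export
match_sites <- function(calc, ref, sg, cell, tol = 1.5) {
  stopifnot(nrow(calc) > 0, nrow(ref) > 0)
  cm <- as.matrix(calc[, c("x", "y", "z")])
  rm_ <- as.matrix(ref[, c("x", "y", "z")])
  polar <- sg$polar_axes
  shifts <- sg$allowed_shifts
  best <- NULL
  score_of <- function(pairs) {
    if (is.null(pairs)) c(0, Inf)
    else c(nrow(pairs), sqrt(mean(pairs[, 3]^2)))
  }
  try_candidate <- function(base, shift, oi, inv) {
    tr <- (sweep(base, 2, shift, "+")) %% 1
    D <- .orbit_dist_matrix(cell, sg, tr, rm_)
    pairs <- .greedy_match(D, tol)
    sc <- score_of(pairs)
    if (is.null(best) || sc[1] > best$score[1] ||
        (sc[1] == best$score[1] && sc[2] < best$score[2]))
      best <<- list(score = sc, pairs = pairs, op = oi, inv = inv,
                    shift = shift, base = base)
    invisible(NULL)
  }
  n_anchor <- min(10, nrow(cm)) # calc sites used to seed shift candidates
  for (oi in seq_along(sg$rotations)) {
    R <- sg$rotations[[oi]]
    for (inv in c(FALSE, TRUE)) {
      base <- t((if (inv) -R else R) %*% t(cm)) %% 1
      # candidate shifts: the discrete permissible set, plus (for polar
      # groups) ref-minus-calc differences with non-polar components
      # snapped onto each permissible discrete value
      cand <- shifts
      if (any(polar)) {
        for (i in seq_len(nrow(rm_))) for (j in seq_len(n_anchor)) {
          d <- (rm_[i, ] - base[j, ]) %% 1
          for (s in seq_len(nrow(shifts))) {
            sn <- d
            sn[!polar] <- shifts[s, !polar]
            cand <- rbind(cand, sn)
          }
        }
        cand <- unique(round(cand, 6))
      }
      for (s in seq_len(nrow(cand)))
        try_candidate(base, cand[s, ], oi, inv)
    }
  }
  # continuous refinement of polar shift components: minimize the rms of
  # currently matched pairs by coordinate-wise line search, then re-match
  if (any(polar) && !is.null(best$pairs)) {
    for (pass in 1:2) {
      for (ax in which(polar)) {
        obj <- function(t_ax) {
          sh <- best$shift; sh[ax] <- t_ax
          tr <- (sweep(best$base, 2, sh, "+")) %% 1
          D <- .orbit_dist_matrix(cell, sg,
                                  tr[best$pairs[, 1], , drop = FALSE],
                                  rm_[best$pairs[, 2], , drop = FALSE])
          mean(diag(D)^2)
        }
        o <- optimize(obj, interval = best$shift[ax] + c(-0.08, 0.08),
                      tol = 1e-7)
        if (o$objective <= obj(best$shift[ax]) + 1e-15)
          best$shift[ax] <- o$minimum %% 1
      }
    }
    try_candidate(best$base, best$shift, best$op, best$inv)
  }
  pairs <- best$pairs
  n_matched <- if (is.null(pairs)) 0L else nrow(pairs)
  dists <- if (is.null(pairs)) numeric(0) else pairs[, 3]
  out <- list(n_ref = nrow(ref), n_calc = nrow(calc), n_matched = n_matched,
              fraction_matched = n_matched / nrow(ref),
              mean_dist = if (n_matched) mean(dists) else NA_real_,
              rmsd_dist = if (n_matched) sqrt(mean(dists^2)) else NA_real_,
              distances = dists,
              transform = list(rotation = sg$rotations[[best$op]],
                               shift = best$shift, inverted = best$inv),
              success = n_matched / nrow(ref) > 0.5)
  class(out) <- "match_report"
  out
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("matched %d / %d reference sites (%.0f%%), rmsd %.3f A [%s]\n",
              x$n_matched, x$n_ref, 100 * x$fraction_matched,
              ifelse(is.na(x$rmsd_dist), NaN, x$rmsd_dist),
              if (x$success) "success" else "failure"))
  invisible(x)
}

#' Summary statistics over a stream of match reports
#'
#' @param reports list of `match_report` objects
#' @return data frame with per-report mean/sd/median of matched distances
#'   plus an `aggregate` attribute of medians over reports
#' @export
positional_stats <- function(reports) {
  stopifnot(length(reports) >= 1)
  per <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    d <- r$distances
    data.frame(report = i, n_matched = r$n_matched,
               fraction = r$fraction_matched,
               mean = if (length(d)) mean(d) else NA_real_,
               sd = if (length(d) > 1) sd(d) else
                 if (length(d) == 1) 0 else NA_real_,
               median = if (length(d)) median(d) else NA_real_)
  }))
  attr(per, "aggregate") <- c(median_mean = median(per$mean, na.rm = TRUE),
                              median_fraction = median(per$fraction))
  per
}

#' Read / write site lists as CSV (x, y, z fractional, height)
#' @param path file path
#' @return a [site_list()]
#' @export
read_sites_csv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",")
  site_list(as.matrix(df[, c("x", "y", "z")]), height = df$height)
}

#' @rdname read_sites_csv
#' @param sites a [site_list()]
#' @export
write_sites_csv <- function(sites, path) {
  utils::write.table(sites[, c("x", "y", "z", "height")], path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write sites as PDB HETATM records (orthogonal angstrom coordinates)
#'
#' Occupancies are heights normalized to the tallest peak; element field is
#' cosmetic.
#'
#' @param sites a [site_list()]
#' @param cell a [unit_cell()]
#' @param path output path
#' @param element two-letter element symbol for the records
#' @export
write_sites_pdb <- function(sites, cell, path, element = "SE") {
  xyz <- frac_to_cart(cell, as.matrix(sites[, c("x", "y", "z")]))
  occ <- sites$height / max(sites$height)
  lines <- sprintf(
    "HETATM%5d %-3s HAT A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(sites)), substr(element, 1, 2), seq_len(nrow(sites)),
    xyz[, 1], xyz[, 2], xyz[, 3], occ, 20.0, element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
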