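# Engine problem construction: translate a prepared reflection set plus
# symmetry into the flat arrays the C++ trial loop consumes.  Built once,
# reused by every trial.

# smallest even 5-smooth integer >= n
.good_dim <- function(n) {
  n <- max(2L, as.integer(ceiling(n)))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L && n %% 2L == 0L) return(n)
    n <- n + 1L
  }
}

#' Set up a phase-retrieval problem
#'
#' Enumerates all Laue-unique reflections inside the resolution sphere,
#' flags systematic absences, matches observed (normalized) data, chooses
#' FFT grid dimensions, and precomputes the symmetry-expansion member
#' tables used by the iteration core.  Grid spacing is at most
#' `d_min / grid_factor` per axis.  The default factor 3 matters: the
#' positivity (absolute-value) step broadens the density spectrum, and on
#' coarser grids (factor 2) the aliased tails fold back into the
#' resolution sphere and breed enantiomorph ghost peaks.
#'
#' @param refl normalized reflection set (E column filled; see
#'   [prep_anomalous()])
#' @param cell a [unit_cell()]
#' @param sg a [space_group()]
#' @param d_min resolution limit; defaults to the best resolution among
#'   kept reflections
#' @param grid_factor oversampling factor (grid spacing <= d_min/factor)
#' @return object of class `engine_problem`
#' @export
build_problem <- function(refl, cell, sg, d_min = NULL, grid_factor = 3) {
  kept <- refl$observed & !refl$beyond_limit & !is.na(refl$E)
  if (!any(kept)) stop("no observed reflections with E values")
  if (is.null(d_min)) d_min <- min(refl$d[kept])
  astar <- sqrt(diag(cell$metric_star))
  hmax <- floor(1 / (d_min * astar)) + 1
  dims <- vapply(1:3, function(i)
    .good_dim(max(grid_factor * c(cell$a, cell$b, cell$c)[i] / d_min,
                  2 * hmax[i] + 2)), integer(1))
  hkl <- unique_hkl(cell, sg, d_min)
  absent <- is_systematically_absent(hkl, sg)
  hkl <- hkl[!absent, , drop = FALSE]
  n_u <- nrow(hkl)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  data_rep <- asu_representative(as.matrix(refl[kept, c("h", "k", "l")]), sg)
  dkey <- key(data_rep$hkl)
  if (anyDuplicated(dkey))
    stop("duplicate Laue-unique reflections in input data")
  pos <- match(key(hkl), dkey)
  obs <- !is.na(pos)
  E_obs <- numeric(n_u)
  E_obs[obs] <- refl$E[kept][pos[obs]]
  members <- .member_tables(hkl, sg, dims)
  # separate alias-free grid for the tangent-formula convolution: index
  # sums reach 2*hmax, so >= 3*hmax + 2 per axis avoids wrap-around onto
  # the strong set (the working grid, sampled for d_min only, does not)
  tf_dims <- vapply(1:3, function(i) .good_dim(3 * hmax[i] + 2), integer(1))
  tf_members <- .member_tables(hkl, sg, tf_dims)
  prob <- list(dims = dims, cell = cell, sg = sg, hkl = hkl,
               obs = obs, E_obs = E_obs, d = d_spacing(cell, hkl),
               d_min = d_min, n_obs = sum(obs),
               member_off = members$off, member_idx = members$idx,
               member_ph = members$ph, member_conj = members$conj,
               member_wt = members$wt,
               tf_dims = tf_dims, tf_member_idx = tf_members$idx,
               tf_member_wt = tf_members$wt)
  class(prob) <- "engine_problem"
  prob
}

#' @export
print.engine_problem <- function(x, ...) {
  cat(sprintf(
    "phase-retrieval problem: %d unique reflections (%d observed), d_min %.2f A, grid %d x %d x %d\n",
    nrow(x$hkl), x$n_obs, x$d_min, x$dims[1], x$dims[2], x$dims[3]))
  invisible(x)
}

# flattened symmetry/Friedel member tables of every unique reflection on
# a given grid: linear indices, unit phases exp(-2 pi i h.t), conjugation
# flags and scatter weights (1 / multiplicity of the index in its unique)
.member_tables <- function(hkl, sg, dims) {
  n_u <- nrow(hkl)
  nops <- length(sg$ops)
  per <- 2L * nops
  idx_m <- matrix(0L, n_u, per)
  conj_m <- matrix(0L, n_u, per)
  ph_m <- matrix(complex(real = 1), n_u, per)
  gidx <- function(m) {
    (m[, 1] %% dims[1]) + dims[1] * (m[, 2] %% dims[2]) +
      dims[1] * dims[2] * (m[, 3] %% dims[3])
  }
  for (o in seq_len(nops)) {
    op <- sg$ops[[o]]
    hr <- hkl %*% op$rot
    p <- exp(-2i * pi * as.vector(hkl %*% op$trans))
    idx_m[, 2 * o - 1] <- as.integer(gidx(hr))
    conj_m[, 2 * o - 1] <- 0L
    ph_m[, 2 * o - 1] <- p
    idx_m[, 2 * o] <- as.integer(gidx(-hr))
    conj_m[, 2 * o] <- 1L
    ph_m[, 2 * o] <- p
  }
  idx <- as.integer(t(idx_m))
  ukey <- rep(seq_len(n_u) - 1, each = per) * prod(dims) + as.numeric(idx)
  o <- order(ukey)
  r <- rle(ukey[o])
  cnt <- numeric(length(ukey))
  cnt[o] <- rep(r$lengths, r$lengths)
  list(off = as.integer(seq(0L, n_u * per, by = per)), idx = idx,
       ph = as.vector(t(ph_m)), conj = as.integer(t(conj_m)),
       wt = 1 / cnt)
}

# R reference implementations of the grid <-> unique-reflection maps,
# used by tests and by init_random_density; the C++ loop replicates them.
.scatter_R <- function(problem, F) {
  N <- prod(problem$dims)
  per <- diff(problem$member_off)
  val <- rep(F, times = per) * problem$member_ph
  cj <- problem$member_conj == 1L
  val[cj] <- Conj(val[cj])
  val <- val * problem$member_wt
  agg <- rowsum(cbind(Re(val), Im(val)), problem$member_idx)
  grid <- complex(real = numeric(N))
  at <- as.integer(rownames(agg)) + 1L
  grid[at] <- complex(real = agg[, 1], imaginary = agg[, 2])
  array(grid, problem$dims)
}

.reduce_R <- function(problem, G) {
  g <- as.vector(G)[problem$member_idx + 1L]
  cj <- problem$member_conj == 1L
  g[cj] <- Conj(g[cj])
  g <- g * Conj(problem$member_ph)
  per <- diff(problem$member_off)
  uid <- rep(seq_along(per), times = per)
  agg <- rowsum(cbind(Re(g), Im(g)), uid)
  complex(real = agg[, 1], imaginary = agg[, 2]) / per
}

#' Random starting density
#'
#' Synthesizes the real map of the symmetry-expanded observed E values
#' combined with random phases satisfying Friedel's law; unobserved
#' coefficients and F(0) are zero, so the map is real with zero mean.
#'
#' @param problem an [build_problem()] result
#' @param seed RNG seed (same stream as the iteration core)
#' @return real 3D array over the unit cell
#' @export
init_random_density <- function(problem, seed) {
  phi <- random_phases_cpp(nrow(problem$hkl), as.integer(seed))
  F <- ifelse(problem$obs,
              complex(modulus = problem$E_obs, argument = phi), 0 + 0i)
  G <- .scatter_R(problem, F)
  N <- prod(problem$dims)
  rho <- fft3_cpp(as.vector(G), as.integer(problem$dims), -1L) / N
  rho <- array(rho, problem$dims)
  imax <- max(abs(Im(rho))); rmax <- max(abs(Re(rho)))
  if (imax > 1e-8 * rmax)
    stop("starting map is not real; symmetry tables inconsistent")
  array(Re(rho), problem$dims)
}
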