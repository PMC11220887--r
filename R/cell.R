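#' Unit cell
#'
#' Construct a crystallographic unit cell from lengths (angstrom) and angles
#' (degrees).  The object carries the orthogonalization matrix (PDB
#' convention: a along x, b in the xy plane), the direct and reciprocal
#' metric tensors and the cell volume.
#'
#' @param a,b,c axis lengths in angstrom (> 0)
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180)
#' @return an object of class `unit_cell`
#' @examples
#' cl <- unit_cell(40, 50, 60)
#' d_spacing(cl, c(1, 0, 0)) # == 40
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("cell lengths must be positive and finite")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  ca <- cospi(alpha / 180); cb <- cospi(beta / 180); cg <- cospi(gamma / 180)
  sg <- sinpi(gamma / 180)
  vfac <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vfac <= 0) stop("cell angles do not define a positive-definite metric")
  vol <- a * b * c * sqrt(vfac)
  orth <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0, vol / (a * b * sg)), 3, 3, byrow = TRUE)
  metric <- crossprod(orth)
  obj <- list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
              orth = orth, metric = metric, metric_star = solve(metric),
              volume = vol)
  class(obj) <- "unit_cell"
  obj
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  %.3f %.3f %.3f  %.2f %.2f %.2f  (V = %.1f A^3)\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

as_hkl_matrix <- function(hkl) {
  if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3, byrow = FALSE,
                                      dimnames = NULL)
}

#' Resolution of reflections
#'
#' @param cell a [unit_cell()]
#' @param hkl integer vector of length 3 or an n x 3 matrix of Miller indices
#' @return d-spacings in angstrom
#' @export
d_spacing <- function(cell, hkl) {
  m <- as_hkl_matrix(hkl)
  if (length(m) == 3 && !is.matrix(hkl)) m <- matrix(hkl, 1, 3)
  q <- rowSums((m %*% cell$metric_star) * m) # |h*|^2 = 1/d^2
  ifelse(q > 0, 1 / sqrt(q), Inf)
}

#' Fractional to Cartesian coordinates
#' @param cell a [unit_cell()]
#' @param x fractional coordinates, length-3 vector or n x 3 matrix
#' @return Cartesian coordinates (angstrom), same shape
#' @export
frac_to_cart <- function(cell, x) {
  m <- if (is.matrix(x)) x else matrix(x, ncol = 3)
  m %*% t(cell$orth)
}

#' Cartesian to fractional coordinates
#' @inheritParams frac_to_cart
#' @export
cart_to_frac <- function(cell, x) {
  m <- if (is.matrix(x)) x else matrix(x, ncol = 3)
  t(solve(cell$orth, t(m)))
}

.cell_is_ortho <- function(cell)
  all(abs(c(cell$alpha, cell$beta, cell$gamma) - 90) < 1e-9)

# minimum-image Cartesian distance between fractional coordinate rows of
# x and y (same number of rows); wrapping alone is exact for rectangular
# cells, oblique cells scan the 27 neighbouring lattice translations
min_image_dist <- function(cell, x, y) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = 3)
  y <- if (is.matrix(y)) y else matrix(y, ncol = 3)
  d0 <- x - y
  d0 <- d0 - round(d0)
  if (.cell_is_ortho(cell))
    return(sqrt((d0[, 1] * cell$a)^2 + (d0[, 2] * cell$b)^2 +
                  (d0[, 3] * cell$c)^2))
  best <- rep(Inf, nrow(d0))
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    dc <- frac_to_cart(cell, sweep(d0, 2, c(i, j, k), "+"))
    best <- pmin(best, sqrt(rowSums(dc^2)))
  }
  best
}

# n_a x n_b matrix of minimum-image distances between fractional rows
pair_dist_matrix <- function(cell, a, b) {
  dx <- outer(a[, 1], b[, 1], "-"); dx <- dx - round(dx)
  dy <- outer(a[, 2], b[, 2], "-"); dy <- dy - round(dy)
  dz <- outer(a[, 3], b[, 3], "-"); dz <- dz - round(dz)
  if (.cell_is_ortho(cell))
    return(sqrt((dx * cell$a)^2 + (dy * cell$b)^2 + (dz * cell$c)^2))
  G <- cell$metric
  best <- matrix(Inf, nrow(a), nrow(b))
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    vx <- dx + i; vy <- dy + j; vz <- dz + k
    d2 <- G[1, 1] * vx^2 + G[2, 2] * vy^2 + G[3, 3] * vz^2 +
      2 * (G[1, 2] * vx * vy + G[1, 3] * vx * vz + G[2, 3] * vy * vz)
    best <- pmin(best, sqrt(pmax(d2, 0)))
  }
  best
}
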