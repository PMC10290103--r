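# 2D Zernike expansion on the unit disk: basis, coefficients,
# rotation-invariant descriptors, reconstruction.
#
# Conventions: indices (n, m) with 0 <= m <= n and n - m even;
# Z_nm(r, psi) = R_nm(r) exp(i m psi);
# c_nm = (n + 1)/pi * integral over the unit disk of conj(Z_nm) f;
# <Z_nm | Z_n'm'> = pi/(n + 1) delta delta.

#' Valid Zernike index set up to a given order
#'
#' @param order maximum radial order N.
#' @return data.frame with columns `n` and `m`, in lexicographic order
#'   (121 rows at N = 20).
#' @export
zernike_index_set <- function(order = 20L) {
  stopifnot(is_number(order), order >= 0)
  order <- as.integer(order)
  idx <- do.call(rbind, lapply(0:order, function(n) {
    m <- seq(n %% 2L, n, by = 2L)
    data.frame(n = n, m = m)
  }))
  rownames(idx) <- NULL
  idx
}

check_index <- function(n, m) {
  if (!(n >= 0 && m >= 0 && m <= n && (n - m) %% 2 == 0))
    stop2("invalid Zernike index (n = ", n, ", m = ", m,
          "): need 0 <= m <= n with n - m even")
}

#' Radial Zernike polynomial
#'
#' `R_nm(r) = sum_k (-1)^k (n-k)! / (k! ((n+m)/2 - k)! ((n-m)/2 - k)!)
#' r^(n-2k)`, for `k = 0 ... (n-m)/2`. The factorial quotients are
#' evaluated in log space so high orders do not overflow, then rounded
#' back to the exact integers they are, which keeps the alternating sum
#' free of cancellation error; at the disk rim `|R_nm(1)| = 1` for every
#' valid index.
#'
#' @param n radial order.
#' @param m azimuthal order (same parity as `n`).
#' @param r radii in `[0, 1]` (vectorized).
#' @return Numeric vector `R_nm(r)`.
#' @export
zernike_radial <- function(n, m, r) {
  check_index(n, m)
  k <- 0:((n - m) / 2)
  coef <- exp(lgamma(n - k + 1) - lgamma(k + 1) -
              lgamma((n + m) / 2 - k + 1) -
              lgamma((n - m) / 2 - k + 1))
  coef <- (-1)^k * ifelse(coef < 2^52, round(coef), coef)
  out <- numeric(length(r))
  for (i in seq_along(k)) out <- out + coef[i] * r^(n - 2 * k[i])
  out
}

#' Complex Zernike polynomial on the disk
#'
#' `Z_nm(r, psi) = R_nm(r) exp(i m psi)`.
#'
#' @inheritParams zernike_radial
#' @param psi azimuthal angles in radians (vectorized with `r`).
#' @return Complex vector.
#' @export
zernike_poly <- function(n, m, r, psi) {
  zernike_radial(n, m, r) * exp(1i * m * psi)
}

# Basis matrix: nodes x indices, Z_nm evaluated at (r, psi).
zernike_basis <- function(r, psi, idx) {
  B <- matrix(0i, length(r), nrow(idx))
  # share radial evaluations across m via a simple loop; orders are small
  for (j in seq_len(nrow(idx)))
    B[, j] <- zernike_poly(idx$n[j], idx$m[j], r, psi)
  B
}

# cache basis matrices for the fixed pixel-center geometry of square grids
.zernike_cache <- new.env(parent = emptyenv())

grid_disk_nodes <- function(pixels) {
  # pixel centers of a pixels x pixels grid spanning [-1, 1]^2,
  # restricted to the unit disk
  step <- 2 / pixels
  cc <- -1 + (seq_len(pixels) - 0.5) * step
  x <- rep(cc, times = pixels)       # row index fastest: matches grid[ix, iy]
  y <- rep(cc, each = pixels)
  r <- sqrt(x^2 + y^2)
  keep <- r <= 1
  list(x = x[keep], y = y[keep], r = r[keep],
       psi = atan2(y[keep], x[keep]), keep = keep,
       weight = step^2)
}

grid_basis_cached <- function(pixels, order) {
  key <- paste0("g", pixels, "_N", order)
  if (!is.null(.zernike_cache[[key]])) return(.zernike_cache[[key]])
  nodes <- grid_disk_nodes(pixels)
  idx <- zernike_index_set(order)
  B <- zernike_basis(nodes$r, nodes$psi, idx)
  val <- list(nodes = nodes, idx = idx, basis = B)
  .zernike_cache[[key]] <- val
  val
}

#' Zernike expansion of scattered disk samples
#'
#' Low-level quadrature behind [zernike_expand()]: treats each sample as
#' a node with the given area weight and evaluates the coefficient
#' integral `c_nm = (n+1)/pi * sum conj(Z_nm) f dA`. Nodes outside the
#' unit disk are dropped.
#'
#' @param x,y node coordinates in unit-disk units.
#' @param f real function values at the nodes.
#' @param weight quadrature area per node (scalar or per-node vector).
#' @param order maximum radial order N.
#' @return An object of class `zernike_expansion` (complex `coefficients`
#'   in [zernike_index_set()] order).
#' @export
zernike_expand_points <- function(x, y, f, weight, order = 20L) {
  r <- sqrt(x^2 + y^2)
  keep <- r <= 1 & is.finite(f)
  if (!any(keep)) stop2("no usable samples inside the unit disk")
  x <- x[keep]; y <- y[keep]; f <- f[keep]
  if (length(weight) > 1L) weight <- weight[keep]
  r <- r[keep]; psi <- atan2(y, x)
  idx <- zernike_index_set(order)
  B <- zernike_basis(r, psi, idx)
  w <- if (length(weight) == 1L) rep(weight, length(f)) else weight
  coef <- as.vector(crossprod(Conj(B), f * w)) * (idx$n + 1) / pi
  structure(list(order = as.integer(order), index = idx,
                 coefficients = coef, disk_scale = NA_real_),
            class = "zernike_expansion")
}

#' Zernike expansion of a projection matrix
#'
#' Discretizes the coefficient integral with the midpoint rule over the
#' pixel centers that fall inside the unit disk (the grid spans the
#' patch's projected disk; `disk_scale` maps it to radius 1). Empty
#' (masked-out) pixels inside the disk are imputed before quadrature:
#' by default each takes the value of its nearest filled pixel, so the
#' sparse hole pattern of a point-sampled patch does not inject spurious
#' high-frequency structure into the coefficients (`fill = "zero"` and
#' `fill = "mean"` are available for comparison).
#'
#' @param pm a `projection_matrix` (any kind with real values: SHAPE,
#'   EM, CEM; SEM works too).
#' @param order maximum radial order N (default 20).
#' @param fill imputation rule for masked pixels inside the disk:
#'   `"nearest"` (default), `"mean"` or `"zero"`.
#' @return A `zernike_expansion`.
#' @export
zernike_expand <- function(pm, order = 20L,
                           fill = c("nearest", "mean", "zero")) {
  stopifnot(inherits(pm, "projection_matrix"))
  fill <- match.arg(fill)
  if (!any(pm$mask)) stop2("all pixels are masked out; nothing to expand")
  pixels <- nrow(pm$grid)
  cache <- grid_basis_cached(pixels, order)
  f <- as.vector(pm$grid)          # column-major: index ix fastest, like nodes
  filled <- as.vector(pm$mask) & !is.na(f)
  hole <- !filled & cache$nodes$keep   # only disk pixels enter the quadrature
  if (any(hole)) {
    f[!filled] <- 0
    if (fill == "mean") {
      f[hole] <- mean(f[filled])
    } else if (fill == "nearest") {
      cc <- -1 + (seq_len(pixels) - 0.5) * (2 / pixels)
      px <- rep(cc, times = pixels); py <- rep(cc, each = pixels)
      src <- which(filled)
      for (i in which(hole)) {
        d2 <- (px[src] - px[i])^2 + (py[src] - py[i])^2
        # average all equidistant nearest neighbours: symmetric in ties
        f[i] <- mean(f[src[d2 <= min(d2) + 1e-12]])
      }
    }
  }
  f <- f[cache$nodes$keep]
  coef <- as.vector(crossprod(Conj(cache$basis), f)) *
    cache$nodes$weight * (cache$idx$n + 1) / pi
  structure(list(order = as.integer(order), index = cache$idx,
                 coefficients = coef, disk_scale = pm$disk_scale),
            class = "zernike_expansion")
}

#' @export
print.zernike_expansion <- function(x, ...) {
  cat(sprintf("zernike_expansion: order %d, %d coefficients\n",
              x$order, length(x$coefficients)))
  invisible(x)
}

#' Rotation-invariant Zernike descriptor
#'
#' The moduli `z_nm = |c_nm|` in fixed index order; invariant under
#' rotations about the disk center (and under global sign flips of the
#' expanded field).
#'
#' @param exp a `zernike_expansion`.
#' @return An object of class `zernike_descriptor` (121 values at
#'   N = 20).
#' @export
zernike_invariants <- function(exp) {
  stopifnot(inherits(exp, "zernike_expansion"))
  structure(list(order = exp$order, index = exp$index,
                 values = Mod(exp$coefficients)),
            class = "zernike_descriptor")
}

#' @export
print.zernike_descriptor <- function(x, ...) {
  cat(sprintf("zernike_descriptor: order %d, length %d, norm %.4g\n",
              x$order, length(x$values), sqrt(sum(x$values^2))))
  invisible(x)
}

#' Reconstruct a field from its Zernike expansion
#'
#' Real-function convention: with coefficients restricted to `m >= 0`,
#' `f = sum w_m Re(c_nm Z_nm)` with `w_0 = 1` and `w_m = 2` for `m > 0`
#' (conjugate-symmetry completion).
#'
#' @param exp a `zernike_expansion`.
#' @param pixels output grid side.
#' @return A `pixels x pixels` matrix over `[-1, 1]^2`, NA outside the
#'   unit disk.
#' @export
zernike_reconstruct <- function(exp, pixels = 25L) {
  stopifnot(inherits(exp, "zernike_expansion"))
  nodes <- grid_disk_nodes(pixels)
  B <- zernike_basis(nodes$r, nodes$psi, exp$index)
  w <- ifelse(exp$index$m == 0L, 1, 2)
  vals <- Re(B %*% (w * exp$coefficients))
  out <- matrix(NA_real_, pixels, pixels)
  out[nodes$keep] <- vals
  out
}

#' Euclidean distance between Zernike descriptors
#'
#' The complementarity metric: the smaller the distance, the more
#' complementary (or similar) the two expanded fields.
#'
#' @param d1,d2 `zernike_descriptor` objects of equal order.
#' @return Non-negative scalar.
#' @export
descriptor_distance <- function(d1, d2) {
  stopifnot(inherits(d1, "zernike_descriptor"),
            inherits(d2, "zernike_descriptor"))
  if (d1$order != d2$order)
    stop2("descriptor order mismatch: ", d1$order, " vs ", d2$order)
  sqrt(sum((d1$values - d2$values)^2))
}

#' Numeric orthogonality check of the Zernike basis
#'
#' Evaluates all pairwise inner products `<Z_nm | Z_n'm'>` on a fine
#' square grid over the unit disk and returns the maximum absolute
#' deviation from the analytic value `pi/(n+1) delta delta`. Pixels cut
#' by the disk rim enter with their coverage fraction (estimated by
#' subpixel sampling) so the quadrature resolves the disk boundary.
#'
#' @param order maximum radial order to include.
#' @param pixels grid side for the quadrature.
#' @return Maximum absolute deviation (scalar), with the full deviation
#'   matrix in attribute `"deviations"`.
#' @export
zernike_orthogonality_check <- function(order = 8L, pixels = 201L) {
  step <- 2 / pixels
  cc <- -1 + (seq_len(pixels) - 0.5) * step
  x <- rep(cc, times = pixels); y <- rep(cc, each = pixels)
  r <- sqrt(x^2 + y^2)
  w <- as.numeric(r <= 1)
  rim <- abs(r - 1) < step
  k <- 8L
  off <- ((seq_len(k) - 0.5) / k - 0.5) * step
  sub <- expand.grid(dx = off, dy = off)
  for (i in which(rim))
    w[i] <- mean((x[i] + sub$dx)^2 + (y[i] + sub$dy)^2 <= 1)
  keep <- w > 0
  idx <- zernike_index_set(order)
  B <- zernike_basis(pmin(r[keep], 1), atan2(y[keep], x[keep]), idx)
  G <- crossprod(Conj(B), B * (w[keep] * step^2))
  expect <- outer(seq_len(nrow(idx)), seq_len(nrow(idx)), function(i, j)
    ifelse(idx$n[i] == idx$n[j] & idx$m[i] == idx$m[j],
           pi / (idx$n[i] + 1), 0))
  dev <- Mod(G - expect)
  structure(max(dev), deviations = dev)
}

#' Serialize a Zernike descriptor as delimited text
#'
#' @param d a `zernike_descriptor`.
#' @param path output path.
#' @return `path` (writer) / a `zernike_descriptor` (reader).
#' @export
write_descriptor <- function(d, path) {
  stopifnot(inherits(d, "zernike_descriptor"))
  df <- data.frame(n = d$index$n, m = d$index$m, z = d$values)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_descriptor
#' @export
read_descriptor <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(list(order = max(df$n), index = df[c("n", "m")],
                 values = df$z),
            class = "zernike_descriptor")
}
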