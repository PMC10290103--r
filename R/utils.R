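# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

as_point_matrix <- function(x, what = "points") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 3L) x <- matrix(x, 1L, 3L)
  if (!is.matrix(x) || ncol(x) != 3L || !is.numeric(x))
    stop2(what, " must be an n x 3 numeric matrix")
  storage.mode(x) <- "double"
  unname(x)
}

row_norms <- function(m) sqrt(rowSums(m * m))

normalize_rows <- function(m) {
  n <- row_norms(m)
  if (any(n < 1e-12)) stop2("cannot normalize zero-length vector(s)")
  m / n
}

unit3 <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop2("cannot normalize a (near-)zero vector")
  v / n
}

#' Rotation matrix from an axis and an angle
#'
#' Rodrigues' formula; the axis need not be normalized.
#'
#' @param axis length-3 numeric rotation axis.
#' @param angle rotation angle in radians.
#' @return A 3x3 orthonormal rotation matrix.
#' @keywords internal
rotation_from_axis_angle <- function(axis, angle) {
  u <- unit3(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Rotation taking unit vector v onto +z. Stable near v == -z.
rotation_to_z <- function(v) {
  v <- unit3(v)
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3L))
  if (c_ < -1 + 1e-12) {
    # 180 degrees about x-axis
    return(diag(c(1, -1, -1)))
  }
  axis <- c(v[2] * z[3] - v[3] * z[2],
            v[3] * z[1] - v[1] * z[3],
            v[1] * z[2] - v[2] * z[1])
  rotation_from_axis_angle(axis, acos(c_))
}

# Per-row minimum Euclidean distance from points in a to points in b,
# computed in chunks to bound memory on large clouds.
min_dist_to_set <- function(a, b, chunk = 1024L) {
  a <- as_point_matrix(a); b <- as_point_matrix(b)
  nb2 <- rowSums(b * b)
  out <- numeric(nrow(a))
  i <- 1L
  while (i <= nrow(a)) {
    j <- min(i + chunk - 1L, nrow(a))
    blk <- a[i:j, , drop = FALSE]
    d2 <- outer(rowSums(blk * blk), nb2, "+") - 2 * tcrossprod(blk, b)
    out[i:j] <- sqrt(pmax(apply(d2, 1L, min), 0))
    i <- j + 1L
  }
  out
}

# Deterministic 32-bit FNV-1a hash of a character scalar, as hex.
# Arithmetic kept in doubles < 2^53 by splitting the 32-bit state.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
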