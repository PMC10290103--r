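# Patch orientation and 2D projection matrices (EM / SEM / CEM / shape).

#' Total-least-squares plane fit
#'
#' Fits a plane through a point set by SVD of the centered coordinates;
#' the normal is the direction of least variance, with its sign aligned
#' to a reference direction (typically the mean surface normal of the
#' patch, so the plane normal points toward the solvent).
#'
#' @param points n x 3 matrix, n >= 3 and not collinear.
#' @param reference_normal optional direction used to pick the normal
#'   sign.
#' @return List with unit `normal`, scalar `offset` (so the plane is
#'   `<x, normal> = offset`) and the point `centroid`.
#' @export
fit_plane <- function(points, reference_normal = NULL) {
  points <- as_point_matrix(points)
  if (nrow(points) < 3L) stop2("plane fit needs at least 3 points")
  centroid <- colMeans(points)
  sv <- svd(sweep(points, 2L, centroid))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop2("degenerate plane fit: points are (near-)collinear")
  normal <- sv$v[, 3L]
  if (!is.null(reference_normal) && sum(normal * reference_normal) < 0)
    normal <- -normal
  list(normal = normal, offset = sum(normal * centroid), centroid = centroid)
}

mean_patch_normal <- function(patch) unit3(colMeans(patch$normals))

make_oriented_patch <- function(points, normals, values, rotation) {
  mz <- mean(normals[, 3L])
  structure(list(points = points, normals = normals, values = values,
                 orientation = if (mz > 0) "up" else "down",
                 rotation = rotation),
            class = "oriented_patch")
}

#' @export
print.oriented_patch <- function(x, ...) {
  cat(sprintf("oriented_patch (%s): %d points%s\n", x$orientation,
              nrow(x$points), if (is.null(x$values)) "" else ", with values"))
  invisible(x)
}

#' Orient a single patch along the z-axis
#'
#' Rotates the patch so that its best-fit-plane normal (solvent side)
#' points along +z (`"up"`) or -z (`"down"`), after translating the patch
#' centroid to the origin. This is the protocol used for independent
#' (decoy) patches and for Zernike comparisons.
#'
#' @param patch a [extract_patch()] result.
#' @param direction `"up"` or `"down"`.
#' @return An `oriented_patch`: rotated points and normals, carried
#'   values, the applied rotation matrix and the realized orientation.
#' @export
orient_single <- function(patch, direction = c("up", "down")) {
  stopifnot(inherits(patch, "surface_patch"))
  direction <- match.arg(direction)
  pl <- fit_plane(patch$points, reference_normal = mean_patch_normal(patch))
  target <- if (direction == "up") pl$normal else -pl$normal
  R <- rotation_to_z(target)
  pts <- sweep(patch$points, 2L, pl$centroid) %*% t(R)
  nrm <- patch$normals %*% t(R)
  make_oriented_patch(pts, nrm, patch$values, R)
}

#' Orient an interacting patch pair with one common rotation
#'
#' The joint orientation axis is the normalized difference between the
#' mean normal of the first patch and the mean normal of the second
#' (i.e. the mean of A's normal and the inverse of B's); one rotation
#' taking that axis to +z is applied to both patches, so partner A ends
#' solvent-up, partner B solvent-down, and the spatial correspondence of
#' facing points is preserved. The midpoint of the two patch centroids is
#' translated to the origin.
#'
#' @param patch_A,patch_B the two interacting patches.
#' @return List of two `oriented_patch` objects (`A`, `B`) sharing the
#'   rotation.
#' @export
orient_pair <- function(patch_A, patch_B) {
  stopifnot(inherits(patch_A, "surface_patch"),
            inherits(patch_B, "surface_patch"))
  nA <- mean_patch_normal(patch_A); nB <- mean_patch_normal(patch_B)
  v <- nA - nB
  if (sqrt(sum(v * v)) < 1e-6)
    stop2("degenerate pair orientation: mean normals coincide")
  v <- unit3(v)
  R <- rotation_to_z(v)
  mid <- (colMeans(patch_A$points) + colMeans(patch_B$points)) / 2
  tr <- function(patch) {
    pts <- sweep(patch$points, 2L, mid) %*% t(R)
    nrm <- patch$normals %*% t(R)
    make_oriented_patch(pts, nrm, patch$values, R)
  }
  list(A = tr(patch_A), B = tr(patch_B))
}

#' Cone origin for the shape projection
#'
#' Finds the point `C = (0, 0, h)` on the z-axis, on the solvent side of
#' an up-oriented patch, such that the largest angle between the
#' (downward) z-axis and a secant from C to any patch point equals
#' `theta` (45 degrees). Solved by bisection on h.
#'
#' @param op an up-oriented `oriented_patch`.
#' @param theta cone half-angle in degrees.
#' @param tol angular tolerance in radians.
#' @return List with `C` (3D point), `h` and `theta`.
#' @export
cone_origin <- function(op, theta = 45, tol = 1e-6) {
  stopifnot(inherits(op, "oriented_patch"))
  if (op$orientation != "up")
    stop2("cone_origin expects an up-oriented patch")
  target <- theta * pi / 180
  p <- op$points
  rho <- sqrt(p[, 1]^2 + p[, 2]^2)
  zmax <- max(p[, 3])
  max_angle <- function(h) max(atan2(rho, h - p[, 3]))
  R <- max(rho, 1e-6)
  lo <- zmax + 1e-9
  hi <- zmax + 10 * max(R, max(rho))
  if (max_angle(hi) > target)
    stop2("no cone origin with theta = ", theta,
          " degrees above the patch (patch too wide/flat for the search range)")
  if (max_angle(lo) < target)
    stop2("no cone origin: even grazing C gives an angle below ", theta,
          " degrees")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (max_angle(mid) > target) lo <- mid else hi <- mid
    if (abs(max_angle(mid) - target) < tol) break
  }
  h <- (lo + hi) / 2
  list(C = c(0, 0, h), h = h, theta = theta)
}

projection_matrix <- function(kind, grid, mask, pixel_size, disk_scale) {
  structure(list(kind = kind, grid = grid, mask = mask,
                 pixel_size = pixel_size, disk_scale = disk_scale),
            class = "projection_matrix")
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat(sprintf("projection_matrix [%s]: %dx%d, %d/%d pixels filled, disk %g A\n",
              x$kind, nrow(x$grid), ncol(x$grid), sum(x$mask),
              length(x$mask), x$disk_scale))
  invisible(x)
}

# Bin projected x-y points on a pixels x pixels grid spanning
# [-extent, extent]^2 and average `values` per pixel.
bin_to_grid <- function(xy, values, pixels, extent) {
  if (is.null(extent)) extent <- max(sqrt(rowSums(xy^2)))
  if (extent <= 0) stop2("degenerate projection: zero planar extent")
  step <- 2 * extent / pixels
  ix <- pmin(pmax(floor((xy[, 1] + extent) / step) + 1L, 1L), pixels)
  iy <- pmin(pmax(floor((xy[, 2] + extent) / step) + 1L, 1L), pixels)
  cell <- (iy - 1L) * pixels + ix
  sums <- rep(0, pixels * pixels)
  cnts <- rep(0L, pixels * pixels)
  agg_s <- tapply(values, cell, sum)
  agg_n <- tapply(values, cell, length)
  at <- as.integer(names(agg_s))
  sums[at] <- agg_s
  cnts[at] <- agg_n
  grid <- matrix(NA_real_, pixels, pixels)
  mask <- matrix(cnts > 0L, pixels, pixels)
  grid[mask] <- (sums / pmax(cnts, 1L))[cnts > 0L]
  list(grid = grid, mask = mask, pixel_size = step, disk_scale = extent)
}

#' Shape projection matrix
#'
#' Projects the oriented patch onto the x-y plane and fills a square
#' pixel grid with the mean distance r from the points in each pixel to
#' the cone origin C; empty pixels are masked out.
#'
#' @param op an up-oriented `oriented_patch`.
#' @param cone a [cone_origin()] result.
#' @param pixels grid side (25).
#' @param extent half-width of the square grid in Angstrom; defaults to
#'   the maximum projected planar radius of the patch, which maps the
#'   projection into the unit disk for the Zernike expansion.
#' @return A `projection_matrix` of kind `"SHAPE"`.
#' @export
project_shape <- function(op, cone, pixels = 25L, extent = NULL) {
  stopifnot(inherits(op, "oriented_patch"))
  r <- sqrt(colSums((t(op$points) - cone$C)^2))
  b <- bin_to_grid(op$points[, 1:2, drop = FALSE], r, pixels, extent)
  projection_matrix("SHAPE", b$grid, b$mask, b$pixel_size, b$disk_scale)
}

#' Electrostatic projection matrix (EM)
#'
#' Projects the oriented patch onto the x-y plane and fills a square
#' pixel grid with the mean electrostatic potential of the points in
#' each pixel; empty pixels are masked out.
#'
#' @inheritParams project_shape
#' @return A `projection_matrix` of kind `"EM"`.
#' @export
project_potential <- function(op, pixels = 25L, extent = NULL) {
  stopifnot(inherits(op, "oriented_patch"))
  if (is.null(op$values))
    stop2("patch carries no potential values; extract it from a potential_surface")
  b <- bin_to_grid(op$points[, 1:2, drop = FALSE], op$values, pixels, extent)
  projection_matrix("EM", b$grid, b$mask, b$pixel_size, b$disk_scale)
}

#' Simplified electrostatic matrix (SEM)
#'
#' Replaces every filled EM pixel by its sign (+1 / -1); exact-zero
#' pixels have no sign and are masked out.
#'
#' @param em a `projection_matrix` of kind `"EM"`.
#' @return A `projection_matrix` of kind `"SEM"` with values in
#'   `{-1, +1}` on filled pixels.
#' @export
em_to_sem <- function(em) {
  stopifnot(inherits(em, "projection_matrix"))
  if (em$kind != "EM") stop2("em_to_sem expects an EM matrix")
  grid <- sign(em$grid)
  mask <- em$mask & !is.na(grid) & grid != 0
  grid[!mask] <- NA_real_
  projection_matrix("SEM", grid, mask, em$pixel_size, em$disk_scale)
}

#' Confined electrostatic matrix (CEM)
#'
#' Clips EM pixels to `[-cap, +cap]` (default 30, in the potential's
#' input units) so the field is bounded for the Zernike expansion.
#'
#' @param em a `projection_matrix` of kind `"EM"`.
#' @param cap clipping bound.
#' @return A `projection_matrix` of kind `"CEM"`.
#' @export
em_to_cem <- function(em, cap = 30) {
  stopifnot(inherits(em, "projection_matrix"))
  if (!em$kind %in% c("EM", "CEM")) stop2("em_to_cem expects an EM matrix")
  grid <- pmin(pmax(em$grid, -cap), cap)
  projection_matrix("CEM", grid, em$mask, em$pixel_size, em$disk_scale)
}

#' Write / read a projection matrix as plain text
#'
#' Serializes the grid (NA for masked pixels) with a small key-value
#' header, so matrices can be exchanged and diffed as text.
#'
#' @param pm a `projection_matrix`.
#' @param path output path.
#' @return `path` (writer) / a `projection_matrix` (reader).
#' @export
write_projection <- function(pm, path) {
  stopifnot(inherits(pm, "projection_matrix"))
  hdr <- c(sprintf("# kind %s", pm$kind),
           sprintf("# pixel_size %.12g", pm$pixel_size),
           sprintf("# disk_scale %.12g", pm$disk_scale))
  rows <- apply(pm$grid, 1L, function(r)
    paste(ifelse(is.na(r), "NA", sprintf("%.12g", r)), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_projection
#' @export
read_projection <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) sub(paste0("# ", key, " "), "", hdr[grepl(key, hdr)])
  body <- lines[!startsWith(lines, "#")]
  grid <- do.call(rbind, lapply(body, function(l)
    as.numeric(ifelse(strsplit(l, "\t")[[1]] == "NA", NA, strsplit(l, "\t")[[1]]))))
  projection_matrix(get("kind"), grid, !is.na(grid),
                    as.numeric(get("pixel_size")), as.numeric(get("disk_scale")))
}
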