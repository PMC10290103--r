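# Synthetic complexes with known ground-truth complementarity.
#
# Two facing sheets sampled at DMS-like density: partner A carries
# Gaussian bumps, partner B the matching dents at a constant gap, so the
# pair is an exact geometric complement. A smooth random potential field
# lives on A; B carries the negated field except on contiguous regions
# covering a controllable fraction of the interface, where the sign is
# flipped back (the cross-interface sign-agreement fraction p).

#' Configuration for the synthetic-complex generator
#'
#' Defaults emulate the study conditions of the real pipeline: 5 surface
#' points per square Angstrom, 9-Angstrom patches, a 2-Angstrom
#' inter-surface gap.
#'
#' @param density surface sampling density (points / Angstrom^2).
#' @param patch_radius patch radius in Angstrom.
#' @param bump_amplitude amplitude of the Gaussian surface bumps
#'   (Angstrom).
#' @param bump_width Gaussian sigma of the bumps (Angstrom).
#' @param noise_sigma vertical Gaussian jitter on sampled points
#'   (Angstrom).
#' @param sign_agreement_p fraction of the facing potential field whose
#'   sign agrees across the interface (0 = perfectly anti-signed fields).
#' @param potential_scale amplitude scale of the potential blobs, in the
#'   field's input units; the default makes a minority of EM pixels
#'   exceed the +/-30 CEM cap so clipping is exercised.
#' @param gap inter-surface distance (Angstrom).
#' @param halfwidth half-width of the square sheets (Angstrom).
#' @param seed integer seed driving all randomness of one complex.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(density = 5, patch_radius = 9,
                             bump_amplitude = 1.5, bump_width = 4,
                             noise_sigma = 0.1, sign_agreement_p = 0.5,
                             potential_scale = 20, gap = 2,
                             halfwidth = 12, seed = 20230623) {
  cfg <- list(density = density, patch_radius = patch_radius,
              bump_amplitude = bump_amplitude, bump_width = bump_width,
              noise_sigma = noise_sigma,
              sign_agreement_p = sign_agreement_p,
              potential_scale = potential_scale, gap = gap,
              halfwidth = halfwidth, seed = as.integer(seed))
  if (cfg$density <= 0) stop2("density must be positive")
  if (cfg$gap <= 0) stop2("gap must be positive")
  if (cfg$sign_agreement_p < 0 || cfg$sign_agreement_p > 1)
    stop2("sign_agreement_p must lie in [0, 1]")
  if (cfg$patch_radius <= 0) stop2("patch_radius must be positive")
  structure(cfg, class = "generator_config")
}

# sum of Gaussian blobs evaluated at (x, y)
blob_field <- function(x, y, centers, widths, amps) {
  out <- numeric(length(x))
  for (i in seq_along(amps)) {
    d2 <- (x - centers[i, 1])^2 + (y - centers[i, 2])^2
    out <- out + amps[i] * exp(-d2 / (2 * widths[i]^2))
  }
  out
}

sample_sheet <- function(n, L) {
  cbind(stats::runif(n, -L, L), stats::runif(n, -L, L))
}

# analytic relief and gradient used for both geometry and normals
make_relief <- function(cfg, L) {
  n_bumps <- max(3L, round((2 * L)^2 / 60))
  centers <- sample_sheet(n_bumps, L * 0.9)
  widths <- stats::runif(n_bumps, 0.7, 1.3) * cfg$bump_width
  amps <- sample(c(-1, 1), n_bumps, replace = TRUE) *
    stats::runif(n_bumps, 0.5, 1) * cfg$bump_amplitude
  f <- function(x, y) blob_field(x, y, centers, widths, amps)
  grad <- function(x, y) {
    gx <- numeric(length(x)); gy <- numeric(length(x))
    for (i in seq_along(amps)) {
      dx <- x - centers[i, 1]; dy <- y - centers[i, 2]
      g <- amps[i] * exp(-(dx^2 + dy^2) / (2 * widths[i]^2)) / widths[i]^2
      gx <- gx - g * dx
      gy <- gy - g * dy
    }
    cbind(gx, gy)
  }
  list(f = f, grad = grad)
}

fake_residue_tags <- function(xy, chain, tile = 2) {
  ix <- floor(xy[, 1] / tile); iy <- floor(xy[, 2] / tile)
  resno <- as.integer(factor(paste(ix, iy)))
  # deterministic residue names without touching the RNG stream
  resname <- AA3[(resno * 7L) %% 20L + 1L]
  data.frame(chain = chain, resno = resno, resname = resname)
}

#' Generate a synthetic complex with known complementarity
#'
#' @param config a [generator_config()].
#' @return A [complex_record()] whose surfaces are
#'   [potential_surface()] objects; the ground truth (interface masks,
#'   patch center indices, realized sign-agreement fraction) is attached
#'   as attribute `"ground_truth"`.
#' @export
gen_complex <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  L <- config$halfwidth
  n <- max(50L, round(config$density * (2 * L)^2))
  relief <- make_relief(config, L)

  xyA <- sample_sheet(n, L)
  xyB <- sample_sheet(n, L)
  fA <- relief$f(xyA[, 1], xyA[, 2])
  fB <- relief$f(xyB[, 1], xyB[, 2])
  zA <- fA + stats::rnorm(n, 0, config$noise_sigma)
  zB <- config$gap + fB + stats::rnorm(n, 0, config$noise_sigma)

  gA <- relief$grad(xyA[, 1], xyA[, 2])
  gB <- relief$grad(xyB[, 1], xyB[, 2])
  nA <- normalize_rows(cbind(-gA[, 1], -gA[, 2], 1))   # A faces up, toward B
  nB <- normalize_rows(cbind(gB[, 1], gB[, 2], -1))    # B faces down, toward A

  surfA <- molecular_surface(cbind(xyA, zA), nA,
                             residue_tags = fake_residue_tags(xyA, "A"),
                             density = config$density)
  surfB <- molecular_surface(cbind(xyB, zB), nB,
                             residue_tags = fake_residue_tags(xyB, "B"),
                             density = config$density)

  # potential: signed Gaussian blobs; B carries the negated field except
  # on flip-back regions selected by thresholding an independent smooth
  # field at the (1 - p) quantile, so the realized point-level
  # sign-agreement fraction is exactly p
  # residue-scale sign domains: blob sigma 1.5-3 A, about one blob per
  # 12 A^2, so a 9-A patch holds a few dozen independent sign regions
  n_pot <- max(8L, round((2 * L)^2 / 12))
  pot_centers <- sample_sheet(n_pot, L)
  pot_widths <- stats::runif(n_pot, 1.5, 3)
  pot_amps <- sample(c(-1, 1), n_pot, replace = TRUE) *
    stats::runif(n_pot, 0.5, 1.5) * config$potential_scale
  phi <- function(x, y) blob_field(x, y, pot_centers, pot_widths, pot_amps)

  flip_centers <- sample_sheet(max(8L, n_pot), L)
  flip_widths <- stats::runif(nrow(flip_centers), 1.5, 3)
  flip_amps <- stats::rnorm(nrow(flip_centers))
  gfield <- function(x, y) blob_field(x, y, flip_centers, flip_widths,
                                      flip_amps)

  potA <- phi(xyA[, 1], xyA[, 2])
  gB_vals <- gfield(xyB[, 1], xyB[, 2])
  p <- config$sign_agreement_p
  agree <- if (p >= 1) rep(TRUE, n) else if (p <= 0) rep(FALSE, n) else
    gB_vals >= stats::quantile(gB_vals, 1 - p)
  potB_base <- phi(xyB[, 1], xyB[, 2])
  potB <- ifelse(agree, potB_base, -potB_base)

  psA <- potential_surface(surfA, potA)
  psB <- potential_surface(surfB, potB)

  # ground truth: constant-gap complement, so the whole facing region is
  # interface; the canonical patch centers are the points nearest the
  # sheet center
  center_A <- which.min(rowSums(cbind(xyA, zA - relief$f(0, 0))^2))
  center_B <- which.min(rowSums(cbind(xyB, zB - config$gap -
                                        relief$f(0, 0))^2))
  gt <- list(sign_agreement_p = p, agree_B = agree,
             mask_A = rep(TRUE, n), mask_B = rep(TRUE, n),
             center_A = center_A, center_B = center_B,
             relief = relief, phi = phi)
  rec <- complex_record(pdb_id = sprintf("SYN%08d", config$seed %% 1e8),
                        surface_A = psA, surface_B = psB)
  attr(rec, "ground_truth") <- gt
  rec
}

#' Generate a pair of random sign matrices (SEM null model)
#'
#' The first matrix has iid equiprobable +/-1 pixels; the second equals
#' the first with probability `p_same` per pixel, independently, and is
#' flipped otherwise. The exact binomial null for the F score: E[F] =
#' `p_same`.
#'
#' @param p_same per-pixel sign-agreement probability.
#' @param pixels grid side.
#' @param seed optional integer seed.
#' @return List of two `projection_matrix` objects of kind `"SEM"` with
#'   all pixels filled.
#' @export
gen_random_sem_pair <- function(p_same = 0.5, pixels = 25L, seed = NULL) {
  if (p_same < 0 || p_same > 1) stop2("p_same must lie in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  m1 <- matrix(sample(c(-1, 1), pixels^2, replace = TRUE), pixels, pixels)
  flip <- matrix(stats::runif(pixels^2) < p_same, pixels, pixels)
  m2 <- ifelse(flip, m1, -m1)
  full <- matrix(TRUE, pixels, pixels)
  list(A = projection_matrix("SEM", m1, full, 2 / pixels, 1),
       B = projection_matrix("SEM", m2, full, 2 / pixels, 1))
}

#' Rigidly rotated copy of a patch
#'
#' Rotates points, normals and center about the patch centroid; values
#' are preserved. Used to exercise the rotation invariance of the
#' descriptor pipeline.
#'
#' @param patch a `surface_patch`.
#' @param axis rotation axis (default: random direction).
#' @param angle rotation angle in radians (default: uniform in
#'   `[0, 2*pi)`).
#' @param seed optional integer seed for the random rotation.
#' @return A `surface_patch` with rotated geometry.
#' @export
gen_rotated_copy <- function(patch, axis = NULL, angle = NULL, seed = NULL) {
  stopifnot(inherits(patch, "surface_patch"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(axis)) axis <- stats::rnorm(3)
  if (is.null(angle)) angle <- stats::runif(1, 0, 2 * pi)
  R <- rotation_from_axis_angle(axis, angle)
  ctr <- colMeans(patch$points)
  rot <- function(m) sweep(sweep(m, 2L, ctr) %*% t(R), 2L, -ctr)
  out <- patch
  out$points <- rot(patch$points)
  out$normals <- patch$normals %*% t(R)
  out$center <- as.vector(ctr + R %*% (patch$center - ctr))
  out
}

#' Write a synthetic complex as DMS and OpenDX files
#'
#' Serializes both partner surfaces in the DMS surface-point dialect and
#' partner A's potential field as an OpenDX grid (the analytic blob
#' field evaluated on a regular 3D grid), so the real file readers can
#' be exercised end to end.
#'
#' @param record a [gen_complex()] result.
#' @param dir output directory (created if needed).
#' @param spacing grid spacing for the OpenDX field (Angstrom).
#' @return Named character vector of the written paths.
#' @export
write_synthetic_complex <- function(record, dir, spacing = 1) {
  stopifnot(inherits(record, "complex_record"))
  gt <- attr(record, "ground_truth")
  if (is.null(gt)) stop2("record carries no generator ground truth")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pA <- file.path(dir, "partnerA.dms")
  pB <- file.path(dir, "partnerB.dms")
  write_dms(record$surface_A$surface, pA)
  write_dms(record$surface_B$surface, pB)
  pts <- rbind(record$surface_A$surface$points, record$surface_B$surface$points)
  lo <- apply(pts, 2L, min) - 2; hi <- apply(pts, 2L, max) + 2
  shape <- pmax(ceiling((hi - lo) / spacing) + 1L, 2L)
  xs <- lo[1] + (seq_len(shape[1]) - 1L) * spacing
  ys <- lo[2] + (seq_len(shape[2]) - 1L) * spacing
  nodes <- expand.grid(x = xs, y = ys)
  plane <- gt$phi(nodes$x, nodes$y)
  vals <- array(rep(plane, times = shape[3]), dim = c(shape[1], shape[2], shape[3]))
  grid <- potential_grid(lo, rep(spacing, 3), shape, vals)
  pDX <- file.path(dir, "potentialA.dx")
  write_dx(grid, pDX)
  c(dms_A = pA, dms_B = pB, dx_A = pDX)
}
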