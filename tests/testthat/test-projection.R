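# Plane fits, patch orientation, cone origin, EM/SEM/CEM/shape matrices.

test_that("fit_plane recovers exact and noisy planes", {
  set.seed(30)
  xy <- cbind(runif(50, -5, 5), runif(50, -5, 5))
  flat <- cbind(xy, 0)
  pl <- fit_plane(flat, reference_normal = c(0, 0, 1))
  expect_close(pl$normal, c(0, 0, 1), 1e-12)
  expect_lt(abs(pl$offset), 1e-12)

  # noiseless tilted plane
  R <- epizern:::rotation_from_axis_angle(c(1, 2, 0), 0.4)
  tilted <- flat %*% t(R)
  true_n <- as.vector(R %*% c(0, 0, 1))
  pl2 <- fit_plane(tilted, reference_normal = true_n)
  expect_close(pl2$normal, true_n, 1e-9)

  # sigma = 0.1 noise: normal within 2 degrees
  noisy <- tilted + cbind(0, 0, rnorm(50, 0, 0.1)) %*% t(R)
  pl3 <- fit_plane(noisy, reference_normal = true_n)
  expect_lt(acos(min(sum(pl3$normal * true_n), 1)) * 180 / pi, 2)

  expect_error(fit_plane(cbind(1:5, 2 * (1:5), 0)), "collinear")
})

test_that("orient_single aligns the patch plane with the z-axis", {
  p <- disk_patch(radius = 6, density = 5, seed = 31)
  up <- orient_single(p, "up")
  expect_equal(up$orientation, "up")
  expect_close(up$rotation %*% t(up$rotation), diag(3), 1e-9)
  expect_close(abs(up$rotation - diag(3)), matrix(0, 3, 3), 1e-6)

  down <- orient_single(p, "down")
  expect_equal(down$orientation, "down")
  # z-coordinates are exactly negated between the two orientations
  expect_close(down$points[, 3], -up$points[, 3], 1e-9)

  # near-planar bumpy patch still ends with |mean normal z| >= 0.99
  rec <- gen_complex(generator_config(bump_amplitude = 0.5, seed = 32))
  gt <- attr(rec, "ground_truth")
  pb <- extract_patch(rec$surface_A, gt$center_A, 9)
  ob <- orient_single(pb, "up")
  expect_gte(mean(ob$normals[, 3]), 0.99)
  od <- orient_single(pb, "down")
  expect_lte(mean(od$normals[, 3]), -0.99)
})

test_that("orient_pair shares one rotation and keeps facing points aligned", {
  rec <- gen_complex(generator_config(bump_amplitude = 0, noise_sigma = 0,
                                      seed = 33))
  gt <- attr(rec, "ground_truth")
  pA <- extract_patch(rec$surface_A, gt$center_A, 6)
  pB <- extract_patch(rec$surface_B, gt$center_B, 6)
  op <- orient_pair(pA, pB)
  expect_identical(op$A$rotation, op$B$rotation)
  expect_gt(mean(op$A$normals[, 3]), 0.9)
  expect_lt(mean(op$B$normals[, 3]), -0.9)
  # flat facing patches: every projected B point has an A point within
  # the sampling spacing (~ 1/sqrt(density))
  dmin <- epizern:::min_dist_to_set(cbind(op$B$points[, 1:2], 0),
                                    cbind(op$A$points[, 1:2], 0))
  expect_lt(stats::median(dmin), 1 / sqrt(5))

  # rigid rotation of the whole complex preserves the paired F score
  f0 <- pair_f_score(pA, pB)$value
  R <- epizern:::rotation_from_axis_angle(c(1, -2, 0.5), 1.1)
  rot_patch <- function(p) {
    p$points <- p$points %*% t(R); p$normals <- p$normals %*% t(R)
    p$center <- as.vector(R %*% p$center); p
  }
  f1 <- pair_f_score(rot_patch(pA), rot_patch(pB))$value
  expect_lt(abs(f1 - f0), 0.1)
})

test_that("cone_origin solves the 45-degree condition", {
  d9 <- orient_single(disk_patch(radius = 9, density = 5, seed = 34), "up")
  c9 <- cone_origin(d9)
  rho_max <- max(sqrt(d9$points[, 1]^2 + d9$points[, 2]^2))
  expect_lt(abs(c9$h - rho_max), 1e-3)   # flat disk: h = disk radius
  d45 <- orient_single(disk_patch(radius = 4.5, density = 10, seed = 35), "up")
  c45 <- cone_origin(d45)
  expect_lt(abs(c45$h - max(sqrt(d45$points[, 1]^2 + d45$points[, 2]^2))),
            1e-3)
  # similarity: scaling the patch scales h
  d9s <- d9
  d9s$points <- d9$points * 2
  expect_lt(abs(cone_origin(d9s)$h - 2 * c9$h), 1e-3)
  # the realized max angle is 45 degrees
  ang <- max(atan2(sqrt(d9$points[, 1]^2 + d9$points[, 2]^2),
                   c9$h - d9$points[, 3]))
  expect_lt(abs(ang - pi / 4), 1e-5)
})

test_that("project_shape holds mean distances to the cone origin", {
  d9 <- orient_single(disk_patch(radius = 9, density = 8, seed = 36), "up")
  c9 <- cone_origin(d9)
  pm <- project_shape(d9, c9)
  expect_equal(pm$kind, "SHAPE")
  expect_equal(dim(pm$grid), c(25L, 25L))
  # center pixel: r = h; near-rim pixel: r = sqrt(h^2 + rho^2)
  h <- c9$h
  expect_lt(abs(pm$grid[13, 13] - h), 0.25)
  rho_rim <- (24 - 12.5) / 12.5 * pm$disk_scale   # center of pixel [13, 24]
  expect_true(pm$mask[13, 24])
  expect_lt(abs(pm$grid[13, 24] - sqrt(h^2 + rho_rim^2)), 0.4)

  # spherical bowl whose rim subtends 45 degrees: the cone origin lands
  # at the center of curvature, so every pixel holds the same r = R0
  set.seed(37)
  R0 <- 12
  rim_rho <- R0 / sqrt(2)
  n <- 3000
  xy <- cbind(runif(n, -rim_rho, rim_rho), runif(n, -rim_rho, rim_rho))
  xy <- xy[rowSums(xy^2) < rim_rho^2, , drop = FALSE]
  xy <- rbind(c(0, 0), xy)
  z <- R0 - sqrt(R0^2 - rowSums(xy^2))
  cap <- cbind(xy, z)
  nrm <- epizern:::normalize_rows(cbind(-xy, R0 - z))  # toward the solvent above
  surf <- molecular_surface(cap, nrm)
  patch <- extract_patch(surf, cap[1, ], 20)
  ocap <- orient_single(patch, "up")
  ccap <- cone_origin(ocap)
  # rim sampling is finite, so h lands slightly below the exact center
  expect_lt(abs(ccap$h - (R0 - mean(z))), 0.2)
  pmc <- project_shape(ocap, ccap)
  vals <- pmc$grid[pmc$mask]
  expect_lt(max(vals) - min(vals), 0.12)
  expect_lt(abs(mean(vals) - R0), 0.2)
})

test_that("project_potential averages per pixel and masks empties", {
  pts <- rbind(c(-0.3, -0.3, 0), c(-0.31, -0.3, 0), c(0.3, 0.3, 0))
  op <- epizern:::make_oriented_patch(pts, matrix(rep(c(0, 0, 1), 3), 3, 3,
                                                  byrow = TRUE),
                                      values = c(2, 4, 7), diag(3))
  pm <- project_potential(op, pixels = 3, extent = 0.45)
  expect_equal(pm$grid[1, 1], 3)       # mean of 2 and 4
  expect_equal(pm$grid[3, 3], 7)
  expect_false(pm$mask[2, 2])          # nothing fell there
  expect_true(is.na(pm$grid[2, 2]))

  # uniform potential fills all masked-in pixels with that value
  d <- disk_patch(radius = 5, density = 5, seed = 38,
                  values = function(xy) rep(7, nrow(xy)))
  pmu <- project_potential(orient_single(d, "up"))
  expect_true(all(pmu$grid[pmu$mask] == 7))

  # linear field phi = x reproduces pixel-center x within pixel_size / 2
  # (orientation recenters the patch, so the centroid shift is added back)
  dl <- disk_patch(radius = 9, density = 20, seed = 39,
                   values = function(xy) xy[, 1])
  pml <- project_potential(orient_single(dl, "up"))
  xbar <- mean(dl$points[, 1])
  centers <- -pml$disk_scale + (seq_len(25) - 0.5) * pml$pixel_size
  xc <- matrix(centers + xbar, 25, 25)
  err <- abs(pml$grid - xc)[pml$mask]
  expect_lt(max(err), pml$pixel_size / 2 + 1e-9)

  # negation symmetry: EM(-phi) = -EM(phi)
  dn <- dl
  dn$values <- -dl$values
  pmn <- project_potential(orient_single(dn, "up"))
  expect_close(pmn$grid[pmn$mask], -pml$grid[pml$mask], 1e-9)
})

test_that("SEM signs and CEM caps follow the printed conventions", {
  grid <- matrix(NA_real_, 25, 25)
  grid[1, 1] <- 12.3; grid[1, 2] <- -4.5; grid[1, 3] <- 0
  grid[2, 1] <- 45; grid[2, 2] <- -100; grid[2, 3] <- 12
  mask <- !is.na(grid)
  em <- epizern:::projection_matrix("EM", grid, mask, 0.72, 9)
  sem <- em_to_sem(em)
  expect_equal(sem$grid[1, 1], 1)
  expect_equal(sem$grid[1, 2], -1)
  expect_false(sem$mask[1, 3])         # zero pixel has no sign
  expect_true(all(sem$grid[sem$mask] %in% c(-1, 1)))

  cem <- em_to_cem(em)
  expect_equal(cem$kind, "CEM")
  expect_equal(cem$grid[2, 1], 30)
  expect_equal(cem$grid[2, 2], -30)
  expect_equal(cem$grid[2, 3], 12)
  # clipping is idempotent
  expect_equal(em_to_cem(cem)$grid, cem$grid)
  expect_error(em_to_sem(sem), "EM")
})

test_that("projection matrices round-trip through text", {
  d <- disk_patch(radius = 5, density = 5, seed = 40,
                  values = function(xy) xy[, 1] - xy[, 2])
  pm <- project_potential(orient_single(d, "up"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_projection(pm, path)
  back <- read_projection(path)
  expect_equal(back$kind, "EM")
  expect_equal(back$mask, pm$mask)
  expect_close(back$grid[back$mask], pm$grid[pm$mask], 1e-10)
  expect_equal(back$disk_scale, pm$disk_scale)
})
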