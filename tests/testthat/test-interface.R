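# Interface masks, patches, surface residues, dimer / structural classes.

test_that("find_interface flags sheets by the 6 A cutoff, symmetrically", {
  A <- flat_sheet(n = 150, halfwidth = 6, z = 0, seed = 10)
  B5 <- flat_sheet(n = 150, halfwidth = 6, z = 5, seed = 11, chain = "B")
  B7 <- flat_sheet(n = 150, halfwidth = 6, z = 7, seed = 11, chain = "B")
  ann5 <- find_interface(A, B5)
  expect_true(all(ann5$mask_A) && all(ann5$mask_B))
  ann7 <- find_interface(A, B7)
  expect_false(any(ann7$mask_A) || any(ann7$mask_B))
  expect_equal(nrow(ann7$residues_A), 0L)

  # symmetry: swapping the arguments transposes the masks
  swapped <- find_interface(B5, A)
  expect_equal(swapped$mask_A, ann5$mask_B)
  expect_equal(swapped$mask_B, ann5$mask_A)
})

test_that("find_interface agrees with the all-pairs distance oracle", {
  rec <- gen_complex(generator_config(halfwidth = 5, seed = 12))
  A <- rec$surface_A$surface; B <- rec$surface_B$surface
  ann <- find_interface(A, B, cutoff = 4)
  d2 <- outer(rowSums(A$points^2), rowSums(B$points^2), "+") -
    2 * tcrossprod(A$points, B$points)
  expect_equal(ann$mask_A, apply(d2, 1, min) < 16)
  expect_equal(ann$mask_B, apply(d2, 2, min) < 16)
})

test_that("patch_center picks the flagged point nearest the centroid", {
  surf <- flat_sheet(n = 80, halfwidth = 6, seed = 13)
  ann <- find_interface(surf, flat_sheet(n = 80, halfwidth = 6, z = 5,
                                         seed = 14, chain = "B"))
  # brute-force oracle over the flagged set
  idx <- which(ann$mask_A)
  centroid <- colMeans(surf$points[idx, ])
  oracle <- idx[which.min(rowSums(sweep(surf$points[idx, ], 2, centroid)^2))]
  got <- patch_center(ann, surf, "A")
  expect_equal(attr(got, "index"), oracle)
  expect_equal(as.numeric(got), unname(surf$points[oracle, ]))

  # single flagged point is its own center
  ann1 <- ann
  ann1$mask_A <- seq_along(ann1$mask_A) == 7L
  expect_equal(attr(patch_center(ann1, surf, "A"), "index"), 7L)

  # symmetric ring: ties broken by lowest index
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  ring <- molecular_surface(cbind(cos(th), sin(th), 0),
                            matrix(rep(c(0, 0, 1), each = 8), 8, 3))
  annr <- list(mask_A = rep(TRUE, 8), mask_B = TRUE,
               residues_A = NULL, residues_B = NULL, cutoff = 6)
  class(annr) <- "interface_annotation"
  expect_equal(attr(patch_center(annr, ring, "A"), "index"), 1L)

  ann0 <- ann
  ann0$mask_A[] <- FALSE
  expect_error(patch_center(ann0, surf, "A"), "empty")
})

test_that("extract_patch honors the radius and the sparse minimum", {
  surf <- flat_sheet(halfwidth = 12, density = 5, seed = 15)
  ctr <- surf$points[which.min(rowSums(surf$points[, 1:2]^2)), ]
  p9 <- extract_patch(surf, ctr, 9)
  expect_true(all(sqrt(rowSums(sweep(p9$points, 2, ctr)^2)) <= 9 + 1e-12))
  # area x density prediction for a fully interior disk
  expect_lt(abs(nrow(p9$points) - 5 * pi * 81) / (5 * pi * 81), 0.10)
  # monotone in radius
  p5 <- extract_patch(surf, ctr, 5)
  expect_true(all(p5$indices %in% p9$indices))
  # radius below the point spacing -> sparse error
  expect_error(extract_patch(surf, ctr, 0.05), "sparse")
  # radius covering everything returns the whole surface
  pall <- extract_patch(surf, ctr, 100)
  expect_equal(nrow(pall$points), nrow(surf$points))
  expect_error(extract_patch(surf, c(50, 50, 50), 9), "not a surface point")
})

test_that("random_patch is seeded, uniform over points, and retries", {
  surf <- flat_sheet(n = 400, halfwidth = 20, seed = 16)
  p1 <- random_patch(surf, radius = 3, rng_seed = 99, min_points = 1)
  p2 <- random_patch(surf, radius = 3, rng_seed = 99, min_points = 1)
  expect_equal(p1$center, p2$center)

  # center distribution uniform over surface points
  set.seed(17)
  counts <- tabulate(replicate(10000, {
    rp <- random_patch(surf, radius = 3, min_points = 1)
    which(rowSums(sweep(surf$points, 2, rp$center)^2) < 1e-12)[1]
  }), nbins = 400)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)

  # min_points is enforced through retries
  p3 <- random_patch(surf, radius = 5, min_points = 3)
  expect_gte(nrow(p3$points), 3)
  expect_error(random_patch(surf, radius = 0.001, min_points = 5,
                            max_retries = 3), "tries")
})

test_that("surface_residues applies a strict RSA threshold", {
  acc <- data.frame(residue = c("r1", "r2", "r3"),
                    resname = c("ALA", "ALA", "GLY"),
                    sasa = c(0.25 * 129, 0.30 * 129, 0))
  out <- surface_residues(acc)
  expect_equal(out$residue, "r2")      # 0.25 exactly is excluded
  expect_equal(out$rsa, 0.30)
  expect_equal(nrow(surface_residues(data.frame(
    residue = "r", resname = "ALA", sasa = 0))), 0L)
  expect_error(surface_residues(data.frame(
    residue = "r", resname = "XXX", sasa = 10)), "XXX")
})

test_that("classify_dimer bins binding-region overlap", {
  expect_equal(as.character(classify_dimer(letters[1:10], letters[1:10])),
               "IBR-hom")
  half <- classify_dimer(letters[1:10], letters[6:15])
  expect_equal(as.character(half), "SBR-hom")
  expect_equal(attr(half, "overlap"), 0.5)
  expect_equal(as.character(classify_dimer(letters[1:5], letters[6:10])),
               "nIBR-hom")
  expect_equal(as.character(classify_dimer(letters[1:5], letters[1:5],
                                           is_heterodimer = TRUE)),
               "nIBR-het")
  # invariant to swapping the partners
  expect_equal(as.character(classify_dimer(letters[6:15], letters[1:10])),
               "SBR-hom")
  # boundary: f exactly 0.7 -> IBR, f exactly 0.3 -> SBR
  expect_equal(as.character(classify_dimer(letters[1:10], letters[4:13])),
               "IBR-hom")
  expect_equal(as.character(classify_dimer(letters[1:10], letters[8:17])),
               "SBR-hom")
  expect_error(classify_dimer(character(), letters[1:3]), "empty")
})

test_that("classify_structural follows the helix/strand majority", {
  expect_equal(classify_structural(rep("H", 5), c("H", "H", "S")), "HH")
  expect_equal(classify_structural(rep("H", 5), rep("S", 4)), "SH")
  expect_equal(classify_structural(rep("S", 3), rep("E", 3)), "SS")
  # tie goes to S
  expect_equal(classify_structural(c("H", "S"), rep("H", 3)), "SH")
  # order-insensitive
  expect_equal(classify_structural(rep("S", 4), rep("H", 5)), "SH")
  expect_error(classify_structural(c("C", "C"), rep("H", 3)),
               "unclassifiable")
})

test_that("complex_record validates Ba against Kd and class labels", {
  s <- flat_sheet(n = 30, seed = 18)
  rec <- complex_record("X", s, s, Kd = 1e-9)
  expect_equal(rec$Ba, -9)
  expect_error(complex_record("X", s, s, Kd = 1e-9, Ba = -3),
               "inconsistent")
  expect_error(complex_record("X", s, s, dimer_class = "nope"), "dimer_class")
})
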