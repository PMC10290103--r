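# DMS / OpenDX / PDB readers and grid-to-surface potential sampling.

dms_lines <- c(
  "SER    1 A  OG   1.000  2.000  3.000 SR0 0.200  0.0000 0.0000 1.0000",
  "SER    1 A  OG   4.000  5.000  6.000 SS0 0.200  0.0000 0.0000 1.0000",
  "GLY    2 A  CA   7.000  8.000  9.000 SC0 0.200  0.0000 0.0000 1.0000")

test_that("read_dms parses surface points, skips atom records, renormalizes", {
  path <- withr::local_tempfile(fileext = ".dms")
  writeLines(c("THR    1 A  OG1  0.1 0.2 0.3 A", dms_lines), path)
  surf <- read_dms(path)
  expect_s3_class(surf, "molecular_surface")
  expect_equal(nrow(surf$points), 3L)  # atom record dropped
  expect_equal(surf$points[1, ], c(1, 2, 3))
  expect_true(all(abs(surf$normals[, 3] - 1) < 1e-9))
  expect_equal(surf$residue_tags$resname, c("SER", "SER", "GLY"))
  expect_equal(surf$residue_tags$chain, c("A", "A", "A"))

  # non-unit stored normal comes back normalized
  path2 <- withr::local_tempfile(fileext = ".dms")
  writeLines("SER 1 A OG 1 2 3 SR0 0.2 0 0 2", path2)
  expect_equal(read_dms(path2)$normals[1, ], c(0, 0, 1))
})

test_that("read_dms rejects malformed records and missing normals", {
  path <- withr::local_tempfile(fileext = ".dms")
  writeLines(c(dms_lines[1], "SER oops"), path)
  expect_error(read_dms(path), "line 2")
  path2 <- withr::local_tempfile(fileext = ".dms")
  writeLines("SER 1 A OG 1 2 3 SR0 0.2", path2)
  expect_error(read_dms(path2), "-n flag")
})

test_that("DMS round-trip preserves geometry to write precision", {
  surf <- flat_sheet(n = 120, seed = 3)
  path <- withr::local_tempfile(fileext = ".dms")
  write_dms(surf, path)
  back <- read_dms(path, density = surf$density)
  expect_close(back$points, surf$points, 1e-4)
  expect_close(back$normals, surf$normals, 1e-3)
  expect_equal(as.character(back$residue_tags$resno),
               as.character(surf$residue_tags$resno))
})

test_that("point count of a density-5 sheet matches area x density", {
  surf <- flat_sheet(halfwidth = 5, density = 5, seed = 4)
  expected <- 5 * 10 * 10
  expect_lt(abs(nrow(surf$points) - expected) / expected, 0.10)
  path <- withr::local_tempfile(fileext = ".dms")
  write_dms(surf, path)
  expect_equal(nrow(read_dms(path)$points), nrow(surf$points))
})

test_that("read_dx parses regular grids in z-fastest order", {
  path <- withr::local_tempfile(fileext = ".dx")
  g0 <- potential_grid(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2), rep(5, 8))
  write_dx(g0, path)
  g <- read_dx(path)
  expect_equal(g$shape, c(2L, 2L, 2L))
  expect_true(all(g$values == 5))

  # 3x4x5: value at linear position ((i-1)*4 + (j-1))*5 + k lands at [i,j,k]
  vals <- seq_len(60)
  g2 <- potential_grid(c(-1, 0, 2), c(0.5, 1, 2), c(3, 4, 5), vals)
  for (probe in list(c(1, 1, 1), c(2, 3, 4), c(3, 4, 5), c(1, 4, 2))) {
    i <- probe[1]; j <- probe[2]; k <- probe[3]
    expect_equal(g2$values[i, j, k], ((i - 1) * 4 + (j - 1)) * 5 + k)
  }
  path2 <- withr::local_tempfile(fileext = ".dx")
  write_dx(g2, path2)
  back <- read_dx(path2)
  expect_equal(back$origin, g2$origin)
  expect_equal(back$spacing, g2$spacing)
  expect_equal(back$shape, g2$shape)
  expect_equal(back$values, g2$values)
})

test_that("read_dx rejects sheared grids and value-count mismatches", {
  path <- withr::local_tempfile(fileext = ".dx")
  writeLines(c("object 1 class gridpositions counts 2 2 2",
               "origin 0 0 0",
               "delta 1 0.5 0", "delta 0 1 0", "delta 0 0 1",
               "object 2 class gridconnections counts 2 2 2",
               "object 3 class array type double rank 0 items 8 data follows",
               "1 2 3", "4 5 6", "7 8"), path)
  expect_error(read_dx(path), "sheared|non-axis")
  writeLines(c("object 1 class gridpositions counts 2 2 2",
               "origin 0 0 0",
               "delta 1 0 0", "delta 0 1 0", "delta 0 0 1",
               "object 2 class gridconnections counts 2 2 2",
               "object 3 class array type double rank 0 items 8 data follows",
               "1 2 3", "4 5 6"), path)
  expect_error(read_dx(path), "integrity")
})

test_that("read_pdb keeps altloc A, drops waters, orders chains by file", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ASP B   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA AASP B   1      12.000   6.000  -6.000  0.60  0.00           C",
    "ATOM      3  CA BASP B   1      13.000   6.000  -6.000  0.40  0.00           C",
    "ATOM      4  N   GLY A   2       1.000   2.000   3.000  1.00  0.00           N",
    "HETATM    5  O   HOH A 101       0.000   0.000   0.000  1.00  0.00           O",
    "END"), path)
  st <- read_pdb(path)
  expect_s3_class(st, "structure3d")
  expect_equal(st$chains, c("B", "A"))
  ca <- st$atoms[st$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1L)       # altloc B dropped
  expect_equal(ca$x, 12)
  expect_false(any(st$atoms$resname == "HOH"))
  writeLines("END", path)
  expect_error(read_pdb(path), "ATOM")
})

test_that("sample_potential follows the nearest-node rule", {
  surf <- flat_sheet(n = 100, halfwidth = 4, z = 0.5, seed = 5)
  g <- potential_grid(c(-5, -5, -1), c(1, 1, 1), c(11, 11, 3),
                      rep(5, 11 * 11 * 3))
  ps <- sample_potential(g, surf)
  expect_true(all(ps$potential == 5))

  # point exactly on a node picks that node's value
  one <- molecular_surface(matrix(c(-5, -5, -1), 1, 3), matrix(c(0, 0, 1), 1, 3))
  vals <- seq_len(11 * 11 * 3)
  gv <- potential_grid(c(-5, -5, -1), c(1, 1, 1), c(11, 11, 3), vals)
  expect_equal(sample_potential(gv, one)$potential, gv$values[1, 1, 1])

  # linear ramp phi = x: nearest-node error bounded by spacing / 2
  set.seed(6)
  pts <- cbind(runif(100, -4, 4), runif(100, -4, 4), runif(100, -0.5, 0.5))
  rand <- molecular_surface(pts, matrix(rep(c(0, 0, 1), each = 100), 100, 3))
  xs <- -5 + 0:10
  ramp <- array(rep(xs, times = 11 * 3), dim = c(11, 11, 3))
  gr <- potential_grid(c(-5, -5, -1), c(1, 1, 1), c(11, 11, 3), ramp)
  smp <- sample_potential(gr, rand)
  expect_lte(max(abs(smp$potential - pts[, 1])), 0.5 + 1e-9)
  # trilinear is exact on a linear field in the interior
  tri <- sample_potential(gr, rand, method = "trilinear")
  expect_close(tri$potential, pts[, 1], 1e-9)
})

test_that("sample_potential names points outside the grid", {
  surf <- molecular_surface(rbind(c(0, 0, 0), c(99, 0, 0)),
                            rbind(c(0, 0, 1), c(0, 0, 1)))
  g <- potential_grid(c(-1, -1, -1), c(1, 1, 1), c(3, 3, 3), rep(0, 27))
  expect_error(sample_potential(g, surf), "indices 2")
})
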