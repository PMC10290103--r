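# Shared fixtures, all built in code.

# flat square sheet of surface points with +z normals
flat_sheet <- function(n = 200L, halfwidth = 10, z = 0, density = NA,
                       seed = 1L, chain = "A") {
  set.seed(seed)
  if (!is.na(density)) n <- round(density * (2 * halfwidth)^2)
  xy <- cbind(runif(n, -halfwidth, halfwidth),
              runif(n, -halfwidth, halfwidth))
  molecular_surface(cbind(xy, z),
                    matrix(rep(c(0, 0, 1), each = n), n, 3),
                    residue_tags = data.frame(
                      chain = chain,
                      resno = floor(xy[, 1] / 2) * 100 + floor(xy[, 2] / 2),
                      resname = "ALA"),
                    density = if (is.na(density)) n / (2 * halfwidth)^2
                              else density)
}

# flat disk patch centered at the origin (exact center point included)
disk_patch <- function(radius = 9, density = 5, z = 0, seed = 2L,
                       values = NULL) {
  set.seed(seed)
  n <- round(density * pi * radius^2 * 1.5)
  xy <- cbind(runif(n, -radius, radius), runif(n, -radius, radius))
  xy <- xy[rowSums(xy^2) <= radius^2, , drop = FALSE]
  xy <- rbind(c(0, 0), xy)
  n <- nrow(xy)
  surf <- molecular_surface(cbind(xy, z),
                            matrix(rep(c(0, 0, 1), each = n), n, 3),
                            density = density)
  ps <- if (is.null(values)) surf else potential_surface(surf, values(xy))
  extract_patch(ps, c(0, 0, z), radius)
}

# projection_matrix holding f(x, y) sampled on a pixel grid over [-1,1]^2
fn_matrix <- function(f, pixels = 201L, kind = "EM") {
  step <- 2 / pixels
  cc <- -1 + (seq_len(pixels) - 0.5) * step
  x <- matrix(cc, pixels, pixels)
  y <- matrix(cc, pixels, pixels, byrow = TRUE)
  g <- f(x, y)
  m <- x^2 + y^2 <= 1
  g[!m] <- NA
  epizern:::projection_matrix(kind, g, m, step, 1)
}

# minimal structure3d from a residue table (one CB-like atom per residue)
toy_structure <- function(df) {
  atoms <- data.frame(chain = df$chain, resno = df$resno, insert = "",
                      resname = df$resname, elety = "CB",
                      x = df$x, y = df$y, z = df$z)
  structure(list(atoms = atoms, chains = unique(atoms$chain)),
            class = "structure3d")
}

coef_at <- function(exp, n, m) {
  exp$coefficients[exp$index$n == n & exp$index$m == m]
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
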