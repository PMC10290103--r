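# Containers and readers for molecular surfaces and potential grids.

#' Construct a molecular surface
#'
#' An oriented point cloud sampling the solvent-accessible surface of a
#' protein, as produced by DMS: 3D points in Angstrom, outward unit
#' normals and per-point residue tags.
#'
#' @param points n x 3 numeric matrix of coordinates (Angstrom).
#' @param normals n x 3 numeric matrix of outward normals; renormalized to
#'   unit length on construction.
#' @param residue_tags optional data.frame with one row per point and
#'   columns `chain`, `resno`, `resname`.
#' @param density nominal sampling density in points per square Angstrom.
#' @return An object of class `molecular_surface`.
#' @export
molecular_surface <- function(points, normals, residue_tags = NULL,
                              density = NA_real_) {
  points <- as_point_matrix(points, "points")
  normals <- as_point_matrix(normals, "normals")
  if (nrow(points) != nrow(normals))
    stop2("points and normals must have the same number of rows")
  if (nrow(points) == 0L) stop2("a molecular surface needs at least one point")
  normals <- normalize_rows(normals)
  if (!is.null(residue_tags)) {
    residue_tags <- as.data.frame(residue_tags)
    if (nrow(residue_tags) != nrow(points))
      stop2("residue_tags must have one row per surface point")
    needed <- c("chain", "resno", "resname")
    if (!all(needed %in% names(residue_tags)))
      stop2("residue_tags needs columns chain, resno, resname")
    residue_tags <- residue_tags[needed]
  }
  if (!is.na(density) && density <= 0) stop2("density must be positive")
  structure(list(points = points, normals = normals,
                 residue_tags = residue_tags, density = density),
            class = "molecular_surface")
}

#' @export
print.molecular_surface <- function(x, ...) {
  cat(sprintf("molecular_surface: %d points (density %s / A^2)\n",
              nrow(x$points),
              if (is.na(x$density)) "?" else format(x$density)))
  invisible(x)
}

n_points <- function(surface) nrow(surface$points)

#' Attach per-point electrostatic potentials to a surface
#'
#' @param surface a [molecular_surface()].
#' @param potential numeric vector, one finite value per surface point, in
#'   the solver's output units (kT/e for APBS); values are carried opaquely.
#' @return An object of class `potential_surface`.
#' @export
potential_surface <- function(surface, potential) {
  stopifnot(inherits(surface, "molecular_surface"))
  potential <- as.numeric(potential)
  if (length(potential) != n_points(surface))
    stop2("need exactly one potential value per surface point")
  if (!all(is.finite(potential))) stop2("potential values must be finite")
  structure(list(surface = surface, potential = potential),
            class = "potential_surface")
}

#' @export
print.potential_surface <- function(x, ...) {
  cat(sprintf("potential_surface: %d points, potential in [%.3g, %.3g]\n",
              n_points(x$surface), min(x$potential), max(x$potential)))
  invisible(x)
}

#' Read a DMS molecular-surface file
#'
#' Parses the DMS surface-point dialect: whitespace-separated records
#' holding residue name, residue number, (optional) chain id, atom name,
#' x y z, a point-type code and, for surface points written with the `-n`
#' flag, an exposed area followed by the unit normal. Atom records (type
#' `A`) are skipped; only surface points (type starting with `S`) are
#' kept. Normals are renormalized to unit length.
#'
#' @param path path to a DMS file.
#' @param density nominal sampling density recorded on the surface
#'   (points per square Angstrom); DMS does not store it in the file.
#' @return A [molecular_surface()].
#' @export
read_dms <- function(path, density = 5) {
  if (!file.exists(path)) stop2("DMS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  pts <- vector("list", length(idx))
  nrm <- vector("list", length(idx))
  tags <- vector("list", length(idx))
  k <- 0L
  for (li in idx) {
    tok <- strsplit(trimws(lines[li]), "[[:space:]]+")[[1]]
    num <- suppressWarnings(as.numeric(tok))
    is_num <- !is.na(num)
    # locate the coordinate triple: first run of >= 3 numeric tokens
    # after at least 3 leading descriptor tokens
    ci <- NA_integer_
    for (i in seq_len(length(tok) - 2L)) {
      if (i >= 3L && all(is_num[i:(i + 2L)])) { ci <- i; break }
    }
    if (is.na(ci) || length(tok) < ci + 3L)
      stop2("malformed DMS record at line ", li)
    type <- tok[ci + 3L]
    if (is_num[ci + 3L])
      stop2("malformed DMS record at line ", li, ": no point-type code")
    if (!startsWith(toupper(type), "S")) next  # atom record
    trail <- num[seq(ci + 4L, length.out = length(tok) - ci - 3L)]
    trail <- trail[!is.na(trail)]
    if (length(trail) < 3L)
      stop2("DMS surface point at line ", li, " has no normal vector; ",
            "regenerate the surface with the -n flag")
    nv <- trail[(length(trail) - 2L):length(trail)]
    resname <- tok[1L]
    resno_tok <- tok[2L]
    chain <- ""
    if (ci - 1L >= 4L) {           # RES NUM CHAIN ATOM
      chain <- tok[3L]
    } else if (grepl("[A-Za-z]$", resno_tok)) {  # chain glued to number
      chain <- sub("^.*?([A-Za-z])$", "\\1", resno_tok)
      resno_tok <- sub("[A-Za-z]$", "", resno_tok)
    }
    k <- k + 1L
    pts[[k]] <- num[ci:(ci + 2L)]
    nrm[[k]] <- nv
    tags[[k]] <- c(chain, resno_tok, resname)
  }
  if (k == 0L) stop2("no surface-point records in ", path)
  pts <- do.call(rbind, pts[seq_len(k)])
  nrm <- do.call(rbind, nrm[seq_len(k)])
  tg <- do.call(rbind, tags[seq_len(k)])
  molecular_surface(pts, nrm,
                    residue_tags = data.frame(chain = tg[, 1L],
                                              resno = tg[, 2L],
                                              resname = tg[, 3L]),
                    density = density)
}

#' Write a molecular surface in the DMS surface-point dialect
#'
#' @param surface a [molecular_surface()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dms <- function(surface, path) {
  stopifnot(inherits(surface, "molecular_surface"))
  tg <- surface$residue_tags
  if (is.null(tg))
    tg <- data.frame(chain = "A", resno = "1",
                     resname = "UNK")[rep(1L, n_points(surface)), ]
  area <- if (is.na(surface$density)) 0.2 else 1 / surface$density
  lines <- sprintf("%-4s %5s %s %-4s %9.4f %9.4f %9.4f SR0 %6.3f %8.4f %8.4f %8.4f",
                   tg$resname, tg$resno,
                   ifelse(nzchar(as.character(tg$chain)), as.character(tg$chain), "A"),
                   "P",
                   surface$points[, 1L], surface$points[, 2L], surface$points[, 3L],
                   area,
                   surface$normals[, 1L], surface$normals[, 2L], surface$normals[, 3L])
  writeLines(lines, path)
  invisible(path)
}

#' Construct a potential grid
#'
#' A regular scalar field such as the Poisson-Boltzmann potential written
#' by APBS in OpenDX format.
#'
#' @param origin length-3 grid origin (Angstrom).
#' @param spacing length-3 positive grid spacing (Angstrom).
#' @param shape length-3 positive integer extents (nx, ny, nz).
#' @param values numeric vector in OpenDX z-fastest order, or a 3D array
#'   with dim `shape`.
#' @return An object of class `potential_grid`.
#' @export
potential_grid <- function(origin, spacing, shape, values) {
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  shape <- as.integer(shape)
  if (length(origin) != 3L || length(spacing) != 3L || length(shape) != 3L)
    stop2("origin, spacing and shape must each have length 3")
  if (any(spacing <= 0)) stop2("grid spacing must be positive")
  if (any(shape < 1L)) stop2("grid shape must be positive")
  if (is.array(values) && length(dim(values)) == 3L) {
    if (!all(dim(values) == shape)) stop2("array dim does not match shape")
    arr <- values
  } else {
    values <- as.numeric(values)
    if (length(values) != prod(shape))
      stop2("value count ", length(values), " does not match grid shape ",
            paste(shape, collapse = "x"))
    # OpenDX order: z fastest, x slowest -> fill (z, y, x) then permute
    arr <- aperm(array(values, dim = rev(shape)), c(3L, 2L, 1L))
  }
  structure(list(origin = origin, spacing = spacing, shape = shape,
                 values = arr),
            class = "potential_grid")
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(sprintf("potential_grid: %s nodes, origin (%s), spacing (%s)\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$origin), collapse = ", "),
              paste(format(x$spacing), collapse = ", ")))
  invisible(x)
}

# values back in OpenDX z-fastest order
dx_value_order <- function(grid) as.vector(aperm(grid$values, c(3L, 2L, 1L)))

#' Read an OpenDX scalar grid
#'
#' Supports the "regular positions, regular connections" dialect written
#' by APBS: `gridpositions counts`, `origin`, three diagonal `delta`
#' rows, and a data block in z-fastest order.
#'
#' @param path path to a `.dx` file.
#' @return A [potential_grid()].
#' @export
read_dx <- function(path) {
  if (!file.exists(path)) stop2("OpenDX file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  grab <- function(pattern) grep(pattern, lines)
  ip <- grab("object\\s+1\\s+class\\s+gridpositions\\s+counts")
  if (length(ip) != 1L)
    stop2("unsupported OpenDX dialect: need a regular 'gridpositions counts' object")
  shape <- as.integer(strsplit(trimws(sub(".*counts", "", lines[ip])),
                               "\\s+")[[1]])
  io <- grab("^\\s*origin\\s")
  if (length(io) != 1L) stop2("unsupported OpenDX dialect: missing origin")
  origin <- as.numeric(strsplit(trimws(sub("origin", "", lines[io])), "\\s+")[[1]])
  id <- grab("^\\s*delta\\s")
  if (length(id) != 3L) stop2("unsupported OpenDX dialect: need three delta rows")
  deltas <- t(vapply(lines[id], function(l)
    as.numeric(strsplit(trimws(sub("delta", "", l)), "\\s+")[[1]]),
    numeric(3)))
  if (any(abs(deltas[upper.tri(deltas) | lower.tri(deltas)]) > 1e-9))
    stop2("unsupported OpenDX dialect: non-axis-aligned (sheared) grid")
  spacing <- diag(deltas)
  ic <- grab("gridconnections")
  if (length(ic) != 1L)
    stop2("unsupported OpenDX dialect: missing regular gridconnections")
  ia <- grab("object\\s+3\\s+class\\s+array")
  if (length(ia) != 1L) stop2("unsupported OpenDX dialect: missing data array")
  body <- lines[(ia + 1L):length(lines)]
  stopat <- grep("^\\s*(attribute|object|component|end)", body)
  if (length(stopat)) body <- body[seq_len(min(stopat) - 1L)]
  values <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "\\s+"))))
  values <- values[!is.na(values)]
  if (length(values) != prod(shape))
    stop2("OpenDX integrity error: ", length(values), " values for shape ",
          paste(shape, collapse = "x"))
  potential_grid(origin, spacing, shape, values)
}

#' Write a potential grid as OpenDX
#'
#' @param grid a [potential_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  stopifnot(inherits(grid, "potential_grid"))
  s <- grid$shape
  hdr <- c(
    "# OpenDX scalar grid",
    sprintf("object 1 class gridpositions counts %d %d %d", s[1], s[2], s[3]),
    sprintf("origin %.6e %.6e %.6e", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6e 0.000000e+00 0.000000e+00", grid$spacing[1]),
    sprintf("delta 0.000000e+00 %.6e 0.000000e+00", grid$spacing[2]),
    sprintf("delta 0.000000e+00 0.000000e+00 %.6e", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", s[1], s[2], s[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(s)))
  v <- dx_value_order(grid)
  pad <- (-length(v)) %% 3L
  if (pad) v <- c(v, rep(NA_real_, pad))
  m <- matrix(v, ncol = 3L, byrow = TRUE)
  rows <- apply(m, 1L, function(r)
    paste(sprintf("%.6e", r[!is.na(r)]), collapse = " "))
  writeLines(c(hdr, rows, 'attribute "dep" string "positions"'), path)
  invisible(path)
}

#' Read a PDB structure for residue bookkeeping
#'
#' Thin wrapper over [bio3d::read.pdb()] that keeps one atom per
#' alternate-location group (altloc blank or 'A'), drops waters and
#' hydrogens, and preserves insertion codes in the residue identity.
#'
#' @param path path to a PDB file.
#' @return An object of class `structure3d`: a list with `atoms` (a
#'   data.frame with chain, resno, insert, resname, elety, x, y, z) and
#'   `chains` (identifiers in file order).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop2("PDB file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop2("PDB parse failure: ",
                                            conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop2("no ATOM records in ", path)
  alt <- a$alt %||% rep("", nrow(a))
  alt[is.na(alt)] <- ""
  keep <- alt %in% c("", "A") &
    !(a$resid %in% c("HOH", "WAT", "DOD")) &
    !(toupper(a$elesy %||% "") %in% "H") &
    !grepl("^[0-9]*H", a$elety)
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L) stop2("no usable ATOM records in ", path)
  ins <- a$insert
  ins[is.na(ins)] <- ""
  atoms <- data.frame(chain = a$chain, resno = a$resno, insert = ins,
                      resname = a$resid, elety = a$elety,
                      x = a$x, y = a$y, z = a$z)
  if (!all(is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop2("non-finite coordinates in ", path)
  structure(list(atoms = atoms, chains = unique(atoms$chain)),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d atoms, chains %s\n", nrow(x$atoms),
              paste(x$chains, collapse = ",")))
  invisible(x)
}

#' Sample a potential grid at surface points
#'
#' Assigns to each surface point the value of the enclosing grid cell
#' (nearest grid node). Trilinear interpolation is available as an
#' option.
#'
#' @param grid a [potential_grid()].
#' @param surface a [molecular_surface()].
#' @param method `"nearest"` (default) or `"trilinear"`.
#' @return A [potential_surface()].
#' @export
sample_potential <- function(grid, surface, method = c("nearest", "trilinear")) {
  stopifnot(inherits(grid, "potential_grid"),
            inherits(surface, "molecular_surface"))
  method <- match.arg(method)
  p <- surface$points
  frac <- sweep(sweep(p, 2L, grid$origin, "-"), 2L, grid$spacing, "/")
  hi <- grid$shape - 1L
  inside <- frac[, 1] >= -1e-9 & frac[, 1] <= hi[1] + 1e-9 &
            frac[, 2] >= -1e-9 & frac[, 2] <= hi[2] + 1e-9 &
            frac[, 3] >= -1e-9 & frac[, 3] <= hi[3] + 1e-9
  if (!all(inside))
    stop2("surface points outside the potential grid: indices ",
          paste(utils::head(which(!inside), 10L), collapse = ", "),
          if (sum(!inside) > 10L) ", ..." else "")
  if (method == "nearest") {
    ijk <- pmin(pmax(round(frac), 0), matrix(hi, nrow(frac), 3L, byrow = TRUE))
    vals <- grid$values[cbind(ijk[, 1] + 1L, ijk[, 2] + 1L, ijk[, 3] + 1L)]
  } else {
    lo <- pmin(pmax(floor(frac), 0), matrix(hi - 1L, nrow(frac), 3L, byrow = TRUE))
    t_ <- pmin(pmax(frac - lo, 0), 1)
    vals <- numeric(nrow(p))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx == 1) t_[, 1] else 1 - t_[, 1]) *
           (if (dy == 1) t_[, 2] else 1 - t_[, 2]) *
           (if (dz == 1) t_[, 3] else 1 - t_[, 3])
      vals <- vals + w * grid$values[cbind(lo[, 1] + dx + 1L,
                                           lo[, 2] + dy + 1L,
                                           lo[, 3] + dz + 1L)]
    }
  }
  potential_surface(surface, vals)
}
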