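# Interface definition, surface residues, patches and complex classification.

residue_keys <- function(tags) {
  if (is.null(tags)) return(NULL)
  paste(tags$chain, tags$resno, sep = ":")
}

unique_residues <- function(tags, which) {
  if (is.null(tags)) return(data.frame(chain = character(), resno = character(),
                                       resname = character()))
  u <- tags[which, , drop = FALSE]
  u <- u[!duplicated(residue_keys(u)), , drop = FALSE]
  rownames(u) <- NULL
  u
}

#' Flag the interacting region of two surfaces
#'
#' A point of one surface belongs to the interface iff its distance to the
#' nearest point of the partner surface is below the cutoff (6 Angstrom by
#' default). The definition is symmetric; interface residue sets are the
#' residues tagged by flagged points.
#'
#' @param surf_A,surf_B [molecular_surface()] (or [potential_surface()])
#'   objects for the two partners.
#' @param cutoff distance cutoff in Angstrom.
#' @return An object of class `interface_annotation` with logical masks
#'   `mask_A`, `mask_B`, residue data.frames `residues_A`, `residues_B`
#'   and the `cutoff`. Empty masks are returned, not an error.
#' @export
find_interface <- function(surf_A, surf_B, cutoff = 6) {
  surf_A <- as_surface(surf_A); surf_B <- as_surface(surf_B)
  stopifnot(is_number(cutoff), cutoff > 0)
  dA <- min_dist_to_set(surf_A$points, surf_B$points)
  dB <- min_dist_to_set(surf_B$points, surf_A$points)
  mask_A <- dA < cutoff
  mask_B <- dB < cutoff
  structure(list(mask_A = mask_A, mask_B = mask_B,
                 residues_A = unique_residues(surf_A$residue_tags, mask_A),
                 residues_B = unique_residues(surf_B$residue_tags, mask_B),
                 cutoff = cutoff),
            class = "interface_annotation")
}

#' @export
print.interface_annotation <- function(x, ...) {
  cat(sprintf("interface_annotation: %d/%d points flagged (A/B), cutoff %g A\n",
              sum(x$mask_A), sum(x$mask_B), x$cutoff))
  invisible(x)
}

as_surface <- function(x) {
  if (inherits(x, "potential_surface")) x$surface
  else if (inherits(x, "molecular_surface")) x
  else stop2("expected a molecular_surface or potential_surface")
}

surface_values <- function(x) {
  if (inherits(x, "potential_surface")) x$potential else NULL
}

#' Geometric center of an interacting region
#'
#' Returns the flagged surface point nearest to the centroid of all
#' flagged points (the centroid itself is generally off-surface). Ties are
#' broken by lowest point index.
#'
#' @param annotation an [find_interface()] result.
#' @param surface the partner surface the mask refers to.
#' @param partner `"A"` or `"B"`: which mask of the annotation to use.
#' @return The 3D coordinates of the chosen surface point, with the point
#'   index in attribute `"index"`.
#' @export
patch_center <- function(annotation, surface, partner = c("A", "B")) {
  stopifnot(inherits(annotation, "interface_annotation"))
  partner <- match.arg(partner)
  surface <- as_surface(surface)
  mask <- if (partner == "A") annotation$mask_A else annotation$mask_B
  if (length(mask) != n_points(surface))
    stop2("annotation mask length does not match the surface")
  if (!any(mask)) stop2("empty interface mask for partner ", partner)
  idx <- which(mask)
  pts <- surface$points[idx, , drop = FALSE]
  centroid <- colMeans(pts)
  d2 <- rowSums(sweep(pts, 2L, centroid)^2)
  best <- idx[which.min(d2)]  # which.min takes the first (lowest index) on ties
  structure(surface$points[best, ], index = best)
}

#' Extract a spherical surface patch
#'
#' All surface points within `radius` (Euclidean) of a center point that
#' must itself lie on the surface.
#'
#' @param surface a [molecular_surface()] or [potential_surface()]; in
#'   the latter case per-point potentials are carried into the patch.
#' @param center 3D coordinates of a surface point (or its index).
#' @param radius patch radius in Angstrom (9 by default).
#' @param min_points patches with fewer points raise a sparse-patch
#'   error (degenerate plane fits downstream).
#' @return An object of class `surface_patch`: points, normals, optional
#'   values, point indices, center and radius.
#' @export
extract_patch <- function(surface, center, radius = 9, min_points = 20L) {
  values <- surface_values(surface)
  surf <- as_surface(surface)
  stopifnot(is_number(radius), radius > 0)
  if (is_number(center)) {
    ci <- as.integer(center)
    if (ci < 1L || ci > n_points(surf)) stop2("center index out of range")
    center <- surf$points[ci, ]
  } else {
    center <- as.numeric(center)
    if (length(center) != 3L) stop2("center must be a 3D point or an index")
  }
  d2 <- rowSums(sweep(surf$points, 2L, center)^2)
  if (min(d2) > 1e-12)
    stop2("patch center is not a surface point")
  idx <- which(d2 <= radius^2)
  if (length(idx) < min_points)
    stop2("sparse patch: ", length(idx), " points (minimum ", min_points, ")")
  structure(list(points = surf$points[idx, , drop = FALSE],
                 normals = surf$normals[idx, , drop = FALSE],
                 values = if (!is.null(values)) values[idx],
                 indices = idx, center = center, radius = radius),
            class = "surface_patch")
}

#' @export
print.surface_patch <- function(x, ...) {
  cat(sprintf("surface_patch: %d points, radius %g A%s\n", nrow(x$points),
              x$radius, if (is.null(x$values)) "" else ", with potentials"))
  invisible(x)
}

#' Random decoy patch
#'
#' Draws a patch center uniformly over the surface points (seeded) and
#' extracts the surrounding patch; sparse draws are resampled up to a
#' retry limit.
#'
#' @inheritParams extract_patch
#' @param rng_seed optional integer seed; `NULL` uses the current RNG
#'   stream.
#' @param max_retries resampling attempts before giving up on a surface
#'   whose random patches keep coming out sparse.
#' @return A `surface_patch`.
#' @export
random_patch <- function(surface, radius = 9, rng_seed = NULL,
                         min_points = 20L, max_retries = 25L) {
  surf <- as_surface(surface)
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  for (i in seq_len(max_retries)) {
    ci <- sample.int(n_points(surf), 1L)
    p <- tryCatch(extract_patch(surface, ci, radius, min_points),
                  error = function(e) NULL)
    if (!is.null(p)) return(p)
  }
  stop2("could not draw a non-sparse random patch in ", max_retries, " tries")
}

#' Theoretical maximum solvent-accessible surface areas
#'
#' Reference per-residue maxima (Angstrom^2) used to normalize solvent
#' accessibility into relative solvent accessibility (RSA); theoretical
#' values of Tien et al. (2013).
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
max_sasa_reference <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
    GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
    LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
    SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
}

#' Select surface (superficial) residues by relative solvent accessibility
#'
#' RSA is the ratio of a residue's solvent accessibility to its reference
#' maximum; residues with RSA strictly greater than the threshold (0.25
#' by default) are surface residues.
#'
#' @param acc data.frame with columns `residue` (identifier), `resname`
#'   (three-letter code) and `sasa` (Angstrom^2); an optional `max_sasa`
#'   column overrides the embedded reference table.
#' @param threshold RSA cutoff; strictly-greater comparison.
#' @return `acc` rows passing the threshold, with `rsa` added.
#' @export
surface_residues <- function(acc, threshold = 0.25) {
  acc <- as.data.frame(acc)
  stopifnot(all(c("residue", "resname", "sasa") %in% names(acc)))
  if (is.null(acc$max_sasa)) {
    ref <- max_sasa_reference()
    unknown <- setdiff(unique(acc$resname), names(ref))
    if (length(unknown))
      stop2("no reference max SASA for residue(s): ",
            paste(unknown, collapse = ", "))
    acc$max_sasa <- unname(ref[acc$resname])
  }
  acc$rsa <- acc$sasa / acc$max_sasa
  if (any(acc$rsa < 0)) stop2("negative SASA encountered")
  out <- acc[acc$rsa > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a dimer by binding-region overlap
#'
#' Homodimers are binned by the fraction of interface residues the two
#' binding regions share, `f = |A intersect B| / min(|A|, |B|)` in a
#' common numbering frame: `f >= 0.7` identical binding regions
#' (IBR-hom), `0.3 <= f < 0.7` shifted (SBR-hom), `f < 0.3` non-identical
#' (nIBR-hom). Heterodimers are `nIBR-het`.
#'
#' @param residues_A,residues_B interface residue identifiers (character
#'   vectors, or data.frames with chain/resno columns from
#'   [find_interface()]; homodimer identity is matched on `resno` so the
#'   two chains share a numbering frame).
#' @param is_heterodimer logical flag.
#' @return One of `"IBR-hom"`, `"SBR-hom"`, `"nIBR-hom"`, `"nIBR-het"`,
#'   with the overlap fraction in attribute `"overlap"`.
#' @export
classify_dimer <- function(residues_A, residues_B, is_heterodimer = FALSE) {
  if (isTRUE(is_heterodimer)) return(structure("nIBR-het", overlap = NA_real_))
  ids <- function(x) {
    if (is.data.frame(x)) as.character(x$resno) else as.character(x)
  }
  A <- unique(ids(residues_A)); B <- unique(ids(residues_B))
  if (length(A) == 0L || length(B) == 0L)
    stop2("empty interface residue set")
  f <- length(intersect(A, B)) / min(length(A), length(B))
  cls <- if (f >= 0.7) "IBR-hom" else if (f >= 0.3) "SBR-hom" else "nIBR-hom"
  structure(cls, overlap = f)
}

#' Classify a complex by prevailing secondary structure
#'
#' Each partner is labeled H if it has more helix than strand residues,
#' otherwise S (ties go to S); the pair label is order-insensitive.
#'
#' @param ss_A,ss_B per-residue secondary-structure labels (DSSP-derived),
#'   with `"H"` for helix, `"S"` (or `"E"`) for strand and anything else
#'   ignored.
#' @return `"HH"`, `"SS"` or `"SH"`.
#' @export
classify_structural <- function(ss_A, ss_B) {
  lab <- function(ss, who) {
    ss <- toupper(as.character(ss))
    h <- sum(ss == "H"); s <- sum(ss %in% c("S", "E"))
    if (h + s == 0L)
      stop2("partner ", who, " has no helix or strand residues; unclassifiable")
    if (h > s) "H" else "S"
  }
  pair <- sort(c(lab(ss_A, "A"), lab(ss_B, "B")), decreasing = TRUE)
  paste(pair, collapse = "")
}

#' Bundle two partners with their annotations
#'
#' @param pdb_id complex identifier.
#' @param surface_A,surface_B partner surfaces ([molecular_surface()] or
#'   [potential_surface()]).
#' @param structure_A,structure_B optional [read_pdb()] structures.
#' @param pH experimental pH.
#' @param Kd equilibrium dissociation constant (mol/L), optional.
#' @param Ba binding affinity, `log10(Kd)`; computed from `Kd` when
#'   absent, and checked for consistency when both are given.
#' @param dimer_class,structural_class optional class labels.
#' @return An object of class `complex_record`.
#' @export
complex_record <- function(pdb_id, surface_A, surface_B,
                           structure_A = NULL, structure_B = NULL,
                           pH = NA_real_, Kd = NA_real_, Ba = NA_real_,
                           dimer_class = NA_character_,
                           structural_class = NA_character_) {
  if (!is.na(Kd)) {
    if (Kd <= 0) stop2("Kd must be positive")
    ba_from_kd <- log10(Kd)
    if (is.na(Ba)) Ba <- ba_from_kd
    else if (abs(Ba - ba_from_kd) > 1e-6)
      stop2("inconsistent Kd and Ba: log10(Kd) = ", ba_from_kd)
  }
  if (!is.na(dimer_class) &&
      !dimer_class %in% c("IBR-hom", "SBR-hom", "nIBR-hom", "nIBR-het"))
    stop2("unknown dimer_class: ", dimer_class)
  if (!is.na(structural_class) && !structural_class %in% c("HH", "SS", "SH"))
    stop2("unknown structural_class: ", structural_class)
  structure(list(pdb_id = pdb_id,
                 surface_A = surface_A, surface_B = surface_B,
                 structure_A = structure_A, structure_B = structure_B,
                 pH = pH, Kd = Kd, Ba = Ba,
                 dimer_class = dimer_class,
                 structural_class = structural_class),
            class = "complex_record")
}

#' @export
print.complex_record <- function(x, ...) {
  cat(sprintf("complex_record %s: pH %s, Ba %s, classes %s/%s\n", x$pdb_id,
              format(x$pH), format(x$Ba),
              x$dimer_class, x$structural_class))
  invisible(x)
}
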