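# Amino-acid composition and charge analyses of binding regions.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Default formal-charge table
#'
#' Physiological-pH formal charges: ASP/GLU -1, LYS/ARG +1, everything
#' else (including HIS) 0. Override entries for other protonation
#' assumptions (e.g. `HIS = +1` below pH ~6).
#'
#' @param ... named integer overrides, e.g. `HIS = 1L`.
#' @return Named integer vector over the 20 standard residues.
#' @export
default_charge_table <- function(...) {
  tab <- stats::setNames(rep(0L, length(AA3)), AA3)
  tab[c("ASP", "GLU")] <- -1L
  tab[c("LYS", "ARG")] <- 1L
  over <- c(...)
  if (length(over)) {
    if (is.null(names(over)) || !all(names(over) %in% AA3))
      stop2("charge overrides must be named with standard residues")
    tab[names(over)] <- as.integer(over)
  }
  if (!all(tab %in% -1:1)) stop2("formal charges must be in {-1, 0, +1}")
  tab
}

#' Formal charge of a residue
#'
#' @param name three-letter residue code(s).
#' @param table a charge table from [default_charge_table()].
#' @return Integer charge(s) in units of e.
#' @export
residue_charge <- function(name, table = default_charge_table()) {
  name <- toupper(as.character(name))
  unknown <- setdiff(unique(name), names(table))
  if (length(unknown))
    stop2("unknown residue(s): ", paste(unknown, collapse = ", "))
  unname(table[name])
}

charge_class <- function(name, table = default_charge_table()) {
  q <- residue_charge(name, table)
  factor(ifelse(q < 0, "negative", ifelse(q > 0, "positive", "neutral")),
         levels = c("negative", "positive", "neutral"))
}

#' Sign of the partner charge products
#'
#' Sums the formal charges of each partner over all residues and over
#' interface residues, multiplies the two partner sums, and reports the
#' sign of each product (0 when either sum is zero). For homodimers the
#' total product is the square of a sum, hence never negative.
#'
#' @param record a [complex_record()] whose surfaces carry residue tags.
#' @param annotation an [find_interface()] result for the pair.
#' @param table a charge table.
#' @return List with `total_sign` and `interface_sign`, each in
#'   `{-1, 0, 1}`, plus the four partner charge sums.
#' @export
charge_products <- function(record, annotation,
                            table = default_charge_table()) {
  stopifnot(inherits(record, "complex_record"),
            inherits(annotation, "interface_annotation"))
  all_res <- function(surf) {
    tg <- as_surface(surf)$residue_tags
    if (is.null(tg)) stop2("surface has no residue tags")
    unique_residues(tg, rep(TRUE, nrow(tg)))
  }
  qsum <- function(res) sum(residue_charge(res$resname, table))
  qA <- qsum(all_res(record$surface_A)); qB <- qsum(all_res(record$surface_B))
  qiA <- qsum(annotation$residues_A);    qiB <- qsum(annotation$residues_B)
  list(total_sign = sign(qA * qB), interface_sign = sign(qiA * qiB),
       total_A = qA, total_B = qB, interface_A = qiA, interface_B = qiB)
}

#' Relative amino-acid abundances per residue category
#'
#' Normalized frequency of each of the 20 residues among (i) all
#' residues, (ii) solvent-exposed residues and (iii) interface residues.
#'
#' @param residues data.frame with columns `id` and `resname`, one row
#'   per residue of the protein.
#' @param exposed,interacting identifier subsets; `interacting` must be
#'   contained in `exposed`, which must be contained in the full set.
#' @return data.frame with a row per residue type and columns `all`,
#'   `exposed`, `interacting`, each summing to 1.
#' @export
composition_profile <- function(residues, exposed, interacting) {
  residues <- as.data.frame(residues)
  stopifnot(all(c("id", "resname") %in% names(residues)))
  ids <- as.character(residues$id)
  exposed <- as.character(exposed); interacting <- as.character(interacting)
  if (!all(exposed %in% ids)) stop2("exposed residues not a subset of all")
  if (!all(interacting %in% exposed))
    stop2("interacting residues not a subset of exposed")
  freq <- function(sel, label) {
    sub <- residues$resname[ids %in% sel]
    if (length(sub) == 0L) stop2("empty residue category: ", label)
    tab <- table(factor(toupper(sub), levels = AA3))
    as.numeric(tab) / length(sub)
  }
  data.frame(resname = AA3,
             all = freq(ids, "all"),
             exposed = freq(exposed, "exposed"),
             interacting = freq(interacting, "interacting"))
}

# side-chain heavy-atom centroid (CA for GLY / side-chain-less residues)
residue_rep_points <- function(structure, residues) {
  a <- structure$atoms
  key <- paste(a$chain, a$resno, sep = ":")
  want <- paste(residues$chain, residues$resno, sep = ":")
  out <- matrix(NA_real_, nrow(residues), 3L)
  backbone <- c("N", "CA", "C", "O", "OXT")
  for (i in seq_len(nrow(residues))) {
    sel <- key == want[i]
    if (!any(sel)) stop2("residue ", want[i], " not found in structure")
    sub <- a[sel, , drop = FALSE]
    sc <- sub[!(sub$elety %in% backbone), , drop = FALSE]
    if (nrow(sc) == 0L) sc <- sub[sub$elety == "CA", , drop = FALSE]
    if (nrow(sc) == 0L) sc <- sub
    out[i, ] <- colMeans(as.matrix(sc[c("x", "y", "z")]))
  }
  out
}

#' Charged-neighbor statistics across an interface
#'
#' For each charge class (negative, positive, neutral) of interface
#' residues, the percentage having a partner-interface residue of each
#' charge class within `radius` of its side-chain centroid. Counts are
#' symmetrized over the two partners.
#'
#' @param structure_A,structure_B [read_pdb()] structures of the partners.
#' @param annotation an [find_interface()] result carrying interface
#'   residue sets.
#' @param table a charge table.
#' @param radius neighborhood radius in Angstrom (default 5; the
#'   reported statistics are radius-dependent, 4-6 is a typical sweep).
#' @return 3x3 matrix of percentages; rows = charge class of the residue,
#'   columns = charge class of the partner neighbor.
#' @export
cross_interface_neighbor_stats <- function(structure_A, structure_B,
                                           annotation,
                                           table = default_charge_table(),
                                           radius = 5) {
  stopifnot(inherits(annotation, "interface_annotation"))
  resA <- annotation$residues_A; resB <- annotation$residues_B
  if (nrow(resA) == 0L || nrow(resB) == 0L) stop2("no interface residues")
  pA <- residue_rep_points(structure_A, resA)
  pB <- residue_rep_points(structure_B, resB)
  clA <- charge_class(resA$resname, table)
  clB <- charge_class(resB$resname, table)
  lev <- levels(clA)
  counts <- matrix(0, 3L, 3L, dimnames = list(lev, lev))
  totals <- stats::setNames(numeric(3L), lev)
  tally <- function(p_from, cl_from, p_to, cl_to) {
    for (i in seq_len(nrow(p_from))) {
      d <- sqrt(colSums((t(p_to) - p_from[i, ])^2))
      near <- d <= radius
      totals[as.character(cl_from[i])] <<-
        totals[as.character(cl_from[i])] + 1
      for (cls in lev) {
        if (any(near & cl_to == cls))
          counts[as.character(cl_from[i]), cls] <<-
            counts[as.character(cl_from[i]), cls] + 1
      }
    }
  }
  tally(pA, clA, pB, clB)
  tally(pB, clB, pA, clA)
  pct <- 100 * counts / pmax(totals, 1)
  pct[totals == 0, ] <- NA_real_
  pct
}
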