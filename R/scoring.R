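# Complementarity scores (F, Zernike distances), decoys, ROC/AUC and
# stratification by pH / affinity / class.

#' F sign-concordance score between two SEMs
#'
#' The fraction of jointly filled pixel pairs, at the same grid
#' position on the two partners' SEMs, that carry the same sign.
#' Electrostatically complementary patches have mostly opposite signs at
#' facing pixels, hence a low F; two unrelated sign patterns give F near
#' 0.5.
#'
#' @param sem_A,sem_B `projection_matrix` objects of kind `"SEM"` on the
#'   same grid frame (pair-oriented projections for interacting patches).
#' @return List with `value` (fraction in `[0, 1]`) and `n_pairs`.
#' @export
f_score <- function(sem_A, sem_B) {
  stopifnot(inherits(sem_A, "projection_matrix"),
            inherits(sem_B, "projection_matrix"))
  if (sem_A$kind != "SEM" || sem_B$kind != "SEM")
    stop2("f_score expects SEM matrices")
  if (!all(dim(sem_A$grid) == dim(sem_B$grid)))
    stop2("SEM grids differ in size")
  joint <- sem_A$mask & sem_B$mask
  n <- sum(joint)
  if (n == 0L) stop2("empty joint mask: the two SEMs share no filled pixels")
  same <- sum(sem_A$grid[joint] == sem_B$grid[joint])
  list(value = same / n, n_pairs = n)
}

#' Zernike complementarity between two patches
#'
#' Orients the two patches independently and contrariwise (A up, B
#' down), projects each (shape matrix with its own cone origin, or
#' EM -> CEM for the electrostatic channel), expands both in the Zernike
#' basis and returns the Euclidean distance between the invariant
#' descriptors. Smaller distance = higher complementarity.
#'
#' @param patch_A,patch_B `surface_patch` objects; the electrostatic
#'   channel requires patches carrying potentials.
#' @param channel `"shape"` or `"electrostatic"`.
#' @param order Zernike expansion order N.
#' @param pixels projection grid side.
#' @param cap CEM clipping bound (electrostatic channel).
#' @return Non-negative scalar distance.
#' @export
zernike_complementarity <- function(patch_A, patch_B,
                                    channel = c("shape", "electrostatic"),
                                    order = 20L, pixels = 25L, cap = 30) {
  channel <- match.arg(channel)
  opA <- orient_single(patch_A, "up")
  opB <- orient_single(patch_B, "down")
  # the down patch is expanded in its own frame: flip to put its relief
  # on the +z side so both projections are comparable
  opB_flipped <- make_oriented_patch(
    opB$points %*% diag(c(1, -1, -1)),
    opB$normals %*% diag(c(1, -1, -1)),
    opB$values, diag(c(1, -1, -1)) %*% opB$rotation)
  pm <- function(op) {
    if (channel == "shape") {
      project_shape(op, cone_origin(op), pixels = pixels)
    } else {
      em_to_cem(project_potential(op, pixels = pixels), cap = cap)
    }
  }
  dA <- zernike_invariants(zernike_expand(pm(opA), order))
  dB <- zernike_invariants(zernike_expand(pm(opB_flipped), order))
  descriptor_distance(dA, dB)
}

#' F score of an interacting patch pair
#'
#' Uses the joint pair orientation (one common rotation preserving the
#' spatial correspondence of facing points) and projects both patches on
#' a shared grid frame before comparing SEMs.
#'
#' @param patch_A,patch_B interacting `surface_patch` objects carrying
#'   potentials.
#' @param pixels projection grid side.
#' @return As [f_score()].
#' @export
pair_f_score <- function(patch_A, patch_B, pixels = 25L) {
  op <- orient_pair(patch_A, patch_B)
  ext <- max(sqrt(rowSums(op$A$points[, 1:2, drop = FALSE]^2)),
             sqrt(rowSums(op$B$points[, 1:2, drop = FALSE]^2)))
  semA <- em_to_sem(project_potential(op$A, pixels = pixels, extent = ext))
  semB <- em_to_sem(project_potential(op$B, pixels = pixels, extent = ext))
  f_score(semA, semB)
}

#' Decoy (random-patch) scores for a complex
#'
#' Draws `n_decoys` random patch pairs, one patch per partner, scores
#' each pair on the requested channel and labels them `"decoy"`. Decoy
#' patches are oriented with the single-patch protocol. Reproducible for
#' a fixed seed.
#'
#' @param record a [complex_record()] whose surfaces carry potentials
#'   (for the F and electrostatic channels).
#' @param n_decoys number of decoy pairs.
#' @param channel `"F"`, `"zernike_shape"` or `"zernike_electro"`.
#' @param rng_seed integer seed (`NULL`: current RNG stream).
#' @param radius patch radius (Angstrom).
#' @param order,pixels,cap projection / expansion parameters.
#' @return data.frame with columns `complex_id`, `score`, `label`,
#'   `channel`.
#' @export
decoy_scores <- function(record, n_decoys, channel = "F", rng_seed = NULL,
                         radius = 9, order = 20L, pixels = 25L, cap = 30) {
  stopifnot(inherits(record, "complex_record"))
  channel <- match.arg(channel, c("F", "zernike_shape", "zernike_electro"))
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  if (n_decoys == 0L)
    return(data.frame(complex_id = character(), score = numeric(),
                      label = character(), channel = character()))
  scores <- vapply(seq_len(n_decoys), function(i) {
    pA <- random_patch(record$surface_A, radius)
    pB <- random_patch(record$surface_B, radius)
    score_patch_pair(pA, pB, channel, order = order, pixels = pixels,
                     cap = cap, paired_frame = FALSE)
  }, numeric(1))
  data.frame(complex_id = record$pdb_id, score = scores,
             label = "decoy", channel = channel)
}

# One scored patch pair on a channel; paired_frame = TRUE uses the joint
# pair orientation (interacting patches), FALSE the independent protocol.
score_patch_pair <- function(patch_A, patch_B, channel, order = 20L,
                             pixels = 25L, cap = 30, paired_frame = TRUE) {
  switch(channel,
    F = {
      if (paired_frame) {
        pair_f_score(patch_A, patch_B, pixels = pixels)$value
      } else {
        opA <- orient_single(patch_A, "up")
        opB <- orient_single(patch_B, "down")
        semA <- em_to_sem(project_potential(opA, pixels = pixels))
        semB <- em_to_sem(project_potential(opB, pixels = pixels))
        f_score(semA, semB)$value
      }
    },
    zernike_shape = zernike_complementarity(patch_A, patch_B, "shape",
                                            order = order, pixels = pixels),
    zernike_electro = zernike_complementarity(patch_A, patch_B,
                                              "electrostatic", order = order,
                                              pixels = pixels, cap = cap))
}

#' Score the annotated interacting patches of a complex
#'
#' Extracts the patch around the geometric center of each partner's
#' interacting region and scores the pair: the F channel uses the joint
#' pair orientation, the Zernike channels the independent protocol.
#'
#' @inheritParams decoy_scores
#' @param annotation an [find_interface()] result (computed from the
#'   surfaces when omitted).
#' @return One-row data.frame as in [decoy_scores()], labeled
#'   `"interacting"`.
#' @export
interacting_score <- function(record, channel = "F", annotation = NULL,
                              radius = 9, order = 20L, pixels = 25L,
                              cap = 30, cutoff = 6) {
  stopifnot(inherits(record, "complex_record"))
  channel <- match.arg(channel, c("F", "zernike_shape", "zernike_electro"))
  if (is.null(annotation))
    annotation <- find_interface(record$surface_A, record$surface_B, cutoff)
  cA <- patch_center(annotation, record$surface_A, "A")
  cB <- patch_center(annotation, record$surface_B, "B")
  pA <- extract_patch(record$surface_A, cA, radius)
  pB <- extract_patch(record$surface_B, cB, radius)
  s <- score_patch_pair(pA, pB, channel, order = order, pixels = pixels,
                        cap = cap, paired_frame = TRUE)
  data.frame(complex_id = record$pdb_id, score = s,
             label = "interacting", channel = channel)
}

#' ROC curve and AUC for decoy discrimination
#'
#' Mann-Whitney AUC with half credit for ties, under the convention that
#' lower scores mark positives (both F and Zernike distances are
#' low-is-complementary). AUC below 0.5 is meaningful and reported as
#' is. The curve is built by sweeping a threshold over the pooled
#' scores.
#'
#' @param positives,negatives numeric score vectors (interacting /
#'   decoy).
#' @param direction only `"lower_is_positive"` is defined.
#' @return An object of class `roc_result`: `auc`, a `curve` data.frame
#'   of (fpr, tpr) from (0,0) to (1,1), and the direction.
#' @export
roc_auc <- function(positives, negatives, direction = "lower_is_positive") {
  direction <- match.arg(direction)
  positives <- as.numeric(positives); negatives <- as.numeric(negatives)
  if (length(positives) == 0L || length(negatives) == 0L)
    stop2("both score sets must be non-empty")
  r <- rank(c(positives, negatives), ties.method = "average")
  n_p <- length(positives); n_n <- length(negatives)
  # pairs with negative ranked above positive, ties half-weighted
  u_neg <- sum(r[(n_p + 1):(n_p + n_n)]) - n_n * (n_n + 1) / 2
  auc <- u_neg / (n_p * n_n)
  th <- c(-Inf, sort(unique(c(positives, negatives))), Inf)
  tpr <- vapply(th, function(t) mean(positives <= t), numeric(1))
  fpr <- vapply(th, function(t) mean(negatives <= t), numeric(1))
  curve <- data.frame(threshold = th, fpr = fpr, tpr = tpr)
  structure(list(auc = auc, curve = curve, direction = direction),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.4f (%s), %d thresholds\n",
              x$auc, x$direction, nrow(x$curve)))
  invisible(x)
}

#' Binding affinity from a dissociation constant
#'
#' `Ba = log10(Kd)`; more negative is tighter binding.
#'
#' @param kd dissociation constant(s) in mol/L, strictly positive.
#' @return Numeric `Ba` value(s).
#' @export
affinity_from_kd <- function(kd) {
  kd <- as.numeric(kd)
  if (any(!is.finite(kd) | kd <= 0)) stop2("Kd must be positive and finite")
  log10(kd)
}

#' Stratification bins for pH, affinity and transience
#'
#' pH: low (pH < 5.5), physiological (5.5 < pH < 7.5), high (pH > 7.5).
#' Ba: high affinity (Ba < -9), medium (-9 < Ba < -6), low (Ba > -6).
#' Transience: transient (Ba > -6) vs permanent (Ba < -6). Exact
#' boundary values are assigned to the lower bin.
#'
#' @param x numeric values to bin.
#' @param what `"pH"`, `"Ba"` or `"transience"`.
#' @return Factor of bin labels.
#' @export
stratification_bin <- function(x, what = c("pH", "Ba", "transience")) {
  what <- match.arg(what)
  x <- as.numeric(x)
  switch(what,
    pH = factor(ifelse(x <= 5.5, "low",
                ifelse(x <= 7.5, "physiological", "high")),
                levels = c("low", "physiological", "high")),
    Ba = factor(ifelse(x <= -9, "high",
                ifelse(x <= -6, "medium", "low")),
                levels = c("high", "medium", "low")),
    transience = factor(ifelse(x <= -6, "permanent", "transient"),
                        levels = c("permanent", "transient")))
}

#' Group score samples by a complex annotation
#'
#' @param samples data.frame of scores with a `complex_id` column (e.g.
#'   rows from [interacting_score()] / [decoy_scores()]).
#' @param records data.frame with one row per complex: `complex_id` and
#'   the annotation columns `pH`, `Ba`, `dimer_class`,
#'   `structural_class` as available.
#' @param by one of `"pH"`, `"Ba"`, `"dimer_class"`,
#'   `"structural_class"`, `"transience"`.
#' @return `samples` with a `group` factor column appended.
#' @export
stratify <- function(samples, records,
                     by = c("pH", "Ba", "dimer_class", "structural_class",
                            "transience")) {
  by <- match.arg(by)
  samples <- as.data.frame(samples); records <- as.data.frame(records)
  stopifnot("complex_id" %in% names(samples),
            "complex_id" %in% names(records))
  col <- switch(by, pH = "pH", Ba = "Ba", transience = "Ba",
                dimer_class = "dimer_class",
                structural_class = "structural_class")
  if (!col %in% names(records))
    stop2("records lack the annotation column '", col, "'")
  i <- match(samples$complex_id, records$complex_id)
  if (any(is.na(i)))
    stop2("no record for complex(es): ",
          paste(unique(samples$complex_id[is.na(i)]), collapse = ", "))
  val <- records[[col]][i]
  if (any(is.na(val)))
    stop2("missing '", by, "' annotation for complex(es): ",
          paste(unique(samples$complex_id[is.na(val)]), collapse = ", "))
  samples$group <- if (by %in% c("pH", "Ba", "transience")) {
    stratification_bin(val, if (by == "transience") "transience"
                       else if (by == "Ba") "Ba" else "pH")
  } else factor(val)
  samples
}
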