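---
title: "Measuring interface complementarity: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring interface complementarity: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epizern)
```

## The model

`epizern` treats a protein–protein interface as a pair of oriented
point clouds: the solvent-accessible surface of each partner, sampled
at about 5 points/Å² (DMS output), each point carrying an outward unit
normal and, optionally, the Poisson–Boltzmann electrostatic potential
sampled from the solver's grid (nearest grid node by default; the
potential is carried opaquely in the solver's output units, kT/e for
APBS, and never converted).

A *patch* is everything within a 9 Å sphere around a surface point.
The analysis rests on one geometric reduction: a patch is near-planar
at this radius, so it can be rotated onto its best-fit plane
(total-least-squares, sign-aligned with the patch's mean surface
normal) and summarized by 25 × 25 pixel matrices — mean potential per
pixel (EM), its sign (SEM) and clipped (CEM, ±30) variants, and a shape
matrix holding mean distances to a cone origin *C* chosen on the z-axis
so the widest secant angle to the patch is 45°. The 45° construction
makes the radial scale of the shape field proportional to the patch
size, so descriptors of patches of equal radius are directly
comparable.

Complementarity is scored two ways:

* **F** — the fraction of jointly filled, spatially corresponding SEM
  pixel pairs with equal sign. This requires a *pair* orientation: one
  common rotation taking the mean of A's normal and the inverse of B's
  onto the z-axis, so facing points land on the same pixel. Low F means
  anti-correlated potentials, i.e. complementarity; unrelated patches
  give F near 0.5.
* **Zernike distance** — each matrix, mapped onto the unit disk, is
  expanded in 2D Zernike polynomials up to order N = 20 and reduced to
  the 121 moduli |c_nm|, which are invariant to in-plane rotation (and
  to a global sign flip of the field). Here each patch is oriented
  *independently*, one up and one down — the rotational invariance is
  exactly what makes a common frame unnecessary, which is what allows
  blind (structure-free) comparison of candidate patches.

Decoy patches — random surface points, patch built per partner, scored
with the independent-orientation protocol — provide the null
distribution; discrimination is summarized by the Mann–Whitney AUC with
half-credit ties, under the fixed convention that *lower* scores mark
interacting pairs. The convention keeps AUC values below 0.5
meaningful (anti-discrimination, which does occur for some strata, e.g.
acidic-pH complexes on the electrostatic channel) instead of silently
flipping them.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| patch radius R | 9 | Å | large enough to hold a distinctive surface neighborhood, small enough to stay near-planar; 6–15 supported for sweeps |
| Zernike order N | 20 | – | resolves sub-pixel-scale structure of a 25 × 25 grid; 121 invariants |
| grid | 25 × 25 | pixels | ≈ 0.7 Å pixels at R = 9: 2–3 surface points per pixel at 5 points/Å² |
| CEM cap | 30 | input units | bounds the field so the truncated expansion converges; applied in the solver's units |
| interface cutoff | 6 | Å | a surface point belongs to the interface iff the partner surface is closer than this |
| RSA threshold | 0.25 | – | residues with relative solvent accessibility strictly above this count as surface residues (Tien-style theoretical maxima embedded) |
| decoys per complex | 100 | – | configurable; the count is a precision/cost trade-off, not part of the definition |

Stratification bins are fixed: pH low < 5.5 < physiological < 7.5 <
high; affinity Ba = log10(Kd) high < −9 < medium < −6 < low, with the
transient/permanent split at Ba = −6. Exact boundary values go to the
lower bin — a documented tie-break, chosen because the definitions are
printed as strict inequalities and some convention must be fixed.

Classification conventions we had to pin down: the homodimer
binding-region overlap fraction uses min(|A|, |B|) as denominator (so
identical regions of unequal sampling still score 1), with half-open
bins f ≥ 0.7 → IBR, 0.3 ≤ f < 0.7 → SBR; the helix/strand tie in the
structural classification goes to S (deterministic and rare).

## Numerical choices

* **Radial polynomials.** The radial part is
  R_nm(r) = Σ_k (−1)^k (n−k)! / [k! ((n+m)/2−k)! ((n−m)/2−k)!] r^(n−2k).
  The factorial quotients are evaluated in log space (no overflow at
  any order) and then rounded back to the integers they exactly are,
  which removes cancellation error from the alternating sum; the
  endpoint identity |R_nm(1)| = 1 then holds to 1e−9 through N = 20 and
  is used as a test oracle, together with closed forms for low orders
  and the numeric orthogonality ⟨Z_nm|Z_n'm'⟩ = π/(n+1) δδ.
* **Quadrature.** Coefficients are midpoint sums over pixel centers
  inside the unit disk (the grid spans the patch's own projected
  radius, guaranteeing full disk coverage). For the basis
  orthogonality *check* the rim pixels additionally enter with their
  coverage fraction, which resolves the disk boundary on a fine grid.
* **Empty pixels.** At 5 points/Å² roughly 8% of disk pixels receive no
  point. Treating them as zeros injects spurious high-frequency
  structure — on a shape field of magnitude ~10 the descriptor drifts
  by ~30% under patch rotation, destroying the invariance the method is
  built on. `zernike_expand()` therefore imputes each empty in-disk
  pixel from its nearest filled pixel (ties averaged, which keeps the
  rule mirror-symmetric); measured descriptor drift under random rigid
  rotations is then below 2%. `fill = "zero"` and `"mean"` remain
  available for comparison.
* **SEM zeros.** An exactly zero EM pixel has no sign; it is masked out
  of the SEM and excluded from F rather than assigned arbitrarily.
* **Cone origin.** Solved by bisection on the apex height to an angular
  tolerance of 1e−6 rad, searching above the patch's maximum z. On a
  flat disk of radius ρ the solution is h = ρ (tan 45° = ρ/h), which
  the tests exploit.
* **Degenerate inputs.** Collinear patches fail the plane fit loudly;
  patches with fewer than 20 points raise a sparse-patch error
  (decoy draws resample); an interacting pair whose mean normals
  coincide cannot be pair-oriented and errors out.

## What the synthetic generator emulates — and what it does not

`gen_complex()` builds two facing square sheets at a constant 2 Å gap:
partner A carries Gaussian relief (bumps *and* dents, amplitude 1.5 Å,
σ ≈ 4 Å), partner B the parallel complement; both are sampled
independently at 5 points/Å² with 0.1 Å vertical jitter and outward
analytic normals. The potential is a sum of signed Gaussian blobs at
residue scale (σ 1.5–3 Å, about one per 12 Å², amplitudes set so a
minority of EM pixels exceed the ±30 cap and clipping is exercised); B
carries the negated field except on contiguous flip-back regions
(threshold of an independent smooth field at the (1−p) quantile), so
the point-level sign-agreement fraction across the interface is
exactly the configured p.

The realized *pixel-level* F is not exactly p: pixels straddling a
flip-region boundary mix both signs, biasing F toward 0.5. Measured at
p = 0.2 the interacting F averages ≈ 0.23. F remains a monotone
readout of p, which is what the discrimination and trend tests rely
on; the exact, unbiased p-recovery test uses the iid sign-matrix
generator (`gen_random_sem_pair()`), whose per-pixel null is binomial
by construction.

At p ≤ 0.2 the benchmark separates interacting pairs from decoys with
AUC ≥ 0.9 (50 complexes, 500 decoys), decaying to ≈ 0.5 as p → 0.5.
Decoy F sits slightly *below* 0.5 at small p — the partner fields are
globally anti-signed, so even randomly placed patches inherit a trace
of complementarity; this mirrors the net-charge complementarity of
real heterodimers and is not a bug.

What passing these tests does **not** show: the generator's sheets are
globally flat, so decoy patches differ only in mild relief — real
surfaces vary far more in curvature, which makes shape decoys easier
to reject than here. The potential field is a stationary blob mixture,
not a solution of the Poisson–Boltzmann equation; no conclusions about
absolute AUC values on real structures follow from the synthetic
benchmark. Real-data numbers require external DMS/APBS runs, which are
out of scope by design.

## Problem sizes used by the shipped checks

The test suite runs the discrimination benchmark at 50 complexes × 10
decoys (24 × 24 Å sheets, ≈ 2900 points per surface), the rotation
suite at 20 random rigid rotations of a 1200-point patch, and the
orthogonality check at order 8 on a 201 × 201 grid; these sizes were
chosen so each property is measured with comfortable statistical
margin while the whole suite stays interactive (≈ 20 s).

## Known limitations

* The projection assumes near-planar patches; at R well above ~12 Å on
  strongly curved surfaces the planar shadow folds surface regions onto
  the same pixels and the matrices lose meaning.
* Modulus descriptors are blind to the sign of the field and to mirror
  reflection: a bump and its dent have identical shape descriptors.
  That is precisely what makes complementary patches score *close*
  (useful), but it also means the descriptor cannot distinguish a
  patch from its own mold.
* Homodimer overlap classification assumes a shared residue numbering
  between the chains; structures with renumbered chains need an
  external mapping.
* The F score needs the pair orientation and therefore a known complex
  geometry; only the Zernike channels are usable for blind patch
  search.
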