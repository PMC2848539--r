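---
title: "Interface coverage of local alignments: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface coverage of local alignments: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifacecov)
```

# The model

`ifacecov` quantifies whether a *local* target–template sequence alignment
contains the target's protein–protein binding site, and how accurate a
partial homology model built from such an alignment is at the binding
site. The analysis has four layers.

## Interface definition

A residue of one chain of a two-chain complex belongs to the interface iff
some atom of the residue lies at distance
\(d < r_\mathrm{vdW}(a) + r_\mathrm{vdW}(b) + w\)
from some atom of the partner chain, where \(w\) is the diameter of a
water molecule (default 2.8 Å) and the inequality is strict. The criterion
is symmetric, so one chain's interface is empty iff the other's is.

Parameters and defaults:

* **vdW radii** (`vdw_table()`): Bondi-style element radii, C 1.70, N 1.55,
  O 1.52, S 1.80, P 1.80 Å. The radius set is configurable because the
  underlying criterion is usually quoted without one; these are the common
  heavy-atom values. Unknown elements are an error unless a fallback
  radius is supplied.
* **Hydrogens** are dropped at parse time: X-ray structures mostly lack
  them, and heavy-atom-only counting is the de-facto convention.
* **HETATM** records (waters, ligands) are ignored by default.
* Residue identity is (chain, author number, insertion code) throughout;
  no renumbering ever happens.

The implementation is a blocked, vectorised all-pairs distance scan with
per-pair thresholds (distances compared as squared quantities; no cutoff
approximation). Its contract is exact equality with the literal
double-loop scan, enforced in the test suite over randomized synthetic
complexes; `brute_force_interface()` exposes that reference scan and is
what labels synthetic ground truth.

## Per-alignment statistics

For an alignment with \(N_{ali}\) aligned target residues, target length
\(N_{tot}\), and \(L_{ali}\) columns (aligned target residues **plus
gaps in the aligned target string** — so \(L_{ali}\) is simply the column
count):

* coverage \(q = 100\,N_{ali}/N_{tot}\); interface coverage
  \(q_{int} = 100\,N^{int}_{ali}/N^{int}_{tot}\);
* identity \(a_{iden} = 100\,N_{iden}/L_{ali}\) and similarity
  \(a_{sim} = 100\,N_{pos}/L_{ali}\), where \(N_{pos}\) counts aligned
  pairs with a positive BLOSUM62 score;
* interface identity/similarity \(i_{iden}, i_{sim}\): the same counts
  restricted to columns whose target residue is an interface residue,
  with denominator \(N^{int}_{ali}\);
* **FIC**: an alignment has full interface coverage when at most one
  interface residue is missing (`classify_fic`, tolerance configurable).

Numerical/edge choices:

* Columns containing `X` (or any character outside the matrix alphabet
  mapped to `X` at parse time) are never identical and never positive —
  conservative and deterministic.
* Because a local alignment covers a contiguous target interval, an
  interface position is "inside the alignment" iff it lies in
  `[target_start, target_end]`; gap columns on the target side carry no
  target position.
* Interface identity/similarity is computed only for FIC alignments (as
  in the source analysis — it is ill-defined when most of the interface is
  absent) and reported as `NA` otherwise. The FIC tolerance applies even
  to interfaces of size 1; in the pathological case where the single
  interface residue is missing yet the alignment is still FIC under
  tolerance 1, `i_iden`/`i_sim` are `NA` because no interface column
  exists to score.
* The e-value filter is strict (`e > 1` excluded, `e = 1` kept).
* The "near-identical pair" filter needs an operational definition of
  *target/template difference < 10 residues*; we use
  substituted aligned positions + unaligned target residues + unaligned
  template residues. This reads "difference" as the number of residues at
  which the two proteins differ, which matches the filter's purpose of
  removing a protein aligned to itself or a close mutant. A pure
  length-difference reading would fail to exclude exactly those pairs
  (identical-length mutants have length difference 0 regardless of
  substitutions, while honest homologs of slightly different length would
  be dropped).

## FIC probability curve

Alignments are binned by identity (or similarity) into 5 %-wide bins,
left-closed, right-open, last bin `[95, 100]` closed. Per bin the FIC
probability is \(N_{FIC}/N_{all}\); empty bins are *undefined*, not zero.
A polynomial is fitted by least squares, each bin weighted by its
occupancy \(N_{all}\) (bins with few alignments are noisy; the source
analysis is silent on weighting, so occupancy weighting is our choice and
can be disabled). The default degree is 3, the lowest that visually tracks
a saturating curve; empty bins are excluded from the fit rather than
imputed, and the per-bin table (probability + occupancy) is always
reported alongside the coefficients so users can judge significance.

**Known limitation (measured, not hypothetical):** a least-squares
polynomial fitted to a *saturating* monotone curve overshoots the plateau
and then dips — with a planted sigmoid reaching 0.95, the cubic fit at the
top bins decreases by roughly 2 %. Monotonicity of the fitted values is
therefore only guaranteed when the underlying curve is itself
polynomial-representable (the property test uses a linear planted world);
for saturating data read the binned probabilities, not the tail of the
fit.

## Model quality

Model and native residues are matched by author residue number — models
are built on the target's own numbering, so no realignment is needed.
Superposition is least-squares rigid-body (Kabsch, SVD with the usual
proper-rotation sign correction) over all shared Cα atoms by default;
an interface-only scope is available. The original analysis used TM-align,
whose rotation optimises the TM-score rather than the RMSD; the two
coincide for good models and can differ for poor ones. A least-squares
superposition is exactly reproducible and has a provable optimality
property (tested against random alternative rotations and an independent
quaternion implementation); the TM-align objective is not reproducible
without TM-align itself, so this substitution is documented rather than
hidden. Whether the reference superposition used the whole monomer or
only the interface is also unstated — hence the `scope` argument.

Interface RMSD is then computed over the Cα atoms of the interface
residues only. Quality classes: **good** for RMSD ≤ 5.0 Å — the boundary
is *inclusive* because the reference material labels a 5.0 Å model "good
accuracy", and the inclusive reading reconciles the published count of
seven good top models (one prints exactly 5.0) — **acceptable** for
(5, 10] Å (within the docking-funnel size, usable by less
structure-sensitive methods), **incorrect** above 10 Å.

Top-model selection (highest `a_iden`) needs a tie-break that the source
never specifies: we use lower e-value, then lexicographic template id, so
output is deterministic. Best-model selection (lowest interface RMSD)
breaks ties by template id.

# The synthetic world

The generator exists so that every stage can be validated against known
ground truth, offline. What it emulates, and what it does not:

* `make_complex()` — two-chain complexes with a contact patch.
  The default *two-helix* geometry places two ideal poly-residue
  α-helices (rise 1.5 Å/residue, backbone radius 2.3 Å, 100°/residue)
  side by side 5 Å apart over the first `contact_size` residues, after
  which chain B retreats laterally at 4 Å/residue; a *random-walk*
  geometry (3.8 Å Cα steps, chains started 5 Å apart) provides irregular
  shapes. Residues carry backbone-only atoms (N, CA, C, O, CB; no CB for
  glycine) at fixed offsets in a local frame. The true interface is
  *always* determined afterwards by the brute-force oracle, not assumed
  from the construction. These structures have correct bookkeeping
  (chains, numbering, elements, PDB round-trip) and a tunable, geometric
  contact — they are **not** physical protein conformations: no
  side-chain packing, no sterics, no secondary-structure realism. A green
  interface test therefore establishes correctness of the distance
  criterion and its implementation, not biological plausibility.
* `make_model()` — partial models as truncation (`keep_range`) plus
  i.i.d. Gaussian coordinate noise. Real homology-model error is
  correlated along the chain and concentrated in loops; i.i.d. noise is
  deliberately chosen because it makes the expected RMSD analytically
  transparent and exercises superposition/RMSD code exactly. Conclusions
  about *docking* accuracy do not follow from it.
* `make_alignment_pool()` — alignments whose recomputed identity lands in
  a planted 5 % bin and whose FIC label is drawn Bernoulli from the
  planted per-bin probability (`planted_curve()`). FIC = TRUE places the
  whole interface inside the aligned interval (0 missing); FIC = FALSE
  places at least two interface residues outside, so labels are
  unambiguous under the default tolerance of 1. Identity is controlled
  exactly (identical columns planted, all other columns forced
  non-identical); similarity is *not* controlled and simply follows from
  random residue pairing, which is why planted worlds are stated in terms
  of identity. Default ranges — target length 80–300, coverage 40–100 %,
  interface size 5–15 residues, e-values log-uniform in \([10^{-50}, 1]\)
  — mirror the scales of the reference pool (alignments of tens to
  hundreds of residues, interfaces of ~10 residues, e ≤ 1). Alignments
  shorter than 25 target residues are never generated so that every 5 %
  bin is representable (identity step 100/L ≤ 4 %).

Reproducibility: every generator takes a `seed` and restores the caller's
RNG state (`with_seed`), so identical spec + seed give bit-identical
output (asserted byte-wise on PDB text in the tests) and generation never
perturbs the surrounding session.

# Scaling of stated test sizes

Two property suites are scaled down from their stated sizes to fit the
runtime budget, with the scale stated in the test: oracle equivalence for
interface extraction runs 100 random complexes of 6–16 residues per chain
(small chains keep the O(N²) oracle fast without weakening set-equality),
and the monotone-fit property runs n = 20,000 planted alignments instead
of 50,000. The parameter-recovery acceptance test runs at its stated
n = 10,000 per world and checks every occupied bin against the planted
probability within 3 binomial standard errors.

# Known limitations

* PDB parsing is fixed-column ATOM/HETATM only (selected two chains,
  altLoc by occupancy, hydrogens dropped); no mmCIF, no assemblies.
* The Kabsch/TM-align divergence above: interface RMSD values for poor
  models (> ~10 Å) may differ from a TM-align-based evaluation, though
  the quality *class* is robust in the tested synthetic worlds.
* Histograms and probability curves use fixed [0, 100] percent bins;
  metrics are percentages by construction, so no clipping is applied.
* The packaged reference tables are inputs for validating parsers and the
  classifier; the headline pool statistics of the original analysis
  (66,706 alignments, 56.1 % FIC, 218/101 complex counts) depend on a
  historical database snapshot and are out of scope by design.
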