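---
title: "Methods: prediction-mode triage of AlphaFold2 models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prediction-mode triage of AlphaFold2 models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barbedwire)
```

## The model

AlphaFold2 writes a per-residue confidence, pLDDT ∈ [0, 100], into the
B-factor field of its output models. Below the conventional pLDDT 70
cutoff, predictions are heterogeneous: some regions are essentially
correct folds scored conservatively, some are isolated
secondary-structure-like elements without tertiary context, and some are
unpredicted filler whose geometry is systematically un-protein-like. This
package classifies each residue into one of six mutually exclusive modes
using three independent observables — confidence, tertiary packing, and
backbone validation — combined in a fixed decision tree:

| pLDDT | packed | outlier evidence | mode |
|---|---|---|---|
| ≥ 70 | yes | (ignored) | predictive |
| ≥ 70 | no | (ignored) | unpacked high-pLDDT |
| < 70 | yes | none | near-predictive |
| < 70 | yes | present | unphysical |
| < 70 | no | none | pseudostructure |
| < 70 | no | present | barbed wire |

"Outlier evidence" means *high outlier density* or a *signature outlier*
(below). Outliers are deliberately ignored at high confidence: occasional
validation outliers occur in good experimental structures too and are not
diagnostic there.

### Packing

The packing score of residue *i* is the number of distinct qualifying
heavy-atom contact pairs touching the window *i−2..i+2* of *i*'s
peptide-bonded segment, divided by the window's heavy-atom count. A pair
qualifies when the distance is at most r₁ + r₂ + 0.25 Å (radii C 1.70,
N 1.625, O 1.40, S 1.80 Å; boundary inclusive), the residues are not
within sequence separation 4 in the same chain, and the residues do not
share one secondary-structure element. The exclusions make helices and
sheets prove tertiary context: their rich internal contacts never count.
Packed means score > 0.6 for helix and coil residues and > 0.35 for
strand residues, whose dominant intra-sheet contacts were excluded.

Two readings of "number of different steric contacts" are possible —
distinct contacting pairs or distinct partner atoms. This implementation
counts **pairs** (contact events); the choice is recorded here because it
changes absolute scores, and the cutoffs are configurable through
`bw_config()` for users who recalibrate.

This is a heavy-atom distance criterion. The hydrogen-placement +
dot-surface pipeline used by the Phenix ecosystem produces different
absolute scores; the cutoffs here are defaults validated against the
synthetic fixtures, not against that pipeline.

### Validation evidence

* **Dihedrals**: φ(i) from C(i−1)–N(i)–CA(i)–C(i), ψ(i) from
  N(i)–CA(i)–C(i)–N(i+1), ω of bond (i, i+1) from
  CA(i)–C(i)–N(i+1)–CA(i+1); undefined at segment termini and for
  degenerate (collinear) quadruples.
* **Peptide bonds**: |ω| ≤ 30° cis (cis-Pro iff the following residue is
  proline), |ω| ≥ 150° trans, otherwise twisted (the MolProbity omegalyze
  convention; boundary values are cis/trans, not twisted).
* **Covalent geometry**: z = (observed − target)/σ for backbone bonds
  N-CA, CA-C, C-O, C-N and angles N-CA-C, CA-C-N, CA-C-O, C-N-CA against
  Engh–Huber-style targets (`backbone_restraints()`). Outlier iff |z| >
  4. Measures spanning the peptide bond mark both sharing residues; the
  C-N-CA angle — the most diagnostic barbed-wire distortion, peaking near
  −4σ in such regions — is additionally tracked per bond.
* **Ramachandran**: status from a bundled coarse rectangle table per
  residue class (general / glycine / proline / pre-proline), with the
  contract that α and β cores are favored and the interior of the
  upper-right signature box is an outlier for the general class. The
  table is deliberately coarse; externally computed statuses (e.g. from a
  MolProbity run) can be injected per residue and override it.
* **CA geometry (CaBLAM proxy)**: residue *i* is flagged iff the virtual
  angle CA(i−1)-CA(i)-CA(i+1) is < 73° or > 155°, or an adjacent
  intra-segment CA–CA distance leaves [2.7, 4.1] Å. Residues without both
  neighbors are never flagged. An injected CaBLAM outlier list overrides
  the proxy.

**High outlier density** at residue *i*: over the window {i−1, i, i+1}
within one segment, at least two of: (c1) ≥ 2 residues carry
cis-nonPro/twisted bond attributes; (c2) ≥ 2 residues are CA-geometry
outliers; (c3) ≥ 2 residues are covalent outliers; (c4) all three lie in
the high-ψ band (+60 < ψ < +170) and ≥ 1 is a Ramachandran outlier.
Truncated terminal windows evaluate c1–c3 over the available residues and
can never satisfy c4. For c4 the Ramachandran outlier may be any window
residue — all three are in the band by the condition's premise, so no
separate in-band requirement is imposed on the outlier itself.

**Signature outliers**: (s1) a Ramachandran outlier inside the open box
(−15, +170) × (+60, +170), regardless of packing or confidence; (s2) a
CA-geometry outlier in a low-pLDDT unpacked region; (s3) sharing a
peptide bond that carries a C-N-CA outlier, a cis-nonPro, or any twisted
ω — both sharers are marked, reflecting that the phenomenon lives on the
bond; (s4) sharing a cis-Pro bond while low-pLDDT and unpacked — cis-Pro
is legitimate in well-predicted context and only counts as a signature
where the context is already suspect.

### Smoothing and survey pruning

Runs of 1–2 residues of one low-pLDDT category surrounded on both sides
by one identical other category are relabeled to match; passes repeat to
a fixed point (each pass strictly reduces the number of maximal runs, so
termination is guaranteed). Two readings were open: whether the flanks
must agree (chosen: yes — "surrounded by residues of another category"
reads as one category) and whether relabeling into a high-pLDDT category
is allowed (chosen: yes — the rule states no restriction on the
surrounding category, only on the surrounded one). Terminal runs and runs
adjacent to unclassified residues are never relabeled. Unphysical is
treated as a low-pLDDT category and is smoothing-eligible.

Pre-smoothing labels are retained, because the survey pruning rule
operates on them: each maximal pre-smoothing run of barbed wire,
pseudostructure, or near-predictive loses 3 residues from each end and
keeps the interior only if ≥ 3 residues remain. The pruned sets feed the
disorder-annotation overlap stage (`overlap_fractions()`), which reports
the fraction of each mode's residues covered by each annotation's
1-based, inclusive residue ranges.

## Tunable parameters

All defaults live in `bw_config()`:

| parameter | default | unit | rationale |
|---|---|---|---|
| `plddt_high` | 70 | pLDDT | conventional high-confidence cutoff; inclusive (≥ 70 is high) |
| `pack_cutoff_helix_coil` | 0.6 | contacts/atom | packed verdict, strict > |
| `pack_cutoff_strand` | 0.35 | contacts/atom | lowered: intra-sheet contacts are excluded |
| `contact_gap` | 0.25 | Å | van der Waals surface separation, boundary inclusive |
| `min_seq_sep` | 4 | residues | excludes local contacts |
| `bond_z_cutoff` | 4.0 | σ | strict >, matching the −4σ convention |
| `high_psi_band` | (60, 170) | degrees ψ | open interval |
| `signature_box` | (−15, 170) × (60, 170) | degrees φ × ψ | open intervals |
| `cis_max` / `trans_min` | 30 / 150 | degrees | omegalyze convention |
| `density_window` / `packing_window` | 3 / 5 | residues | stated window sizes |
| `smoothing_max_run` | 2 | residues | longest absorbable run |
| `ca_angle_lo/hi`, `ca_d_lo/hi` | 73/155°, 2.7/4.1 Å | | CA-proxy bounds |

## The synthetic generator

`make_fixture()` fabricates one world per failure mode from torsion
scripts (`torsion_script()` → `build_backbone()`, a sequential
natural-extension construction placing N/CA/C/O and CB from ideal
restraint geometry). Distortions are injected as offsets to named
internal coordinates in σ units, so the validator recovers an injected
k·σ offset as z = k exactly — the builder and validator are exercised
against each other, not against themselves.

Stated worlds and their defaults:

* pLDDT profiles: predictive 85–95, unpacked helix 90–98, near-predictive
  55–65, pseudostructure 25–45, poly-proline II 22–40, barbed wire 20–45
  (the observed pLDDT floor is about 20), unphysical core 38–48.
* Packed assemblies are four parallel 12-residue strands 4.6 Å apart —
  inter-chain contacts are always eligible, so the packed verdict is
  structural, not tuned. The unphysical core distorts the C-N-CA angle by
  −4.5σ on four bonds of one interior chain; −4.5σ clears the |z| > 4
  cutoff with margin while barely moving the chain, so packing persists.
* The barbed-wire coil draws φ uniformly in (−15, +170) and ψ uniformly
  in (+60, +170), twists ≥ 40% of its peptide bonds and distorts C-N-CA
  by −4.5σ on ≥ 40% of its bonds. Unconstrained iid draws from the box
  produce tight random coils (persistence ≈ 2 residues) that pack against
  themselves at sequence separation 5–9 — which the classifier correctly
  calls unphysical, but which is not the wide-arc phenomenon the mode
  describes. The generator therefore mirrors the phenomenon's own
  account — a default conformation whose deviations exist to avoid
  clashes — by resampling per-residue draws that land on the tight-spiral
  diagonal of the box (constant-torsion 5-mer extension ≤ 9 Å) and
  rebuilding chains with any CA–CA approach < 9 Å at separation ≥ 5.
  Twisted ω values are ±140°, classifying as twisted while preserving the
  local chain direction.

What a green fixture test establishes: that the pipeline's stages compose
correctly on geometry whose ground truth is known by construction. What
it does not establish: fidelity to real AlphaFold2 output (no sidechains
beyond CB, no PAE, no genuine hydrogen bonding, idealized bond geometry
outside the scripted distortions), or that the packing cutoffs match the
Probe-based reference scores.

## Numerical choices

* Torsions are reported in (−180, 180]; test comparisons near the ±180
  seam use circular differences.
* The |z| > 4 outlier comparison carries a 10⁻⁶ guard so an observation
  sitting exactly on the boundary (e.g. C-N-CA at 114.5°, z = −4) is not
  flagged when floating-point noise lands it infinitesimally past the
  cutoff. Undistorted builds reconstruct with |z| < 10⁻⁶.
* Box and band bounds are open intervals: φ = −15 or ψ = +60 exactly is
  outside.
* Secondary-structure window hits mark only their central residues
  (middle two of a helix window, middle one of a strand window), so an
  element needs several consecutive hits; alternating torsions yield
  coil. Helix wins ties; minimum lengths are 5 (helix) and 3 (strand).
* Degenerate dihedral quadruples yield undefined torsions and an
  `unevaluable` Ramachandran status; residues missing N, CA, or C are
  parsed but ineligible for classification and break peptide segments
  (continuity requires C–N ≤ 2.5 Å).
* Contact search uses a uniform grid (cell edge = maximum contact
  distance); the test suite proves it equal to an O(n²) scan.

## Limitations

* The CA-geometry proxy is not CaBLAM, and the coarse Ramachandran table
  is not the MolProbity contour set; both are injection-overridable and
  documented as proxies. Rotamers, Cβ deviations, and clash analysis are
  out of scope (non-diagnostic for these modes).
* Absolute packing scores are not comparable to dot-surface pipelines.
* The disorder-annotation overlap stage asserts, and does not remap,
  agreement between structure numbering and annotation numbering, and
  reads only locally supplied range files (no database client).
* Signature rules are specific to AlphaFold2's failure behavior; newer
  model generations may not exhibit them.
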