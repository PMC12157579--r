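# barbedwire

Per-residue triage of AlphaFold2 structure predictions into six
**prediction modes**, for structural biologists who need to decide which
parts of a prediction to trust, trim, or feed into molecular replacement.

AlphaFold2 models routinely contain long regions below the rule-of-thumb
confidence cutoff pLDDT ≥ 70. Those regions are not uniformly useless: some
are nearly correct predictions scored too pessimistically, others are
isolated secondary-structure-like elements with no tertiary context, and
others are unpredicted filler — wide, looping coils dense with backbone
geometry errors. This package classifies every residue by combining three
observables:

1. **pLDDT**, read from the B-factor field of the input model;
2. a **packing score** — tertiary steric contacts per heavy atom over a
   5-residue window (i−2..i+2), counting heavy-atom pairs within 0.25 Å of
   van der Waals surface contact, excluding pairs at sequence separation
   ≤ 4 and pairs internal to one secondary-structure element. Packed means
   score > 0.6 for helix/coil residues, > 0.35 for strands (whose
   intra-sheet contacts were excluded);
3. **backbone validation evidence** — Ramachandran status, cis/twisted
   peptide bonds (|ω| ≤ 30° cis, ≥ 150° trans, else twisted), a
   CA-virtual-geometry proxy for CaBLAM, and covalent bond/angle z-scores
   against Engh–Huber-style restraints with outliers at |z| > 4.

The decision tree: pLDDT ≥ 70 → *predictive* (packed) or *unpacked
high-pLDDT* (not). Below 70, with `bad` = high outlier density ∨ signature
outlier: packed ∧ ¬bad → *near-predictive*; packed ∧ bad → *unphysical*;
¬packed ∧ ¬bad → *pseudostructure*; ¬packed ∧ bad → *barbed wire*.
A residue has **high outlier density** when ≥ 2 of four conditions hold on
its 3-residue window (≥2 residues with cis-nonPro/twisted bonds; ≥2 with
CA-geometry outliers; ≥2 with covalent outliers; all three in the high-ψ
band +60 < ψ < +170 with ≥1 Ramachandran outlier). A **signature outlier**
is a Ramachandran outlier in the upper-right box (−15 < φ < +170,
+60 < ψ < +170), a shared C-N-CA angle outlier / cis-nonPro / twisted bond
(both bond sharers marked), or a context-dependent CA-geometry or cis-Pro
outlier in a low-pLDDT unpacked region. Isolated runs of 1–2 low-pLDDT
residues surrounded by one identical other category are smoothed into their
surroundings.

The package also ships a torsion-script backbone builder and a synthetic
decoy generator (`make_fixture()`) that fabricates each failure mode with
controlled distortions, a survey pruning rule (trim 3 from each end of a
pre-smoothing run, keep interiors ≥ 3), and an overlap stage scoring mode
residue sets against locally supplied disorder-annotation range files.

## Worked example

```r
library(barbedwire)

# a packed four-strand assembly at high pLDDT + a distorted low-pLDDT coil
pred <- make_fixture("predictive_bundle", seed = 1)$model
coil <- make_fixture("barbed_wire_coil", seed = 1)$model
coil$atoms$x <- coil$atoms$x + 60   # keep the parts apart
coil$atoms$chain <- "X"
model <- combine_models(pred, coil)

ann <- bw_analyze(model)
print(ann)
#> <bw_annotation> 78 residues
#>   predictive           48
#>   unpacked_high_plddt  0
#>   near_predictive      0
#>   pseudostructure      1
#>   barbed_wire          29
#>   unphysical           0

head(render_annotation(ann, "text"), 4)
#> residue      aa   plddt mode                 mode_pre             lprocg   score ss
#> A:1:         ALA   87.7 predictive           predictive           ------   1.133 coil
#> A:2:         ALA   88.7 predictive           predictive           ------   0.900 strand
#> A:3:         ALA   90.7 predictive           predictive           ------   1.160 strand
```

The assembly's residues are *predictive*: high pLDDT with packing scores
well above the 0.35 strand cutoff, and `------` Lprocg labels (not
barbed-wire-like in any regard). The coil's residues come out *barbed
wire* with labels like `Lpr--g` — low pLDDT (`L`), unpacked (`p`),
high-ψ-band Ramachandran outlier (`r`), covalent-geometry outlier (`g`).
The trailing residue reads `Lp----`, the typical *pseudostructure* label.

```r
sel <- write_selection_file(ann)      # default: predictive + near-predictive
sum(grepl("^ATOM", sel))
#> [1] 240                             # of 390 input atoms

kin <- render_kinemage(ann)           # toggleable per-mode groups,
                                      # blue/gray/green/gold/red/purple balls
```

Command line (phenix-style flags):

```sh
Rscript -e 'barbedwire::bwa_cli(standalone = TRUE)' model.pdb \
    output.type=selection_file modes=predictive,near_predictive --out trimmed.pdb
```

## Notes

- Contacts use a heavy-atom distance criterion, not hydrogen-inclusive
  dot surfaces; absolute packing scores therefore differ from
  Probe/Reduce-based pipelines, while the 0.6/0.35 cutoffs remain
  configurable defaults (`bw_config()`).
- Ramachandran status comes from a bundled coarse region table;
  externally computed per-residue statuses and CA-geometry outliers can be
  injected (`bw_analyze(..., inject = )`, CLI `--inject`).

See `vignettes/barbed-wire-analysis.Rmd` for the full methods account.
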