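# bsrkit

Binding-specificity residue (BSR) inference for paralogous
ligand–receptor families, developed around the human gonadotropin
system: FSH and LH are heterodimeric glycoprotein hormones that share
an α-subunit and ~80% β-subunit similarity between the LH/CG pair, yet
each binds its own receptor ectodomain with high selectivity. The
residues that enforce that selectivity are a small set at the
interface — conserved within each hormone (or receptor) family, but
chemically divergent between the two families. `bsrkit` identifies
them from two inputs a structural biologist typically has: one complex
structure (PDB) and multiple-sequence alignments of the two paralogous
families.

## Method

The inference chain combines structural and evolutionary evidence:

1. **Interface contacts.** From the complex structure, five
   interaction types are detected with explicit geometric criteria
   (all configurable): hydrogen bonds (donor–acceptor heavy-atom
   distance ≤ 3.5 Å; with explicit hydrogens ≤ 3.9 Å and
   ∠D–H⋯A ≥ 90°), salt bridges (side-chain N⁺⋯O⁻ ≤ 4.0 Å),
   longer-range ionic pairs (≤ 6.0 Å), hydrophobic contacts (apolar
   carbon pairs ≤ 5.0 Å) and cation-π interactions
   (Lys Nζ / Arg Cζ to aromatic ring centroid ≤ 6.0 Å).
2. **Interface shells.** Receptor residues with a direct
   inter-molecular contact form the *first shell*; residues that
   instead contact a first-shell residue intra-molecularly (within a
   configurable 8 Å proximity of the hormone) form the supporting
   *second shell*.
3. **Reduced-alphabet conservation.** Alignment columns are scored
   under a physicochemical alphabet — neutral {N,Q,S,T}, acidic {D,E},
   basic {K,R}, aromatic {F,Y,W}, aliphatic {V,A,L,I,M}, with C, P, H,
   G kept as singletons — so "conserved" means conserved chemistry. A
   position is a *specificity-determining position* when both families
   are class-conserved at corresponding columns but on different
   classes (e.g. acidic in one receptor family, basic in the other).
4. **BSR calls and products.** A residue is a BSR iff it is in the
   interface shell *and* its position is family-divergent. From the
   calls the package derives family-swap mutant tables
   (`E50R`-style), cross-species compatibility reports (why a
   non-cognate hormone from another species can bind), and a
   pharmacophore feature template (donor/acceptor/cation/anion/
   aromatic/hydrophobe points anchored at side-chain coordinates) for
   peptidomimetic design.

A synthetic-data module generates toy complexes with interactions
planted at exact distances and two-family alignments with planted
divergent columns, so the whole chain is testable without downloads.

## Worked example

Plant a salt bridge and a cation-π contact in a toy complex and detect
them:

```r
library(bsrkit)
toy <- make_toy_complex(list(c("LYS", "ASP", "SALT_BRIDGE", 3.5),
                             c("ARG", "TYR", "CATION_PI",  5.5)),
                        seed = 1)
sel <- select_entities(toy$model, hormone_chains = "A",
                       receptor_chains = "B")
detect_interactions(toy$model, sel)
#>   label_a atom_a label_b atom_b        type distance
#> 1      1K     NZ      1D    OD1 SALT_BRIDGE      3.5
#> 2      2R     CZ      2Y  RING1   CATION_PI      5.5
```

Each row is one residue pair: the lysine ammonium nitrogen 3.5 Å from
an aspartate carboxylate oxygen is typed as a salt bridge; the
arginine guanidinium carbon 5.5 Å from the tyrosine ring centroid as a
cation-π contact.

Cross-species compatibility against the FSH family's BSR positions,
using a horse-type LH β-subunit query (which, unlike other LH
sequences, carries a valine at position 96):

```r
sf <- synthetic_fsh_family()
pr <- profile_columns(sf$aln)
cross_react(sf$query_horse_lh, sf$aln, pr, sf$bsr_positions,
            query_id = "horse_LH")
#> <compatibility_report> horse_LH vs FSH BSR positions: score 0.14
#>  position cognate_class query_residue query_class match unresolved
#>        42             P             L   ALIPHATIC FALSE      FALSE
#>        89       NEUTRAL             R       BASIC FALSE      FALSE
#>        90        ACIDIC             S     NEUTRAL FALSE      FALSE
#>        95       NEUTRAL             G           G FALSE      FALSE
#>        96     ALIPHATIC             V   ALIPHATIC  TRUE      FALSE
#>        97         BASIC             P           P FALSE      FALSE
#>       103      AROMATIC             T     NEUTRAL FALSE      FALSE
```

Position 96 is flagged class-compatible (valine is aliphatic, the
class the FSH family conserves there) — the single-residue signature
that rationalizes horse LH binding to mammalian FSH receptors.

For a complete run on real inputs, describe the structure, chains and
the four family alignments in a YAML configuration (see
`?bsr_config`), then `run_pipeline(read_bsr_config("pipeline.yaml"))`
or use the wrapper `inst/scripts/bsr.R run --config pipeline.yaml`.
`write_report()` exports interaction/shell/profile/BSR tables, mutant
lists and a Markdown report embedding every cutoff used.

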