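---
title: "Inferring binding-specificity residues from structure and paralogous family alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring binding-specificity residues from structure and paralogous family alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsrkit)
```

## The inference model

`bsrkit` operationalizes a simple, widely used idea about paralogous
ligand–receptor systems such as the gonadotropins (FSH/LH) and their
receptor ectodomains: selectivity is carried by a small set of
interface residues that are conserved *within* each family but
chemically divergent *between* the two families. The package therefore
combines two orthogonal lines of evidence:

* **structural evidence** — the residue participates in the interface,
  either by direct inter-molecular contact (first shell) or by
  stabilizing a contact residue intra-molecularly (second shell);
* **sequence evidence** — the residue's alignment column is conserved
  in its own family and class-divergent from the corresponding column
  of the paralogous family, under a reduced physicochemical alphabet.

A binding-specificity residue (BSR) is a residue with both. The
procedure is deterministic: given the same structure, alignments and
configuration it always produces the same calls.

Assumptions worth keeping in mind: the complex structure is taken as
representative of the bound state (no conformational ensembles); the
interface is interaction-defined, not buried-surface-defined; residue
author numbering in the structure is assumed to match the reference
numbering of the corresponding family alignment unless an explicit
position map or cross-family reference alignment is supplied; and the
two families are assumed alignable one-to-one at the positions of
interest.

## Geometric criteria and their defaults

Published interface analyses usually state only that "default
parameters" of classical tools were used; those defaults are not part
of any archive. The package therefore pins explicit, conventional
values and records them in every report (`write_report()` embeds the
full `geometry_config`). All are per-call overridable:

| criterion | default | unit | rationale |
|---|---|---|---|
| H-bond donor–acceptor (heavy atom) | 3.5 | Å | common heavy-atom convention when hydrogens are absent |
| H-bond donor–acceptor (with H) | 3.9 | Å | with an explicit H the D–A distance may be longer |
| H-bond ∠D–H⋯A minimum | 90 | deg | permissive angular screen in the HBPLUS tradition |
| salt bridge | 4.0 | Å | charged-group N⁺⋯O⁻ ion-pair convention |
| ionic (electrostatic) | 6.0 | Å | longer-range ion-pair convention |
| hydrophobic | 5.0 | Å | apolar carbon–carbon contact convention |
| cation-π | 6.0 | Å | cation-to-ring-centroid convention |

Classification rules that avoid double counting:

* One record per (residue pair, type), carrying the closest qualifying
  atom pair; `verbose = TRUE` exposes all qualifying pairs.
* Charged-group pairs are typed by a distance band: salt bridge within
  4.0 Å, otherwise ionic within 6.0 Å. A salt bridge therefore always
  satisfies the ionic criterion but is reported once. A consequence is
  that per-label monotonicity in the cutoffs holds for the merged
  ionic class (a pair migrates from ionic to salt bridge as the band
  widens), which is how the invariance tests assert it.
* A donor–acceptor pair whose donor belongs to a cationic side-chain
  group and whose acceptor to a carboxylate is classified ionic only,
  never additionally as a hydrogen bond.
* Contacts below 2.2 Å are chemically implausible (clash range); they
  are flagged `short_contact` but never silently dropped.
* Hydrophobic contacts are defined over side-chain carbons bonded only
  to carbon or hydrogen, for *every* residue type — so the aliphatic
  stem of an arginine can contact a valine — rather than over a
  whitelist of "hydrophobic residues". Under the strict bonding rule
  this set is {CB, CG} for arginine (Cδ bonds the side-chain nitrogen
  and is excluded).
* Histidine is treated as cationic for ionic detection by default
  (`his_cationic = TRUE`) and not as a cation-π acceptor
  (`his_aromatic = FALSE`); both are exposed because protonation is
  structure-dependent and deposited coordinates carry no charge state.
* In intra-molecular scans, residues adjacent in sequence only count
  when at least one participating atom is a side-chain atom; covalent
  backbone neighbours would otherwise satisfy any cutoff trivially,
  while genuine side-chain packing between neighbours (a real
  second-shell mechanism) is preserved.

Alternate locations are resolved before any geometry: highest
occupancy wins, ties break on the alt-loc label, deterministically.
Waters, hetero ligands and non-standard residues are removed (the
latter with a warning). Hydrogens are kept but flagged, and the
detectors use heavy-atom criteria unless a donor hydrogen is actually
present.

## Shells

First shell: any receptor residue with an inter-molecular record.
Second shell: a receptor residue, not first shell, with an
intra-molecular record (any of the five types — curated interface
tables show second-shell support via ionic, hydrophobic and
hydrogen-bond links alike) to a first-shell residue. Because "second
shell of the interface region" is meaningless for a residue on the far
side of the domain, a proximity filter additionally requires one atom
within `proximity_limit` (default 8 Å, `NULL` to disable) of any
hormone atom. The value is a design choice, not a published one, and
is recorded in reports. Hormone-side second shells can be computed but
are off by default; in this system hormone specificity evidence
concentrates in directly contacting residues.

Shell membership and BSR status are deliberately decoupled: the shell
table reports every supported residue, and the divergence criterion
then decides which become BSRs.

## Conservation under the reduced alphabet

The alphabet partitions the 20 standard residues into neutral
{N,Q,S,T}, acidic {D,E}, basic {K,R}, aromatic {F,Y,W}, aliphatic
{V,A,L,I,M} and singletons C, P, H, G. Column conservation is the
modal class frequency among non-gap residues; a column is "conserved"
at or above `cons_threshold`. The default threshold is 1.0 — strict
class conservation — because that is the regime in which the method's
logic ("conserved here, different there") is cleanest; 0.9 is the
documented relaxation for noisy or larger families, where single
exceptions (themselves biologically interesting, as the cross-species
compatibility checker shows) would otherwise erase a position.
`max_gap` (default 0.3) drops columns whose evidence is mostly
missing. Non-standard codes (X, B, Z) count as gaps.

Cross-family correspondence comes from a two-row alignment of the
family references (`build_correspondence()`), or defaults to identity
when the two numbering schemes already agree. A structural-alignment
cross-check of the correspondence is intentionally out of scope; an
explicit user-supplied map overrides everything.

## BSR calls and downstream products

`call_bsrs()` intersects shells with divergent positions. The default
is strict (divergence required). `admit_structural_only = TRUE` keeps
shell residues without divergence, flagged `waived = TRUE`: curated
BSR sets in the literature sometimes admit structurally central
residues whose class divergence is partial (e.g. a leucine facing a
tyrosine — both large and hydrophobic, different classes only at the
aromatic boundary), and the flag makes that editorial judgement
explicit rather than silent.

Mutant tables (`make_mutant_spec()`) render family swaps in
`E50R` notation; identity substitutions are skipped, gap partners are
omitted with a warning, and `apply_mutant_spec()` verifies the
wild-type letter before substituting — the round trip (A's reference
becomes B's at every substituted position) is a tested invariant.

The pharmacophore extractor maps side chains to abstract features via
a frozen dictionary (hydroxyl → donor+acceptor, carboxylate → anion at
the O–O midpoint, Lys/Arg → cation at Nζ/Cζ, aromatics → ring
centroid with tyrosine also a donor, aliphatics/proline → hydrophobe
at the side-chain carbon centroid, amides → donor+acceptor, cysteine →
hydrophobe+donor, histidine → donor+aromatic, glycine → nothing). For
tryptophan the six-membered ring anchors the aromatic feature. Feature
sets are invariant under rigid-body motion and anchors transform
covariantly — also a tested invariant.

## The synthetic generators, and what passing tests mean

`make_toy_complex()` builds residues from internal-coordinate
templates (ideal bond lengths/angles, extended side chains) and places
each requested pair so that the governing atom pair sits at an exact
distance, bodies pointing apart, pairs 30 Å from each other. Only that
governing distance is exact; the detectors are pure distance/angle
thresholds, so exactness elsewhere is unnecessary.
`make_random_system()` scatters randomly oriented residues in a box to
stress the engine against a brute-force scan, including clash-range
geometry. `make_family_pair()` plants class-divergent and class-shared
columns in otherwise uniform alignments, with i.i.d. substitution
noise and optional gaps.

Chosen study conditions for the planted-recovery checks: 20 sequences
per family, 120 columns, 10 divergent + 10 shared columns, noise 0
(strict threshold) and 0.05 (threshold 0.9), 20 seeds — small enough
to run in seconds, large enough that background columns essentially
never mimic a planted signal.

What the generators do **not** emulate: real folds and rotamers,
phylogenetic correlation between sequences (noise is i.i.d., real
families share ancestry), alignment errors, indel structure beyond
uniform gaps, and coupled structural/sequence noise. Green tests
therefore certify the *logic* — detectors fire exactly at their
cutoffs, the pipeline recovers what was planted — not performance on
real, noisy families, which depends on curation quality and is why the
conservation threshold is exposed rather than fixed.

## Numerical and degenerate-input choices

* Interaction records are canonically ordered (lower chain/number
  first, then sorted), so detection is symmetric in the two entities
  and re-runs are byte-identical.
* Empty inputs degrade explicitly: a structure with no standard
  residues errors; an empty inter-molecular record set yields an empty
  shell table with a warning; an empty divergent set yields zero BSRs.
* Spatial pruning (bounding-sphere test per residue pair at the
  largest cutoff) is exact; the brute-force path exists as the
  reference and both are exercised in tests.
* Seeds: generators take explicit seeds and restore the caller's RNG
  state; equal seeds give byte-identical FASTA/PDB output.
* Configuration is YAML (the R-ecosystem convention) and round-trips
  unchanged; every run records its full parameter set in the report.

## Known limitations

* No mmCIF input; no structure repair or homology modelling — the
  complex must arrive as a usable PDB file.
* π–π stacking, disulfides and aromatic–sulfur contacts are not
  detected (they do not enter the BSR logic here).
* The interface definition is interaction-based; ΔSASA-style
  definitions would classify marginal residues differently.
* Reproducing any published residue table on real data depends on the
  user's family curation; the package ships curated residue-level
  tables for the human gonadotropin system and a synthetic alignment
  stand-in for worked examples, clearly labelled as such.
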