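---
title: "Repeat-swap homology modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat-swap homology modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swapsmith)
```

## The scientific problem

Secondary active transporters work by alternating access: the substrate
site is exposed to one side of the membrane at a time, and transport
requires a conformational change between an outward-facing and an
inward-facing state. Most transporter folds contain *inverted-topology
repeats* — two structurally similar segments of one chain related by a
two-fold pseudo-symmetry axis lying in the membrane plane, so the two
copies run through the membrane with opposite orientation. In any one
captured state the two repeats adopt *different* conformations; exchanging
those conformations between the repeats converts the structure into the
complementary state ("asymmetry exchange").

Repeat-swap homology modeling turns this observation into a prediction
machine: given one crystal structure, model repeat 1 on repeat 2's
structure and repeat 2 on repeat 1's, and the result is a model of the
other conformation. swapsmith implements the standardized protocol around
this idea — everything except the restraint-based model optimisation
itself, which remains the job of an external engine such as Modeller —
plus the analysis used to quantify the predicted motion.

## The protocol as implemented

1. **Repeat definition** (input, never inferred). Repeat boundaries are
   user-supplied residue ranges in author numbering
   (`repeat_definition()`); presets for the glutamate-transporter homolog
   Glt_Ph and the concentrative nucleoside transporter VcCNT are packaged
   (`glt_ph_repeats()` etc.). Automatic repeat detection is excluded on
   purpose: repeats in asymmetric, low-identity folds are identified
   manually in practice, and no reliable automated procedure exists.

2. **Structural alignment of the repeats** (`align_repeats()`). A
   sequence-independent alignment by iterative dynamic programming over
   the TM-score local similarity `1/(1 + (d_ij/d0)^2)`, alternating with
   Kabsch superposition on the current pair list, until the pair list is
   stable (at most 30 iterations; the best-scoring iteration is kept, with
   a warning on non-convergence). Gap opening costs 0.6 on the local-score
   scale and extension is free; these defaults are package choices,
   recorded here and in the configuration, not published values. Seeding
   is by gapless correspondences at several offsets.

3. **Duplicated full-length alignment** (`build_swap_alignment()`). The
   target's RU1 columns are paired with the template's RU2 residues and
   vice versa (the transposed pair list); peripheral segments outside both
   repeats are self-aligned gaplessly; linker residues belonging to no
   block become target-only columns. When a repeat unit is split into two
   sequence segments (as in Glt_Ph), the complementary repeat's residues
   are distributed across the segments at the pairing boundary, which is
   exactly the order that keeps the alignment monotone — and therefore
   Modeller-valid — against the swapped coordinate file.

4. **Swapped template assembly** (`assemble_swapped_template()`). The
   coordinate file is rewritten with RU2 first and RU1 second, peripheral
   segments at their swapped sequence positions, and residues renumbered
   consecutively; the old-to-new numbering map is kept and also written as
   a `REMARK 300` block. Because the swapped model is upside-down with
   respect to the template, peripheral fragments are reoriented by
   superposing the input structure onto a preliminary swapped model via an
   RU1-onto-RU1 fit and applying that transform to the peripherals.

5. **Alignment refinement** (`refine_alignment()`). Gap openings inside
   helical runs of the template are relocated to the nearest non-helix
   column (ties broken toward the N terminus), preserving the number of
   aligned pairs. Helix assignments come from a DSSP file (`read_dssp()`)
   or from a CA-geometry fallback (`assign_ss()`: i to i+3 CA distance
   5.1 ± 0.6 Å sustained over at least 4 positions). Conservation-based
   refinement is deliberately advisory only — the package reports highly
   conserved template residues left unaligned, and changes nothing —
   because that step is human-in-the-loop in practice.

6. **Distance restraints** (`intra_domain_restraints()`,
   `ligand_restraints()`). Gaussian restraints with σ = 0.1 Å preserve
   the internal structure of the scaffold/oligomerization and transport
   domains independently: one restraint per unordered CA pair strictly
   closer than 60 Å within a domain, never across domains. Ligand
   restraints connect every heavy ligand atom to every heavy protein atom
   strictly within 5 Å (Glt_Ph aspartate/Na⁺ convention) or 3.5 Å
   (VcCNT uridine convention); a named-pair mode adds specific partners —
   for the VcCNT sodium site, the backbone O of N149, V152 and I184, the
   S183 hydroxyl oxygen and a crystallographic water — regardless of
   distance. "Strictly less than" is read literally; pairs at exactly the
   cutoff are excluded. Restraints measured on the template are translated
   to model numbering through the swap alignment (`map_restraints()`);
   restraints touching unaligned residues are dropped with a warning. We
   restrain *all* intra-domain pairs, including pairs already implied by
   the template; the redundancy is harmless for a Gaussian form.

7. **Model building.** Two routes. `emit_modeling_inputs()` writes a
   complete, self-consistent Modeller input bundle (template PDB, PIR
   alignment, restraint TSV plus a Modeller-syntax stanza, driver
   skeleton; 200 models per refinement round and 2000 for the restrained
   stages by default). `build_naive_model()` is a dependency-free
   coordinate-transfer builder: each aligned target residue takes its
   template partner's backbone coordinates, and unaligned residues are
   placed by linear CA interpolation and marked with occupancy 0. The
   naive builder exists so that the full protocol and the motion analysis
   are testable end to end without external binaries; it is not a
   substitute for restraint-based modeling and produces backbone-only
   coordinates.

## Quantifying the motion

`analyze_change()` compares two conformations sharing residue numbering:

* superpose on scaffold CA atoms (the static reference frame; a
  `fit_ranges` override exposes the narrower oligomerization-helices
  convention),
* Kabsch-fit the transport-domain CA atoms to obtain the rigid transform
  carrying the reference transport domain onto the model's,
* decompose it into the rotation angle (matrix trace), rotation axis
  (antisymmetric part; near 180° the dominant eigenvector of the
  symmetric part), and the transport-centroid displacement expressed in a
  membrane frame,
* report per-domain RMSD and TM-score — each from its own domain
  superposition, i.e. the internal difference of that domain between the
  conformations — and the per-residue CA displacement profile after the
  scaffold fit.

Conventions worth stating. The membrane frame defaults to the laboratory
frame with the normal along z, matching membrane-oriented (OPM-style)
input; displacements are reported as (dx, dy, dz) in that frame, and the
(x, y, z) convention for the centroid displacement is a package choice
recorded in the report metadata. The rotation angle is always in
[0, 180°] with the axis sign conventional, so the axis-versus-normal
angle is folded into [0, 90°]. The angle, RMSDs, TM-scores and the
displacement profile are invariant under a common rigid transform of both
structures; the displacement *components* co-rotate with the frame, so
the frame must be co-transformed for component-wise comparisons. Motion
is computed from CA atoms only; an all-atom variant would change results
only marginally for rigid domains and is not the field's convention for
domain motions.

The TM-score follows the published formula
`TM = max (1/L) Σ 1/(1+(d_i/d0)^2)` with
`d0 = 1.24 (L-15)^(1/3) - 1.8`, clamped below at 0.5 because the formula
turns negative for normalisation lengths under about 21 residues. The
maximisation uses the standard iterative fragment search (seeds of length
n, n/2, n/4; close-pair refitting until stable). For 8 or fewer residues
the search enumerates every aligned subset, which makes it provably
exhaustive at that size — the property the test suite exploits.

## The synthetic generator: what it emulates, and what it does not

`make_toy_transporter()` builds a toy with the inverted-repeat
architecture: ideal poly-alanine helices (rise 1.5 Å per residue, 100°
per residue) along the membrane normal; RU2 is RU1 mapped through an
exact 180° rotation about an in-plane axis; the conformational asymmetry
is a rigid swing of RU2's transport sub-repeat about an in-plane axis
through its scaffold anchor plus a shift along the membrane normal; and
straight-line glycine connectors stand in for loops. The generator
records the exact symmetry operation, the true residue correspondence,
the true swapped-conformation structure (each repeat residue takes its
partner's coordinates mapped back through the symmetry operation), and
the exact transport-domain motion between the two states, obtained by
Kabsch-fitting its own truth pair — the oracle every downstream check
recovers.

Default conditions: 4 helices per repeat (half scaffold, half transport),
12 residues per helix, a 20° swing with a 5 Å normal shift, one
peripheral helix, and 0.3 Å Gaussian coordinate jitter — a swing of the
magnitude seen in elevator transporters and jitter of the order of
crystallographic coordinate uncertainty. Two geometric choices deserve
explanation. First, the swing axis passes through the *scaffold anchor*
of the swung repeat, so rotation and translation are coupled as in a
lever — the essence of an elevator motion. Second, the transport helices
sit at the lever distance `shift / sin(angle)` from that axis, where the
normal shift cancels the lever's drop along the helix axes: the
asymmetric repeat keeps its helix register recoverable by automatic
structural alignment. Real transporters offer no such guarantee — in
practice register errors between repeats are fixed by manual alignment
refinement against secondary structure and conservation, a step no
generator can emulate. Passing the toy suite therefore demonstrates that
the pipeline machinery is correct and self-consistent, not that automatic
alignment suffices for real, highly diverged repeats. The toys also lack
side chains, sequence divergence between repeats (they are poly-alanine,
so alignment carries no sequence signal — arguably the hard case),
ligands, loops with realistic geometry, and crystallographic artefacts.

Noise is applied to the original structure and carried into the swapped
truth through the exchange map, so the truth pair is self-consistent at
any noise level; noise therefore stresses alignment and superposition
robustness rather than adding irreducible error.

## Numerical choices and degenerate inputs

* Kabsch superposition rejects inputs with fewer than 3 pairs or with
  collinear/coincident geometry (rank check at 1e-9); the proper-rotation
  branch of the SVD is always taken, so reflections cannot appear.
* Altloc resolution keeps the highest occupancy, ties broken by the
  alphabetically first identifier; the policy is recorded in the
  structure's provenance attribute.
* Strict `<` at every distance cutoff; boundary pairs are excluded.
* `read_pdb()` refuses files without ATOM records and names the line of
  the first malformed fixed-column record; `write_pdb()` refuses more
  than 99999 atoms rather than silently truncating serials.
* Gap relocation during refinement only moves a gap across a span where
  the other row is gapless, which is what guarantees the aligned-pair
  count is conserved; an infeasible move is skipped rather than forced.
* The toy generator is bit-reproducible for a given spec; it saves and
  restores the caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
data: toys of ~126 residues (~500 atoms), 20-seed recovery sweeps at the
default asymmetry, 50 random restraint fixtures of 20–45 residues, and
exhaustive TM-score oracles at 6–8 residues. These sizes were chosen so
the whole suite exercises every code path in well under a minute of
compute per component while keeping the statistical checks meaningful.
The Glt_Ph calibration checks (crystal-pair motion of 39.6° and domain
similarity) require the PDB entries 3KBC and 1XFH, which are not
redistributed with the package; point `options(swapsmith.pdb_dir = ...)`
at a directory containing them to activate those tests.

## Known limitations

* The naive builder transfers backbone atoms only and does not satisfy
  restraints; accuracy on real proteins is bounded by alignment quality.
* Single protomer, single chain: trimer assembly, cross-protomer symmetry
  restraints and multi-chain repeat units are out of scope.
* No automated repeat detection, conservation computation, or membrane
  positioning; these are accepted as inputs (membrane normal defaults to
  z).
* The restraint-violation score is a crude internal ranking aid, not a
  model-quality assessment.
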