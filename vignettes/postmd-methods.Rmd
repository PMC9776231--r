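---
title: "Methods and design of postmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of postmd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`postmd` analyses saved molecular-dynamics trajectories of protein
complexes, with the insulin-degrading enzyme (IDE) entrapping amyloid-β
(Aβ) dimers as the motivating system. This vignette records the models the
package implements, the parameters that matter, the numerical choices made
where the design was genuinely open, and what the synthetic fixtures do and
do not demonstrate.

## Data model

A trajectory is an ordered set of frames sharing one topology: an atom
table (serial, atom name, element, residue name, chain, 1-based residue
number) plus an `atoms x 3 x frames` coordinate array in Å and a strictly
increasing time vector in ps. Frames are read from multi-model PDB files
(one frame per `MODEL`); when the file carries no time metadata, frame
times are assigned as `(model - 1) * frame_interval` with a 10 ps default,
the usual save interval for trajectories of this kind. HETATM records,
waters and ions are skipped with a logged count; alternate locations keep
the highest-occupancy conformer; insertion codes are rejected because the
residue-numbering scheme of the analyses (H134, D1–K16, …) assumes plain
sequence numbers. Missing element columns are inferred from the leading
letter of the atom name.

Residue-range bookkeeping uses *region schemes*: `ide_regions()` encodes
the enzyme's four domains (43–285, 286–515, 542–768, 769–1016; domains 1–2
form IDE-N and 3–4 IDE-C), `abeta_regions()` the peptide's N/C split at
K16/L17. Analysis windows are closed intervals in ps; the pipeline defaults
to the first and last 5 ns of the trajectory (clipped to its span), the
conventional "initial versus final" comparison windows.

## Superposition, RMSD, RMSF

Superposition uses the Kabsch SVD solution with the usual determinant
correction so only proper rotations are returned; collinear point sets are
rejected since the in-line rotation is undefined. RMSD series fit each
frame onto a reference frame (default the first). The fitted atom set is
Cα only by default: the interface analyses are Cα-centric and Cα fitting is
standard practice; the atom set is configurable through `atom_names` since
backbone or heavy-atom variants are equally defensible. When a per-domain
RMSD is wanted, the fit is performed on that domain's own Cα atoms, so the
series tracks domain-local convergence rather than whole-complex motion.

RMSF is computed about an iteratively converged mean structure: frames are
fitted to the current mean, the mean is recomputed, and the loop stops when
the mean moves less than 1e-6 Å (at most 10 passes; in practice two
suffice). A mean-structure reference avoids biasing fluctuations toward
whichever single frame would otherwise be chosen. A strictly static
selection short-circuits to exact zeros rather than accumulating
floating-point noise through the fit.

## Secondary structure

Assignment is the classic electrostatic hydrogen-bond model: partial
charges on N–H and C=O give

E = 27.888 · (1/d(O,N) + 1/d(C,H) − 1/d(O,H) − 1/d(C,N)) kcal/mol,

with a bond called when E < −0.5 kcal/mol. The 27.888 kcal·Å/mol factor is
the canonical product of the partial charges and conversion constant that
reproduces the −0.5 threshold. Pairs within one sequence position on the
same chain are excluded, and donor/acceptor pairs whose Cα atoms are more
than 9 Å apart are pre-screened out (they cannot reach bonding geometry).
Missing amide hydrogens — minimised frames often lack them — are
synthesised 1.0 Å from N opposite the bisector of C(prev)–N–Cα, the
standard planar reconstruction; chain-initial residues have no donor and
therefore label C.

Labels are three-state by design: H where two consecutive i→i+4 bonds back
a helical run (residues i…i+3), E where residues take part in parallel or
antiparallel bridge patterns (partner strands may lie on other chains), C
otherwise. 3₁₀/π helices, turns and bends fold into C unless they form
i→i+4 runs, because only α-helix and β-strand percentages are reported
downstream. Isolated single bridges are labelled E rather than a separate
bridge state, since the three-state surface has nowhere else to put them.
Chains shorter than five residues are labelled all C. One consequence worth
noting: a five-residue helix supports only a single i→i+4 bond, so under
the two-consecutive-bonds rule it cannot score H — the rule's minimum
helix needs six residues.

Windowed percentages count, per residue, the fraction of window frames
labelled H (and E). Because it is ambiguous whether such percentages are
best reported per residue or chain-averaged, both are emitted: the profile
per residue, and the chain means as an attribute.

## Interaction maps and the contact rubric

Occurrence is the percentage of frames in which a residue pair satisfies
its distance criterion; every value is an exact frame count divided by the
frame total, and all cutoffs are inclusive (≤):

* hydrophobic: Cα–Cα ≤ 10 Å between hydrophobic residues;
* electrostatic: minimum distance between side-chain charged-group atoms
  (Asp/Glu carboxylate O versus Lys NZ, Arg NE/NH1/NH2, His ND1/NE2) ≤ 4 Å,
  opposite charges only;
* hydrogen bond: any donor hydrogen (H covalently attached to N or O,
  detected at 1.25 Å in the first frame) to any N/O acceptor of the partner
  residue ≤ 2.4 Å, in either direction. The criterion is purely
  distance-based — no angle term — matching the single-cutoff convention
  the analyses are built on. Structures without hydrogens are rejected with
  advice rather than silently returning zeros.

The hydrophobic inventory is Ala, Val, Leu, Ile, Met, Phe, Trp, Tyr, Pro —
Tyr and Pro included so aromatic/proline contacts of the Aβ F19/F20 type
are captured, Gly excluded for having no side chain — and is configurable
because no single inventory is universal. Histidine counts as positively
charged by default (configurable), consistent with simulation protonation
at the pH of interest.

Region-pair contacts are classified by four rules: (1) the side chains
face each other — the Cα→side-chain-centroid vector of each residue makes
an angle below 90° with the direction to the partner's Cα; facing is
summarised per pair as the fraction of frames facing, thresholded at 0.5,
because the rule acts as a static qualitative judgement; (2) the pair came
within the Cα cutoff in at least one frame (the occurrence map itself);
(3) the number of qualifying residue pairs between the two regions; and
(4) their occurrence percentages. A region pair is **strong** when at
least 2 qualifying pairs reach ≥ 85% occurrence, **weak** when qualifying
pairs exist but the strong condition fails, **none** when no pair
qualifies. The strong and weak conditions overlap at exactly (2 pairs,
85%); the overlap is resolved to strong, reading the ≥ of the strong rule
as governing. "Number of interactions" is read as the count of qualifying
residue pairs because contacts are reported at region (domain) level.
Glycine, lacking a side chain, is treated as always facing.

## Conformational gauges

Gauge series evaluate named inter-residue distances and three-residue
angles per frame; the default spec carries the six IDE descriptors
(distances H134–K884, F424–G615, V410–A614, K353–K657; angles
E176–A403–S721, A403–S721–D876). Measurements default to Cα because the
descriptors name residues, not atoms; the atom is configurable per site
(`chain:resid:atom`). No numeric open/closed threshold is asserted — none
is established — so the package reports descriptor traces and per-window
mean ± sd (population sd, the descriptive spread of the frames actually in
the window) and leaves state labelling to a user-supplied threshold.

## Conformer populations

Input is a set of conformers, each a list of per-conformation energies in
kcal/mol (computed externally, e.g. by an implicit-solvent method over the
final trajectory segment; energy evaluation is out of scope). The Monte
Carlo procedure: start at a uniformly random conformation of the pooled
set; each step proposes a uniformly random conformation of a uniformly
random *other* conformer and accepts the move when
exp(−(E_j − E_i)/kT) exceeds a uniform(0,1) draw — Metropolis acceptance,
factors above 1 always accepted. The occupied conformer is tallied every
step, rejected moves included, which is what makes ΣN_n equal the step
count; P_n = N_n/N_total. Defaults: T = 298 K, 10⁶ steps,
k = 0.0019872041 kcal/(mol·K). The walk runs in compiled code on R's RNG
stream, so a seed makes it exactly reproducible. No burn-in is applied —
the plain walk is the procedure being reproduced — and at 10⁶ steps over
the default problem size the initialisation bias is far below the Monte
Carlo error, which the oracle-agreement tests bound directly. Standard
errors come from batch means over 10 batches, appropriate for an
autocorrelated chain. Counting every step rather than only accepted moves
changes nothing asymptotically (both converge to the stationary law); the
every-step rule is chosen because it makes the counts sum to N_total.

`exact_populations()` is the independent check: P_n ∝ Σ_{c∈n}
exp(−(E_c − E_min)/kT), energies shifted by their minimum before
exponentiation so the sums cannot overflow. One caveat is recorded rather
than hidden: the other-conformer proposal is symmetric only when all
conformers carry equal conformation counts (the study design here: 500
each of 7). With unequal counts the proposal is no longer symmetric and
the walk's stationary law acquires the conformation counts as weights, so
the oracle and the walk are compared at equal counts. Relative free
energies are ΔG_n = −kT ln(P_n/P_max), zero for the most populated
conformer; zero populations yield Inf flagged via an attribute rather than
an error.

## Synthetic data: what it emulates, what it does not

The generators produce inputs with known ground truth:

* `make_ideal_helix()` builds poly-alanine backbones from φ = −57°,
  ψ = −47° with standard bond geometry and explicit amide hydrogens;
  `backbone_frame()` generalises to any dihedrals (extended strands for
  coil controls).
* `make_ideal_sheet()` places two idealised extended strands (separate
  chains) with amide H and carbonyl O oriented so the cross-strand
  hydrogen bonds of the requested sense register at ≈1.9 Å H⋯O — mutual
  (narrow-pair) bonds for antiparallel, the staggered pattern for
  parallel.
* `make_dimer_trajectory()` builds a two-chain poly-leucine toy whose
  residues carry a Cα, a single pseudo-side-chain atom (exactly
  controllable facing), and one hydrogen (so hydrogen-bond analysis runs;
  occurrences are zero since the toy is apolar). Scheduled pairs sit at
  the contact distance in exactly `round(occupancy × n_frames / 100)`
  frames — the frames chosen by a seeded permutation, so occurrence values
  are exact rather than binomially scattered; non-representable
  percentages round to the nearest frame count with the achieved value
  logged and returned. A small deterministic zigzag keeps chain geometry
  non-collinear (superposition-safe), and Gaussian coordinate noise of
  chosen amplitude can be overlaid.
* `make_salt_bridge_trajectory()` is the real-residue fixture (full-ish
  Lys/Glu side chains) for electrostatic and hydrogen-bond criteria; the
  NZ-attached hydrogen lies on the NZ→OE1 axis, so the H⋯O distance is the
  NZ–OE1 distance minus exactly 1 Å — convenient for boundary tests.
* `make_open_closed_toy()` arranges the twelve gauge residues in four
  rigid pseudo-domains such that every default distance gauge at least
  doubles from closed to open and both angles change by more than 20°.
* `make_conformer_energies()` draws Gaussian energies per conformer; the
  default is 7 conformers × 500 conformations with means spanning
  3 kcal/mol and 1 kcal/mol spread — the scale of a typical
  implicit-solvent conformer comparison.

All generators are deterministic given their seed and leave the session
RNG state untouched. What they do *not* emulate: force-field physics,
solvent, realistic side-chain rotamer statistics, correlated domain
motions, or the gradual interconversion of contact patterns — trajectories
are schedules, not dynamics. Passing tests therefore demonstrate that the
measurement and classification machinery is exact and invariant where it
should be, not that any biological conclusion about IDE–Aβ systems is
reproduced; on real trajectories the inputs are noisier and the cutoff
sensitivity of occurrence values is correspondingly larger.

## Pipeline and problem sizes

`run_pipeline()` validates its configuration fully before computing
anything (missing files, malformed criteria, windows outside the
trajectory span, regions outside chains, unresolvable gauges), then runs
the requested stages and writes one CSV per stage plus a JSON manifest of
inputs, parameters, seed, package version and per-stage status — enough to
re-run the pipeline exactly. All stochastic behaviour flows from the
single top-level seed, so identical configs give byte-identical outputs.

The shipped tests and the acceptance script run at desk scale, chosen so
the whole suite completes in well under five minutes on one CPU while
leaving Monte Carlo error comfortably below the tolerances being asserted:
trajectories of 2–100 frames and tens of residues, 7 × 500 energy
ensembles, 10⁶-step walks (a walk takes well under a second in compiled
code), 1000-case rubric randomisations, and 100-transform invariance
sweeps.

## Known limitations

* Secondary structure is three-state; no κ/α curvature-based bends, no
  eight-state output, no solvent accessibility.
* The hydrogen-bond criterion has no angular term; at 2.4 Å this is the
  intended convention but it will admit geometries a DSSP-style energy
  would reject.
* Electrostatics uses a fixed charged-atom inventory; non-standard
  protonation states beyond the His toggle require editing the inventory.
* The population walk's stationary law matches the Boltzmann oracle
  exactly only for equal conformation counts per conformer (see above).
* PDB support covers ATOM/MODEL records with plain numbering; insertion
  codes, DCD/XTC binary formats and topology files are out of scope.
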