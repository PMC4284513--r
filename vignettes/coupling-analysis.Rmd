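---
title: "Methods: salt-bridge statistics, nonbonded energetics and gating analysis"
author: "kvcoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: salt-bridge statistics, nonbonded energetics and gating analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kvcoupling)
```

# Scope and model

Voltage-gated potassium channels couple the activation of their voltage
sensor (helices S1–S4) to the opening of the pore (S5–S6 of four subunits).
In Kv7.1 this coupling has two components: direct protein–protein contacts
between the S4–S5 linker and the S6 gate helix, and a protein–lipid
component mediated by PIP~2~, whose headgroup phosphates form salt bridges
with basic residues of the S2–S3 loop, the S4–S5 linker and the S6
terminus. `kvcoupling` implements the quantitative machinery for both
components: contact statistics and binding-site classification from
trajectories, per-residue nonbonded energy decomposition, and the
electrophysiology layer (ΔF/F, Boltzmann fits, mutant-cycle energies) that
probes coupling functionally.

## Salt-bridge criterion

A protein–lipid salt bridge is declared formed in a frame when the minimum
over all pairs of (basic side-chain nitrogen, phosphate oxygen) of the
minimum-image distance is **strictly less than 3.2 Å**. The tie case
matters for reproducibility: a pair at exactly 3.20 Å is *not* formed
(`detect_bridges()` uses `<`, never `<=`), while 3.19 Å always is. The
charged-group atom sets default to NE/NH1/NH2 for arginine, NZ for lysine,
and the phosphomonoester oxygens of the lipid's P1/P4/P5 phosphates; both
sets are ordinary named selections on the topology and therefore fully
configurable. Distances are always computed under the orthorhombic
minimum-image convention — headgroups sitting near a box face otherwise
produce spurious misses — and detection refuses to run when any box edge is
shorter than twice the cutoff, where the minimum-image argument breaks
down.

Formation probabilities are ratios of formed frames to total frames. The
four subunit copies are treated as exchangeable samples and pooled by
concatenation (`pool_subunits = TRUE`), so a probability keyed by residue
number aggregates 4 × n_frames observations. When several independent runs
are supplied, the pooled probability is the frame-weighted mean across
runs — an invariant the test suite checks — and the error bar is the
standard deviation of per-run probabilities. The SD divides by the number
of runs (population convention): the error bar describes the dispersion of
the runs actually performed rather than estimating a hypothetical
run-population variance. `sd_convention = "sample"` switches to the n−1
denominator; with a single run the SD is 0 and the row is flagged
`single_run`.

Probability bins follow the descriptive categories used for this system:
frequent (p > 0.75), moderate (0.25 ≤ p ≤ 0.50), intermittent
(0 < p < 0.25 or 0.50 < p ≤ 0.75), none (p = 0). A lipid is classified as
bound at the *intrasubunit* site when its partner residues span at least
two of {S2–S3, S4–S5, S6} and all partners lie on one subunit. When a
residue touches two lipids simultaneously its residue-level occupancy is
the logical OR (the interaction exists); per-lipid summaries keep lipids
separate, and one residue–lipid pair bridged through two oxygens still
counts once (boolean per pair).

Mutation effects are assessed by `compare_probability_tables()`: a
probability change is flagged when |Δp| exceeds the first (wild-type)
table's error bar, which is the operational rule for declaring that a
mutant redistributed the salt-bridge network beyond run-to-run noise.

## Nonbonded energetics

Pair energies use the CHARMM functional forms with combination rules
ε~ij~ = √(ε~i~ε~j~), r~min,ij~ = r~min,i~/2 + r~min,j~/2, a Coulomb
constant of 332.0636 kcal·Å/(mol·e²), an 11 Å cutoff and a switching
polynomial between 8 and 11 Å,

$$\mathrm{sw}(r) = \frac{(c^2-r^2)^2 (c^2 + 2r^2 - 3s^2)}{(c^2-s^2)^3},
\qquad s = 8\ \text{Å},\ c = 11\ \text{Å},$$

which is 1 below s, 0 above c, and C¹-continuous at both knots (verified
numerically on a 0.001 Å grid). Two deliberate choices:

* **Switched-cutoff Coulomb.** A per-residue decomposition is only
  well-defined for a pairwise-assignable potential; the reciprocal-space
  part of Ewald electrostatics is not. The decomposition therefore uses
  switched cutoff electrostatics at 11 Å. This is declared as the package's
  scheme, not inferred as the exact scheme of any particular engine; the
  dielectric is configurable and switching of the Coulomb term can be
  turned off (`switch_electrostatics = FALSE`), which then truncates at the
  cutoff.
* **No bonded exclusions.** The two regions analysed (residues 247–260 and
  323–358) share no chemical bonds, so every cross pair is genuinely
  nonbonded; the code asserts the ranges are disjoint rather than carrying
  a 1–2/1–3/1–4 exclusion machinery it would never use.

Each residue of region A is assigned the sum of its atoms' pair energies to
*all* atoms of region B, and vice versa; each atom pair is counted exactly
once, so per-residue values of either direction sum to the group total —
the suite enforces this per frame to 10⁻⁶ kcal/mol. Positive per-residue
values flag repulsive (destabilizing) contributions, the signature of the
like-charged R249/K358 pair; negative values stabilize.

Error bars are block SEs: the window is split into 5 consecutive,
near-equal blocks (remainder frames go to the leading blocks) and the SE is
the population SD of block means. Five blocks is the default because the
canonical analysis window (the last 50 ns) divides naturally into 10 ns
blocks that exceed typical bridge lifetimes; it is configurable.

For charge-reversal mutants an artificial salt bridge can form between the
mutated pair (e.g. R249E–K358); `exclude_bridge_frames()` removes frames
where the carboxylate-oxygen / basic-nitrogen distance is strictly below
the same 3.2 Å criterion — deliberately the mirror of the protein–lipid
rule.

## Equilibration, windows and headgroup shifts

Equilibration is usually declared by eyeballing a backbone-RMSD plateau.
`equilibration_start()` operationalizes it: the earliest time t such that
max − min of the RMSD within [t, t + window] stays within a tolerance
(defaults 20 ns and 1.0 Å). The criterion is monotone — tightening the
tolerance can only delay the detected onset — and returns `NA` ("not
equilibrated") for drifting series. RMSD uses least-squares rigid-body
superposition (via bio3d) of the N/CA/C/O backbone; superposition can only
lower the RMSD, which the suite checks property-style.

Convergence between analysis windows (e.g. 50–100 vs 100–120 vs 120–140 ns)
is summarized by the maximum per-residue pairwise probability difference;
the default threshold of 0.15 was chosen to exceed typical wild-type
across-run SDs so that "converged" is not triggered by sampling noise, and
it is always reported, never silently applied.

The state-dependent displacement of the lipid is quantified by projecting
the change in mean headgroup position (the P1/P4/P5 phosphorus centroid)
onto the unit vector from an S4 landmark centroid to an S6 landmark
centroid. Positive values mean "toward S6" (the activated/open-state pose);
the measure is antisymmetric under swapping conditions, and a degenerate
axis (coincident landmarks) is an error. No published numeric target exists
for this shift, so the tests validate it against constructions with
prescribed displacements.

## Gating layer

ΔF/F fits an ordinary least-squares line to the 2 s of fluorescence at the
holding potential preceding the test pulse, extrapolates it across the
record, and returns (F − F~b~)/F~b~ pointwise; a baseline line crossing
zero makes the division meaningless and is an error rather than a warning.

Activation curves are fit with
P(V) = 1/(1 + exp(−zF(V − V~1/2~)/RT)) — voltages in mV converted to volts
internally, F and R in SI units, T defaulting to 293.15 K (room
temperature). The fit is bounded Levenberg–Marquardt (minpack.lm) with
z ∈ (0, 10], V~1/2~ within the data span ± 100 mV, multi-start: V~1/2~
starts at the observed voltages nearest half-activation, z at the
finite-difference slope estimate z₀ = 4RT·s~max~/F and at 2z₀, z₀/2; the
converged start with the lowest residual sum of squares wins and standard
errors come from the fit curvature. All-equal responses are rejected as
degenerate instead of returning a spurious fit. Logistic evaluation goes
through `plogis`, so extreme voltages saturate without overflow.

The apparent closed→open free energy is ΔG = zFV~1/2~ in kcal/mol
(F = 23.0605 kcal·mol⁻¹·V⁻¹) — the chemical potential of the two-state
transition at zero voltage. Published mutant-cycle ΔΔG values for this
system do not come with a printed formula or wild-type V~1/2~/z, so those
values function as inputs: the cycle coupling energy is the exact
difference ΔΔG₁₂ − ΔΔG₁ − ΔΔG₂ with quadrature SEs, and an additive triple
returns exactly zero. Whether "normalized ΔF" was min–max scaled or scaled
by the Boltzmann asymptote is not stated in the source material; the module
therefore ingests already-normalized responses in [0, 1] and leaves raw
conductance normalization (tail currents, driving-force division) out of
scope.

# The synthetic-data generators

Real inputs of this kind — microsecond-scale all-atom trajectories of a
channel in a PIP~2~-containing bilayer, and oocyte voltage-clamp
fluorometry records — are not desk-computable and are rarely deposited.
Every estimator is therefore validated on generated data with known ground
truth:

* **Toy trajectories** (`gen_toy_trajectory()`): a rigid scaffold of
  basic-residue beads (4 subunits × 9 residues by default, one bead
  carrying the charged-group nitrogen), one lipid per subunit with P1/P4/P5
  marker beads and one phosphate-oxygen bead per residue–lipid pair. Per
  frame and pair, the oxygen sits at a distance drawn uniformly from
  [2.6, 3.19] Å (strictly inside the cutoff) with the target probability
  p\*, else from [5, 12] Å (strictly outside), so p\* is realized exactly
  in expectation and the binomial sampling error is the *only* error a
  correct estimator should show. The default p\* values mirror the
  wild-type activated/open pattern (R190/R195/R249 above 0.8, K354 at
  0.26, K358 at 0.42, K196/R259 intermittent). The 26 Å scaffold spacing
  exceeds twice the outer non-contact distance, so a pair bead can never
  stray within the cutoff of a foreign residue. Contacts are
  frame-independent Bernoulli draws by default; `dwell_frames` switches to
  a two-state Markov chain with the prescribed stationary probability and
  mean bound lifetime, mimicking long-lived bridges for
  autocorrelation-sensitive checks. Defaults are 250 frames at 0.2 ns —
  one 50 ns analysis window's worth of configurations.
* **Two-condition systems** (`gen_two_condition_system()`): prescribed
  per-residue probability deltas and a prescribed headgroup displacement
  along a given axis, for recovery tests of the mutation-comparison and
  headgroup-shift code.
* **Energy toys** (`gen_region_system()`): two bead strands standing in for
  the S4–S5 linker and S6 (residues 247–260 and 323–358, R249 and K358
  carrying +1 e), geometrically spanning the plateau, the switching window
  and the beyond-cutoff regime of the potential.
* **Gating data** (`gen_gating_curve()`, `gen_fluorescence_trace()`):
  Boltzmann responses plus Gaussian noise clipped to [−0.2, 1.2], and
  drifting-baseline traces with a known pulse amplitude.
* **Synthetic alignment** (`gen_synthetic_alignment()`): the supplementary
  alignment behind the published Kv1.2/Kv7.1 identity figures is not
  deposited, so a stand-in alignment (labelled synthetic in name and
  output) is *constructed* to carry that identity structure — 36% over the
  pore domain, 25% over the voltage sensor excluding the S2–S3 loop, with
  the reference sequence gapped inside the loop, which is shorter and
  unrelated in Kv1.2. The percent-identity code is generic; the fixture
  realizes the documented identities by construction, and checks against
  it validate the implementation, not the published alignment.

What the toys do **not** emulate: physical bilayer dynamics, correlated
protein motions, force-field-accurate geometries or energies, multi-oxygen
coordination geometry, and the conformational coupling between binding and
gating. Passing tests therefore demonstrate that the estimators recover
known statistical and geometric ground truth under the stated noise models
— they do not validate any biological conclusion about real trajectories.

All generators are bit-reproducible for a fixed seed, restore the caller's
RNG state, and the pipeline writes ground truth as a machine-readable JSON
sidecar next to the data.

# Numerical and design choices

* **Residue numbering** is author numbering taken verbatim from the
  structure file; all ranges (247–260, 323–358) are closed intervals.
* **Percent identity** divides by the reference-sequence non-gap columns
  within the region (after exclusions). This reproduces a well-defined
  number from a manually corrected alignment where the reference carries
  the gaps; the symmetric alternative (columns where *neither* sequence is
  gapped) is one argument away (`denominator = "both"`) and is the
  convention under which identity is symmetric in the two sequences.
* **Boxes are orthorhombic only**; triclinic cells are out of scope, which
  keeps the minimum-image arithmetic exact and testable.
* **DCD** reading accepts big- and little-endian files with 32-bit record
  markers (via bio3d); the package's own DCD writer exists because no
  installed R package writes DCD, and is validated by round-trip through
  the independent reader. The plain-text `xyz_frames` format (atom count,
  `t= … box= …` header, one `name x y z` line per atom) is the
  human-readable interchange format; it round-trips to the written
  precision.
* **Tie-breaks and degenerate inputs** are errors, not silent choices:
  empty atom selections in distance kernels, boxes smaller than twice the
  cutoff, overlapping energy groups, unparameterized atoms (named in the
  message), zero-frame windows, all-equal gating responses, a baseline
  crossing zero, landmark centroids that coincide.
* **Problem sizes.** The shipped tests and the acceptance script run on
  4-subunit toys at 250–1000 frames (20 seeds for the recovery study),
  100-frame energy toys, and 200 synthetic gating curves — sizes chosen so
  the statistical bounds being checked (3 binomial SEs, RMSE limits) are
  meaningful while the whole suite stays interactive.

# Known limitations

* The energy decomposition is a pairwise switched-cutoff model; it cannot
  reproduce decompositions defined against Ewald electrostatics, and
  absolute values depend on the externally supplied charge/LJ parameter
  table.
* The two-state Boltzmann is the only gating model; channels with multiple
  voltage-sensor steps or non-equilibrium artefacts need a different
  module.
* Conductance normalization, leak subtraction and tail-current extraction
  are upstream of this package: G/V inputs must already be normalized.
* Binding-pose clustering and automatic state assignment (activated vs
  resting from S4 charge positions) are intentionally out of scope.
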