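---
title: "Transition-state-analogue-guided enzyme redesign: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transition-state-analogue-guided enzyme redesign: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsadesign)
```

## The idea

Improving an enzyme's Michaelis constant ($K_M$) for a new substrate is a
ground-state problem: it depends on how tightly the enzyme binds the
substrate in the Michaelis complex. Improving the turnover number
($k_{cat}$) or the catalytic efficiency ($k_{cat}/K_M$) is a
transition-state problem — and transition-state structures are almost never
available. The framework implemented here substitutes a **transition state
analogue** (TSA) — a stable compound whose geometry and charge distribution
mimic the transition state, such as 1,5-glucarolactone for a
glucuronidase — and postulates that mutations improving the enzyme's
interaction with the TSA improve it with the true transition state by the
same amount.

Everything downstream follows from two computable quantities per variant:

* $IE_S$ — the interaction energy of the enzyme with its substrate, and
* $IE_{TSA}$ — the interaction energy with the transition state analogue,

where the interaction energy of a complex is

$$IE = E(\text{complex}) - E(\text{enzyme}) - E(\text{ligand}),$$

with the complex minimized once and both subsystem energies evaluated at
the complex coordinates. The binding energy (`binding_energy()`) instead
minimizes all three systems independently; IE approximates BE whenever
binding involves no induced fit, and is less force-field-sensitive because
conformational relaxation of the separated parts never enters.

## The energy model

`total_energy()` evaluates a molecular-mechanics potential with nine
components, all in kJ/mol:

* **Bonded**: harmonic bond, angle, Urey–Bradley (1–3 distance) and
  improper terms in the $k(x - x_0)^2$ convention (the force constant
  absorbs the usual 1/2, as in CHARMM-style parameter files), and proper
  torsions $k_\phi(1 + \cos(n\phi - \delta))$.
* **Nonbonded**: Lennard-Jones in the $r_{min}$ convention with geometric
  mixing of well depths and additive $r_{min}/2$, plus Coulomb with
  $K_e = 1389.354$ kJ·Å/(mol·e²). Pairs separated by one or two bonds are
  excluded; 1–4 pairs interact at full strength; no distance cutoff is
  applied, so brute-force pair summation is exactly reproducible.
* **Implicit solvation**: a pairwise generalized-Born polar term in the
  Still functional form
  $f_{GB} = \sqrt{r^2 + a_i a_j \exp(-r^2/4a_ia_j)}$ with user-supplied
  Born radii (interior dielectric 1, exterior 80), including self-terms;
  and a nonpolar accessible-surface-area term
  $\sum_i \sigma_i \cdot SASA_i$ with Shrake–Rupley areas from a
  deterministic 256-point golden-spiral sphere and a 1.4 Å probe
  (default $\sigma$ = 0.0226 kJ/(mol·Å²)). Supplying Born radii as input
  keeps the polar term's role in the interaction energy while leaving the
  radius model (e.g. molecular-volume schemes) pluggable.
* **NOE restraints**: flat-bottom distance restraints
  ($k_{min}(d-d_{min})^2$ below the window, zero inside,
  $k_{max}(d-d_{max})^2$ above) that hold catalytic contacts in place
  during minimization. The softer lower wall reflects that catalytic
  contacts survive at shorter distances. The packaged restraint set for
  the glucuronidase active site (four contacts around the anomeric carbon,
  windows of 1.7–1.8 Å and 2.5–2.6 Å, constants 75/100 kJ/(mol·Å²)) ships
  in `extdata/catalytic_restraints.tsv`. Because the restraints couple
  enzyme and ligand atoms, their energy is charged to the complex
  evaluation only; they are undefined for the separated parts.

`minimize()` is steepest descent with a backtracking Armijo line search
(initial maximum atomic displacement 0.01 Å, halving, $c = 10^{-4}$;
default gradient tolerance 0.1 kJ/(mol·Å), 500 steps). The analytic
gradient covers every smooth term; the point-sampled surface area is
piecewise constant and carries no analytic gradient, so the line search
tests the *full* energy (including the surface term) before accepting any
step — the energy trace is therefore non-increasing by construction
regardless. "One minimization run before each IE evaluation" is the
reading adopted for the upstream protocol's single-minimization phrasing;
a single-iteration minimization is available as `max_steps = 1`.

## The redesign loop

`run_trajectory()` iterates on a pair of complexes (substrate and TSA)
sharing the enzyme:

1. **Propose**: with probability 0.5 mutate one random design position to
   a random permitted amino acid; otherwise perturb the backbone dihedrals
   in a window of the design positions ± 1 residue by uniform draws within
   ± 2° and reassign rotamers for the current sequence. The proposal
   distribution is a design choice of this package — the upstream
   description fixes the loop's stages (perturb, assign rotamers, relax)
   but not the move mix.
2. **Relax and evaluate**: both complexes are minimized and the two
   interaction energies computed. Sequence changes are applied identically
   to both complexes; backbone moves are drawn independently per complex.
3. **Screen**: candidates are feasible only if $IE_S < 0$ and
   $IE_{TSA} < 0$ (both ligands must actually bind), at most two glycines
   occur across the design positions (matching wild-type glycine usage and
   preventing the optimizer from hollowing out the active site), and every
   amino acid is in its position's permitted set.
4. **Accept**: greedy descent for the first 100 iterations, then
   Metropolis acceptance $\min(1, e^{-\Delta E / RT})$ at a constant
   7268 K. That temperature accepts an objective increase of 10 kcal/mol
   (41.9 kJ/mol) with probability ≈ 0.5, which keeps the search mobile
   across mutants within that band of the incumbent.

Default study conditions (`redesign_config()`): 5000 iterations per
trajectory, annealing from iteration 100, 25 trajectories for
interaction-energy estimation (the reported IE of a variant is the mean of
the per-trajectory bests, `aggregate_best_ie()`), 50 for library design
with one best mutant emitted per trajectory.

Rotamers are rigid bodies placed through the local backbone frame (origin
CA, x toward N, z normal to the N–CA–C plane): side chains carry no bonded
terms — their internal geometry is fixed by the library — and intra-residue
nonbonded pairs are excluded. `assign_rotamers()` enumerates exhaustively
up to 10,000 combinations (ties resolved to the first candidate in
position-ascending, alphabetical order) and falls back to greedy
position-by-position search in seeded random order above that.

The three redesign objectives map onto the correlating model below:
minimize $IE_S$ for $K_M$; minimize $IE_{TSA}$ for $k_{cat}/K_M$; minimize
$IE_{TSA}/(RT)_{TSA} - IE_S/(RT)_S$ for $k_{cat}$.

## The correlating model

Linking energies to kinetics uses transition-state theory (the
Eyring–Polanyi equation, `eyring_rate()`) and the invariance postulate —
that the free-energy offset between the bound transition state and the
bound analogue does not change under mutation. That postulate is embodied
in the sign conventions and delta-relations below; it is not itself a
computation. The resulting linear relations are:

$$\ln K_M = \frac{IE_S}{(RT)_S} + c_1, \qquad
\ln \frac{k_{cat}}{K_M} = -\frac{IE_{TSA}}{(RT)_{TSA}} + c_2, \qquad
\ln k_{cat} = -\frac{IE_{TSA}}{(RT)_{TSA}} + \frac{IE_S}{(RT)_S} + c_3.$$

`fit_ln_km()`, `fit_ln_efficiency()` and `fit_ln_kcat()` recover the
effective $(RT)$ constants by ordinary least squares on the natural-log
scale (the intercepts absorb unit choices; $K_M$ is standardized to mM).
The benchmark values for the glucuronidase system are
$(RT)_S = 386.7$ kJ/mol and $(RT)_{TSA} = 15.3$ kJ/mol. These are
*effective* temperatures obtained by correlation — they absorb the
non-quantitative scale of computed interaction energies and are not
physical temperatures. Note the self-consistent conversions are
$386.7/R = 4.65\times10^4$ K and $15.3/R = 1840$ K; the source text pairs
the two printed temperatures the other way around, which is inconsistent
with its own RT values, so this package implements only the
self-consistent conversion (`rt_to_temperature()`) and leaves the printed
pairing as an observed discrepancy rather than silently "correcting"
either number. Similarly, the printed weights 0.06 and 0.002 mol/kJ are
rounded reciprocals (1/15.3 = 0.0654, 1/386.7 = 0.0026) and are not used
as targets anywhere.

Mutant-versus-wild-type predictions (`predict_deltas()`) follow by
differencing, which eliminates the intercepts:
$\Delta\ln K_M = \Delta IE_S/(RT)_S$,
$\Delta\ln(k_{cat}/K_M) = -\Delta IE_{TSA}/(RT)_{TSA}$, and
$\Delta \ln k_{cat}$ is their sum by construction.

## Sequence constraints

Unconstrained optimization of packed active sites drifts toward glycine
(it evades steric clashes that no rotamer of a larger residue can).  Two
counters are implemented:

* **Permitted sets** (`permitted_amino_acids()`): an amino acid is allowed
  at a design position if it is observed **at least once** in an alignment
  of close homologs or in **at least 5%** of the ungapped rows of a
  superfamily alignment, both thresholds inclusive. Gaps are excluded
  from counts and denominators; ambiguity codes are ignored (and counted)
  rather than fractionally distributed, since no fractional scheme is
  canonical. The 5% denominator is the per-column ungapped row count — the
  "excluding gaps" phrasing supports this reading, though the source is
  not fully explicit; the choice is exposed through `ColumnProfile`
  anyway. The column-to-position mapping is explicit user input: the
  original alignments are not recoverable, so no hidden mapping is baked
  in. The derived sets for the nine glucuronidase design positions ship as
  `extdata/permitted_sets.txt`.
* **Glycine cap** (`glycine_count()`): at most two glycines across the
  design positions, matching wild-type usage.

## Library analysis

`frequency_table()` computes per-position amino-acid fractions over a
library's mutants (pooling concatenates mutant lists; the wild type is
never counted). Two published rules are implemented:

* **Representative mutations**: present in ≥ 15% of the target library's
  mutants *and* ≥ 10 percentage points more frequent than in the
  comparison libraries. "More frequently than in the other libraries" is
  read as the *maximum* over the others (the strictest interpretation); a
  `compare = "mean"` flag implements the alternative. Comparisons are
  inclusive, with a 10⁻⁹ guard so that fractions like 3/20 compare as
  intended against binary-rounded thresholds. Wild-type residues are
  excluded — a representative *mutation* must differ from wild type.
* **Group enrichment** (`enriched_in_group_absent_in_group()`): present at
  ≥ `present_threshold` in every library of one group and ≤
  `absent_threshold` in every library of another. The source gives no
  numeric values for "enriched" and "largely absent", so the defaults
  (0.10 / 0.05) are exposed parameters, not published constants.

The two published top-10 mutant tables (three libraries each for the
glucuronide and galactoside substrates, with wild-type rows) ship as TSV
fixtures and load through `published_libraries()`; on them, pooled serine
at position 162 is 4/30 ≈ 13.3% for the glucuronide libraries and
11/30 ≈ 36.7% for the galactoside libraries, and no mutant exceeds the
glycine cap.

## Synthetic data: what it emulates and what it does not

Two generators make the whole toolkit testable offline:

* `generate_toy_complex()` builds a polyglycine backbone from ideal
  internal coordinates with a small chain ligand, bonded constants set to
  the built geometry, and a TSA complex whose ligand is a flattened
  (z-scaled), re-charged copy of the substrate ligand — the toy analogue of
  a lactone's planarized ring and shifted charge at the anomeric carbon.
  Charge patterns are complementary (attractive, the default study
  condition for redesign tests), neutral and repulsive. The neutral
  pattern places the ligand 10 Å out so the surface areas of the parts
  stay additive and a zero interaction energy is exact. Coordinates carry
  a ± 0.02 Å seeded jitter so no two seeds are degenerate.
* `generate_synthetic_kinetics()` draws interaction energies uniformly on
  [−1600, −100] kJ/mol — the span of the published library energies — and
  builds $K_M$, $k_{cat}/K_M$ and $k_{cat}$ *exactly* from the correlating
  equations with configurable intercepts ($c_1 = 2.5$ on ln mM,
  $c_2 = -3$; arbitrary, since only slopes matter) and optional Gaussian
  noise on the ln scale.

What passing tests on these fixtures shows: the energy function, search
machinery, constraint logic and regression framework are internally
correct and mutually consistent (oracle equivalence against brute-force
enumeration, generator recovery of the RT constants to $10^{-6}$ relative
error without noise and within 15% in the median at ln-scale noise 0.2).
What it does not show: that the toy force field's absolute energies
resemble a real enzyme's (they are orders of magnitude smaller and the
published headline correlations, $R^2$ = 0.960/0.864/0.854, depend on
full-scale CHARMM/molecular-volume energies that are not tabulated and are
out of reach at desk scale), nor that a 16-atom polyglycine models real
active-site packing. Problem sizes used by the test suite — 2 design
positions on a 4-residue/4-atom toy pair, 60 iterations per trajectory, 20
seeded trajectories against a 9-sequence exhaustive enumeration — were
chosen as the smallest spaces on which convergence of the sampler is a
meaningful claim.

## Numerical choices and degenerate inputs

* All energies kJ/mol, distances Å, charges e;
  R = 8.3145×10⁻³ kJ/(mol·K); kcal inputs convert at 4.184 at the I/O
  layer.
* Seeding: all generators and trajectories are pure functions of their
  integer seed via R's default Mersenne–Twister; trajectory $i$ of a
  redesign uses seed + $i$.
* The minimizer treats a failed line search (no decreasing step above
  10⁻¹² Å) as convergence at a non-smooth point; non-finite energies
  abort with an error.
* Flat-bottom restraints are continuous (zero) at both walls; improper
  deviations are wrapped to (−π, π] before squaring.
* Zero-variance predictors abort a fit; a zero-variance response yields
  $R^2 = 0$ with a warning; collinear predictors abort the two-predictor
  fit.
* Rotation invariance of the point-sampled surface area holds to sampling
  resolution (the 256-point sphere is fixed in the laboratory frame), not
  to machine precision; translation invariance is exact. All other terms
  are rotation- and translation-invariant to machine precision.
* Exhaustive rotamer enumeration breaks ties toward the first candidate
  in deterministic order, so results are reproducible across platforms.

## Known limitations

* The generalized-Born term uses fixed input Born radii; no
  self-consistent radius model is computed.
* Side chains are rigid rotamers without bonded terms; strain within a
  side chain cannot be represented.
* Backbone perturbation is a plain dihedral rotation without closure, so
  a perturbation propagates downstream rather than staying local.
* No cutoffs or neighbor lists: quadratic cost in atom count, intended
  for desk-scale systems (≲ 10³ atoms).
* The correlating model is linear on the ln scale by derivation; it
  cannot represent saturation or mutations that change the mechanism.
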