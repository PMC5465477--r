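---
title: "Methods: trajectory analysis of anesthetic-channel interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis of anesthetic-channel interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(channelprobe)
```

## Scope and model system

`channelprobe` analyses molecular-dynamics trajectories of a pentameric
ligand-gated ion channel (pLGIC) interacting with a volatile anesthetic such
as desflurane. The channel is a C5-symmetric homopentamer whose pore-lining
M2 helices carry, in prime notation, the -2' selectivity-filter glutamate
(Glu-222), and the 9' (Ile-233) and 16' (Ile-240) isoleucines that bound the
hydrophobic gate; dewetting of the 9'-16' stretch blocks ion conduction.
Two transmembrane anesthetic sites are tracked: the intrasubunit lumen site
seen crystallographically (TM1, thirteen lining residues), and a second
membrane-facing pocket held together by the Tyr-254 hydroxyl and Asn-307
(TM2).

The package implements the measurements used to characterize this system:
ligand-residue contact probabilities, binding/unbinding events with
residence times and bound-ligand fluctuations, pore radius profiles along
the channel axis, gate hydration, M2 tilt angles, backbone RMSD against
reference structures, ligand phase partitioning, and reconstruction of a
one-dimensional potential of mean force (PMF) for ion translocation from
umbrella-sampling windows. Running the MD itself, building the simulation
system, and force-field parameterization are out of scope: inputs are
structures (PDB), trajectories (multi-MODEL PDB, XYZ series, or DCD), and
plain-text umbrella window files.

## Conventions

* Lengths in angstrom, times in ps (residence times reported in ns),
  energies in kcal/mol, temperatures in K; `kB = 0.0019872` kcal/mol/K.
* The pore axis is approximately +z with the extracellular side at high z.
  Analyses that depend on the axis re-fit it per frame from the M2 ring
  centroids (a fixed laboratory-z fallback is available).
* Distances use the minimum-image convention under the orthorhombic box.
  Whether published contact criteria used minimum-image distances is rarely
  stated; it is the safer default for membrane systems that wrap in xy, and
  a `periodic` flag disables it.
* Contact criteria use heavy atoms only by default (an
  `include_hydrogens` flag exists); synthetic fixtures are hydrogen-free, so
  the choice is inert in tests but matters on real trajectories.

## The binding criterion and event detection

A ligand is *in contact* with a residue when any ligand heavy atom lies
within 3.5 angstrom (boundary inclusive — a convention that must be fixed
for reproducibility) of any heavy atom of the residue. Contact
probabilities are the percentage of sampled frames (default every 1 ns) in
contact, tabulated per subunit; the cross-subunit aggregate is the
arithmetic mean and the sample (n-1) standard deviation, the convention
that reproduces 11 of the 13 published mean/SD pairs exactly from the
printed per-subunit integers (the remaining two differ by one unit in the
final printed digit, consistent with the source having computed SDs from
unrounded percentages).

Binding events use a hysteresis state machine per ligand: the bound state
begins at the first frame with minimum distance to a site's atoms at or
below the 3.5 angstrom enter cutoff, and ends only when the ligand moves
more than 5 angstrom from the *whole protein*. The enter/exit asymmetry
suppresses boundary flicker; events shorter than `min_duration_frames`
(default 2) are discarded. A ligand contacting two subunits at entry is
assigned to the subunit of minimum distance, ties going to the first
alphabetically and logged in the result's `ties` attribute. Because
per-replicate event counts differ, residence statistics over replicates are
reported both event-weighted and replicate-weighted (`event_report()`);
the two conventions are not distinguishable from published rounded values.

Bound-ligand RMSF is computed in the laboratory frame (no superposition)
against the time-averaged ligand coordinates, sampled every 0.2 ns by
default: a point ligand alternating between two positions d apart gives
d/2, and an isotropic Gaussian wobble of sigma per coordinate gives
sigma * sqrt(3) — both closed forms are test oracles.

## Pore geometry and hydration

The pore-radius profiler is a functional analogue of HOLE-style profilers,
not a bit-exact clone: at each axial position the radius is
`min_i (|c - x_i| - r_vdw,i)` over protein atoms, clamped at zero, with the
probe center `c` either fixed on the axis or optimized in the perpendicular
plane by a deterministic coarse grid (0.5 angstrom) plus Nelder-Mead
refinement within 5 angstrom of the axis (the searched radius therefore
never falls below the on-axis one). Van der Waals radii come from a fixed
element table (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80 angstrom),
overridable per topology.

Gate hydration counts water oxygens (one counting atom per molecule avoids
multiple counting) inside a cylinder of radius 4 angstrom about the pore
axis, spanning the axial band between the mean z of the five 9' C-beta
atoms and the mean z of the five 16' C-beta atoms. The band uses ring means
rather than per-subunit pairs for C5 robustness, and both the axis and the
band are re-read each frame (a fixed-axis flag exists). A frame with strictly
fewer than 5 gate waters is classified dehydrated; exactly 5 is hydrated.

## Helix tilt and structure comparison

M2 tilt uses three four-residue turns (defaults: intracellular 222-225,
middle 230-233, extracellular 237-240 — the published analysis does not
name its exact residues, so these defaults are an explicit, configurable
assumption spanning the -2'..16' stretch). The mass-weighted center of mass
of the backbone (N, CA, C, O) of each turn defines two vectors
(intracellular to middle, middle to extracellular); each is measured
against the membrane normal (default z). Superposition is the standard
Kabsch SVD solution restricted to proper rotations; RMSD reports superpose
each named residue range independently (whole protein, ECD 14-192, TMD
195-315, pore 221-244) over the trajectory tail and report mean and sample
SD.

## Phase partitioning

Each ligand is classified per frame with the precedence protein >
membrane > aqueous: protein when any ligand heavy atom is within 3.5
angstrom of the protein (reusing the contact criterion), else membrane when
the ligand center of mass lies between the per-frame mean phosphate z of
the two leaflets, else aqueous. The published figures do not state their
classification rule; this one is recorded in every output header. Aqueous
molarity is `n / (N_A V)`; the aqueous volume is user-supplied or estimated
as box volume minus the membrane slab minus protein volume outside the
slab — an explicitly rough estimator, bounded by construction to
[0, box volume].

## Umbrella sampling and WHAM

Umbrella windows are harmonic, `w(z) = k/2 (z - z0)^2` with k = 7.17
kcal/mol/A^2 by default; because MD engines disagree on whether the printed
constant multiplies the half square or the full square, a `full_k`
convention flag exists. Window layouts step inclusively from a start toward
an end (50 windows for a 1-angstrom spacing over a 49-angstrom span), and a
10 ns window recorded every 0.2 ps carries 50,000 frames, 47,500 after
discarding the first 5% as equilibration (`retained_fraction = 0.95`, the
package default mirroring a 10 ns window analysed over its last 9.5 ns).

`wham_solve()` iterates the standard self-consistent equations on a
fixed-width histogram (default bin 0.1 angstrom, tolerance 1e-6 kcal/mol on
the window constants, at most 1e5 iterations — all package choices):
unbiased bin probabilities from bias-weighted counts, window free-energy
constants from the unbiased distribution. Each window's bias is shifted by
its minimum over occupied bins before exponentiation — a pure gauge change
absorbed by the window constants that prevents exp underflow when a strong
external potential displaces samples far from the window centers. Adjacent
windows must share at least one occupied bin (a gap is an error naming the
pair), non-convergence is an error carrying the residual, and the PMF
`-kB T ln P(z)` is pinned to zero exactly at the occupied bin nearest the
requested reference z (the profile minimum when none is given).

The validation route replaces unavailable MD windows with Metropolis
samples from analytic potentials (flat, harmonic, double-well), for which
the biased stationary distribution is known in closed form: a flat
potential gives an exact Gaussian of variance `kB T / k` (0.0826 A^2 at
298 K, k = 7.17). The default sampler proposes from a Gaussian fitted at
the mode and local curvature of the biased energy (independence
Metropolis-Hastings), giving essentially uncorrelated draws for the
near-Gaussian window distributions of umbrella sampling; a plain
random-walk chain is available for comparison. Published PMF magnitudes
for the real channel (the ~15 kcal/mol closed-state barrier) require the
original umbrella trajectories and are deliberately not reproduced; the
recovery suite instead checks flat/harmonic landscapes to 0.1 kcal/mol RMSD
over the central 80% of the range and a constructed 3 kcal/mol double-well
barrier to 0.15 kcal/mol, at the published window layout (50 windows, 1
angstrom spacing, k = 7.17, 10^4 samples per window).

## The synthetic toy channel

`build_toy_channel()` constructs the ground-truth fixture all analyses are
tested against: a C_n-symmetric (default pentamer) arrangement of
subunits, each carrying a 24-residue pseudo-M2 (residues 221-244, four
backbone atoms per residue) whose atoms form a cylinder of the requested
ring radius about z, C-beta markers at the 9' and 16' z positions, the
twelve lumen residues of the TM1 site (V242 lives on the M2 ring) with a
hydroxyl oxygen on Tyr-254 and an amide nitrogen on Asn-307, phosphate
markers at plus/minus the membrane half-width (default 18.655 angstrom,
i.e. the 37.31 angstrom converged width used as a fixture target), waters
on an exclusion-respecting lattice inside the gate cylinder, and
single-particle ligands in the aqueous phase.

Two deliberate idealizations matter for interpreting green tests:

* The pseudo-M2 is a straight vertical column, not a twisted helix. This
  keeps the four-residue-turn centers of mass collinear — the tilt oracle
  reads exactly 0 degrees untilted and exactly the programmed angle after a
  scripted rigid tilt — and keeps the pore wall an analytic cylinder
  (profile = ring radius - vdW radius). In a real alpha helix the ~100
  degrees-per-residue twist is what re-centers four-residue-turn COMs on
  the helix axis; a partially twisted toy would break both oracles without
  adding realism.
* All pseudo-atoms share the carbon-like 1.7 angstrom vdW radius, recorded
  in the topology, so pore-radius truth is independent of force-field
  radius tables.

`script_trajectory()` then realizes ground truth exactly: ligands sit at a
site anchor (a point 2.5 angstrom radially inward of a marker atom, hence
unambiguously within the 3.5 angstrom contact cutoff) during scripted
bound intervals and at their phase anchor otherwise, with optional
isotropic Gaussian noise; M2 helices are rigidly rotated toward the pore
axis to the programmed tilt; gate waters are moved between the gate lattice
and an aqueous parking region to match the hydration program. Seeded runs
are bit-reproducible. What passing tests therefore demonstrate is that the
*measurement* operations are correct; they say nothing about force fields,
sampling adequacy, or the biology of the real channel.

## Problem sizes and numerical choices

The test and validation suites run at sizes chosen to keep the full check
under a few minutes on one core while leaving comfortable statistical
margins: toy systems of ~650 atoms, scripted trajectories of 100-500
frames, 10^4 samples per umbrella window (10^5 where a closed-form variance
is checked at 5% tolerance), 100 random hydration fixtures. Degenerate
inputs are errors, not warnings: empty atom selections, non-monotone frame
times, collinear superposition selections, one-leaflet membranes, gapped
umbrella windows, tilt programs beyond the toy's 60-degree geometric limit.

## Known limitations

* The pore profiler is a geometric analogue of HOLE, not a re-implementation
  of its Monte Carlo search; absolute radii can differ near highly
  non-circular cross sections.
* Subunit assignment of an event is by minimum distance at entry only; a
  ligand that migrates between subunits while continuously bound remains
  assigned to its entry subunit.
* The aqueous-volume estimator ignores protein volume inside the membrane
  slab and solvent excluded volume; treat derived molarities as
  order-of-magnitude.
* One-dimensional WHAM only; no MBAR, no multidimensional reaction
  coordinates.
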