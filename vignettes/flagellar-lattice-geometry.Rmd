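---
title: "Helical lattice geometry of flagellar filaments: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helical lattice geometry of flagellar filaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flagsym)
```

# The lattice model

Everything in this package derives from a single screw operation: subunit
i of a helical polymer sits at rotation `i·Ω` about z and translation
`i·h` along z, with rise `h > 0` in Ångström and twist `Ω` in degrees.
We adopt the convention that **positive twist is a right-handed screw
advancing along +z**, and wrap every angle into `(−180°, 180°]` so that a
wrapped value of exactly +180° has a deterministic sign.

The n-start family (every n-th subunit) then has step rise `n·h` and step
twist `wrap(n·Ω)`; its handedness is the sign of the step twist, with
`|step twist| < 10⁻⁹°` classified *axial*. For an 11-protofilament
filament the published "tilted left by ~1.7° / right by ~3.9°" figures are
exactly the wrapped 11-step twists of the tabulated (4.72 Å, 65.30°) and
(4.65 Å, 65.81°) symmetries; we deliberately interpret the tilt as this
lattice angle rather than as a geometric line slope on the unrolled net,
because the latter depends on the display radius and does not reproduce
the printed values.

`protofilament_count()` searches n ∈ [2, n_max] for the minimal
`|wrap(n·Ω)|`, breaking ties toward smaller n. n = 1 is excluded: it is
the lattice generator, not a protofilament family. The principal layer
line of family n is `Z = wrap(n·Ω)/(360·h)` (Å⁻¹, so `|Z| ≤ 1/(2h)`),
with Bessel order ±n signed like the step twist. We predict positions and
orders only — no Bessel amplitudes — which is all that comparing power
spectra of filament images requires. The test suite validates the closed
form against a brute-force structure-factor peak search on a 2000-point
ideal helix for all nine tabulated symmetries.

## Floating-point wrap invariance

Results should be unchanged when `Ω` is replaced by `Ω ± 360`. In double
precision the shift itself rounds (`65.30 − 360 + 360 ≠ 65.30` bitwise),
so bit-identity is unattainable in general; the package guarantees wrap
invariance to ~1 ulp of 360 and the tests assert it at 10⁻¹² relative
tolerance.

# Seam lattices

Outer-domain dimerization pairs subunit S_N (donor) with S_N+11
(acceptor). With 11 protofilaments this makes the repeating unit 22
subunits: the filament is an ideal helix whose asymmetric unit contains
k = 22 subunits, related to its neighbors by super-rise `22·h` and
super-twist `wrap(22·Ω)`. For the tabulated (4.61 Å, 65.75°) symmetry the
super-rise is 101.4 Å; with the refined super-twist of 6.41° the
asymmetric-unit 1-start makes 360/6.41 = 56.16 units per turn with a
~5700 Å pitch. Because a twist printed to two decimals cannot reproduce a
refined super-twist (22 × 65.75 wraps to 6.50°, not 6.41°),
`seam_supersymmetry()` accepts an explicit `super_twist` for the refined
value; rise-derived quantities are unaffected.

**Where is the seam?** Walk one turn of the lattice in azimuthal order —
one subunit per protofilament — and close the circuit with the subunit 11
indices above the start, which returns to the starting azimuth. The
closing step advances the 1-start index by 11, i.e. half the asymmetric
unit, so the donor/acceptor phase flips: exactly one azimuthal boundary
per turn must join mismatched roles. That boundary is the seam.
`locate_seam()` verifies the one-mismatch-per-turn property for every
complete turn and reports the flanking protofilament classes of the basal
turn (for the canonical 22/11 lattice with the documented "index 0 is a
donor" origin: classes 5 and 0). The classes are reported *at the base*
because protofilament strands wind slowly about the axis (by the 11-step
residual per turn), carrying the seam's azimuthal position with them; in
long filaments the flanking pair migrates even though the seam line is
continuous. Index shifts by whole asymmetric units leave the result
unchanged.

The spec of the pairing direction is genuinely ambiguous in the field's
descriptions (pairing "across the 5-start helices" versus the explicit
S_N/S_N+11 statement); we default `pair_offset = 11` per the explicit
statement and leave the offset configurable.

# Filament building and comparison

`apply_symmetry()` places exact copies of a protomer; the filament axis
is assumed to be z through the origin, which is true of helically refined
depositions — no axis fitting is attempted (documented limitation). Chains
are named A–Z, a–z, 0–9, then two-character identifiers that only mmCIF
can carry; PDB output stops at 62 chains. I/O is restricted to coordinate
records, read and written at the formats' precision.

Comparisons use Kabsch superposition (SVD with determinant correction, so
reflections are rejected) on Cα atoms. Conventions that matter:

* **Domain annotations** follow the two-domain flagellin architecture;
  only the NL (31–47) and CL (264–267) linkers are firmly established for
  real flagellin, so `flagellin_domains()` marks the remaining boundaries
  as configurable inference. The synthetic protomer carries its own exact
  annotations.
* **Packing RMSD** concatenates the five-subunit unique-contact complex
  (S0, S+5, S+6, S+11, S+16 — every interface of the lattice once) and
  superposes globally. This is the statistic that separates filament
  hands: with the default generators, within-hand means are ~0.05 Å and
  between-hand means ~2.4 Å, inside the observed 1.5–3.3 Å between-hand
  range.
* **Clustering** is single linkage at a default 1.5 Å cut — the claim
  being tested is a two-block distance pattern, not a dendrogram
  topology.
* **Buried area** is ΔSASA/2 with a 1.4 Å probe (the PISA-style
  convention behind published ~1900/600/270 Å² interface figures), using
  deterministic golden-spiral Shrake–Rupley quadrature (default 240
  points per atom for interfaces; an isolated sphere is exact by
  construction, and two-sphere burial matches the analytic spherical-cap
  area within 2%). Contact listing uses a 4.0 Å heavy-atom cutoff meant
  for all-atom models; Cα-only models need a wider cutoff, as their
  nearest interface atoms can sit beyond 4 Å without side chains.
* **Cross-species comparison** takes a user-supplied two-column residue
  map from any alignment tool; the same-species default is the identity
  on shared modeled residues. No aligner is built in.

A note on an expectation that did *not* survive implementation: for a
single subunit, a 6° rigid D1 rotation yields a combined-D0+D1 RMSD of
only ~0.45 Å with the prescribed mock geometry (a global superposition
absorbs much of a rotation confined to one narrow azimuthal wedge),
not the >1 Å one might guess from the between-hand range. The
hand-discriminating signal genuinely lives in multi-subunit packing, which
is why the five-subunit statistic exists; the tests assert the
combined-versus-individual contrast (two orders of magnitude) rather than
an absolute single-subunit value.

# Supercoil waveforms

The supercoil centerline is a circular helix with radius `r = D/2` and
reduced rise `h = P/(2π)`; curvature and twist are `κ = r/(r²+h²)` and
`τ = h/(r²+h²)`, satisfying `κ² + τ² = 1/(r²+h²)`. Units are µm and µm⁻¹
(the fluorescence-microscopy scale); Å is used everywhere else. Pitch is
measured along the supercoil axis, the standard reading for these
formulas. Handedness is not observable in a single 2D projection, so τ is
reported positive by default and the sign must come from user metadata.

`measure_pitch_diameter()` fits `x(s) = (D/2)·sin(2πs/P + φ₀) + x₀`. The
period enters nonlinearly and the objective has many local minima, so the
fit profiles the linear parameters over a 200-point log-spaced period grid
(from ~4 sampling steps to twice the span) and polishes the best candidate
with a bounded 1D optimizer. Two guarded failure modes: a fitted amplitude
below `noise_floor` (default 0.05 µm) flags the pitch indeterminate
(straight filament), and a fitted period exceeding the trace span raises
an insufficient-span error. Aggregation converts each trace's (P, D) to
(κ, τ) *before* averaging, mirroring per-filament measurement practice.

# The synthetic generators: what they do and do not establish

`make_protomer()` builds a Cα-only, 174-residue mock flagellin: two
antiparallel ideal α-helices (1.5 Å rise/residue, 2.3 Å helix radius,
100°/residue) near the axis as D0, three helices at the outer radius as
D1, joined by linkers, spanning the filament's ~12.5–62.5 Å radial range.
Defaults encode the stated world: inner/outer diameters ~25/~125 Å, a
default two-state D1 rotation of 6° (midpoint of the observed 2–10°
range, with per-atom displacement growing linearly with axial distance —
so the observed 1.5–11 Å displacement range emerges from the rotation
alone, and the default rigid shift is 0), waveform defaults P = 2.2 µm,
D = 0.6 µm, σ = 0.02 µm, ten traces — a realistic normal-waveform scale
for fluorescence imaging, chosen once. Generators are pure functions of
their spec (seed included) and restore the global RNG stream.

What a green synthetic test establishes: the *operations* are correct —
symmetry application is exact, implanted rotations are recovered within
0.5°, packing RMSD separates constructed states, fitted waveforms recover
their generating parameters. What it does not establish: agreement with
experimental structures. The mock protomer has no side chains, no
sequence, idealized secondary structure and a schematic topology; absolute
interface areas and contact maps are not comparable to all-atom values,
and cross-species correspondence handling is exercised only with identity
maps. Benchmarks that require the deposited atomic models (cross-species
packing RMSD ≈ 0.8 Å, S+6 interface ≈ 600 Å², the 6.5/7.3 Å designed
disulfide Cα distances) are supported by the same operations but need the
models supplied by the user.

# Degenerate inputs and tie-breaks

* `normalize_twist(±180) = +180` (half-open interval).
* Axial families report infinite strand pitch and a layer line at the
  equator.
* `protofilament_count` ties break toward smaller n (e.g. twist 90° gives
  4, not 8).
* Seam nets require `count` to be a multiple of `unit_size` and
  `pair_offset < unit_size`; a `unit_size = 2, pair_offset = 1` net is
  the smallest valid seam lattice.
* Kabsch requires ≥3 non-collinear atoms; collinear selections error
  rather than returning an under-determined rotation.
* Interface area is clamped at 0 (quadrature noise can make ΔSASA
  slightly negative for separated subunits).
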