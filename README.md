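# flagsym

Helical lattice geometry and structural comparison of bacterial flagellar
filaments.

## The problem

A flagellar filament is a tube of ~11 protofilaments built from tens of
thousands of copies of one protein, flagellin. Each subunit can sit in one
of two conformations (the L- and R-states); mixtures of all-L and all-R
protofilaments supercoil the filament into the waveforms that propel the
cell, while homogeneous filaments are straight. Understanding switching
requires a chain of geometric analyses that this package implements for
structural biologists working on flagella or any helical polymer:

1. **Lattice arithmetic.** A helical filament is generated by a single
   (rise `h`, twist `Ω`) screw. Connecting every n-th subunit yields the
   *n-start* families; family n has step twist `wrap(n·Ω) ∈ (−180°, 180°]`
   whose sign is its handedness, and a principal layer line at axial
   frequency `Z = wrap(n·Ω)/(360·h)` with Bessel order ±n. The near-axial
   family (minimal |step twist|) is the protofilament count.
2. **Seam lattices.** Outer-domain dimerization (subunit S_N pairing with
   S_N+11) makes the lattice non-helical at the single-subunit level while
   leaving it an ideal helix with a 22-subunit asymmetric unit; the pairing
   phase cannot close around the circumference, so exactly one boundary
   between adjacent protofilaments is out of phase — the seam, as in
   microtubules.
3. **Model building and comparison.** Filaments are built by applying the
   screw to a protomer; L/R differences are quantified by Kabsch
   superposition: per-domain RMSD, the rigid rotation of the outer (D1)
   domain after aligning the inner (D0) domain, the five-subunit
   (S0, S+5, S+6, S+11, S+16) packing RMSD that clusters filaments by
   hand, buried interface areas (Shrake–Rupley SASA, ΔSASA/2), and
   residue-pair distances for mutant design.
4. **Supercoil waveforms.** A supercoil of pitch P and diameter D is a
   circular helix with curvature `κ = r/(r²+h²)` and twist
   `τ = h/(r²+h²)`, where `r = D/2`, `h = P/(2π)`; the package converts
   both ways and fits (P, D) to digitized centerline traces.

Seeded synthetic generators (an idealized two-domain flagellin-like
protomer, paired L/R-like variants differing by a 2–10° rigid D1 rotation,
noisy filaments, waveform traces) provide ground truth for every analysis.

## Worked example

```r
library(flagsym)

sym <- helical_symmetry(4.72, 65.30)      # L-type straight filament
enumerate_families(sym, 11)[c(1, 5, 6, 11), ]
#>     n step_rise step_twist handedness strand_pitch layer_line_height bessel_order
#> 1   1      4.72       65.3      right     26.02144       0.038429849            1
#> 5   5     23.60      -33.5       left    253.61194      -0.019715160           -5
#> 6   6     28.32       31.8      right    320.60377       0.018714689            6
#> 11 11     51.92       -1.7       left  10994.82353      -0.001000471          -11
protofilament_count(sym)
#> [1] 11
```

Read: the 1-start is right-handed with a 26 Å pitch, the 5-start left, the
6-start right, and the 11 protofilaments tilt left by 1.7° — the L-type
signature (the R-type symmetry 4.65/65.81 tilts right by 3.9°).

```r
seam_supersymmetry(helical_symmetry(4.61, 65.75), 22, super_twist = 6.41)
#> Seam supersymmetry: 22-subunit asymmetric unit, super-rise 101.4 A, super-twist 6.41 deg
#>   1-start of asymmetric units: 56.16 units/turn, pitch 5696 A

curvature_twist(2.2, 0.6)                 # supercoil with P = 2.2 um, D = 0.6 um
#>     kappa      tau
#> 1 1.41111 1.646957
```

Synthetic two-state comparison:

```r
ts  <- make_two_state_protomers(protomer_spec(seed = 1), d1_rotation = 6)
domain_rotation(ts$reference, ts$rotated)$angle   # recovers 6 (degrees)
fil <- apply_symmetry(ts$reference, sym, indices = unique_contact_indices())
interface_area(fil, 5)                            # S0:S+5 buried area report
```

A command-line interface wrapping these operations is installed at
`system.file("cli", "flagsym.R", package = "flagsym")`.

## Documentation

`vignettes/flagellar-lattice-geometry.Rmd` describes the models,
conventions (sign of twist, outside-view nets, seam location), numerical
choices and the limits of what the synthetic generators establish.
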