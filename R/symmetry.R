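#' Normalize an angle to the half-open interval (-180, 180]
#'
#' Helical twists are only defined modulo 360 degrees; all lattice
#' arithmetic in this package wraps angles into `(-180, 180]` so that a
#' wrapped angle of exactly +180 has a deterministic sign.
#'
#' @param angle Numeric vector of angles in degrees. Must be finite.
#' @return Numeric vector of the same length, each element congruent to the
#'   input modulo 360 and lying in `(-180, 180]`.
#' @examples
#' normalize_twist(65.30)
#' normalize_twist(718.30)   # -1.70
#' normalize_twist(c(180, -180))  # both 180
#' @export
normalize_twist <- function(angle) {
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    stop("'angle' must be finite numeric (degrees)", call. = FALSE)
  }
  out <- angle - 360 * floor(angle / 360)   # [0, 360)
  ifelse(out > 180, out - 360, ifelse(out == -180, 180, out))
}

#' One-start helical symmetry
#'
#' The generator of a helical lattice: the axial rise (Angstrom) and
#' rotation (degrees) relating consecutive subunits along the 1-start
#' helix.  Positive twist denotes a right-handed screw advancing along +z.
#' The twist is stored wrapped to `(-180, 180]`, so constructing with
#' `twist + 360` yields an identical object.
#'
#' @param rise Axial translation per subunit in Angstrom; must be > 0.
#' @param twist Rotation per subunit in degrees (any finite value; wrapped).
#' @return An object of class `helical_symmetry` with fields `rise` and
#'   `twist`.
#' @examples
#' helical_symmetry(4.72, 65.30)
#' identical(helical_symmetry(4.72, 65.30), helical_symmetry(4.72, 425.30))
#' @export
helical_symmetry <- function(rise, twist) {
  if (!is.numeric(rise) || length(rise) != 1L || !is.finite(rise) || rise <= 0) {
    stop("'rise' must be a single positive finite number (Angstrom)", call. = FALSE)
  }
  if (!is.numeric(twist) || length(twist) != 1L) {
    stop("'twist' must be a single number (degrees)", call. = FALSE)
  }
  structure(list(rise = as.numeric(rise), twist = normalize_twist(twist)),
            class = "helical_symmetry")
}

#' @export
print.helical_symmetry <- function(x, ...) {
  cat(sprintf("Helical symmetry: rise %.4g A, twist %.4g deg (%s-handed 1-start)\n",
              x$rise, x$twist,
              if (x$twist > 0) "right" else if (x$twist < 0) "left" else "axial"))
  invisible(x)
}

# classify a wrapped step twist; |t| below tol counts as axial
.handedness <- function(step_twist, tol = 1e-9) {
  if (abs(step_twist) < tol) "axial" else if (step_twist > 0) "right" else "left"
}

#' n-start helical family
#'
#' Connecting every n-th subunit along the 1-start helix yields a family of
#' n parallel strands (an "n-start helix").  Its geometry follows from the
#' base symmetry: step rise `n * rise`, wrapped step twist
#' `normalize_twist(n * twist)`, handedness from the sign of the step
#' twist, strand pitch `360 / |step_twist| * step_rise` (infinite for an
#' exactly axial family), and the principal layer-line height
#' `step_twist / (360 * rise)` in reciprocal Angstrom, whose Bessel order
#' is `n` signed like the step twist.
#'
#' @param sym A [helical_symmetry()].
#' @param n Positive integer family order.
#' @return An object of class `start_family`: a list with fields `n`,
#'   `step_rise`, `step_twist`, `handedness` (`"left"`, `"right"` or
#'   `"axial"`), `strand_pitch`, `layer_line_height`, `bessel_order`.
#' @examples
#' sym <- helical_symmetry(4.72, 65.30)
#' start_family(sym, 11)   # step twist -1.70 deg: left-handed protofilaments
#' @export
start_family <- function(sym, n) {
  stopifnot(inherits(sym, "helical_symmetry"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("'n' must be a positive integer family order", call. = FALSE)
  }
  n <- as.integer(n)
  step_twist <- normalize_twist(n * sym$twist)
  hand <- .handedness(step_twist)
  structure(list(
    n = n,
    step_rise = n * sym$rise,
    step_twist = step_twist,
    handedness = hand,
    strand_pitch = if (hand == "axial") Inf else 360 / abs(step_twist) * (n * sym$rise),
    layer_line_height = step_twist / (360 * sym$rise),
    bessel_order = if (hand == "axial") n else as.integer(sign(step_twist)) * n
  ), class = "start_family")
}

#' @export
print.start_family <- function(x, ...) {
  cat(sprintf("%d-start family: step %.4g A / %.4g deg, %s-handed, pitch %.5g A, layer line %.4g 1/A (Bessel %+d)\n",
              x$n, x$step_rise, x$step_twist, x$handedness, x$strand_pitch,
              x$layer_line_height, x$bessel_order))
  invisible(x)
}

#' Enumerate n-start families 1..n_max
#'
#' @param sym A [helical_symmetry()].
#' @param n_max Largest family order, >= 1.
#' @return A data frame with one row per family order (columns as the
#'   fields of [start_family()]).
#' @examples
#' enumerate_families(helical_symmetry(4.72, 65.30), 11)
#' @export
enumerate_families <- function(sym, n_max) {
  stopifnot(inherits(sym, "helical_symmetry"))
  if (!is.numeric(n_max) || length(n_max) != 1L || n_max < 1) {
    stop("'n_max' must be >= 1", call. = FALSE)
  }
  fams <- lapply(seq_len(n_max), function(n) start_family(sym, n))
  data.frame(
    n = vapply(fams, `[[`, integer(1), "n"),
    step_rise = vapply(fams, `[[`, numeric(1), "step_rise"),
    step_twist = vapply(fams, `[[`, numeric(1), "step_twist"),
    handedness = vapply(fams, `[[`, character(1), "handedness"),
    strand_pitch = vapply(fams, `[[`, numeric(1), "strand_pitch"),
    layer_line_height = vapply(fams, `[[`, numeric(1), "layer_line_height"),
    bessel_order = vapply(fams, `[[`, integer(1), "bessel_order")
  )
}

#' Number of protofilaments implied by a helical symmetry
#'
#' The protofilaments of a filament are the near-axial n-start family: the
#' order n whose wrapped step twist is closest to zero.  For all straight
#' flagellar filament symmetries considered here this returns 11; a twist
#' of exactly `2 * 360 / 7` degrees (a 7-protofilament filament, as in
#' Campylobacter) returns 7.
#'
#' @param sym A [helical_symmetry()].
#' @param n_max Largest order searched (default 15); must be >= 2.
#' @return Integer protofilament count, the n in `[2, n_max]` minimizing
#'   `|normalize_twist(n * twist)|`; ties break toward smaller n.  n = 1 is
#'   excluded: it is the lattice generator, not a protofilament family.
#' @examples
#' protofilament_count(helical_symmetry(4.72, 65.30))   # 11
#' @export
protofilament_count <- function(sym, n_max = 15L) {
  stopifnot(inherits(sym, "helical_symmetry"))
  if (!is.numeric(n_max) || length(n_max) != 1L || n_max < 2) {
    stop("'n_max' must be >= 2", call. = FALSE)
  }
  n <- 2:as.integer(n_max)
  resid <- abs(normalize_twist(n * sym$twist))
  n[which.min(resid)]   # which.min takes the first minimum: smallest n wins
}

#' Principal layer-line height of an n-start family
#'
#' In the power spectrum of a helical object, the n-start family
#' contributes layer lines at axial frequencies `Z = (n * twist / 360 + m)
#' / rise` for integer m; the principal line is the one closest to the
#' equator, `Z = normalize_twist(n * twist) / (360 * rise)`.  Its sign
#' matches the handedness of the family and its magnitude never exceeds
#' `1 / (2 * rise)`.
#'
#' @param sym A [helical_symmetry()].
#' @param n Positive integer family order.
#' @return Signed axial frequency in reciprocal Angstrom.
#' @examples
#' principal_layer_line(helical_symmetry(4.72, 65.30), 1)    # +0.03843 (26 A period)
#' principal_layer_line(helical_symmetry(4.72, 65.30), 11)   # -0.00100
#' @export
principal_layer_line <- function(sym, n) {
  stopifnot(inherits(sym, "helical_symmetry"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  normalize_twist(n * sym$twist) / (360 * sym$rise)
}

#' Supersymmetry of a seam lattice with a k-subunit asymmetric unit
#'
#' A filament with a seam is non-helical at the single-subunit level but
#' remains an ideal helix whose asymmetric unit contains k subunits
#' (k = 22 for an 11-protofilament filament dimerized along the
#' protofilaments).  Consecutive asymmetric units are related by a
#' super-rise `k * rise` and a super-twist `normalize_twist(k * twist)`,
#' which generate a 1-start helix of `360 / |super_twist|` units per turn
#' and pitch `units_per_turn * super_rise`.
#'
#' Because a published per-subunit rotation is typically printed to two
#' decimals, the wrapped `k`-fold twist can differ from the refined
#' super-twist; pass `super_twist` to use a directly refined value (the
#' rise-derived quantities are unaffected).
#'
#' @param sym A [helical_symmetry()].
#' @param k Integer >= 1, subunits per asymmetric unit.
#' @param super_twist Optional refined super-twist in degrees; default
#'   `normalize_twist(k * sym$twist)`.
#' @return An object of class `seam_symmetry`: list with `base`, `k`,
#'   `super_rise`, `super_twist`, `units_per_turn`, `super_pitch`.
#' @examples
#' sym <- helical_symmetry(4.61, 65.75)
#' seam_supersymmetry(sym, 22)
#' seam_supersymmetry(sym, 22, super_twist = 6.41)  # refined rotation
#' @export
seam_supersymmetry <- function(sym, k, super_twist = NULL) {
  stopifnot(inherits(sym, "helical_symmetry"))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("'k' must be an integer >= 1", call. = FALSE)
  }
  k <- as.integer(k)
  st <- if (is.null(super_twist)) normalize_twist(k * sym$twist) else normalize_twist(super_twist)
  upt <- if (st == 0) Inf else 360 / abs(st)
  structure(list(
    base = sym,
    k = k,
    super_rise = k * sym$rise,
    super_twist = st,
    units_per_turn = upt,
    super_pitch = upt * k * sym$rise
  ), class = "seam_symmetry")
}

#' @export
print.seam_symmetry <- function(x, ...) {
  cat(sprintf("Seam supersymmetry: %d-subunit asymmetric unit, super-rise %.4g A, super-twist %.4g deg\n",
              x$k, x$super_rise, x$super_twist))
  cat(sprintf("  1-start of asymmetric units: %.4g units/turn, pitch %.5g A\n",
              x$units_per_turn, x$super_pitch))
  invisible(x)
}

#' Published straight-filament helical symmetries
#'
#' Refined helical symmetry parameters and 11-start handedness of nine
#' straight flagellar filament mutants (seven Bacillus subtilis, two
#' Pseudomonas aeruginosa), as printed in the source refinement table.
#' These serve as canonical inputs for the lattice analyses.
#'
#' @return Data frame with columns `mutant`, `species`, `hand_11`
#'   (`"left"` for L-type, `"right"` for R-type), `rise` (Angstrom) and
#'   `twist` (degrees).
#' @examples
#' tab <- filament_symmetry_table()
#' protofilament_count(helical_symmetry(tab$rise[1], tab$twist[1]))
#' @export
filament_symmetry_table <- function() {
  data.frame(
    mutant = c("S285P", "E115G", "S17P", "N226Y", "A39VN133H", "H84R",
               "A233V", "G420A", "A443V"),
    species = c(rep("B. subtilis", 7), rep("P. aeruginosa", 2)),
    hand_11 = c("left", "left", "left", "right", "right", "right", "right",
                "left", "right"),
    rise = c(4.72, 4.72, 4.68, 4.64, 4.65, 4.64, 4.64, 4.73, 4.61),
    twist = c(65.30, 65.30, 65.29, 65.83, 65.81, 65.81, 65.81, 65.27, 65.75)
  )
}
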