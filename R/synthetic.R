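# run expr with a local RNG stream; global .Random.seed is untouched
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Specification for a synthetic flagellin-like protomer
#'
#' The generated protomer emulates the two-domain architecture of a
#' flagellin subunit: an inner D0 domain of two antiparallel alpha-helices
#' near the filament axis and an outer D1 domain of three helices, spanning
#' the ~25 Angstrom inner to ~125 Angstrom outer filament diameter.
#'
#' @param seed Integer RNG seed (controls only a small reproducible
#'   coordinate jitter).
#' @param inner_radius Inner filament radius in Angstrom (default 12.5).
#' @param outer_radius Outer filament radius in Angstrom (default 62.5).
#' @param d1_rotation Rigid rotation of the D1 domain about the filament
#'   axis, degrees in `[0, 15]` (0 = reference state; the L/R difference
#'   observed in real subunits spans 2-10 degrees).
#' @param d1_shift Rigid axial shift of D1 in Angstrom.
#' @param jitter_sd Coordinate jitter standard deviation (default 0.02).
#' @return Object of class `protomer_spec`.
#' @export
protomer_spec <- function(seed = 1L, inner_radius = 12.5, outer_radius = 62.5,
                          d1_rotation = 0, d1_shift = 0, jitter_sd = 0.02) {
  if (inner_radius <= 0 || outer_radius <= inner_radius) {
    stop("need 0 < inner_radius < outer_radius", call. = FALSE)
  }
  if (d1_rotation < 0 || d1_rotation > 15) {
    stop("'d1_rotation' must be in [0, 15] degrees", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), inner_radius = inner_radius,
                 outer_radius = outer_radius, d1_rotation = d1_rotation,
                 d1_shift = d1_shift, jitter_sd = jitter_sd),
            class = "protomer_spec")
}

# ideal alpha-helix C-alpha trace: rise 1.5 A/residue, helix radius 2.3 A,
# 100 deg/residue, axis vertical through (r_axis, azimuth), z ascending
# (direction +1) or descending (-1) from z0
.helix_ca <- function(n_res, r_axis, azimuth_deg, z0, direction = 1,
                      helix_radius = 2.3, rise = 1.5, turn = 100) {
  az <- azimuth_deg * pi / 180
  center <- c(r_axis * cos(az), r_axis * sin(az))
  e1 <- c(cos(az), sin(az))        # radial unit vector
  e2 <- c(-sin(az), cos(az))       # tangential unit vector
  i <- seq_len(n_res) - 1
  theta <- i * turn * pi / 180
  offs <- helix_radius * (outer(cos(theta), e1) + outer(sin(theta), e2))
  cbind(center[1] + offs[, 1], center[2] + offs[, 2], z0 + direction * rise * i)
}

# straight linker of n_res C-alphas interpolating between two points
.linker_ca <- function(n_res, from, to) {
  t <- seq_len(n_res) / (n_res + 1)
  cbind(from[1] + t * (to[1] - from[1]),
        from[2] + t * (to[2] - from[2]),
        from[3] + t * (to[3] - from[3]))
}

#' Generate a synthetic flagellin-like protomer
#'
#' Builds a C-alpha-only model of 174 residues: ND0 (1-32) and CD0
#' (143-174) as antiparallel inner helices, three D1 helices (41-134) at
#' the outer radius, joined by NL (33-40) and CL (135-142) linkers.
#' Helices are ideal (1.5 Angstrom rise, 2.3 Angstrom radius, 100 degrees
#' per residue, hence consecutive C-alpha distances near 3.8 Angstrom).
#' If `d1_rotation` or `d1_shift` is nonzero the whole D1 block is rigidly
#' moved about/along the filament (z) axis, so C-alpha displacement grows
#' linearly with distance from the axis -- the geometry of an L/R state
#' change.  Identical specs give bit-identical output.
#'
#' @param spec A [protomer_spec()].
#' @return A [protomer()] with domains D0, D1, ND0, NL, CL, CD0 annotated
#'   and the spec stored in `$metadata$spec`.
#' @examples
#' p <- make_protomer(protomer_spec(seed = 7))
#' range(sqrt(p$atoms$x^2 + p$atoms$y^2))  # ~ 12.5 .. 62.5
#' @export
make_protomer <- function(spec) {
  stopifnot(inherits(spec, "protomer_spec"))
  hr <- 2.3
  r_in <- spec$inner_radius + hr     # helix axis so atoms reach inner_radius
  r_out <- spec$outer_radius - hr
  nd0 <- .helix_ca(32, r_in, 0, z0 = 2, direction = 1)
  d1a <- .helix_ca(26, r_out, 10, z0 = 44, direction = -1)
  d1b <- .helix_ca(26, r_out, 22, z0 = 6.5, direction = 1)
  d1c <- .helix_ca(26, r_out, 34, z0 = 44, direction = -1)
  cd0 <- .helix_ca(32, r_in, 18, z0 = 48.5, direction = -1)
  nl <- .linker_ca(8, nd0[32, ], d1a[1, ])
  l1 <- .linker_ca(8, d1a[26, ], d1b[1, ])
  l2 <- .linker_ca(8, d1b[26, ], d1c[1, ])
  cl <- .linker_ca(8, d1c[26, ], cd0[1, ])
  xyz <- rbind(nd0, nl, d1a, l1, d1b, l2, d1c, cl, cd0)
  n <- nrow(xyz)                     # 174
  if (spec$jitter_sd > 0) {
    xyz <- xyz + .with_seed(spec$seed,
                            matrix(stats::rnorm(3 * n, 0, spec$jitter_sd), n, 3))
  }
  d1_res <- 41:134
  if (spec$d1_rotation != 0 || spec$d1_shift != 0) {
    a <- spec$d1_rotation * pi / 180
    rot <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                  3, 3, byrow = TRUE)
    xyz[d1_res, ] <- sweep(xyz[d1_res, ] %*% t(rot), 2,
                           c(0, 0, spec$d1_shift), "+")
  }
  atoms <- atom_table(serial = seq_len(n), atom = "CA", resname = "ALA",
                      chain = "A", resno = seq_len(n), element = "C",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  protomer(atoms,
           domains = list(ND0 = list(c(1L, 32L)), NL = list(c(33L, 40L)),
                          D1 = list(c(41L, 134L)), CL = list(c(135L, 142L)),
                          CD0 = list(c(143L, 174L)),
                          D0 = list(c(1L, 32L), c(143L, 174L))),
           metadata = list(spec = spec))
}

#' Generate an L/R-like two-state protomer pair
#'
#' Returns a reference protomer and a copy whose D1 domain is rigidly
#' rotated about the filament axis by `d1_rotation` degrees (plus an
#' optional axial shift), with the D0 domain untouched -- the minimal
#' geometric model of the polymorphic L/R subunit difference.  The
#' implanted ground truth is stored in the second protomer's metadata.
#'
#' @param spec A [protomer_spec()] (its own `d1_rotation` is ignored; the
#'   reference state uses 0).
#' @param d1_rotation Implanted rotation in degrees (default 6, the
#'   midpoint of the observed 2-10 degree range).
#' @param d1_shift Implanted axial shift in Angstrom (default 0).
#' @return List with elements `reference`, `rotated`, `d1_rotation`,
#'   `d1_shift`.
#' @export
make_two_state_protomers <- function(spec, d1_rotation = 6, d1_shift = 0) {
  stopifnot(inherits(spec, "protomer_spec"))
  ref_spec <- spec; ref_spec$d1_rotation <- 0; ref_spec$d1_shift <- 0
  rot_spec <- spec; rot_spec$d1_rotation <- d1_rotation
  rot_spec$d1_shift <- d1_shift
  if (d1_rotation < 0 || d1_rotation > 15) {
    stop("'d1_rotation' must be in [0, 15] degrees", call. = FALSE)
  }
  list(reference = make_protomer(ref_spec), rotated = make_protomer(rot_spec),
       d1_rotation = d1_rotation, d1_shift = d1_shift)
}

#' Generate a (optionally noisy) synthetic filament
#'
#' Applies helical symmetry to the protomer, then adds isotropic Gaussian
#' coordinate noise.  The true symmetry and noise level are kept in the
#' model's metadata for oracle tests.
#'
#' @param protomer A [protomer()].
#' @param sym A [helical_symmetry()].
#' @param count Number of subunits (indices `0:(count-1)`).
#' @param noise_sd Per-coordinate Gaussian noise in Angstrom (default 0).
#' @param seed RNG seed for the noise.
#' @return A `filament_model` with `$truth = list(symmetry, noise_sd, seed)`.
#' @export
make_filament <- function(protomer, sym, count, noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  fil <- apply_symmetry(protomer, sym, count = count)
  if (noise_sd > 0) {
    n <- nrow(fil$atoms)
    noise <- .with_seed(seed, matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3))
    fil$atoms$x <- fil$atoms$x + noise[, 1]
    fil$atoms$y <- fil$atoms$y + noise[, 2]
    fil$atoms$z <- fil$atoms$z + noise[, 3]
  }
  fil$truth <- list(symmetry = sym, noise_sd = noise_sd, seed = as.integer(seed))
  fil
}

#' Specification for synthetic waveform traces
#'
#' Defaults model a supercoiled filament at the fluorescence-microscopy
#' scale: pitch 2.2 micrometers, diameter 0.6 micrometers, measurement
#' noise 0.02 micrometers, ten filaments per strain spanning three
#' supercoil periods.
#'
#' @param seed RNG seed.
#' @param P True supercoil pitch (micrometers).
#' @param D True supercoil diameter (micrometers).
#' @param n_periods Periods spanned by each trace (>= 1).
#' @param noise_sd Gaussian noise on the lateral displacement (micrometers).
#' @param n_traces Number of filaments.
#' @param points_per_period Sampling density (default 40).
#' @return Object of class `waveform_spec`.
#' @export
waveform_spec <- function(seed = 1L, P = 2.2, D = 0.6, n_periods = 3L,
                          noise_sd = 0.02, n_traces = 10L,
                          points_per_period = 40L) {
  if (n_periods < 1) stop("'n_periods' must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  structure(list(seed = as.integer(seed), P = P, D = D,
                 n_periods = as.integer(n_periods), noise_sd = noise_sd,
                 n_traces = as.integer(n_traces),
                 points_per_period = as.integer(points_per_period)),
            class = "waveform_spec")
}

#' Generate synthetic projected-waveform traces
#'
#' Each trace is `x(s) = (D / 2) * sin(2 * pi * s / P + phi_i) + noise`
#' with a random phase per filament; the ground truth is attached to each
#' trace.  Identical specs give identical traces.
#'
#' @param spec A [waveform_spec()].
#' @return List of [waveform_trace()] objects with attribute `truth`.
#' @export
make_waveform_traces <- function(spec) {
  stopifnot(inherits(spec, "waveform_spec"))
  .with_seed(spec$seed, {
    lapply(seq_len(spec$n_traces), function(i) {
      s <- seq(0, spec$n_periods * spec$P,
               length.out = spec$n_periods * spec$points_per_period + 1L)
      phi <- stats::runif(1, 0, 2 * pi)
      x <- spec$D / 2 * sin(2 * pi * s / spec$P + phi) +
        stats::rnorm(length(s), 0, spec$noise_sd)
      tr <- waveform_trace(s, x, id = sprintf("synthetic_%02d", i))
      attr(tr, "truth") <- list(P = spec$P, D = spec$D, phase = phi,
                                noise_sd = spec$noise_sd)
      tr
    })
  })
}
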