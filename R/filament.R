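#' Screw transform placing subunit i of a helical filament
#'
#' Rotation about the z axis by `i * twist` and translation along z by
#' `i * rise`.  Transforms form a group: `subunit_transform(sym, 0)` is the
#' identity and composing the transforms for i and j gives the transform
#' for i + j.
#'
#' @param sym A [helical_symmetry()] or `seam_symmetry` (which uses the
#'   super-rise/super-twist).
#' @param i Integer subunit (or asymmetric-unit) index; may be negative.
#' @return Object of class `rigid_transform`: list with `rotation` (3x3)
#'   and `translation` (length 3, Angstrom).
#' @examples
#' tr <- subunit_transform(helical_symmetry(4.72, 65.30), 11)
#' tr$translation[3]   # 51.92 A; rotation wraps to -1.70 deg
#' @export
subunit_transform <- function(sym, i) {
  if (inherits(sym, "seam_symmetry")) {
    rise <- sym$super_rise; twist <- sym$super_twist
  } else {
    stopifnot(inherits(sym, "helical_symmetry"))
    rise <- sym$rise; twist <- sym$twist
  }
  stopifnot(length(i) == 1L, is.finite(i), i == round(i))
  a <- i * twist * pi / 180
  rot <- matrix(c(cos(a), -sin(a), 0,
                  sin(a),  cos(a), 0,
                  0,       0,      1), 3, 3, byrow = TRUE)
  rigid_transform(rot, c(0, 0, i * rise))
}

#' Rigid transform constructor, application and composition
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Numeric length-3 translation (Angstrom).
#' @return `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)),
            length(translation) == 3)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @param tr,a,b `rigid_transform` objects.
#' @param xyz n x 3 coordinate matrix.
#' @rdname rigid_transform
#' @export
apply_transform <- function(tr, xyz) {
  stopifnot(inherits(tr, "rigid_transform"))
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(xyz %*% t(tr$rotation), 2, tr$translation, "+")
}

#' @rdname rigid_transform
#' @export
compose_transforms <- function(a, b) {
  # (a o b)(x) = a(b(x))
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Build a filament model by applying helical symmetry to a protomer
#'
#' Each requested subunit index i receives an exact copy of the protomer
#' transformed by [subunit_transform()] and its own chain identifier.  The
#' filament axis is assumed to run along z through the origin (the frame
#' of helically refined depositions); no axis fitting is attempted.
#'
#' @param protomer A [protomer()].
#' @param sym A [helical_symmetry()].
#' @param indices Integer vector of distinct subunit indices (default
#'   `0:(count-1)` via `count`).
#' @param count Convenience: `indices = 0:(count-1)`.
#' @return Object of class `filament_model`: list with `atoms` (all
#'   subunits, chain per subunit), `protomer`, `symmetry`, `indices` and
#'   `chains` (named map from index to chain id).
#' @examples
#' p <- make_protomer(protomer_spec(seed = 1))
#' f <- apply_symmetry(p, helical_symmetry(4.72, 65.30), indices = c(0, 5, 6, 11, 16))
#' @export
apply_symmetry <- function(protomer, sym, indices = NULL, count = NULL) {
  stopifnot(inherits(protomer, "protomer"), inherits(sym, "helical_symmetry"))
  if (is.null(indices)) {
    if (is.null(count)) stop("supply 'indices' or 'count'", call. = FALSE)
    indices <- 0:(count - 1L)
  }
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("duplicate subunit indices", call. = FALSE)
  if (nrow(protomer$atoms) == 0) stop("empty protomer", call. = FALSE)
  chains <- .chain_ids(length(indices))
  blocks <- lapply(seq_along(indices), function(j) {
    at <- protomer$atoms
    xyz <- apply_transform(subunit_transform(sym, indices[j]),
                           cbind(at$x, at$y, at$z))
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    at$chain <- chains[j]
    at
  })
  atoms <- do.call(rbind, blocks)
  atoms$serial <- seq_len(nrow(atoms))
  structure(list(atoms = atoms, protomer = protomer, symmetry = sym,
                 indices = indices,
                 chains = stats::setNames(chains, as.character(indices))),
            class = "filament_model")
}

#' @export
print.filament_model <- function(x, ...) {
  cat(sprintf("Filament model: %d subunits (%d atoms)\n",
              length(x$indices), nrow(x$atoms)))
  print(x$symmetry)
  invisible(x)
}

#' Coordinates of one subunit of a filament
#'
#' @param filament A `filament_model`.
#' @param index Subunit index (as used when building).
#' @param atoms Atom-name filter (default `"CA"`; `NULL` for all atoms).
#' @param residues Optional residue-number filter.
#' @return n x 3 coordinate matrix, rows ordered as in the protomer.
#' @export
subunit_coords <- function(filament, index, atoms = "CA", residues = NULL) {
  stopifnot(inherits(filament, "filament_model"))
  ch <- filament$chains[as.character(index)]
  if (is.na(ch)) stop("subunit index ", index, " not present in filament", call. = FALSE)
  at <- filament$atoms[filament$atoms$chain == ch, ]
  if (!is.null(atoms)) at <- at[at$atom %in% atoms, ]
  if (!is.null(residues)) at <- at[at$resno %in% residues, ]
  cbind(x = at$x, y = at$y, z = at$z)
}

#' Build a seam filament from asymmetric units
#'
#' Places `n_units` copies of a k-subunit asymmetric unit (k subunits of
#' the base helix, e.g. 22) using the seam supersymmetry, and records each
#' subunit's donor/acceptor role from the seam net.
#'
#' @param protomer A [protomer()].
#' @param seam A [seam_supersymmetry()].
#' @param seam_net A [build_seam_net()] with matching `unit_size`.
#' @param n_units Number of asymmetric units (>= 1).
#' @return A `filament_model` whose subunit indices run
#'   `0:(n_units * k - 1)`; `$roles` maps each index to `"donor"` or
#'   `"acceptor"`.
#' @examples
#' sym <- helical_symmetry(4.61, 65.75)
#' sn <- build_seam_net(sym, count = 44)
#' p <- make_protomer(protomer_spec(seed = 1))
#' f <- build_seam_filament(p, seam_supersymmetry(sym, 22), sn, n_units = 1)
#' @export
build_seam_filament <- function(protomer, seam, seam_net, n_units) {
  stopifnot(inherits(seam, "seam_symmetry"), inherits(seam_net, "seam_net"))
  if (seam$k != seam_net$unit_size) {
    stop(sprintf("asymmetric unit size mismatch: supersymmetry k = %d, net unit_size = %d",
                 seam$k, seam_net$unit_size), call. = FALSE)
  }
  if (n_units < 1) stop("'n_units' must be >= 1", call. = FALSE)
  idx <- 0:(n_units * seam$k - 1L)
  fil <- apply_symmetry(protomer, seam$base, indices = idx)
  u <- idx %% seam$k
  fil$roles <- stats::setNames(
    ifelse(u < seam_net$pair_offset, "donor", "acceptor"), as.character(idx))
  fil$seam <- seam
  fil$seam_boundary <- seam_net$seam_boundary
  fil
}

#' Re-estimate helical symmetry from a filament model
#'
#' Recovers (rise, twist) from the centroids of consecutively indexed
#' subunits: the rise as the mean axial step and the twist as the mean
#' wrapped azimuthal step.  Exact for noise-free models; for noisy models
#' the averaging over consecutive pairs gives an unbiased estimate.
#'
#' @param filament A `filament_model` whose indices contain consecutive runs.
#' @return A [helical_symmetry()].
#' @export
estimate_symmetry <- function(filament) {
  stopifnot(inherits(filament, "filament_model"))
  idx <- sort(filament$indices)
  consec <- idx[which(diff(idx) == 1L)]
  if (!length(consec)) stop("no consecutive subunit pairs in filament", call. = FALSE)
  steps <- vapply(consec, function(i) {
    a <- colMeans(subunit_coords(filament, i, atoms = NULL))
    b <- colMeans(subunit_coords(filament, i + 1L, atoms = NULL))
    c(b[3] - a[3],
      normalize_twist((atan2(b[2], b[1]) - atan2(a[2], a[1])) * 180 / pi))
  }, numeric(2))
  helical_symmetry(mean(steps[1, ]), mean(steps[2, ]))
}
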