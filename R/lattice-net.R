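#' Strand membership of a subunit in an n-start family
#'
#' Subunit `index` along the 1-start belongs to strand `index mod n` of the
#' n-start family (protofilament membership is the case n = 11).
#'
#' @param index Integer subunit ordinal(s) along the 1-start (0-based).
#' @param n Family order, >= 1.
#' @return Integer strand class(es) in `[0, n)`.
#' @examples
#' strand_assignment(16, 11)   # subunit S+16 sits on the protofilament of S+5
#' @export
strand_assignment <- function(index, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("'n' must be an integer >= 1", call. = FALSE)
  }
  as.integer(index %% n)
}

#' Unrolled helical net
#'
#' Places `count` subunits on the 1-start helix and unrolls the cylindrical
#' surface at the given radius onto a plane, using the convention that the
#' surface is viewed from the outside: the circumferential coordinate
#' `x_unrolled` increases with the cumulative rotation `phi`, and z points
#' up the filament axis.
#'
#' @param sym A [helical_symmetry()].
#' @param count Number of points, >= 1.
#' @param radius Cylinder radius in Angstrom (default 62.5, the outer
#'   radius of a flagellar filament); the apparent tilt of strand lines
#'   depends on it.
#' @param strands Integer family orders for which strand-class columns are
#'   added (default `c(5, 6, 11)`).
#' @return Data frame of class `helical_net` with columns `index`, `phi_deg`
#'   (cumulative, unwrapped), `z` (Angstrom), `x_unrolled` (Angstrom,
#'   wrapped to `[0, 2*pi*radius)`), and one `strand_<n>` column per
#'   requested family.
#' @examples
#' net <- build_net(helical_symmetry(4.72, 65.30), 100)
#' head(net)
#' @export
build_net <- function(sym, count, radius = 62.5, strands = c(5L, 6L, 11L)) {
  stopifnot(inherits(sym, "helical_symmetry"))
  if (!is.numeric(count) || length(count) != 1L || count < 1) {
    stop("'count' must be >= 1", call. = FALSE)
  }
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    stop("'radius' must be > 0", call. = FALSE)
  }
  idx <- seq_len(count) - 1L
  phi <- idx * sym$twist
  circ <- 2 * pi * radius
  net <- data.frame(
    index = idx,
    phi_deg = phi,
    z = idx * sym$rise,
    x_unrolled = (radius * phi * pi / 180) %% circ
  )
  for (n in strands) net[[paste0("strand_", n)]] <- strand_assignment(idx, n)
  attr(net, "radius") <- radius
  attr(net, "symmetry") <- sym
  class(net) <- c("helical_net", "data.frame")
  net
}

#' Seam-perturbed helical net
#'
#' Decorates a helical net with a subunit-pairing (dimerization) rule that
#' makes the lattice non-helical at the single-subunit level while leaving
#' it an ideal helix with a `unit_size`-subunit asymmetric unit.  Within
#' each asymmetric unit the first `pair_offset` subunits are donors, each
#' paired with the acceptor `pair_offset` indices above it (for a
#' flagellar filament, `unit_size = 22`, `pair_offset = 11`: the outer
#' domain of subunit S_N pairs with subunit S_N+11).  The pairing phase
#' cannot close smoothly around the circumference, so exactly one boundary
#' between adjacent protofilaments is out of phase: the seam.
#'
#' @param sym A [helical_symmetry()].
#' @param count Number of subunits; must be a positive multiple of
#'   `unit_size`.
#' @param radius Net radius in Angstrom.
#' @param pair_offset Index offset between a donor and its acceptor
#'   (default 11, the protofilament step).
#' @param unit_size Subunits per asymmetric unit (default 22); must exceed
#'   `pair_offset`.
#' @return Object of class `seam_net`: list with `net` (the
#'   [build_net()] data frame plus `role` and `partner` columns),
#'   `pair_offset`, `unit_size`, `pairs` (data frame of donor/acceptor
#'   index pairs) and `seam_boundary` (ordered pair of adjacent
#'   protofilament classes, from [locate_seam()]).
#' @examples
#' sn <- build_seam_net(helical_symmetry(4.61, 65.75), count = 44)
#' sn$seam_boundary
#' @export
build_seam_net <- function(sym, count, radius = 62.5, pair_offset = 11L,
                           unit_size = 22L) {
  stopifnot(inherits(sym, "helical_symmetry"))
  pair_offset <- as.integer(pair_offset)
  unit_size <- as.integer(unit_size)
  if (pair_offset < 1 || unit_size < 1 || pair_offset >= unit_size) {
    stop("'pair_offset' must be in [1, unit_size)", call. = FALSE)
  }
  if (!is.numeric(count) || length(count) != 1L || count < 1 ||
      count %% unit_size != 0) {
    stop(sprintf("'count' must be a positive multiple of unit_size (%d)", unit_size),
         call. = FALSE)
  }
  net <- build_net(sym, count, radius)
  u <- net$index %% unit_size
  net$role <- ifelse(u < pair_offset, "donor", "acceptor")
  net$partner <- ifelse(u < pair_offset, net$index + pair_offset,
                        net$index - pair_offset)
  donors <- net$index[net$role == "donor"]
  pairs <- data.frame(donor = donors, acceptor = donors + pair_offset)
  out <- structure(list(net = net, pair_offset = pair_offset,
                        unit_size = unit_size, pairs = pairs,
                        seam_boundary = NULL),
                   class = "seam_net")
  out$seam_boundary <- locate_seam(out)
  out
}

#' @export
print.seam_net <- function(x, ...) {
  cat(sprintf("Seam net: %d subunits, %d-subunit asymmetric unit, pair offset %d\n",
              nrow(x$net), x$unit_size, x$pair_offset))
  cat(sprintf("  %d donor/acceptor pairs; seam between protofilaments %d and %d\n",
              nrow(x$pairs), x$seam_boundary[1], x$seam_boundary[2]))
  invisible(x)
}

#' Locate the seam of a dimerized helical lattice
#'
#' Walks each full turn of the lattice in azimuthal order (one subunit per
#' protofilament, closed by the subunit one `pair_offset` step up, which
#' returns to the starting azimuth) and finds the boundary between
#' azimuthally adjacent protofilaments whose donor/acceptor roles
#' disagree.  Because one turn advances the 1-start index by `pair_offset`
#' -- half the asymmetric unit -- the pairing phase flips on closing the
#' circuit and exactly one boundary per turn must be mismatched: the seam.
#' Every full turn is checked for this uniqueness; the reported classes
#' are those flanking the seam in the first (basal) turn, since the
#' protofilament strands themselves wind slowly around the axis and carry
#' the seam line with them.
#'
#' @param seam_net A [build_seam_net()] object.
#' @return Ordered integer pair of protofilament classes (each in
#'   `[0, pair_offset)`) flanking the seam at the filament base, lower
#'   azimuth first.
#' @examples
#' sn <- build_seam_net(helical_symmetry(4.61, 65.75), count = 44)
#' locate_seam(sn)   # 5 0 for the canonical 22/11 lattice
#' @export
locate_seam <- function(seam_net) {
  stopifnot(inherits(seam_net, "seam_net"))
  net <- seam_net$net
  p <- seam_net$pair_offset
  if (is.null(net$role) || nrow(seam_net$pairs) == 0) {
    stop("seam net has no pairing decoration", call. = FALSE)
  }
  n_turns <- nrow(net) %/% p - 1L   # need the closing subunit of each turn
  if (n_turns < 1) stop("net too short to contain one full turn", call. = FALSE)
  boundaries <- vector("list", n_turns)
  for (t in seq_len(n_turns)) {
    base <- (t - 1L) * p
    members <- base + 0:(p - 1L)
    ord <- members[order(net$phi_deg[members + 1L] %% 360)]
    circuit <- c(ord, base + p)                    # closes at same azimuth as ord[1]
    roles <- net$role[circuit + 1L]
    mism <- which(roles[-length(roles)] != roles[-1L])
    if (length(mism) != 1L) {
      stop("inconsistent pairing rule: expected exactly one phase break per turn, found ",
           length(mism), call. = FALSE)
    }
    boundaries[[t]] <- as.integer(c(circuit[mism] %% p, circuit[mism + 1L] %% p))
  }
  boundaries[[1L]]
}

#' Write a helical or seam net to CSV
#'
#' Columns follow the outside-view convention documented in [build_net()].
#'
#' @param net A `helical_net` data frame or a `seam_net`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_net_csv <- function(net, path) {
  df <- if (inherits(net, "seam_net")) net$net else net
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
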