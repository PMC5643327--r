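#' Kabsch least-squares superposition
#'
#' Optimal proper rigid superposition of `moving` onto `fixed`: the
#' rotation is constrained to determinant +1 (reflections are rejected by
#' flipping the smallest singular direction), so mirror-image inputs give
#' a nonzero RMSD rather than an improper fit.
#'
#' @param moving,fixed n x 3 coordinate matrices with matching row order
#'   (atom correspondence); n >= 3 and not collinear.
#' @return Object of class `superposition`: `rotation` (3x3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom over the input atoms) and
#'   `n_atoms`.  The fitted coordinates are
#'   `moving %*% t(rotation) + translation` (see [apply_transform()]).
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' s <- kabsch_superpose(a, a)
#' s$rmsd   # 0
#' @export
kabsch_superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (ncol(moving) != 3L || ncol(fixed) != 3L) {
    stop("coordinate matrices must have 3 columns", call. = FALSE)
  }
  if (nrow(moving) != nrow(fixed)) {
    stop(sprintf("atom count mismatch: %d vs %d", nrow(moving), nrow(fixed)),
         call. = FALSE)
  }
  n <- nrow(moving)
  if (n < 3L) stop("need at least 3 atoms", call. = FALSE)
  cm <- colMeans(moving); cf <- colMeans(fixed)
  P <- sweep(moving, 2, cm); Q <- sweep(fixed, 2, cf)
  if (svd(P, nu = 0, nv = 0)$d[2] < 1e-8 * max(1, svd(P, nu = 0, nv = 0)$d[1])) {
    stop("degenerate (collinear) selection", call. = FALSE)
  }
  s <- svd(crossprod(P, Q))            # H = U D V^T
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- P %*% t(R)
  structure(list(rotation = R,
                 translation = as.numeric(cf - R %*% cm),
                 rmsd = sqrt(sum((fitted - Q)^2) / n),
                 n_atoms = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition over %d atoms: rmsd %.4g A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

# resolve a residue correspondence between two protomers; default identity
# on shared modeled residues.  `correspondence` is a 2-column data frame
# (res_a, res_b) from any external alignment.
.match_residues <- function(res_a, res_b, correspondence = NULL) {
  if (is.null(correspondence)) {
    shared <- intersect(res_a, res_b)
    if (!length(shared)) stop("no shared residues and no correspondence map",
                              call. = FALSE)
    data.frame(res_a = shared, res_b = shared)
  } else {
    cm <- as.data.frame(correspondence)
    if (ncol(cm) < 2L || nrow(cm) == 0L) {
      stop("empty correspondence map", call. = FALSE)
    }
    names(cm)[1:2] <- c("res_a", "res_b")
    cm <- cm[cm$res_a %in% res_a & cm$res_b %in% res_b, 1:2]
    if (!nrow(cm)) stop("correspondence map covers no modeled residues",
                        call. = FALSE)
    cm
  }
}

.ca_coords <- function(x, residues = NULL) {
  at <- if (inherits(x, "protomer")) x$atoms else as.data.frame(x)
  at <- at[at$atom == "CA", ]
  if (!is.null(residues)) at <- at[match(residues, at$resno), ]
  cbind(at$resno, at$x, at$y, at$z)
}

#' Per-domain backbone RMSD between two protomers
#'
#' Superposes the C-alpha atoms of the named domain (or `"D0D1"` for the
#' connected two-domain core) of `model_b` onto `model_a` and returns the
#' RMSD over that selection.
#'
#' @param model_a,model_b [protomer()] objects with domain annotations.
#' @param domain Domain name (`"D0"`, `"D1"`, `"D0D1"`, ...); resolved in
#'   `model_a` (and through the correspondence for `model_b`).
#' @param correspondence Optional two-column residue map (model_a residue,
#'   model_b residue) for cross-species comparison; default identity on
#'   shared residues.
#' @return RMSD in Angstrom.
#' @export
domain_rmsd <- function(model_a, model_b, domain, correspondence = NULL) {
  res_dom <- domain_residues(model_a, domain)
  ca_a <- .ca_coords(model_a); ca_b <- .ca_coords(model_b)
  cm <- .match_residues(ca_a[, 1], ca_b[, 1], correspondence)
  cm <- cm[cm$res_a %in% res_dom, , drop = FALSE]
  if (!nrow(cm)) stop("correspondence covers no residue of domain ", domain,
                      call. = FALSE)
  a <- ca_a[match(cm$res_a, ca_a[, 1]), 2:4, drop = FALSE]
  b <- ca_b[match(cm$res_b, ca_b[, 1]), 2:4, drop = FALSE]
  kabsch_superpose(b, a)$rmsd
}

#' Displacements and rigid rotation of one domain after aligning another
#'
#' Aligns `model_b` onto `model_a` using the C-alpha atoms of
#' `align_domain`, then reports, for the atoms of `domain`, the
#' per-residue displacement and the residual rigid rotation
#' (Kabsch of the aligned `domain` block, angle from the rotation trace).
#' Used to quantify the rigid outer-domain rotation distinguishing L- and
#' R-state subunits.
#'
#' @inheritParams domain_rmsd
#' @param align_domain Domain used for the alignment frame (default `"D0"`).
#' @param domain Domain measured (default `"D1"`).
#' @return List with `angle` (degrees, in `[0, 180]`), `rmsd` (of `domain`
#'   after `align_domain` alignment), and `displacements` (data frame:
#'   residue, radial distance from the z axis in `model_a`, displacement).
#' @export
domain_rotation <- function(model_a, model_b, align_domain = "D0",
                            domain = "D1", correspondence = NULL) {
  ca_a <- .ca_coords(model_a); ca_b <- .ca_coords(model_b)
  cm <- .match_residues(ca_a[, 1], ca_b[, 1], correspondence)
  pick <- function(dom) {
    sel <- cm[cm$res_a %in% domain_residues(model_a, dom), , drop = FALSE]
    list(a = ca_a[match(sel$res_a, ca_a[, 1]), 2:4, drop = FALSE],
         b = ca_b[match(sel$res_b, ca_b[, 1]), 2:4, drop = FALSE],
         res = sel$res_a)
  }
  al <- pick(align_domain); me <- pick(domain)
  sup <- kabsch_superpose(al$b, al$a)
  tr <- rigid_transform(sup$rotation, sup$translation)
  b_aligned <- apply_transform(tr, me$b)
  resid_rot <- kabsch_superpose(b_aligned, me$a)
  ang <- acos(pmin(1, pmax(-1, (sum(diag(resid_rot$rotation)) - 1) / 2))) * 180 / pi
  disp <- sqrt(rowSums((b_aligned - me$a)^2))
  list(angle = ang,
       rmsd = sqrt(mean(disp^2)),
       displacements = data.frame(residue = me$res,
                                  radius = sqrt(me$a[, 1]^2 + me$a[, 2]^2),
                                  displacement = disp))
}

#' Subunit offsets forming all unique contacts of a filament subunit
#'
#' A subunit S0 touches eight neighbors (S+-5, S+-6, S+-11, S+-16); by
#' symmetry the complex S0, S+5, S+6, S+11, S+16 contains every unique
#' interface once.
#'
#' @return Integer vector `c(0, 5, 6, 11, 16)`.
#' @export
unique_contact_indices <- function() c(0L, 5L, 6L, 11L, 16L)

#' Extract the five-subunit unique-contact complex
#'
#' @param filament A `filament_model` containing subunits 0, 5, 6, 11, 16.
#' @param atoms Atom filter (default `"CA"`; `NULL` for all).
#' @return Named list (`S0`, `S+5`, `S+6`, `S+11`, `S+16`) of coordinate
#'   matrices, each in protomer atom order.
#' @export
extract_five_subunit_complex <- function(filament, atoms = "CA") {
  stopifnot(inherits(filament, "filament_model"))
  idx <- unique_contact_indices()
  missing <- setdiff(idx, filament$indices)
  if (length(missing)) {
    stop("filament lacks subunit indices: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(idx, function(i) subunit_coords(filament, i, atoms = atoms))
  names(out) <- c("S0", "S+5", "S+6", "S+11", "S+16")
  out
}

#' Pairwise packing RMSD of five-subunit complexes
#'
#' For each pair of filaments, concatenates the C-alpha coordinates of the
#' five-subunit unique-contact complex (after applying the residue
#' correspondence) and computes the Kabsch RMSD of one complex globally
#' superposed on the other.  The resulting matrix captures subunit
#' packing, not just fold: filaments of the same protofilament hand
#' cluster tightly even across species.
#'
#' @param filaments Named list of `filament_model`s (names label the matrix).
#' @param correspondence Optional list: `correspondence[[c(a, b)]]` ignored;
#'   either `NULL` (identity on shared residues, same-species default) or a
#'   single two-column map applied to every pair.
#' @return Object of class `rmsd_matrix`: `labels`, `values` (symmetric,
#'   zero diagonal), `selection = "five-subunit"`.
#' @export
packing_rmsd_matrix <- function(filaments, correspondence = NULL) {
  if (length(filaments) < 2L) stop("need at least 2 filaments", call. = FALSE)
  labels <- names(filaments)
  if (is.null(labels)) labels <- paste0("model", seq_along(filaments))
  blocks <- lapply(filaments, function(f) {
    resno <- f$protomer$atoms$resno[f$protomer$atoms$atom == "CA"]
    list(complex = extract_five_subunit_complex(f), resno = resno)
  })
  m <- length(filaments)
  values <- matrix(0, m, m, dimnames = list(labels, labels))
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      cm <- .match_residues(blocks[[i]]$resno, blocks[[j]]$resno, correspondence)
      sel_i <- match(cm$res_a, blocks[[i]]$resno)
      sel_j <- match(cm$res_b, blocks[[j]]$resno)
      a <- do.call(rbind, lapply(blocks[[i]]$complex, function(x) x[sel_i, , drop = FALSE]))
      b <- do.call(rbind, lapply(blocks[[j]]$complex, function(x) x[sel_j, , drop = FALSE]))
      values[i, j] <- values[j, i] <- kabsch_superpose(b, a)$rmsd
    }
  }
  structure(list(labels = labels, values = values, selection = "five-subunit"),
            class = "rmsd_matrix")
}

#' @export
print.rmsd_matrix <- function(x, ...) {
  cat(sprintf("RMSD matrix (%s selection), Angstrom:\n", x$selection))
  print(round(x$values, 3))
  invisible(x)
}

#' Partition models by single-linkage clustering of an RMSD matrix
#'
#' Single linkage is the right notion for the two-block "clusters by
#' protofilament hand" pattern: models join a cluster if any member is
#' within the threshold.
#'
#' @param matrix An `rmsd_matrix` (or plain symmetric matrix).
#' @param threshold Linkage cut height in Angstrom (default 1.5, the lower
#'   edge of the observed between-hand RMSD range).
#' @return Named integer vector of cluster memberships.
#' @export
cluster_by_hand <- function(matrix, threshold = 1.5) {
  v <- if (inherits(matrix, "rmsd_matrix")) matrix$values else as.matrix(matrix)
  if (threshold <= 0) {
    return(stats::setNames(seq_len(nrow(v)), rownames(v)))
  }
  hc <- stats::hclust(stats::as.dist(v), method = "single")
  stats::cutree(hc, h = threshold)
}

#' Distance between named atoms of two residues in a filament
#'
#' @param filament A `filament_model`.
#' @param residue_i,residue_j Residue numbers.
#' @param offset_i,offset_j Subunit indices carrying each residue
#'   (defaults 0).
#' @param atom Atom name (default `"CA"`).
#' @return Euclidean distance in Angstrom.
#' @examples
#' # C-alpha distance of residue 47 on S+11 to residue 233 on S0
#' @export
residue_pair_distance <- function(filament, residue_i, residue_j,
                                  offset_i = 0L, offset_j = 0L, atom = "CA") {
  one <- function(res, off) {
    xyz <- subunit_coords(filament, off, atoms = atom, residues = res)
    if (nrow(xyz) != 1L || any(!is.finite(xyz))) {
      stop(sprintf("residue %d (atom %s) not modeled in subunit %d", res, atom, off),
           call. = FALSE)
    }
    xyz[1, ]
  }
  sqrt(sum((one(residue_i, offset_i) - one(residue_j, offset_j))^2))
}
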