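#' Atom table constructor
#'
#' The coordinate carrier used throughout the package: a plain data frame
#' with one row per atom.  Columns: `serial` (int), `atom` (name, e.g.
#' `"CA"`), `resname`, `chain`, `resno` (int), `element`, `x`, `y`, `z`
#' (Angstrom) and `b` (B-factor).
#'
#' @param serial,atom,resname,chain,resno,element,x,y,z,b Column vectors,
#'   recycled to a common length.
#' @return Data frame with the columns above.
#' @export
atom_table <- function(serial, atom = "CA", resname = "ALA", chain = "A",
                       resno = serial, element = "C", x = 0, y = 0, z = 0,
                       b = 0) {
  df <- data.frame(serial = as.integer(serial), atom = atom, resname = resname,
                   chain = chain, resno = as.integer(resno), element = element,
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   b = as.numeric(b))
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))) {
    stop("atom positions must be finite", call. = FALSE)
  }
  df
}

#' Protomer: one subunit with domain annotations
#'
#' @param atoms An [atom_table()] data frame (single chain).
#' @param domains Named list mapping a domain name (e.g. `"D0"`, `"D1"`,
#'   `"ND0"`, `"NL"`) to a list of residue-number ranges, each a length-2
#'   integer vector `c(first, last)`.
#' @param metadata Optional list of generator ground truth or provenance.
#' @return Object of class `protomer`.
#' @examples
#' p <- make_protomer(protomer_spec(seed = 1))
#' domain_residues(p, "D1")[1:5]
#' @export
protomer <- function(atoms, domains = list(), metadata = list()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  span <- range(atoms$resno)
  for (nm in names(domains)) {
    for (rg in domains[[nm]]) {
      if (length(rg) != 2L || rg[1] > rg[2]) {
        stop("domain ranges must be c(first, last) with first <= last", call. = FALSE)
      }
      if (rg[1] < span[1] || rg[2] > span[2]) {
        stop(sprintf("domain '%s' range [%d, %d] outside residue span [%d, %d]",
                     nm, rg[1], rg[2], span[1], span[2]), call. = FALSE)
      }
    }
  }
  d0 <- unlist(lapply(domains[["D0"]], function(r) r[1]:r[2]))
  d1 <- unlist(lapply(domains[["D1"]], function(r) r[1]:r[2]))
  if (length(intersect(d0, d1))) stop("D0 and D1 must be disjoint", call. = FALSE)
  structure(list(atoms = atoms, domains = domains, metadata = metadata),
            class = "protomer")
}

#' @export
print.protomer <- function(x, ...) {
  cat(sprintf("Protomer: %d atoms, residues %d-%d, domains: %s\n",
              nrow(x$atoms), min(x$atoms$resno), max(x$atoms$resno),
              paste(names(x$domains), collapse = ", ")))
  invisible(x)
}

#' Residue numbers belonging to a domain
#'
#' @param x A [protomer()] or `filament_model`.
#' @param name Domain name; `"D0D1"` is accepted as the union of D0 and D1.
#' @return Sorted integer vector of residue numbers.
#' @export
domain_residues <- function(x, name) {
  if (inherits(x, "filament_model")) x <- x$protomer
  stopifnot(inherits(x, "protomer"))
  nms <- if (identical(name, "D0D1")) c("D0", "D1") else name
  missing <- setdiff(nms, names(x$domains))
  if (length(missing)) {
    stop("unknown domain(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  sort(unique(unlist(lapply(nms, function(nm) {
    unlist(lapply(x$domains[[nm]], function(r) r[1]:r[2]))
  }))))
}

#' Default flagellin domain ranges
#'
#' Inferred two-domain architecture of a Bacillus subtilis-like flagellin:
#' the N- and C-terminal helices (ND0, CD0) form the inner D0 domain,
#' joined to the outer D1 domain by the NL (residues 31-47) and CL
#' (264-267) linker loops.  Only NL and CL are firmly established; the
#' remaining boundaries are a documented inference and fully configurable.
#'
#' @param last_residue Last modeled residue number (default 304).
#' @return Named list of domain range lists suitable for [protomer()].
#' @export
flagellin_domains <- function(last_residue = 304L) {
  list(
    ND0 = list(c(5L, 30L)),
    NL  = list(c(31L, 47L)),
    D1  = list(c(48L, 263L)),
    CL  = list(c(264L, 267L)),
    CD0 = list(c(268L, as.integer(last_residue))),
    D0  = list(c(5L, 30L), c(268L, as.integer(last_residue)))
  )
}

# chain id alphabet: 62 single characters, then two-character ids (mmCIF only)
.chain_ids <- function(n) {
  single <- c(LETTERS, letters, as.character(0:9))
  if (n <= length(single)) return(single[seq_len(n)])
  two <- as.vector(outer(single, single, paste0))
  c(single, two)[seq_len(n)]
}

#' Read an atomic model from PDB or mmCIF
#'
#' Coordinate records only (`ATOM`/`HETATM`, or the `_atom_site` loop); no
#' header metadata is interpreted.  Single-chain files are returned as a
#' [protomer()] (domains unset), multi-chain files as a bare atom table
#' which [apply_symmetry()] consumers can split by chain.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param as `"auto"`, `"protomer"` or `"atoms"`.
#' @return A [protomer()] or an [atom_table()] data frame.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           as = c("auto", "protomer", "atoms")) {
  format <- match.arg(format)
  as <- match.arg(as)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  atoms <- if (format == "pdb") .read_pdb(path) else .read_cif(path)
  if (as == "atoms" || (as == "auto" && length(unique(atoms$chain)) > 1L)) {
    atoms
  } else {
    protomer(atoms)
  }
}

.read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(keep)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  rec <- lines[keep]
  ln <- which(keep)
  fx <- function(from, to) trimws(substr(rec, from, to))
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(fx(from, to)))
    if (any(is.na(v))) {
      bad <- ln[which(is.na(v))[1]]
      stop(sprintf("malformed %s field at line %d of %s", what, bad, path),
           call. = FALSE)
    }
    v
  }
  atom_table(
    serial = num(7, 11, "serial"), atom = fx(13, 16), resname = fx(18, 20),
    chain = fx(22, 22), resno = num(23, 26, "residue number"),
    element = fx(77, 78),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    b = suppressWarnings(as.numeric(replace(fx(61, 66), fx(61, 66) == "", "0")))
  )
}

.read_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tags <- grep("^_atom_site\\.", lines)
  if (!length(tags)) stop("no _atom_site loop in ", path, call. = FALSE)
  fields <- sub("^_atom_site\\.", "", trimws(lines[tags]))
  body_start <- max(tags) + 1L
  body <- character()
  for (i in body_start:length(lines)) {
    l <- trimws(lines[i])
    if (l == "" || grepl("^(#|loop_|_|data_)", l)) break
    body <- c(body, l)
  }
  if (!length(body)) stop("empty _atom_site loop in ", path, call. = FALSE)
  mat <- do.call(rbind, strsplit(body, "[[:space:]]+"))
  if (ncol(mat) != length(fields)) {
    stop("malformed _atom_site loop in ", path, ": ", ncol(mat), " values for ",
         length(fields), " fields", call. = FALSE)
  }
  colnames(mat) <- fields
  get <- function(...) {
    for (nm in c(...)) if (nm %in% fields) return(mat[, nm])
    NULL
  }
  atom_table(
    serial = as.integer(get("id")),
    atom = get("label_atom_id", "auth_atom_id"),
    resname = get("label_comp_id", "auth_comp_id"),
    chain = get("auth_asym_id", "label_asym_id"),
    resno = as.integer(get("auth_seq_id", "label_seq_id")),
    element = get("type_symbol"),
    x = as.numeric(mat[, "Cartn_x"]), y = as.numeric(mat[, "Cartn_y"]),
    z = as.numeric(mat[, "Cartn_z"]),
    b = if (is.null(get("B_iso_or_equiv"))) 0 else as.numeric(get("B_iso_or_equiv"))
  )
}

#' Write an atomic model to PDB or mmCIF
#'
#' PDB coordinates are written at the format's precision (3 decimals) and
#' are limited to 62 single-character chain identifiers; models with more
#' chains must be written as mmCIF.
#'
#' @param x A [protomer()], `filament_model` or [atom_table()] data frame.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  atoms <- if (inherits(x, "protomer")) x$atoms
           else if (inherits(x, "filament_model")) x$atoms
           else x
  stopifnot(is.data.frame(atoms))
  if (format == "pdb") {
    chains <- unique(atoms$chain)
    if (length(chains) > 62L || any(nchar(chains) > 1L)) {
      stop("more than 62 chains (or multi-character chain ids): write mmCIF instead",
           call. = FALSE)
    }
    .write_pdb(atoms, path)
  } else {
    .write_cif(atoms, path)
  }
  invisible(path)
}

.write_pdb <- function(atoms, path) {
  name <- ifelse(nchar(atoms$atom) >= 4, atoms$atom,
                 paste0(" ", formatC(atoms$atom, width = -3)))
  rec <- sprintf("ATOM  %5d %-4s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 atoms$serial %% 100000L, name, atoms$resname, atoms$chain,
                 atoms$resno, atoms$x, atoms$y, atoms$z, 1, atoms$b,
                 atoms$element)
  writeLines(c(rec, "END"), path)
}

.write_cif <- function(atoms, path) {
  hdr <- c("data_flagsym", "#", "loop_",
           paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                   "label_atom_id", "label_comp_id",
                                   "label_asym_id", "label_seq_id",
                                   "auth_asym_id", "auth_seq_id",
                                   "Cartn_x", "Cartn_y", "Cartn_z",
                                   "B_iso_or_equiv")))
  rec <- sprintf("ATOM %d %s %s %s %s %d %s %d %.3f %.3f %.3f %.2f",
                 atoms$serial, atoms$element, atoms$atom, atoms$resname,
                 atoms$chain, atoms$resno, atoms$chain, atoms$resno,
                 atoms$x, atoms$y, atoms$z, atoms$b)
  writeLines(c(hdr, rec, "#"), path)
}
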