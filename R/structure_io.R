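#' Read heavy-atom records from a PDB structure
#'
#' Parses ATOM records of the first model of a PDB file (or PDB-format text),
#' drops hydrogens and waters, resolves alternate locations by keeping the
#' highest-occupancy altloc (ties go to the first listed), and retains a single
#' chain.
#'
#' @param source path to a PDB file, or a character string of PDB-format text.
#' @param chain chain identifier to retain; default the first chain present.
#' @param include_hetatm keep HETATM records (waters are always removed).
#' @return a data frame of atom records with columns `serial`, `atom_name`,
#'   `element`, `residue_name`, `residue_seq`, `chain_id`, `altloc`, `x`, `y`,
#'   `z`, `occupancy`, one row per retained heavy atom.
#' @export
read_pdb <- function(source, chain = NULL, include_hetatm = FALSE) {
  stopifnot(is.character(source), length(source) == 1)
  path <- source
  if (grepl("\n", source, fixed = TRUE) || !file.exists(source)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(source, path)
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (!include_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(at) == 0) stop("empty atom selection")

  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("empty atom selection for chain ", chain)
  if (any(!is.na(at$insert) & at$insert != "")) {
    stop("insertion codes are not supported (residue ",
         at$resno[which(!is.na(at$insert) & at$insert != "")[1]], ")")
  }

  # hydrogen / deuterium filter: element symbol if present, else atom-name rule
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- sub("^[0-9]*", "", at$elety)
    elem <- substr(elem, 1, 1)
  }
  elem <- trimws(elem)
  is_h <- toupper(elem) %in% c("H", "D") |
    grepl("^[0-9]*[HD]", toupper(trimws(at$elety)))
  at <- at[!is_h, , drop = FALSE]
  elem <- elem[!is_h]
  if (nrow(at) == 0) stop("empty atom selection after hydrogen filtering")

  # altloc resolution: per (residue, atom name), keep highest occupancy,
  # ties resolved in file order
  at$alt[is.na(at$alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$resno, at$elety)
  ord <- order(key, -occ, seq_len(nrow(at)))
  keep <- !duplicated(key[ord])
  sel <- sort(ord[keep])
  at <- at[sel, , drop = FALSE]
  elem <- elem[sel]

  out <- data.frame(
    serial = at$eleno,
    atom_name = trimws(at$elety),
    element = toupper(elem),
    residue_name = at$resid,
    residue_seq = at$resno,
    chain_id = at$chain,
    altloc = at$alt,
    x = at$x, y = at$y, z = at$z,
    occupancy = occ[sel],
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(out[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")

  missing_ca <- setdiff(unique(out$residue_seq),
                        out$residue_seq[out$atom_name == "CA"])
  if (length(missing_ca) > 0) {
    rn <- out$residue_name[match(missing_ca[1], out$residue_seq)]
    stop("missing CA in residue ", rn, missing_ca[1])
  }
  out
}

#' Build the heavy-atom native contact map
#'
#' A residue pair (i, j) is a native contact when any two heavy atoms of the
#' two residues are closer than `cutoff` and the sequence separation satisfies
#' `j - i >= min_seq_sep` (which excludes pairs sharing a pseudo-bond or
#' pseudo-dihedral). The equilibrium contact length is the C-alpha distance.
#'
#' @param atoms atom records from [read_pdb()] (or a fixture atom table).
#' @param cutoff heavy-atom distance cutoff in Angstrom.
#' @param min_seq_sep minimum residue-index separation.
#' @return data frame with columns `i`, `j` (1-based internal residue indices,
#'   i < j, sorted, duplicate-free) and `r0` (native C-alpha distance, Angstrom).
#' @export
build_contact_map <- function(atoms, cutoff = 4.5, min_seq_sep = 4) {
  res <- sort(unique(atoms$residue_seq))
  n <- length(res)
  ridx <- match(atoms$residue_seq, res)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  ca <- atoms$atom_name == "CA"
  if (sum(ca) != n) stop("every residue needs exactly one CA atom")
  ca_xyz <- xyz[ca, , drop = FALSE][order(ridx[ca]), , drop = FALSE]

  d2 <- as.matrix(stats::dist(xyz))^2
  cut2 <- cutoff^2
  hit <- which(d2 < cut2, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  ri <- ridx[hit[, 1]]
  rj <- ridx[hit[, 2]]
  lo <- pmin(ri, rj)
  hi <- pmax(ri, rj)
  ok <- (hi - lo) >= min_seq_sep
  pairs <- unique(data.frame(i = lo[ok], j = hi[ok]))
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs$r0 <- sqrt(rowSums((ca_xyz[pairs$i, , drop = FALSE] -
                              ca_xyz[pairs$j, , drop = FALSE])^2))
  pairs
}

#' Extract the coarse-grained native topology
#'
#' Collects C-alpha coordinates, residue labels, native bonded geometry (bond
#' lengths, pseudo-bond angles, signed pseudo-dihedrals in (-pi, pi]) and the
#' native contact list into the reference object used by the Go model and the
#' entanglement analysis.
#'
#' @param atoms atom records from [read_pdb()].
#' @param contacts contact map from [build_contact_map()]; computed with
#'   defaults when omitted.
#' @return a `native_topology` object.
#' @export
extract_native_geometry <- function(atoms, contacts = NULL) {
  if (is.null(contacts)) contacts <- build_contact_map(atoms)
  res <- sort(unique(atoms$residue_seq))
  if (length(res) < 4) stop("fewer than 4 residues: no dihedral definable")
  ca <- atoms[atoms$atom_name == "CA", , drop = FALSE]
  ca <- ca[order(ca$residue_seq), , drop = FALSE]
  labels <- paste0(bio3d::aa321(ca$residue_name), ca$residue_seq)
  native_topology(as.matrix(ca[, c("x", "y", "z")]), contacts, labels)
}

#' Construct a native topology from C-alpha coordinates
#'
#' Low-level constructor shared by [extract_native_geometry()] and the
#' synthetic fixtures. Validates the contact list: i < j, j - i >= 4 (every
#' contact must define a valid loop), positive contact lengths, sorted and
#' duplicate-free.
#'
#' @param ca N x 3 matrix of C-alpha coordinates (Angstrom).
#' @param contacts data frame with columns `i`, `j`, and optionally `r0`
#'   (recomputed from `ca` when missing).
#' @param labels residue labels (one-letter code + PDB number); generated
#'   as G1..GN when omitted.
#' @return a `native_topology` object: a list with `n_residues`, `ca`,
#'   `residue_labels`, `bond_lengths`, `angles`, `dihedrals`, `contacts`,
#'   and a `degenerate_dihedrals` flag vector for collinear quadruplets.
#' @export
native_topology <- function(ca, contacts, labels = NULL) {
  ca <- as.matrix(ca)
  storage.mode(ca) <- "double"
  n <- nrow(ca)
  if (n < 2) stop("need at least 2 residues")
  if (any(!is.finite(ca))) stop("non-finite coordinates")
  contacts <- as.data.frame(contacts)
  if (nrow(contacts) > 0) {
    stopifnot(all(contacts$j > contacts$i))
    if (any(contacts$j - contacts$i < 4))
      stop("contacts must satisfy j - i >= 4 to define a loop")
    if (anyDuplicated(contacts[, c("i", "j")]) > 0) stop("duplicate contacts")
    contacts <- contacts[order(contacts$i, contacts$j), , drop = FALSE]
    rownames(contacts) <- NULL
    if (is.null(contacts$r0)) {
      contacts$r0 <- sqrt(rowSums((ca[contacts$i, , drop = FALSE] -
                                     ca[contacts$j, , drop = FALSE])^2))
    }
    if (any(contacts$r0 <= 0)) stop("contact lengths must be positive")
  } else {
    contacts <- data.frame(i = integer(0), j = integer(0), r0 = numeric(0))
  }
  if (is.null(labels)) labels <- paste0("G", seq_len(n))
  geo <- internal_geometry_cpp(ca)
  # flag dihedrals whose defining cross products vanish (collinear triples)
  degen <- vapply(seq_len(max(n - 3, 0)), function(i) {
    b1 <- ca[i + 1, ] - ca[i, ]
    b2 <- ca[i + 2, ] - ca[i + 1, ]
    b3 <- ca[i + 3, ] - ca[i + 2, ]
    c1 <- crossprod3(b1, b2)
    c2 <- crossprod3(b2, b3)
    sqrt(sum(c1^2)) < 1e-8 || sqrt(sum(c2^2)) < 1e-8
  }, logical(1))
  structure(list(
    n_residues = n, ca = ca, residue_labels = labels,
    bond_lengths = geo$bond_lengths, angles = geo$angles,
    dihedrals = geo$dihedrals, contacts = contacts,
    degenerate_dihedrals = degen
  ), class = "native_topology")
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' @export
print.native_topology <- function(x, ...) {
  cat("Native topology:", x$n_residues, "residues,",
      nrow(x$contacts), "native contacts\n")
  cat("  residues:", x$residue_labels[1], "...",
      x$residue_labels[x$n_residues], "\n")
  cat("  bond lengths:", sprintf("%.2f-%.2f A", min(x$bond_lengths),
                                 max(x$bond_lengths)), "\n")
  if (any(x$degenerate_dihedrals))
    cat("  note:", sum(x$degenerate_dihedrals), "degenerate (collinear) dihedrals\n")
  invisible(x)
}

#' Rebuild chain coordinates from internal geometry
#'
#' Forward kinematics: places a chain from bond lengths, bond angles and
#' signed dihedrals using the standard natural-extension reference frame. The
#' result reproduces the original chain up to a rigid motion.
#'
#' @param bond_lengths length N-1 vector (Angstrom).
#' @param angles length N-2 vector of bond angles (rad).
#' @param dihedrals length N-3 vector of signed dihedrals (rad).
#' @return N x 3 coordinate matrix.
#' @export
chain_from_internal <- function(bond_lengths, angles, dihedrals) {
  n <- length(bond_lengths) + 1
  stopifnot(length(angles) == n - 2, length(dihedrals) == n - 3)
  x <- matrix(0, n, 3)
  x[2, ] <- c(bond_lengths[1], 0, 0)
  if (n >= 3) {
    th <- angles[1]
    x[3, ] <- x[2, ] + bond_lengths[2] * c(-cos(th), sin(th), 0)
  }
  if (n >= 4) {
    for (k in 4:n) {
      d <- bond_lengths[k - 1]
      th <- angles[k - 2]
      ph <- dihedrals[k - 3]
      bc <- x[k - 1, ] - x[k - 2, ]
      bc <- bc / sqrt(sum(bc^2))
      ab <- x[k - 2, ] - x[k - 3, ]
      nv <- crossprod3(ab, bc)
      nn <- sqrt(sum(nv^2))
      if (nn < 1e-12) stop("collinear triple: dihedral frame undefined")
      nv <- nv / nn
      mv <- crossprod3(nv, bc)
      local <- c(-d * cos(th), d * sin(th) * cos(ph), d * sin(th) * sin(ph))
      x[k, ] <- x[k - 1, ] + local[1] * bc + local[2] * mv + local[3] * nv
    }
  }
  x
}

# ---------------------------------------------------------------------------
# file formats
# ---------------------------------------------------------------------------

#' Write a native topology as a JSON document
#'
#' Stores residue labels, the contact list (internal indices and residue
#' labels) and the geometry arrays. Round-trips through
#' [read_topology_json()].
#'
#' @param topology a `native_topology`.
#' @param path output file.
#' @export
write_topology_json <- function(topology, path) {
  ct <- topology$contacts
  doc <- list(
    n_residues = topology$n_residues,
    residue_labels = topology$residue_labels,
    ca = topology$ca,
    bond_lengths = topology$bond_lengths,
    angles = topology$angles,
    dihedrals = topology$dihedrals,
    contacts = list(i = ct$i, j = ct$j, r0 = ct$r0,
                    label_i = topology$residue_labels[ct$i],
                    label_j = topology$residue_labels[ct$j])
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a native topology from JSON
#' @param path file written by [write_topology_json()].
#' @return a `native_topology`.
#' @export
read_topology_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ct <- data.frame(i = doc$contacts$i, j = doc$contacts$j, r0 = doc$contacts$r0)
  if (nrow(ct) == 0) ct <- data.frame(i = integer(0), j = integer(0), r0 = numeric(0))
  native_topology(doc$ca, ct, doc$residue_labels)
}

#' Write trajectory frames as multi-frame XYZ
#' @param frames list of N x 3 coordinate matrices.
#' @param path output file.
#' @param element atom label written on each line.
#' @export
write_xyz <- function(frames, path, element = "CA") {
  if (is.matrix(frames)) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(c(as.character(nrow(fr)), "frame"), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", element, fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file
#' @param path file written by [write_xyz()].
#' @return list of N x 3 coordinate matrices.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    frames[[length(frames) + 1]] <-
      matrix(as.numeric(parts[, 2:4]), ncol = 3)
    i <- i + 2 + n
  }
  frames
}

#' Write an observable time series as TSV
#'
#' Columns: `step` (MD steps), `Q`, `Gprime` (the indicator
#' \eqn{\langle G' \rangle}), `E` (epsilon units), `RMSD` (Angstrom).
#'
#' @param series a data frame (or `observable_series`).
#' @param path output file.
#' @export
write_observables <- function(series, path) {
  df <- as.data.frame(unclass(series))[, c("step", "Q", "Gprime", "E", "RMSD")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an observable time series TSV
#' @param path file written by [write_observables()].
#' @return a data frame with class `observable_series`.
#' @export
read_observables <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  class(df) <- c("observable_series", "data.frame")
  df
}
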