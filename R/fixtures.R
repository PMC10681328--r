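#' Polygonal ring pairs with known linking number
#'
#' Generates two polygonal circles whose analytic linking number is known:
#' coplanar well-separated rings (linking 0), Hopf-linked rings (+-1, the
#' sign set by orientation), or one ring threaded twice by a doubly-winding
#' curve (+-2). The discrete Gauss double sum ([gauss_linking()]) converges
#' to `true_linking` as `n_segments` grows.
#'
#' @param n_segments vertices per curve, >= 16.
#' @param linking requested linking number, one of 0, +-1, +-2.
#' @param separation center-center clearance used for the unlinked pair
#'   (Angstrom).
#' @param radius ring radius (Angstrom).
#' @return list with `curve_a`, `curve_b` (vertex matrices), `closed = TRUE`
#'   and `true_linking`.
#' @export
make_linked_rings <- function(n_segments, linking, separation = 10, radius = 5) {
  stopifnot(n_segments >= 16)
  if (!linking %in% c(0L, 1L, -1L, 2L, -2L)) stop("unsupported linking value")
  t1 <- 2 * pi * (seq_len(n_segments) - 1) / n_segments
  a <- cbind(radius * cos(t1), radius * sin(t1), 0)
  if (linking == 0) {
    b <- cbind(2 * radius + separation + radius * cos(t1),
               radius * sin(t1), 0)
  } else if (abs(linking) == 1) {
    # Hopf link: second ring in the xz-plane through the first ring's rim
    b <- cbind(radius + radius * cos(t1), 0, radius * sin(t1))
  } else {
    # second curve winds twice through the first ring; small y-offset keeps
    # the two passes apart
    t2 <- 4 * pi * (seq_len(n_segments) - 1) / n_segments
    b <- cbind(radius + 0.6 * radius * cos(t2),
               0.15 * radius * sin(t2 / 2),
               0.6 * radius * sin(t2))
  }
  if (linking != 0) {
    g <- gauss_linking_cpp(a, b, TRUE, TRUE)
    if (sign(g) != sign(linking)) b <- b[rev(seq_len(nrow(b))), , drop = FALSE]
  }
  list(curve_a = a, curve_b = b, closed = TRUE, true_linking = as.integer(linking))
}

#' Open lasso chain with a designated loop and thread
#'
#' A single open chain: a near-closed circular loop (endpoints within contact
#' distance) followed by a connector and a straight terminal thread that
#' either passes through the loop center perpendicular to its plane
#' (`pierce = TRUE`, |G'| close to 1) or runs outside the loop
#' (`pierce = FALSE`, |G'| small). The chirality sign of the loop orientation
#' equals the sign of the resulting G'.
#'
#' @param loop_radius loop radius (Angstrom).
#' @param thread_halflength half-length of the straight thread, >=
#'   `loop_radius`.
#' @param pierce whether the thread passes through the loop.
#' @param chirality +1 or -1.
#' @param n_loop,n_thread vertex counts of loop and thread.
#' @return list with `coords`, `loop` (index pair of the loop endpoints),
#'   `thread` (index pair of the thread portion) and `chirality`.
#' @export
make_open_lasso <- function(loop_radius = 5, thread_halflength = 50,
                            pierce = TRUE, chirality = 1,
                            n_loop = 36, n_thread = 41) {
  stopifnot(thread_halflength >= loop_radius, chirality %in% c(-1, 1),
            n_thread >= 11)
  gap <- 0.6 / loop_radius  # endpoint gap, ~0.6 A of arc on each side
  th <- chirality * (gap + (seq_len(n_loop) - 1) *
                       (2 * pi - 2 * gap) / (n_loop - 1))
  loop <- cbind(loop_radius * cos(th), loop_radius * sin(th), 0)
  h <- thread_halflength
  x0 <- if (pierce) 0 else 3 * loop_radius
  zs <- seq(-h, h, length.out = n_thread)
  thread <- cbind(x0, 0, zs)
  # connector: drop below the plane outside the loop, then over to the thread
  conn <- rbind(
    c(1.6 * loop_radius, 0, -0.5 * h),
    c(max(x0, 0.8 * loop_radius), 0, -0.9 * h)
  )
  coords <- rbind(loop, conn, thread)
  list(coords = coords,
       loop = c(1L, n_loop),
       thread = c(n_loop + nrow(conn) + 1L, nrow(coords)),
       chirality = chirality)
}

#' Toy native structures for the Go model
#'
#' Self-avoiding C-alpha structures with bond lengths close to 3.8 Angstrom
#' and a contact list derived from the 4.5-Angstrom heavy-atom rule applied
#' to the pseudo-atoms (C-alpha plus one pseudo side-chain bead per residue).
#' Motifs: `"hairpin"` (two paired strands, unentangled), `"helix"` (local
#' i, i+4 contacts) and `"lasso"` (a loop closed by a contact and threaded by
#' the N-terminal segment, with at least one |G'| > 0.75 contact).
#'
#' @param n_residues chain length, >= 10 (>= 28 for the lasso motif).
#' @param motif `"hairpin"`, `"helix"` or `"lasso"`.
#' @return list with `topology` (a [native_topology()]), `native` (the N x 3
#'   native conformation) and `atoms` (the pseudo-atom table used for the
#'   contact map, in [read_pdb()] column layout).
#' @export
make_toy_native <- function(n_residues, motif = c("hairpin", "helix", "lasso")) {
  motif <- match.arg(motif)
  stopifnot(n_residues >= 10)
  built <- switch(motif,
                  hairpin = toy_hairpin(n_residues),
                  helix = toy_helix(n_residues),
                  lasso = toy_lasso(n_residues))
  atoms <- built$atoms
  contacts <- build_contact_map(atoms)
  topo <- extract_native_geometry(atoms, contacts)
  list(topology = topo, native = topo$ca, atoms = atoms)
}

fixture_atoms <- function(ca, cb = NULL) {
  n <- nrow(ca)
  df <- data.frame(
    serial = seq_len(n), atom_name = "CA", element = "C",
    residue_name = "GLY", residue_seq = seq_len(n), chain_id = "A",
    altloc = "", x = ca[, 1], y = ca[, 2], z = ca[, 3], occupancy = 1,
    stringsAsFactors = FALSE
  )
  if (!is.null(cb)) {
    keep <- !is.na(cb[, 1])
    db <- data.frame(
      serial = n + seq_len(sum(keep)), atom_name = "CB", element = "C",
      residue_name = "GLY", residue_seq = which(keep), chain_id = "A",
      altloc = "", x = cb[keep, 1], y = cb[keep, 2], z = cb[keep, 3],
      occupancy = 1, stringsAsFactors = FALSE
    )
    df <- rbind(df, db)
    df <- df[order(df$residue_seq, df$atom_name), , drop = FALSE]
    df$serial <- seq_len(nrow(df))
  }
  rownames(df) <- NULL
  df
}

# two antiparallel strands 4.55 A apart with inward CB beads; a two-residue
# turn; small alternating z offsets avoid collinear triples
toy_hairpin <- function(n) {
  s1 <- ceiling((n - 2) / 2)
  ca <- matrix(NA_real_, n, 3)
  cb <- matrix(NA_real_, n, 3)
  d <- 4.55
  zig <- 0.3 * (-1)^(seq_len(n))
  for (k in seq_len(s1)) ca[k, ] <- c(0, 3.8 * (k - 1), zig[k])
  y_top <- 3.8 * (s1 - 1)
  ca[s1 + 1, ] <- c(0.375, y_top + 3.78, 0)
  ca[s1 + 2, ] <- c(d - 0.375, y_top + 3.78, 0)
  for (m in (s1 + 3):n) ca[m, ] <- c(d, 3.8 * (n - m), zig[m])
  for (k in seq_len(s1)) cb[k, ] <- ca[k, ] + c(1.2, 0, 0)
  for (m in (s1 + 3):n) cb[m, ] <- ca[m, ] + c(-1.2, 0, 0)
  cb[s1 + 1, ] <- ca[s1 + 1, ] + c(0, 1.2, 0)
  cb[s1 + 2, ] <- ca[s1 + 2, ] + c(0, 1.2, 0)
  list(atoms = fixture_atoms(ca, cb))
}

# compressed helix (99 deg / 1.3 A rise) whose i, i+4 contacts come from a
# pseudo side chain pointing along the chain axis towards residue i+4
toy_helix <- function(n) {
  omega <- 99 * pi / 180
  r <- 2.42
  rise <- 1.3
  th <- omega * (seq_len(n) - 1)
  ca <- cbind(r * cos(th), r * sin(th), rise * (seq_len(n) - 1))
  cb <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (i + 4 <= n) {
      u <- ca[i + 4, ] - ca[i, ]
      cb[i, ] <- ca[i, ] + 1.5 * u / sqrt(sum(u^2))
    } else {
      cb[i, ] <- ca[i, ] + c(1.5 * cos(th[i]), 1.5 * sin(th[i]), 0)
    }
  }
  list(atoms = fixture_atoms(ca, cb))
}

# N-terminal thread along z through a loop in the z = 0 plane; the loop is
# closed by a CA-CA contact between its first and last residues
toy_lasso <- function(n) {
  stopifnot(n >= 28)
  n_thread <- 11
  n_conn <- 7
  n_loop <- n - n_thread - n_conn
  # loop radius from its perimeter: n_loop - 1 bonds plus the closure gap
  gap <- 4.2
  rho <- ((n_loop - 1) * 3.8 + gap) / (2 * pi)
  ca <- matrix(NA_real_, n, 3)
  for (k in seq_len(n_thread))
    ca[k, ] <- c(0, 0.25 * (-1)^k, 19 - 3.8 * (k - 1))
  z0 <- ca[n_thread, 3]
  # loop in the z = 0 plane; clockwise so the designated thread (descending
  # through it) gives a positive closure-contact G'
  th0 <- gap / (2 * rho)
  th <- th0 + (seq_len(n_loop) - 1) * (2 * pi - 2 * th0) / (n_loop - 1)
  i0 <- n_thread + n_conn
  for (k in seq_len(n_loop))
    ca[i0 + k, ] <- c(rho * cos(-th[k]), rho * sin(-th[k]), 0)
  # connector: out below the loop plane at the loop-start azimuth, then up
  # the outside of the loop rim (waypoints in the (radial, z) half-plane)
  wp <- rbind(
    c(0.49 * rho, z0 - 1.3),
    c(0.98 * rho, z0),
    c(rho + 2.7, z0 + 2.5),
    c(rho + 3.9, z0 + 6.1),
    c(rho + 3.9, z0 + 9.9),
    c(rho + 3.3, z0 + 13.65),
    c(rho + 1.9, z0 + 17.2)
  )
  phi0 <- -th0
  for (k in seq_len(n_conn)) {
    ca[n_thread + k, ] <- c(wp[k, 1] * cos(phi0), wp[k, 1] * sin(phi0),
                            wp[k, 2])
  }
  list(atoms = fixture_atoms(ca))
}

#' Synthetic per-contact formation time series
#'
#' Independent Bernoulli draws with formation probability
#' `p(t) = A - B exp(-k t)` at integer times t = 0, ..., n_steps - 1; the
#' parameter-recovery ground truth for the kinetics fit.
#'
#' @param A saturation probability.
#' @param B gain, with `0 <= A - B <= A <= 1`.
#' @param k rate per MD step, > 0.
#' @param n_traj number of trajectories.
#' @param n_steps series length.
#' @param seed RNG seed.
#' @return `n_traj` x `n_steps` binary matrix (one row per trajectory), with
#'   attribute `p_true` holding p(t).
#' @export
make_synthetic_kinetics <- function(A, B, k, n_traj, n_steps, seed) {
  if (!(A - B >= 0 && A - B <= A && A <= 1)) stop("invalid probability bounds")
  if (k <= 0) stop("k must be positive")
  set.seed(seed)
  t <- seq_len(n_steps) - 1
  p <- A - B * exp(-k * t)
  m <- matrix(rbinom(n_traj * n_steps, 1, rep(p, each = n_traj)),
              nrow = n_traj)
  attr(m, "p_true") <- p
  m
}

# centroids of the named regions in the (Q, <G'>) plane
region_centroids <- function() {
  rbind(
    U = c(0.1875, 0),
    IT = c(0.625, -0.2 * 0.625 + 0.1),
    `IE-` = c(0.39, -1.07 * 0.39 - 0.185),
    F = c(0.875, -0.75)
  )
}

#' Scripted (Q, <G'>) series for the pathway classifier
#'
#' Emits a reaction-coordinate series that sits at the centroid of each named
#' region for the scripted duration, with small additive jitter (well inside
#' the region margins), so the classification a series should receive is
#' known by construction.
#'
#' @param script list of `(state_label, duration)` pairs, labels among
#'   `"U"`, `"IT"`, `"IE-"`, `"F"`; durations in MD steps and larger than the
#'   rolling window used by the classifier.
#' @param jitter additive jitter amplitude in both coordinates.
#' @param seed RNG seed.
#' @return data frame (`observable_series`) with `step`, `Q`, `Gprime`.
#' @export
make_scripted_series <- function(script, jitter = 0.02, seed = 1) {
  cen <- region_centroids()
  labs <- vapply(script, function(s) as.character(s[[1]]), character(1))
  durs <- vapply(script, function(s) as.numeric(s[[2]]), numeric(1))
  if (!all(labs %in% rownames(cen))) {
    stop("unknown label: ", paste(setdiff(labs, rownames(cen)), collapse = ", "))
  }
  set.seed(seed)
  q <- unlist(mapply(function(l, d) rep(cen[l, 1], d), labs, durs,
                     SIMPLIFY = FALSE))
  g <- unlist(mapply(function(l, d) rep(cen[l, 2], d), labs, durs,
                     SIMPLIFY = FALSE))
  nt <- length(q)
  df <- data.frame(step = seq_len(nt),
                   Q = q + runif(nt, -jitter, jitter),
                   Gprime = g + runif(nt, -jitter, jitter))
  class(df) <- c("observable_series", "data.frame")
  df
}

#' Write fixture atoms as minimal PDB ATOM records
#'
#' The fixture-side PDB writer: C-alpha (and pseudo side-chain) beads as
#' standard fixed-width ATOM records, so fixtures round-trip through
#' [read_pdb()] and external tools.
#'
#' @param atoms atom table in [read_pdb()] column layout.
#' @param path output file.
#' @export
write_fixture_pdb <- function(atoms, path) {
  lines <- sprintf(
    "ATOM  %5d %4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
    atoms$serial,
    formatC(atoms$atom_name, width = -4),
    atoms$residue_name, atoms$chain_id, atoms$residue_seq,
    atoms$x, atoms$y, atoms$z, atoms$occupancy, 0,
    atoms$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
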