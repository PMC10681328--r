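#' Go-model parameters
#'
#' Energy parameters of the C-alpha structure-based potential, in units of the
#' overall energy scale epsilon. Defaults: bond stiffness 100, angle stiffness
#' 20, dihedral / native-contact / excluded-volume amplitudes 1, excluded
#' volume size `sigma_nn = 4` Angstrom (repulsion truncated at
#' `2^(1/6) sigma_nn` and shifted to zero there), native 12/6 Lennard-Jones
#' truncated (not shifted) beyond `2.5 sigma_ij` with
#' `sigma_ij = 2^(-1/6) r0_ij` so the minimum -epsilon sits at the native
#' distance. A contact counts as formed when `r < g * r0` with `g = 1.2`.
#'
#' The alternative `"12-10"` flavour uses
#' `eps * (5 (r0/r)^12 - 6 (r0/r)^10)` (same minimum -epsilon at r0), plainly
#' truncated at `flavour_1210_cutoff_factor * r0`.
#'
#' @param epsilon overall energy scale (reduced units).
#' @param lj_flavour `"12-6"` (default) or `"12-10"`.
#' @param g contact-formation factor.
#' @param flavour_1210_cutoff_factor truncation radius factor for the 12/10
#'   flavour (in units of r0).
#' @return list of parameters consumed by [potential_energy()], [forces()]
#'   and [run_langevin()].
#' @export
go_parameters <- function(epsilon = 1, lj_flavour = c("12-6", "12-10"),
                          g = 1.2, flavour_1210_cutoff_factor = 3) {
  lj_flavour <- match.arg(lj_flavour)
  list(
    epsilon = epsilon,
    eps_bond = 100 * epsilon,
    eps_angle = 20 * epsilon,
    eps_dihedral = epsilon,
    eps_contact = epsilon,
    eps_nn = epsilon,
    sigma_nn = 4,
    native_cutoff_factor = 2.5,
    lj_flavour = lj_flavour,
    flavour_1210_cutoff_factor = flavour_1210_cutoff_factor,
    g = g
  )
}

topo_args <- function(topology) {
  list(
    r0_bond = as.numeric(topology$bond_lengths),
    theta0 = as.numeric(topology$angles),
    phi0 = as.numeric(topology$dihedrals),
    ci = as.integer(topology$contacts$i),
    cj = as.integer(topology$contacts$j),
    r0_c = as.numeric(topology$contacts$r0)
  )
}

as_coords <- function(conf) {
  x <- if (is.list(conf) && !is.null(conf$coords)) conf$coords else conf
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' Go-model potential energy
#'
#' Evaluates the structure-based potential: harmonic bonds and angles,
#' the periodic dihedral term
#' `eps * ((1 - cos(dphi)) + (1 - cos(3 dphi)) / 2)`, native-contact
#' Lennard-Jones attraction, and shifted-truncated excluded-volume repulsion
#' between all non-native pairs with j >= i + 2.
#'
#' @param conf N x 3 coordinate matrix (or a list with a `coords` element).
#' @param topology a [native_topology()].
#' @param params see [go_parameters()].
#' @return list with `total` (epsilon units) and the named `components`
#'   vector (bond, angle, dihedral, native, nonnative).
#' @export
potential_energy <- function(conf, topology, params = go_parameters()) {
  x <- as_coords(conf)
  stopifnot(nrow(x) == topology$n_residues)
  a <- topo_args(topology)
  r <- go_energy_cpp(x, a$r0_bond, a$theta0, a$phi0, a$ci, a$cj, a$r0_c, params)
  list(total = r$total, components = r$components)
}

#' Analytic Go-model forces
#'
#' Negative gradient of every term of [potential_energy()], including the
#' chain-rule terms of the angle and (four-body) dihedral contributions.
#' Discontinuities at the plain truncation radii are accepted. Near-collinear
#' angles are regularized by clamping cos(theta).
#'
#' @inheritParams potential_energy
#' @return N x 3 force matrix (epsilon / Angstrom).
#' @export
forces <- function(conf, topology, params = go_parameters()) {
  x <- as_coords(conf)
  stopifnot(nrow(x) == topology$n_residues)
  a <- topo_args(topology)
  r <- go_forces_cpp(x, a$r0_bond, a$theta0, a$phi0, a$ci, a$cj, a$r0_c, params)
  r$forces
}

#' Fraction of native contacts
#'
#' Q = (number of native pairs with r_ij < g r0_ij) / (total native
#' contacts), with a strict inequality at the boundary. The formed-contact
#' list feeds [entanglement_indicator()].
#'
#' @inheritParams potential_energy
#' @param g contact-formation factor (default from `params` if given).
#' @return list with `q` and logical vector `formed` (one entry per native
#'   contact, in topology order).
#' @export
fraction_native <- function(conf, topology, g = 1.2) {
  x <- as_coords(conf)
  if (nrow(topology$contacts) == 0) stop("topology has no native contacts")
  fraction_native_cpp(x, as.integer(topology$contacts$i),
                      as.integer(topology$contacts$j),
                      as.numeric(topology$contacts$r0), g)
}

#' Optimal-superposition RMSD to the native structure
#'
#' Minimal C-alpha RMSD after optimal rigid superposition (Kabsch, rotation +
#' translation, no reflection).
#'
#' @inheritParams potential_energy
#' @return RMSD in Angstrom.
#' @export
rmsd_to_native <- function(conf, topology) {
  x <- as_coords(conf)
  kabsch_rmsd(x, topology$ca)
}

# Kabsch superposition RMSD of two N x 3 point sets (no reflection).
kabsch_rmsd <- function(x, y) {
  stopifnot(nrow(x) == nrow(y))
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  s <- svd(crossprod(xc, yc))   # X^T Y = U D V^T; R = V' U^T, no reflection
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((xc %*% t(rot) - yc)^2)))
}
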