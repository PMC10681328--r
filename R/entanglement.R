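#' Default Hill-weight parameters for the entanglement indicator
#'
#' The indicator weights each loop's Gaussian entanglement with an activation
#' Hill function of |G'|: `h = 1 / (1 + (g0/|G'|)^m)`. With the default
#' threshold `g0 = 0.5` a loop threaded once (|G'| near 1) weighs close to 1,
#' an unentangled loop close to 0, and `h(g0) = 1/2` exactly. The cooperativity
#' index `m = 3` sets how sharp the activation is.
#'
#' @param g0 activation threshold (dimensionless), > 0.
#' @param m cooperativity index, >= 1.
#' @return list with `g0` and `m`.
#' @export
hill_params <- function(g0 = 0.5, m = 3) {
  stopifnot(g0 > 0, m >= 1)
  list(g0 = g0, m = m)
}

#' Activation Hill weight of an entanglement magnitude
#'
#' @param g_abs |G'| value(s), >= 0.
#' @param params see [hill_params()].
#' @return weight(s) in \[0, 1); 0 at `g_abs = 0` (the limit of the Hill form).
#' @export
hill_weight <- function(g_abs, params = hill_params()) {
  stopifnot(all(g_abs >= 0))
  ifelse(g_abs > 0, 1 / (1 + (params$g0 / g_abs)^params$m), 0)
}

#' Per-bond-pair Gauss terms of a chain
#'
#' Entry (i, j) is the discrete Gauss kernel
#' \eqn{(1/4\pi)\,(R_i - R_j)/|R_i - R_j|^3 \cdot (\Delta R_i \times \Delta R_j)}
#' built from bond midpoints \eqn{R_i} and bond vectors \eqn{\Delta R_i}.
#' The matrix is symmetric under swapping (i, j) and has a zero diagonal;
#' coincident bond midpoints (self-intersecting chain) give a zero entry with
#' a warning.
#'
#' @param coords N x 3 coordinate matrix.
#' @return (N-1) x (N-1) matrix of Gauss terms.
#' @export
gauss_pair_matrix <- function(coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  gauss_pair_matrix_cpp(coords)
}

#' Gaussian entanglement of a loop-thread pair
#'
#' The discrete Gauss double sum over the bonds of two non-overlapping
#' portions of one chain: the loop (i1, i2), closed by a native contact, and
#' the thread (j1, j2). Real valued; near +-1 when the thread pierces the loop
#' once, with the sign encoding chirality.
#'
#' @param coords N x 3 coordinate matrix.
#' @param loop integer pair (i1, i2) with i2 - i1 >= 4.
#' @param thread integer pair (j1, j2) with j2 - j1 >= 10, sharing no bond
#'   with the loop (j2 <= i1 or j1 >= i2).
#' @param pair_matrix optional precomputed [gauss_pair_matrix()].
#' @param mi,mj minimal loop / thread lengths enforced.
#' @return G' (scalar).
#' @export
gaussian_entanglement <- function(coords, loop, thread, pair_matrix = NULL,
                                  mi = 4, mj = 10) {
  i1 <- loop[1]; i2 <- loop[2]; j1 <- thread[1]; j2 <- thread[2]
  n <- nrow(coords)
  if (i2 - i1 < mi) stop("loop shorter than m_i = ", mi)
  if (j2 - j1 < mj) stop("thread shorter than m_j = ", mj)
  if (!(j2 <= i1 || j1 >= i2)) stop("thread overlaps the loop")
  if (i1 < 1 || i2 > n || j1 < 1 || j2 > n) stop("index out of bounds")
  M <- if (is.null(pair_matrix)) gauss_pair_matrix(coords) else pair_matrix
  sum(M[i1:(i2 - 1), j1:(j2 - 1)])
}

#' Maximal-entanglement thread of a loop
#'
#' Maximizes |G'| over every contiguous thread (j1, j2) with j2 - j1 >= `mj`
#' lying entirely on one side of the loop. Implemented with per-column
#' loop-row sums and 1-D prefix sums, so the scan over all intervals is linear
#' after the prefix pass. Ties are broken towards smaller j1, then smaller j2.
#'
#' @param coords N x 3 coordinate matrix.
#' @param loop integer pair (i1, i2), i2 - i1 >= 4.
#' @param pair_matrix optional precomputed [gauss_pair_matrix()].
#' @param mj minimal thread length (residue-index span).
#' @return an `entanglement_record`: list with `loop`, `thread`, `g_prime`
#'   and `flagged` (TRUE when the chain admits no thread, in which case
#'   `g_prime = 0` and the thread is empty).
#' @export
max_thread <- function(coords, loop, pair_matrix = NULL, mj = 10) {
  if (loop[2] - loop[1] < 4) stop("loop shorter than m_i = 4")
  M <- if (is.null(pair_matrix)) gauss_pair_matrix(coords) else pair_matrix
  n <- nrow(M) + 1
  r <- max_thread_cpp(M, loop[1], loop[2], n, mj)
  flagged <- r[1] == 0
  structure(list(
    loop = as.integer(loop),
    thread = if (flagged) integer(0) else as.integer(r[1:2]),
    g_prime = r[3], flagged = flagged
  ), class = "entanglement_record")
}

#' @export
print.entanglement_record <- function(x, ...) {
  if (x$flagged) {
    cat(sprintf("loop (%d, %d): no admissible thread, G' = 0\n",
                x$loop[1], x$loop[2]))
  } else {
    cat(sprintf("loop (%d, %d), thread (%d, %d): G' = %.3f\n",
                x$loop[1], x$loop[2], x$thread[1], x$thread[2], x$g_prime))
  }
  invisible(x)
}

#' Whole-configuration entanglement indicator
#'
#' For every formed native contact, treats the enclosed chain portion as a
#' loop, searches its maximal thread on the current coordinates, and averages
#' the per-loop G' values with activation Hill weights:
#' \eqn{\langle G' \rangle = \sum_i G'_i h(|G'_i|) / \sum_i h(|G'_i|)}.
#' A contact-free snapshot (or one in which all weights vanish) yields an
#' indicator of 0, flagged.
#'
#' @param coords N x 3 coordinate matrix.
#' @param formed_contacts data frame (or 2-column matrix) of formed contacts
#'   `i`, `j`, each with j - i >= 4.
#' @param params Hill parameters, see [hill_params()].
#' @param mj minimal thread length.
#' @return a `snapshot_entanglement`: list with `records` data frame
#'   (i, j, j1, j2, g_prime, h), `H`, `indicator` and `flagged`.
#' @export
entanglement_indicator <- function(coords, formed_contacts,
                                   params = hill_params(), mj = 10) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  fc <- as.data.frame(formed_contacts)
  if (ncol(fc) >= 2) names(fc)[1:2] <- c("i", "j")
  if (nrow(fc) == 0) {
    return(structure(list(
      records = data.frame(i = integer(0), j = integer(0), j1 = integer(0),
                           j2 = integer(0), g_prime = numeric(0), h = numeric(0)),
      H = 0, indicator = 0, flagged = TRUE
    ), class = "snapshot_entanglement"))
  }
  if (any(fc$j - fc$i < 4)) stop("formed contacts must satisfy j - i >= 4")
  r <- snapshot_entanglement_cpp(coords, as.integer(fc$i), as.integer(fc$j),
                                 as.integer(mj), params$g0, params$m)
  structure(list(
    records = data.frame(i = fc$i, j = fc$j, j1 = r$j1, j2 = r$j2,
                         g_prime = r$gprime, h = r$h),
    H = r$H, indicator = r$indicator, flagged = r$H <= 0
  ), class = "snapshot_entanglement")
}

#' @export
print.snapshot_entanglement <- function(x, ...) {
  cat(sprintf("snapshot entanglement: %d loops, <G'> = %.3f%s\n",
              nrow(x$records), x$indicator,
              if (x$flagged) " (no active loops)" else ""))
  invisible(x)
}

#' Count entangled loops
#'
#' Counts per-contact entanglement records beyond a threshold, either
#' one-sided on the signed G' (`mode = "below"`: G' strictly below
#' `threshold`, the natural convention for negative-chirality entanglement)
#' or on the magnitude (`mode = "abs_above"`: |G'| strictly above).
#'
#' @param records data frame with a `g_prime` column (e.g. from
#'   [entanglement_indicator()]), or a vector of G' values.
#' @param threshold threshold value.
#' @param mode `"below"` or `"abs_above"`.
#' @return integer count.
#' @export
count_entangled <- function(records, threshold, mode = c("below", "abs_above")) {
  mode <- match.arg(mode)
  g <- if (is.data.frame(records)) records$g_prime else as.numeric(records)
  if (length(g) == 0) return(0L)
  if (mode == "below") sum(g < threshold) else sum(abs(g) > threshold)
}

#' Gauss linking double sum of two curves
#'
#' The discrete Gauss double sum between two separate polygonal curves.
#' For closed curves this converges to the integer linking number as the
#' discretization is refined; for open curves it is the real-valued Gaussian
#' entanglement.
#'
#' @param curve_a,curve_b vertex matrices (n x 3).
#' @param closed_a,closed_b whether each curve wraps around (a bond connects
#'   the last vertex to the first).
#' @return the Gauss sum (scalar).
#' @export
gauss_linking <- function(curve_a, curve_b, closed_a = TRUE, closed_b = TRUE) {
  gauss_linking_cpp(as.matrix(curve_a), as.matrix(curve_b), closed_a, closed_b)
}
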