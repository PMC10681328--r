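#' Two-dimensional negative-log KDE landscape in (Q, <G'>)
#'
#' Gaussian product-kernel density estimate of the sample cloud, evaluated on
#' a regular grid, with per-dimension Scott's-rule bandwidths (sample
#' standard deviation times n^(-1/6) for two dimensions). The landscape is
#' the negative log of the density, shifted so its minimum is 0; for
#' equilibrium samples those units are k_B T.
#'
#' @param samples data frame or 2-column matrix of (Q, <G'>) points,
#'   >= 100 rows.
#' @param grid_q,grid_g evaluation grids (defaults span the samples with a
#'   small margin).
#' @param n_grid grid points per dimension when defaults are used.
#' @param contour_step contour spacing recorded in the result
#'   (log-histogram units).
#' @return a `landscape_grid`: list with `q`, `g`, `neg_log_density`
#'   (matrix, rows follow `q`), `bandwidths`, `contour_step`.
#' @export
kde_landscape <- function(samples, grid_q = NULL, grid_g = NULL, n_grid = 60,
                          contour_step = 0.4) {
  m <- as.matrix(as.data.frame(samples)[, 1:2])
  stopifnot(nrow(m) >= 100)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) stop("zero variance in a dimension")
  bw <- sds * nrow(m)^(-1 / 6)
  if (is.null(grid_q)) grid_q <- seq(min(m[, 1]) - 2 * bw[1],
                                     max(m[, 1]) + 2 * bw[1],
                                     length.out = n_grid)
  if (is.null(grid_g)) grid_g <- seq(min(m[, 2]) - 2 * bw[2],
                                     max(m[, 2]) + 2 * bw[2],
                                     length.out = n_grid)
  # product kernel: outer sums of 1-D Gaussian weights
  wq <- outer(grid_q, m[, 1], function(a, b) stats::dnorm(a, b, bw[1]))
  wg <- outer(grid_g, m[, 2], function(a, b) stats::dnorm(a, b, bw[2]))
  dens <- (wq %*% t(wg)) / nrow(m)
  nld <- -log(pmax(dens, 1e-300))
  nld <- nld - min(nld)
  structure(list(q = grid_q, g = grid_g, neg_log_density = nld,
                 bandwidths = bw, contour_step = contour_step),
            class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf(
    "Landscape grid %d x %d, bandwidths (%.4f, %.4f), contour step %.1f\n",
    length(x$q), length(x$g), x$bandwidths[1], x$bandwidths[2],
    x$contour_step))
  invisible(x)
}

#' Named ensemble regions in the (Q, <G'>) plane
#'
#' Closed-form membership predicates for the ensembles used to read the
#' refolding landscape: the unfolded (U) and folded (F) boxes, the
#' transition-state Q band (TSE), and the two rhomboidal intermediate
#' regions -- the non-entangled kinetic trap IT and the natively entangled
#' short-lived intermediate IE-. Box bounds are closed intervals; the
#' rhomboid bounds on <G'> are strict, exactly as defined.
#'
#' @param q_tse TSE center on Q.
#' @param delta_q TSE half-width.
#' @return a `region_set` list of predicate parameters.
#' @export
region_set <- function(q_tse = 0.5, delta_q = 0.03) {
  structure(list(q_tse = q_tse, delta_q = delta_q), class = "region_set")
}

#' Region membership of a (Q, <G'>) point
#'
#' Evaluates the region predicates: U is Q in \[0, 0.375\] and <G'> in
#' \[-0.25, 0.25\]; F is Q in \[0.75, 1\] and <G'> in \[-1, -0.5\]; IT is
#' Q in \[0.5, 0.75\] with -0.2 Q < <G'> < -0.2 Q + 0.2; IE- is Q in
#' \[0.32, 0.46\] with -1.07 Q - 0.26 < <G'> < -1.07 Q - 0.11. Returns the
#' unique matching label or NA.
#'
#' @param point numeric pair (Q, <G'>), or a 2-column matrix of points.
#' @param regions a [region_set()].
#' @return character label(s) among "U", "F", "IT", "IE-", or NA.
#' @export
region_membership <- function(point, regions = region_set()) {
  m <- if (is.matrix(point) || is.data.frame(point)) as.matrix(point)
       else matrix(point, ncol = 2)
  q <- m[, 1]
  g <- m[, 2]
  lab <- rep(NA_character_, length(q))
  lab[q >= 0 & q <= 0.375 & g >= -0.25 & g <= 0.25] <- "U"
  lab[q >= 0.75 & q <= 1 & g >= -1 & g <= -0.5] <- "F"
  it <- q >= 0.5 & q <= 0.75 & g > -0.2 * q & g < -0.2 * q + 0.2
  lab[it] <- "IT"
  ie <- q >= 0.32 & q <= 0.46 & g > -1.07 * q - 0.26 & g < -1.07 * q - 0.11
  lab[ie] <- "IE-"
  if (length(lab) == 1) lab[1] else lab
}

#' Membership in the transition-state ensemble Q band
#'
#' @param q fraction of native contacts.
#' @param regions a [region_set()].
#' @return logical.
#' @export
in_tse <- function(q, regions = region_set()) {
  q >= regions$q_tse - regions$delta_q & q <= regions$q_tse + regions$delta_q
}

rolling_mean_centered <- function(x, window) {
  n <- length(x)
  half <- window %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Classify a refolding trajectory into a folding pathway
#'
#' Applies a centered rolling average (default window 555 MD steps, shrunken
#' at the endpoints) to both reaction coordinates, labels each smoothed point
#' by [region_membership()], compresses the label stream into the visited
#' sequence (dropping unlabeled points and merging consecutive duplicates),
#' and applies the pathway rules: a trajectory that reaches F without ever
#' visiting IT folds through the fast channel ("fast_folding"); one that
#' visits IT and whose last non-F state is IT folds by "threading"; last
#' non-F state U after visiting IT is "backtracking"; never reaching F while
#' ending in IT is "trapped"; a series with no labeled state at all is
#' "unclassified".
#'
#' @param series an `observable_series` (columns `Q`, `Gprime`, `step`).
#' @param regions a [region_set()].
#' @param window rolling-average window in recorded steps.
#' @param protein_mode folding-time criterion mode passed to
#'   [folding_time()].
#' @return a `pathway_record`: list with `label`, `folding_time` (MD steps
#'   or NA), `visited` (ordered region sequence) and `window`.
#' @export
classify_pathway <- function(series, regions = region_set(), window = 555,
                             protein_mode = c("entangled", "plain")) {
  protein_mode <- match.arg(protein_mode)
  s <- as.data.frame(series)
  if (nrow(s) < window) stop("series shorter than the rolling window")
  qs <- rolling_mean_centered(s$Q, window)
  gs <- rolling_mean_centered(s$Gprime, window)
  lab <- region_membership(cbind(qs, gs), regions)
  seqv <- lab[!is.na(lab)]
  visited <- seqv[c(TRUE, seqv[-1] != seqv[-length(seqv)])]
  ft <- folding_time(s, protein_mode)
  label <- if (length(visited) == 0) {
    "unclassified"
  } else if ("F" %in% visited) {
    if (!("IT" %in% visited)) {
      "fast_folding"
    } else {
      pre_f <- visited[seq_len(max(which(visited == "F")) - 1)]
      # decide on the most recent decision state (IT or U); the short-lived
      # IE- is visited on the fast channel of either escape route
      pre_f <- pre_f[pre_f %in% c("IT", "U")]
      last_state <- tail(pre_f, 1)
      if (identical(last_state, "IT")) "threading"
      else if (identical(last_state, "U")) "backtracking"
      else "unclassified"
    }
  } else if (identical(tail(visited, 1), "IT")) {
    "trapped"
  } else {
    "unclassified"
  }
  structure(list(label = label, folding_time = ft, visited = visited,
                 window = window),
            class = "pathway_record")
}

#' @export
print.pathway_record <- function(x, ...) {
  cat(sprintf("pathway: %s (visited %s; folding time %s)\n", x$label,
              paste(x$visited, collapse = " -> "),
              if (is.na(x$folding_time)) "none" else x$folding_time))
  invisible(x)
}

#' First-passage folding time of a trajectory
#'
#' Block-averages Q and <G'> over 250-MD-step windows and returns the first
#' block time at which the mode's folding condition holds: for the entangled
#' protein mode, Q >= 0.75 together with <G'> <= -0.5; for the plain
#' (non-entangled) mode, Q >= 0.7 alone.
#'
#' @param series an `observable_series`.
#' @param protein_mode `"entangled"` or `"plain"`.
#' @param block block-averaging window (MD steps).
#' @param q_threshold,g_threshold override the mode thresholds.
#' @return folding time in MD steps, or NA if never reached.
#' @export
folding_time <- function(series, protein_mode = c("entangled", "plain"),
                         block = 250, q_threshold = NULL, g_threshold = NULL) {
  protein_mode <- match.arg(protein_mode)
  s <- as.data.frame(series)
  bq <- block_average(s$Q, block, times = s$step)
  ok <- if (protein_mode == "entangled") {
    bg <- block_average(s$Gprime, block, times = s$step)
    bq$mean >= (q_threshold %||% 0.75) & bg$mean <= (g_threshold %||% -0.5)
  } else {
    bq$mean >= (q_threshold %||% 0.7)
  }
  if (!any(ok)) return(NA_real_)
  bq$time[which(ok)[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ensemble contact-formation probability map
#'
#' Per-native-contact fraction of ensemble conformations in which the
#' contact is formed (C-alpha distance below `g` times its native value).
#'
#' @param conformations list of N x 3 coordinate matrices.
#' @param topology a [native_topology()].
#' @param g contact-formation factor.
#' @return a `contact_probability_map`: data frame with `i`, `j`, `p`.
#' @export
ensemble_contact_map <- function(conformations, topology, g = 1.2) {
  stopifnot(length(conformations) >= 1)
  ct <- topology$contacts
  p <- rowMeans(vapply(conformations, function(x) {
    as.numeric(fraction_native(x, topology, g)$formed)
  }, numeric(nrow(ct))))
  structure(data.frame(i = ct$i, j = ct$j, p = p),
            class = c("contact_probability_map", "data.frame"))
}

#' Per-contact formation-probability Z-scores
#'
#' `z_i = (p_i - mean(p)) / sd_pop(p)` with the population standard
#' deviation over contacts (no Bessel correction), so the z-scores have
#' mean 0 over the contact list.
#'
#' @param map a [ensemble_contact_map()] result.
#' @return numeric z-score vector.
#' @export
contact_zscores <- function(map) {
  p <- map$p
  sp <- sqrt(mean((p - mean(p))^2))
  if (sp == 0) stop("zero variance of contact probabilities: z undefined")
  (p - mean(p)) / sp
}

#' Select trap-avoiding and first-entangling contacts
#'
#' Compares the contact maps of the two intermediate ensembles:
#' "trap-avoiding" contacts have Z-score > 1 in the entangled intermediate
#' IE- and < 1 in the trap IT (formed distinctly more often on the fast
#' channel than in the trap); "first-entangling" contacts have Z-score > 0
#' in IE- and belong to the supplied set of natively entangled contacts.
#'
#' @param map_ie,map_it [ensemble_contact_map()] results over the same
#'   contact list.
#' @param entangled_set data frame of entangled native contacts (columns
#'   `i`, `j`).
#' @return list with `trap_avoiding` and `first_entangling` contact data
#'   frames.
#' @export
select_special_contacts <- function(map_ie, map_it, entangled_set) {
  stopifnot(nrow(map_ie) == nrow(map_it),
            all(map_ie$i == map_it$i), all(map_ie$j == map_it$j))
  z_ie <- contact_zscores(map_ie)
  z_it <- contact_zscores(map_it)
  pick <- function(sel) {
    data.frame(i = map_ie$i[sel], j = map_ie$j[sel])
  }
  ent_key <- character(0)
  if (!is.null(entangled_set) && nrow(as.data.frame(entangled_set)) > 0) {
    es <- as.data.frame(entangled_set)
    ent_key <- paste(es$i, es$j)
  }
  list(trap_avoiding = pick(z_ie > 1 & z_it < 1),
       first_entangling = pick(z_ie > 0 &
                                 paste(map_ie$i, map_ie$j) %in% ent_key))
}
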