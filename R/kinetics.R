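#' Block-average a time series
#'
#' Non-overlapping block means; each block is timestamped at its center, and
#' a trailing partial block is kept as its own mean. With `window = 1` the
#' series is returned unchanged.
#'
#' @param x numeric series.
#' @param window block length in the units of `times` (MD steps at the
#'   default cadence).
#' @param times sample times (defaults to 1..n).
#' @return data frame with `time` (block centers) and `mean`.
#' @export
block_average <- function(x, window, times = NULL) {
  stopifnot(window >= 1)
  n <- length(x)
  if (is.null(times)) times <- seq_len(n)
  idx <- floor((times - times[1]) / window)
  data.frame(
    time = as.numeric(tapply(times, idx, mean)),
    mean = as.numeric(tapply(x, idx, mean))
  )
}

#' Contact formation probability curve across trajectories
#'
#' For one native contact, the binary formation indicator (formed when the
#' C-alpha distance is below `g` times the native distance) is averaged per
#' time point over refolding trajectories -- optionally restricted to a
#' subset, e.g. only fast-channel trajectories.
#'
#' @param trajectories a `refolding_batch` (or list of `trajectory` objects
#'   whose `formed` matrices are available), or a list of binary vectors /
#'   a binary matrix (rows = trajectories) as produced by
#'   [make_synthetic_kinetics()].
#' @param contact contact index into the topology contact list (ignored for
#'   precomputed binary input).
#' @param topology the [native_topology()] (required for trajectory input).
#' @param subset optional trajectory subset (indices or logical).
#' @param g contact-formation factor.
#' @return data frame with `time` and `p` (per-time formation fraction).
#' @export
contact_formation_curve <- function(trajectories, contact = NULL,
                                    topology = NULL, subset = NULL, g = 1.2) {
  if (is.matrix(trajectories)) {
    m <- trajectories
    times <- seq_len(ncol(m)) - 1
  } else if (length(trajectories) > 0 && is.numeric(trajectories[[1]])) {
    m <- do.call(rbind, trajectories)
    times <- seq_len(ncol(m)) - 1
  } else {
    stopifnot(!is.null(contact), !is.null(topology))
    rows <- lapply(trajectories, function(tr) {
      if (is.null(tr$frames)) stop("trajectory frames not kept; rerun with keep_frames = TRUE")
      vapply(tr$frames, function(x) {
        fraction_native_cpp(x, as.integer(topology$contacts$i[contact]),
                            as.integer(topology$contacts$j[contact]),
                            as.numeric(topology$contacts$r0[contact]),
                            g)$formed[1]
      }, logical(1))
    })
    m <- do.call(rbind, lapply(rows, as.numeric))
    times <- trajectories[[1]]$series$step
  }
  if (!is.null(subset)) m <- m[subset, , drop = FALSE]
  if (nrow(m) == 0) stop("empty trajectory subset")
  data.frame(time = times, p = colMeans(m))
}

#' Fit exponential kinetics to a contact formation curve
#'
#' Block-averages the curve, then fits `A - B exp(-k t)` by bounded
#' nonlinear least squares (A, B in \[0, 1.2\], k > 0). Initialization:
#' A from the final block, B from the rise over the curve, k from a third of
#' the time span. A flat or non-converging curve is flagged "no-kinetics"
#' (A = curve mean, B = 0, k undefined). Parameter standard deviations come
#' from the fit covariance.
#'
#' @param curve data frame with `time` and `p` (see
#'   [contact_formation_curve()]).
#' @param block_window block-averaging window in the curve's time units.
#' @return a `contact_kinetics` record: list with `A`, `B`, `k`, `sd_A`,
#'   `sd_B`, `sd_k`, `flagged`.
#' @export
fit_contact_kinetics <- function(curve, block_window = 100) {
  bl <- block_average(curve$p, block_window, times = curve$time)
  if (nrow(bl) < 5) stop("need at least 5 blocks after averaging")
  a0 <- tail(bl$mean, 1)
  b0 <- a0 - bl$mean[1]
  span <- diff(range(bl$time))
  k0 <- 3 / span
  no_kin <- function() {
    structure(list(A = mean(bl$mean), B = 0, k = NA_real_,
                   sd_A = sd(bl$mean) / sqrt(nrow(bl)), sd_B = NA_real_,
                   sd_k = NA_real_, flagged = TRUE),
              class = "contact_kinetics")
  }
  if (b0 <= 1e-6) return(no_kin())
  fit <- tryCatch(
    minpack.lm::nlsLM(mean ~ A - B * exp(-k * time), data = bl,
                      start = list(A = min(max(a0, 0), 1.2),
                                   B = min(max(b0, 1e-3), 1.2), k = k0),
                      lower = c(0, 0, 1e-12), upper = c(1.2, 1.2, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500,
                                                           ftol = 1e-14,
                                                           ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) return(no_kin())
  cf <- coef(fit)
  if (cf[["B"]] <= 1e-8) return(no_kin())
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  structure(list(A = cf[["A"]], B = cf[["B"]], k = cf[["k"]],
                 sd_A = se[1], sd_B = se[2], sd_k = se[3], flagged = FALSE),
            class = "contact_kinetics")
}

#' @export
print.contact_kinetics <- function(x, ...) {
  if (x$flagged) {
    cat(sprintf("no-kinetics fit: flat curve at A = %.3f\n", x$A))
  } else {
    cat(sprintf("A = %.3f +- %.3f, B = %.3f +- %.3f, k = %.3g +- %.2g\n",
                x$A, x$sd_A, x$B, x$sd_B, x$k, x$sd_k))
  }
  invisible(x)
}

#' Contact formation probability in the unfolded ensemble
#'
#' Formation fraction of one contact over unfolded conformations, with the
#' binomial standard error `sqrt(p (1 - p) / n)`.
#'
#' @param unfolded_samples list of N x 3 coordinate matrices.
#' @param contact contact index into the topology contact list.
#' @param topology a [native_topology()].
#' @param g contact-formation factor.
#' @return list with `p_u` and `sd`.
#' @export
unfolded_probability <- function(unfolded_samples, contact, topology, g = 1.2) {
  n <- length(unfolded_samples)
  stopifnot(n >= 2)
  formed <- vapply(unfolded_samples, function(x) {
    fraction_native_cpp(x, as.integer(topology$contacts$i[contact]),
                        as.integer(topology$contacts$j[contact]),
                        as.numeric(topology$contacts$r0[contact]),
                        g)$formed[1]
  }, logical(1))
  p <- mean(formed)
  list(p_u = p, sd = sqrt(p * (1 - p) / n))
}
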