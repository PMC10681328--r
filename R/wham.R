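#' Assemble WHAM input from equilibrium runs
#'
#' Collects per-run histograms of the fraction of native contacts Q (binned
#' naturally by the integer formed-contact count) and the per-bin mean
#' energies, after discarding an initial burn-in fraction of every series.
#' The bin energy is the run-average of per-run bin means: each run that
#' visited a bin contributes its own mean energy there, and those run means
#' are averaged.
#'
#' @param runs list of runs; each a list with `temperature` (epsilon / k_B)
#'   and `series` (a data frame with columns `Q` and `E`).
#' @param n_contacts total native contacts (sets the Q bin grid
#'   `0, 1/n, ..., 1`).
#' @param burn_in_fraction fraction of each series discarded from the front.
#' @return a `wham_input`: list with `beta` (inverse temperatures), `counts`
#'   (R x n_bins matrix), `n_i` (per-run totals), `mean_energy` (per-bin
#'   averaged energy, NA on unvisited bins) and `q_values`.
#' @export
build_wham_input <- function(runs, n_contacts, burn_in_fraction = 0.10) {
  stopifnot(length(runs) >= 1, n_contacts >= 1)
  qgrid <- (0:n_contacts) / n_contacts
  nb <- length(qgrid)
  R <- length(runs)
  counts <- matrix(0, R, nb)
  esum <- matrix(0, R, nb)
  for (r in seq_len(R)) {
    s <- as.data.frame(runs[[r]]$series)
    drop <- floor(burn_in_fraction * nrow(s))
    if (drop > 0) s <- s[-seq_len(drop), , drop = FALSE]
    bin <- round(s$Q * n_contacts) + 1
    for (b in unique(bin)) {
      sel <- bin == b
      counts[r, b] <- sum(sel)
      esum[r, b] <- sum(s$E[sel])
    }
  }
  if (all(counts == 0)) stop("empty bin set")
  # run-average of per-run bin means
  with_data <- counts > 0
  runmean <- ifelse(with_data, esum / pmax(counts, 1), NA_real_)
  mean_energy <- colMeans(runmean, na.rm = TRUE)
  mean_energy[colSums(with_data) == 0] <- NA_real_
  structure(list(
    beta = 1 / vapply(runs, function(r) r$temperature, numeric(1)),
    counts = counts, n_i = rowSums(counts),
    mean_energy = mean_energy, q_values = qgrid,
    n_contacts = n_contacts
  ), class = "wham_input")
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Solve the WHAM self-consistent equations
#'
#' Iterates the coupled fixed point
#' \deqn{S(Q) = \ln\!\left[\sum_i N_i(Q) \middle/ \sum_j n_j e^{-\beta_j \langle E\rangle_Q + f_j}\right]}
#' \deqn{e^{-f_k} = \sum_Q e^{-\beta_k \langle E\rangle_Q + S(Q)}}
#' from the initialization f = 0, S = 0, with all exponentials evaluated in
#' log space. Convergence requires the mean absolute change of both S (over
#' populated bins) and f (over runs) to drop below `tol`. Bins never visited
#' by any run are excluded from both sums.
#'
#' @param input a [build_wham_input()] result.
#' @param tol convergence tolerance on the mean absolute change.
#' @param max_iter iteration cap.
#' @return a `wham_solution`: list with `S` (entropy per populated bin,
#'   anchored to max S = 0), `f` (dimensionless run free energies),
#'   `mean_energy`, `q_values` (populated bins only), `iterations`,
#'   `residual`.
#' @export
solve_wham <- function(input, tol = 1e-14, max_iter = 100000) {
  pop <- colSums(input$counts) > 0
  if (any(input$n_i == 0)) stop("every run needs a non-empty histogram")
  Nq <- colSums(input$counts)[pop]
  E <- input$mean_energy[pop]
  q <- input$q_values[pop]
  beta <- input$beta
  logn <- log(input$n_i)
  R <- length(beta)
  S <- rep(0, length(Nq))
  f <- rep(0, R)
  it <- 0
  resid <- Inf
  logNq <- log(Nq)
  repeat {
    it <- it + 1
    # S(Q) update: denominator sum_j n_j exp(-beta_j E + f_j)
    denom <- vapply(seq_along(E), function(b) {
      log_sum_exp(logn - beta * E[b] + f)
    }, numeric(1))
    S_new <- logNq - denom
    f_new <- -vapply(seq_len(R), function(k) {
      log_sum_exp(-beta[k] * E + S_new)
    }, numeric(1))
    # anchor the gauge freedom (S + c, f - c) at f[1] = 0: the plain
    # iteration is marginally stable along that direction
    c0 <- f_new[1]
    f_new <- f_new - c0
    S_new <- S_new + c0
    resid <- max(mean(abs(S_new - S)), mean(abs(f_new - f)))
    S <- S_new
    f <- f_new
    if (resid < tol) break
    if (it >= max_iter) {
      stop(sprintf("WHAM did not converge in %d iterations (residual %.3e)",
                   it, resid))
    }
  }
  structure(list(S = S - max(S), f = f, mean_energy = E, q_values = q,
                 iterations = it, residual = resid,
                 t_range = 1 / rev(range(beta))),
            class = "wham_solution")
}

#' @export
print.wham_solution <- function(x, ...) {
  cat("WHAM solution:", length(x$S), "populated Q bins,",
      x$iterations, "iterations (residual", format(x$residual, digits = 3),
      ")\n")
  invisible(x)
}

#' Free-energy profiles, specific heat, and the folding temperature
#'
#' From a converged WHAM entropy: the free-energy profile
#' `F(Q; T) = <E>_Q - T S(Q)` and the per-residue specific heat
#' `Cv(T) = (<E^2>_T - <E>_T^2) / (T^2 N)`, with thermal averages reweighted
#' over the Q bins as `<E^n>_T \propto sum_Q <E>_Q^n exp(S(Q) - <E>_Q / T)`
#' (bin-mean energy approximation). The folding temperature is the grid
#' argmax of Cv, refined by a local quadratic fit through the three
#' surrounding grid points.
#'
#' @param solution a [solve_wham()] result.
#' @param t_grid temperature grid (epsilon / k_B).
#' @param n_residues residue count N used in the per-residue normalization.
#' @return a `thermo_curves`: list with `t_grid`, `cv`, `t_f`,
#'   `free_energy(T)` (function returning the F(Q; T) profile on the
#'   populated bins) and `q_values`.
#' @export
thermo_curves <- function(solution, t_grid, n_residues) {
  S <- solution$S
  E <- solution$mean_energy
  if (!is.null(solution$t_range) &&
      (min(t_grid) < 0.8 * solution$t_range[1] ||
       max(t_grid) > 1.2 * solution$t_range[2])) {
    warning("temperature grid extends well beyond the sampled range [",
            signif(solution$t_range[1], 3), ", ",
            signif(solution$t_range[2], 3), "]; extrapolated curves are unreliable")
  }
  stats_t <- vapply(t_grid, function(tt) {
    lw <- S - E / tt
    lz <- log_sum_exp(lw)
    w <- exp(lw - lz)
    e1 <- sum(w * E)
    e2 <- sum(w * E^2)
    c(e1, e2)
  }, numeric(2))
  cv <- (stats_t[2, ] - stats_t[1, ]^2) / (t_grid^2 * n_residues)
  i <- which.max(cv)
  t_f <- t_grid[i]
  if (i > 1 && i < length(t_grid)) {
    # quadratic refinement through the three points around the peak
    x <- t_grid[(i - 1):(i + 1)]
    y <- cv[(i - 1):(i + 1)]
    d <- (y[1] - 2 * y[2] + y[3])
    if (d < 0) t_f <- x[2] - 0.5 * (x[3] - x[1]) / 2 * (y[3] - y[1]) / d
  }
  structure(list(
    t_grid = t_grid, cv = cv, t_f = t_f,
    mean_energy_t = stats_t[1, ],
    q_values = solution$q_values,
    free_energy = function(tt) E - tt * S
  ), class = "thermo_curves")
}

#' @export
print.thermo_curves <- function(x, ...) {
  cat(sprintf("Thermo curves on T in [%.3f, %.3f]: T_f = %.4f (Cv peak %.3f)\n",
              min(x$t_grid), max(x$t_grid), x$t_f, max(x$cv)))
  invisible(x)
}

#' Free-energy barrier height between the folded and unfolded minima
#'
#' Locates the two lowest local minima of the binned profile (after a 3-bin
#' moving-average smoothing) and returns the barrier measured from the
#' lower-Q minimum: `F(top of the barrier between them) - F(unfolded
#' minimum)`.
#'
#' @param f_profile free-energy values per Q bin (epsilon, or k_B T units at
#'   the evaluation temperature).
#' @param q_values matching Q values (defaults to bin index).
#' @return list with `delta_f`, `q_unfolded`, `q_folded`, `q_barrier`.
#' @export
barrier_height <- function(f_profile, q_values = seq_along(f_profile)) {
  n <- length(f_profile)
  if (n < 3) stop("no barrier: profile too short")
  sm <- f_profile
  if (n >= 9) {  # 3-bin smoothing only on real (many-bin) profiles
    sm <- stats::filter(f_profile, rep(1 / 3, 3), sides = 2)
    sm[1] <- mean(f_profile[1:2])
    sm[n] <- mean(f_profile[(n - 1):n])
    sm <- as.numeric(sm)
  }
  is_min <- vapply(seq_len(n), function(i) {
    left_ok <- i == 1 || sm[i] <= sm[i - 1]
    right_ok <- i == n || sm[i] <= sm[i + 1]
    strict <- (i > 1 && sm[i] < sm[i - 1]) || (i < n && sm[i] < sm[i + 1]) ||
      (i == 1 || i == n)
    left_ok && right_ok && strict
  }, logical(1))
  mins <- which(is_min)
  # merge adjacent plateau minima
  mins <- mins[c(TRUE, diff(mins) > 1)]
  if (length(mins) < 2) stop("no barrier: profile has fewer than 2 local minima")
  best <- mins[order(sm[mins])][1:2]
  lo <- min(best)
  hi <- max(best)
  ib <- (lo:hi)[which.max(sm[lo:hi])]
  unf <- lo  # lower-Q minimum is the unfolded basin
  list(delta_f = sm[ib] - sm[unf],
       q_unfolded = q_values[lo], q_folded = q_values[hi],
       q_barrier = q_values[ib])
}
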