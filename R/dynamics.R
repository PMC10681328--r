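#' Langevin integrator settings
#'
#' Reduced units: mass m = 1, energy epsilon = 1, length 1 Angstrom,
#' k_B = 1 (temperature in epsilon). The damping follows m/gamma = 0.1 and
#' the time step is dt = 0.001; one MD step -- the package's time unit --
#' is 24000 integrations of the Langevin equation. Observables are recorded
#' every `record_every` MD steps.
#'
#' @param temperature heat-bath temperature (epsilon / k_B).
#' @param dt integration time step (reduced time).
#' @param mass bead mass (reduced).
#' @param m_over_gamma damping ratio m/gamma (reduced time).
#' @param steps_per_md integrations per MD step.
#' @param record_every recording cadence in MD steps.
#' @param seed RNG seed for the noise stream.
#' @return list of settings for [run_langevin()].
#' @export
integrator_settings <- function(temperature, dt = 0.001, mass = 1,
                                m_over_gamma = 0.1, steps_per_md = 24000,
                                record_every = 1, seed = 1) {
  stopifnot(dt > 0, m_over_gamma > 0, temperature >= 0, steps_per_md >= 1)
  list(temperature = temperature, dt = dt, mass = mass,
       gamma = mass / m_over_gamma, steps_per_md = as.integer(steps_per_md),
       record_every = as.integer(record_every), seed = as.integer(seed))
}

maxwell_boltzmann_velocities <- function(n, temperature, mass) {
  matrix(rnorm(3 * n, sd = sqrt(max(temperature, 0) / mass)), n, 3)
}

#' Run Langevin dynamics
#'
#' Integrates the Langevin equation of motion
#' \eqn{m \ddot r = -\gamma \dot r - \nabla V + R(t)} with Gaussian noise
#' satisfying \eqn{\langle R(t) R(t') \rangle = 2 k_B T \gamma \delta(t-t')},
#' using the Gronbech-Jensen-Farago velocity-Verlet discretization (correct
#' configurational sampling at finite dt). Velocities are drawn from the
#' Maxwell-Boltzmann distribution at the run temperature when absent.
#' Trajectories are fully reproducible given the seed.
#'
#' @param initial N x 3 coordinate matrix (or list with `coords` and
#'   optionally `velocities`).
#' @param topology a [native_topology()].
#' @param params see [go_parameters()].
#' @param settings see [integrator_settings()].
#' @param n_md_steps simulation length in MD steps.
#' @param observables compute Q, the entanglement indicator, energy and RMSD
#'   at each recorded frame (set FALSE to record coordinates only).
#' @param keep_frames retain recorded coordinate frames in the result.
#' @return a `trajectory`: list with `series` (an `observable_series` data
#'   frame: step, Q, Gprime, E, RMSD), `frames` (list of coordinate
#'   matrices, if kept), `final` (coords + velocities) and `settings`.
#' @export
run_langevin <- function(initial, topology, params = go_parameters(),
                         settings, n_md_steps, observables = TRUE,
                         keep_frames = FALSE) {
  x <- as_coords(initial)
  stopifnot(all(is.finite(x)))
  set.seed(settings$seed)
  v <- if (is.list(initial) && !is.null(initial$velocities)) initial$velocities
       else maxwell_boltzmann_velocities(nrow(x), settings$temperature, settings$mass)
  a <- topo_args(topology)
  rec <- settings$record_every
  n_rec <- n_md_steps %/% rec
  steps_chunk <- rec * settings$steps_per_md
  out <- data.frame(step = numeric(n_rec), Q = numeric(n_rec),
                    Gprime = numeric(n_rec), E = numeric(n_rec),
                    RMSD = numeric(n_rec))
  frames <- if (keep_frames) vector("list", n_rec) else NULL
  for (r in seq_len(n_rec)) {
    chunk_seed <- runif(1) * 2^52  # from R's stream: set.seed() fixes it
    st <- langevin_chunk_cpp(x, v, a$r0_bond, a$theta0, a$phi0, a$ci, a$cj,
                             a$r0_c, params, steps_chunk, settings$dt,
                             settings$gamma, settings$mass,
                             settings$temperature, chunk_seed)
    x <- st$coords
    v <- st$vels
    out$step[r] <- r * rec
    if (observables) {
      fn <- fraction_native(x, topology, params$g)
      snap <- entanglement_indicator(x, topology$contacts[fn$formed, c("i", "j")])
      en <- go_energy_cpp(x, a$r0_bond, a$theta0, a$phi0, a$ci, a$cj, a$r0_c,
                          params)
      out$Q[r] <- fn$q
      out$Gprime[r] <- snap$indicator
      out$E[r] <- en$total
      out$RMSD[r] <- kabsch_rmsd(x, topology$ca)
    }
    if (keep_frames) frames[[r]] <- x
  }
  class(out) <- c("observable_series", "data.frame")
  structure(list(series = out, frames = frames,
                 final = list(coords = x, velocities = v),
                 settings = settings, n_md_steps = n_md_steps),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Langevin trajectory:", x$n_md_steps, "MD steps at T =",
      x$settings$temperature, "\n")
  if (nrow(x$series) > 0 && !all(x$series$Q == 0)) {
    cat(sprintf("  final Q = %.3f, <G'> = %.3f, E = %.2f\n",
                tail(x$series$Q, 1), tail(x$series$Gprime, 1),
                tail(x$series$E, 1)))
  }
  invisible(x)
}

#' Sample uncorrelated unfolded conformations
#'
#' Runs equilibrium dynamics above the folding temperature, at
#' `T = c_factor * t_fold` with `c_factor > 1`, discards a burn-in, and saves
#' snapshots separated by a decorrelation interval. These conformations serve
#' as initial conditions for refolding runs and as the unfolded ensemble for
#' contact statistics.
#'
#' @param topology a [native_topology()].
#' @param params see [go_parameters()].
#' @param t_fold folding temperature (epsilon / k_B).
#' @param c_factor multiplicative factor above `t_fold`.
#' @param n_samples snapshots to return.
#' @param decorrelation_interval MD steps between snapshots.
#' @param seed RNG seed.
#' @param burn_in MD steps discarded before sampling.
#' @param initial starting conformation (native by default).
#' @return list of N x 3 coordinate matrices.
#' @export
sample_unfolded <- function(topology, params = go_parameters(), t_fold,
                            c_factor = 1.25, n_samples, decorrelation_interval,
                            seed = 1, burn_in = 50, initial = NULL) {
  stopifnot(c_factor > 1)
  settings <- integrator_settings(temperature = c_factor * t_fold,
                                  record_every = 1, seed = seed)
  x <- if (is.null(initial)) topology$ca else as_coords(initial)
  n_md <- burn_in + n_samples * decorrelation_interval
  tr <- run_langevin(x, topology, params, settings, n_md,
                     observables = FALSE, keep_frames = TRUE)
  idx <- burn_in + seq_len(n_samples) * decorrelation_interval
  if (max(idx) > length(tr$frames)) stop("requested samples exceed trajectory capacity")
  tr$frames[idx]
}

#' Run a batch of refolding trajectories
#'
#' Simulates independent refolding trajectories below the folding
#' temperature (the study protocol uses `T = 0.9 t_fold`), one unfolded
#' initial conformation and one noise seed per trajectory. Batch metadata
#' (seeds, temperature, length) is attached for exact re-runs.
#'
#' @param topology a [native_topology()].
#' @param params see [go_parameters()].
#' @param temperature refolding temperature (epsilon / k_B).
#' @param initials list of starting conformations, one per trajectory.
#' @param n_md_steps MD steps per trajectory.
#' @param seeds integer vector, one seed per trajectory.
#' @param keep_frames retain coordinate frames (memory-heavy).
#' @return a `refolding_batch`: list of `trajectory` objects with a
#'   `metadata` attribute.
#' @export
run_refolding_batch <- function(topology, params = go_parameters(), temperature,
                                initials, n_md_steps, seeds,
                                keep_frames = FALSE) {
  stopifnot(length(initials) == length(seeds))
  runs <- vector("list", length(seeds))
  for (k in seq_along(seeds)) {
    settings <- integrator_settings(temperature = temperature,
                                    record_every = 1, seed = seeds[k])
    runs[[k]] <- run_langevin(initials[[k]], topology, params, settings,
                              n_md_steps, keep_frames = keep_frames)
  }
  structure(runs, class = "refolding_batch",
            metadata = list(seeds = as.integer(seeds),
                            temperature = temperature,
                            n_md_steps = n_md_steps))
}

#' @export
print.refolding_batch <- function(x, ...) {
  md <- attr(x, "metadata")
  cat("Refolding batch:", length(x), "trajectories,",
      md$n_md_steps, "MD steps at T =", md$temperature, "\n")
  invisible(x)
}
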