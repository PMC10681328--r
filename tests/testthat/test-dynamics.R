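test_that("zero-temperature dynamics leave the native stationary point fixed", {
  tn <- make_toy_native(12, "hairpin")
  st <- integrator_settings(temperature = 0, seed = 3)
  tr <- run_langevin(tn$native, tn$topology, go_parameters(), st, 10)
  expect_lt(max(abs(tr$final$coords - tn$native)), 1e-6)
  expect_lt(diff(range(tr$series$E)), 1e-8)
})

test_that("trajectories are deterministic given the seed", {
  tn <- make_toy_native(12, "hairpin")
  st <- integrator_settings(temperature = 0.8, seed = 11)
  a <- run_langevin(tn$native, tn$topology, go_parameters(), st, 15)
  b <- run_langevin(tn$native, tn$topology, go_parameters(), st, 15)
  expect_identical(a$final, b$final)
  expect_identical(a$series, b$series)
  st2 <- integrator_settings(temperature = 0.8, seed = 12)
  c <- run_langevin(tn$native, tn$topology, go_parameters(), st2, 15)
  expect_false(identical(a$final$coords, c$final$coords))
})

test_that("free beads equilibrate to the Maxwell-Boltzmann temperature", {
  # V = 0: every interaction amplitude zeroed; <v^2> per component = T/m
  p0 <- go_parameters()
  for (nm in c("eps_bond", "eps_angle", "eps_dihedral", "eps_contact", "eps_nn"))
    p0[[nm]] <- 0
  topo <- native_topology(cbind(c(0, 40, 80, 120), 0, 0),
                          data.frame(i = integer(0), j = integer(0)))
  # drive the integrator chunk-wise to capture velocities each MD step
  set.seed(6)
  x <- topo$ca
  v <- entfold:::maxwell_boltzmann_velocities(4, 1, 1)
  a <- entfold:::topo_args(topo)
  vs <- numeric(700)
  for (r in 1:700) {
    rr <- entfold:::langevin_chunk_cpp(x, v, a$r0_bond, a$theta0, a$phi0,
                                       a$ci, a$cj, a$r0_c, p0, 24000L, 0.001,
                                       10, 1, 1, runif(1) * 2^52)
    x <- rr$coords; v <- rr$vels
    vs[r] <- mean(v^2)
  }
  se <- sd(vs) / sqrt(length(vs))
  expect_lt(abs(mean(vs) - 1), 3 * se)
})

test_that("bond fluctuations follow Boltzmann statistics in the harmonic limit", {
  # two-bead bond at T = 0.5: var(r - r0) = T / (2 eps_bond)
  topo <- native_topology(rbind(c(0, 0, 0), c(3.8, 0, 0)),
                          data.frame(i = integer(0), j = integer(0)))
  st <- integrator_settings(temperature = 0.5, seed = 8)
  tr <- run_langevin(topo$ca, topo, go_parameters(), st, 2500,
                     observables = FALSE, keep_frames = TRUE)
  dr <- vapply(tr$frames, function(x) sqrt(sum((x[2, ] - x[1, ])^2)) - 3.8,
               numeric(1))
  v_exp <- 0.5 / (2 * 100)
  expect_lt(abs(var(dr) - v_exp) / v_exp, 0.15)
})

test_that("sample_unfolded bookkeeping, decorrelation and determinism", {
  tn <- make_toy_native(28, "lasso")
  s <- sample_unfolded(tn$topology, go_parameters(), t_fold = 1.0,
                       c_factor = 1.3, n_samples = 10,
                       decorrelation_interval = 5, seed = 4, burn_in = 10)
  expect_length(s, 10)
  expect_true(all(vapply(s, nrow, integer(1)) == 28))
  s2 <- sample_unfolded(tn$topology, go_parameters(), t_fold = 1.0,
                        c_factor = 1.3, n_samples = 10,
                        decorrelation_interval = 5, seed = 4, burn_in = 10)
  expect_identical(s, s2)
  expect_error(sample_unfolded(tn$topology, go_parameters(), t_fold = 1.0,
                               c_factor = 0.9, n_samples = 2,
                               decorrelation_interval = 5, seed = 1),
               "c_factor")
})

test_that("well above the folding temperature the toy lasso unfolds", {
  tn <- make_toy_native(28, "lasso")
  s <- sample_unfolded(tn$topology, go_parameters(), t_fold = 1.6,
                       c_factor = 1.3, n_samples = 8,
                       decorrelation_interval = 8, seed = 5, burn_in = 40)
  qs <- vapply(s, function(x) fraction_native(x, tn$topology)$q, numeric(1))
  expect_lt(mean(qs), 0.5)
})

test_that("refolding batches are independent, reproducible and fold the hairpin", {
  tn <- make_toy_native(12, "hairpin")
  # reference temperature: 0.9 x the WHAM folding-temperature estimate for
  # this motif (about 1.4 on the Cv peak; see the methods vignette)
  inits <- sample_unfolded(tn$topology, go_parameters(), t_fold = 1.7,
                           c_factor = 1.3, n_samples = 3,
                           decorrelation_interval = 10, seed = 9,
                           burn_in = 20)
  batch <- run_refolding_batch(tn$topology, go_parameters(),
                               temperature = 1.25, initials = inits,
                               n_md_steps = 120, seeds = 31:33)
  expect_length(batch, 3)
  md <- attr(batch, "metadata")
  expect_identical(md$seeds, 31:33)
  expect_equal(md$temperature, 1.25)
  # distinct noise streams -> pairwise distinct series
  expect_false(identical(batch[[1]]$series$Q, batch[[2]]$series$Q))
  expect_false(identical(batch[[2]]$series$Q, batch[[3]]$series$Q))
  # every trajectory reaches near-native Q within the budget
  expect_true(all(vapply(batch, function(tr) max(tr$series$Q) >= 0.9,
                         logical(1))))
})
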