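test_that("build_wham_input discards the burn-in and averages run bin means", {
  ser <- data.frame(Q = rep(c(0, 1), 5), E = 1:10)
  run <- list(temperature = 1, series = ser)
  wi <- build_wham_input(list(run), 1, burn_in_fraction = 0.10)
  expect_equal(wi$n_i, 9)   # first of 10 frames dropped

  # constructed bin: run A sees energies {1, 3}, run B sees {5}
  ra <- list(temperature = 1, series = data.frame(Q = c(0, 0), E = c(1, 3)))
  rb <- list(temperature = 1.2, series = data.frame(Q = 0, E = 5))
  wi2 <- build_wham_input(list(ra, rb), 4, burn_in_fraction = 0)
  expect_equal(wi2$mean_energy[1], (2 + 5) / 2)

  # two identical runs: bin means equal the single-run means
  wi3 <- build_wham_input(list(ra, ra), 4, burn_in_fraction = 0)
  expect_equal(wi3$mean_energy[1], 2)
})

test_that("single-run WHAM reduces to F = -T log N(Q) up to a constant", {
  set.seed(1)
  qv <- (0:12) / 12
  ser <- data.frame(Q = sample(qv, 3000, TRUE, prob = dnorm(qv, 0.5, 0.25)))
  ser$E <- -8 * ser$Q + rnorm(3000, 0, 0.3)
  run <- list(temperature = 0.8, series = ser)
  wi <- build_wham_input(list(run), 12, burn_in_fraction = 0)
  sol <- solve_wham(wi)
  th <- thermo_curves(sol, seq(0.65, 0.95, 0.01), 12)
  F1 <- th$free_energy(0.8)
  Nq <- colSums(wi$counts)[colSums(wi$counts) > 0]
  ref <- -0.8 * log(Nq)
  expect_lt(diff(range(F1 - ref)), 1e-10)

  # duplicating the run changes S only by an additive constant
  sol2 <- solve_wham(build_wham_input(list(run, run), 12, 0))
  expect_lt(diff(range(sol2$S - sol$S)), 1e-10)

  # energy-shift gauge invariance of free-energy differences
  run_shift <- run
  run_shift$series$E <- run_shift$series$E + 5
  sol3 <- solve_wham(build_wham_input(list(run_shift), 12, 0))
  F3 <- thermo_curves(sol3, seq(0.65, 0.95, 0.01), 12)$free_energy(0.8)
  expect_lt(diff(range(F3 - F1)), 1e-10)
})

test_that("two-state model recovers the closed-form crossing temperature", {
  e0 <- 4
  omega <- 60
  t_star <- e0 / log(omega)
  runs <- list(
    list(temperature = 0.9 * t_star, series = two_state_series(0.9 * t_star, omega, e0, 6000, 21)),
    list(temperature = 1.1 * t_star, series = two_state_series(1.1 * t_star, omega, e0, 6000, 22))
  )
  sol <- solve_wham(build_wham_input(runs, 1, 0))
  tg <- seq(0.8 * t_star, 1.25 * t_star, length.out = 401)
  th <- thermo_curves(sol, tg, 1)
  f_gap <- vapply(tg, function(tt) diff(th$free_energy(tt)), numeric(1))
  t_cross <- tg[which.min(abs(f_gap))]
  # grid resolution plus sampling error on ln(Omega)
  expect_lt(abs(t_cross - t_star) / t_star, 0.03)
  # recovered entropy gap matches ln(Omega)
  expect_lt(abs(diff(sol$S) + log(omega)) / log(omega), 0.05)
})

test_that("degenerate thermo cases behave", {
  ser <- data.frame(Q = rep(1, 50), E = rnorm(50))
  sol <- solve_wham(build_wham_input(list(list(temperature = 1, series = ser)), 1, 0))
  th <- thermo_curves(sol, seq(0.9, 1.1, 0.02), 5)
  expect_true(all(th$cv == 0))   # single populated bin: no fluctuations

  expect_error(solve_wham(build_wham_input(
    list(list(temperature = 1, series = ser[0, ])), 1, 0)))
})

test_that("barrier height measures the saddle between the two lowest minima", {
  expect_equal(barrier_height(c(0, 1, 0.5))$delta_f, 1)
  b <- barrier_height(c(0.2, 0, 1, 0, 0.2), q_values = seq(0, 1, 0.25))
  expect_equal(b$delta_f, 1)
  expect_equal(b$q_barrier, 0.5)
  # symmetric double well: identical measured from either side
  prof <- c(0, 0.9, 0)
  expect_equal(barrier_height(prof)$delta_f, barrier_height(rev(prof))$delta_f)
  expect_error(barrier_height(c(0, 0.5, 1)), "barrier")
})

test_that("log-domain arithmetic survives large beta * E magnitudes", {
  # absolute energies of order -1e4: exp(-beta E) overflows naive arithmetic
  set.seed(12)
  qv <- (0:8) / 8
  mk <- function(tt, seed) {
    set.seed(seed)
    q <- sample(qv, 800, TRUE, prob = dnorm(qv, 0.5, 0.3))
    list(temperature = tt,
         series = data.frame(Q = q, E = -10000 - 4 * q + rnorm(800, 0, 0.2)))
  }
  sol <- solve_wham(build_wham_input(list(mk(0.9, 1), mk(1.1, 2)), 8, 0))
  expect_true(all(is.finite(sol$S)))
  expect_true(all(is.finite(sol$f)))
  # and the shifted system gives identical free-energy differences
  runs2 <- list(mk(0.9, 1), mk(1.1, 2))
  runs2[[1]]$series$E <- runs2[[1]]$series$E + 10000
  runs2[[2]]$series$E <- runs2[[2]]$series$E + 10000
  sol2 <- solve_wham(build_wham_input(runs2, 8, 0))
  expect_lt(diff(range(sol2$S - sol$S)), 1e-8)
})
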