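test_that("ring pairs realize their analytic linking numbers", {
  for (lk in c(0L, 1L, -1L, 2L, -2L)) {
    r <- make_linked_rings(200, lk)
    g <- gauss_linking(r$curve_a, r$curve_b)
    tol <- if (abs(lk) == 2) 0.02 else 0.01
    expect_lt(abs(g - lk), tol)
    expect_identical(r$true_linking, lk)
  }
  expect_error(make_linked_rings(200, 3), "unsupported")
})

test_that("discrete Gauss sum converges monotonically on a doubling ladder", {
  errs <- vapply(c(50, 100, 200, 400), function(n) {
    r <- make_linked_rings(n, 1)
    abs(gauss_linking(r$curve_a, r$curve_b) - 1)
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
})

test_that("orientation reversal flips the sign of the Gauss sum", {
  r <- make_linked_rings(200, 1)
  g <- gauss_linking(r$curve_a, r$curve_b)
  g_rev <- gauss_linking(r$curve_a, r$curve_b[rev(seq_len(200)), ])
  expect_equal(g_rev, -g, tolerance = 1e-12)
})

test_that("open lasso matches the smooth-curve Gauss integral oracle", {
  lp <- make_open_lasso(loop_radius = 5, thread_halflength = 50, pierce = TRUE)
  g <- gaussian_entanglement(lp$coords, lp$loop, lp$thread)
  oracle <- smooth_lasso_gauss(5, 50)
  expect_gte(abs(g), 0.9)
  expect_lt(abs(g - oracle), 0.05)

  ln <- make_open_lasso(loop_radius = 5, thread_halflength = 50, pierce = FALSE)
  gn <- gaussian_entanglement(ln$coords, ln$loop, ln$thread)
  oracle_n <- smooth_lasso_gauss(5, 50, x0 = 15)
  expect_lt(abs(gn), 0.2)
  expect_lt(abs(gn - oracle_n), 0.05)
})

test_that("lasso chirality mirrors exactly", {
  gp <- with(make_open_lasso(chirality = 1), gaussian_entanglement(coords, loop, thread))
  gm <- with(make_open_lasso(chirality = -1), gaussian_entanglement(coords, loop, thread))
  expect_equal(gp, -gm, tolerance = 1e-9)
  expect_equal(sign(gp), 1)
})

test_that("toy natives have the advertised contact structure", {
  hp <- make_toy_native(12, "hairpin")
  expect_gte(nrow(hp$topology$contacts), 2)
  snap <- entanglement_indicator(hp$native, hp$topology$contacts[, c("i", "j")])
  expect_true(all(abs(snap$records$g_prime) < 0.5))

  ls <- make_toy_native(30, "lasso")
  snap_ls <- entanglement_indicator(ls$native, ls$topology$contacts[, c("i", "j")])
  expect_true(any(abs(snap_ls$records$g_prime) > 0.75))

  for (m in c("hairpin", "helix", "lasso")) {
    tn <- make_toy_native(if (m == "lasso") 30 else 12, m)
    expect_equal(fraction_native(tn$native, tn$topology)$q, 1)
  }
})

test_that("toy natives are unstrained at the native state", {
  # all non-native pairs beyond the excluded-volume cutoff, so the native
  # structure is an exact stationary point of the potential
  for (m in c("hairpin", "helix")) {
    tn <- make_toy_native(12, m)
    f <- forces(tn$native, tn$topology)
    expect_lt(max(abs(f)), 1e-9)
    expect_equal(potential_energy(tn$native, tn$topology)$total,
                 -nrow(tn$topology$contacts))
  }
})

test_that("synthetic kinetics series follow A - B exp(-kt)", {
  m <- make_synthetic_kinetics(0.9, 0.7, 1e-4, 100, 5e4, 7)
  p0 <- mean(m[, 1])
  se0 <- sqrt(0.2 * 0.8 / 100)
  expect_lt(abs(p0 - 0.2), 3 * se0)
  tail_mean <- mean(m[, (5e4 - 999):5e4])
  expect_lt(abs(tail_mean - 0.9), 0.02)
  expect_error(make_synthetic_kinetics(0.5, 0.7, 1e-4, 2, 10, 1), "probability")

  # determinism: same seed, identical draw
  expect_identical(make_synthetic_kinetics(0.9, 0.7, 1e-4, 5, 100, 3),
                   make_synthetic_kinetics(0.9, 0.7, 1e-4, 5, 100, 3))
})

test_that("scripted series land in their named regions", {
  s <- make_scripted_series(list(list("U", 700), list("IE-", 700),
                                 list("F", 700)), seed = 2)
  lab <- region_membership(cbind(s$Q, s$Gprime))
  expect_equal(unique(lab[1:700]), "U")
  expect_equal(unique(lab[701:1400]), "IE-")
  expect_equal(unique(lab[1401:2100]), "F")
  expect_error(make_scripted_series(list(list("X", 700))), "unknown label")
})

test_that("fixture PDB writer round-trips through the reader", {
  tn <- make_toy_native(12, "hairpin")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(tn$atoms, f)
  at <- read_pdb(f)
  expect_equal(nrow(at), nrow(tn$atoms))
  expect_identical(build_contact_map(at), tn$topology$contacts)
})
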