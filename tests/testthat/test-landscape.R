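test_that("KDE landscape finds cluster minima and uses Scott bandwidths", {
  set.seed(2)
  tight <- cbind(rnorm(400, 0.5, 0.01), rnorm(400, -0.3, 0.01))
  g <- kde_landscape(tight)
  idx <- which(g$neg_log_density == 0, arr.ind = TRUE)
  expect_lt(abs(g$q[idx[1]] - 0.5), 0.02)
  expect_lt(abs(g$g[idx[2]] + 0.3), 0.02)

  # two equal, well-separated clusters: two minima of equal depth
  two <- rbind(cbind(rnorm(500, 0.2, 0.015), rnorm(500, 0, 0.015)),
               cbind(rnorm(500, 0.8, 0.015), rnorm(500, -0.6, 0.015)))
  g2 <- kde_landscape(two, n_grid = 101)
  near <- function(q0, g0) {
    iq <- which.min(abs(g2$q - q0))
    ig <- which.min(abs(g2$g - g0))
    min(g2$neg_log_density[iq + (-2:2), ig + (-2:2)])
  }
  expect_lt(abs(near(0.2, 0) - near(0.8, -0.6)), 0.05)

  # Scott's rule: duplicating the sample shrinks the bandwidth by the
  # n^(-1/6) factor (times the Bessel effect of doubling on the sample sd)
  n <- nrow(two)
  bw1 <- kde_landscape(two)$bandwidths
  bw2 <- kde_landscape(rbind(two, two))$bandwidths
  sd_ratio <- sqrt(2 * (n - 1) / (2 * n - 1))
  expect_equal(unname(bw2 / bw1), rep(sd_ratio * 2^(-1 / 6), 2),
               tolerance = 1e-12)

  expect_error(kde_landscape(cbind(rep(0.5, 200), rnorm(200))), "variance")
})

test_that("region membership follows the printed inequalities", {
  expect_equal(region_membership(c(0.6, -0.1)), "IT")
  expect_equal(region_membership(c(0.4, -0.6)), "IE-")
  expect_equal(region_membership(c(0.9, -0.7)), "F")
  expect_equal(region_membership(c(0.2, 0.1)), "U")
  expect_true(is.na(region_membership(c(0.6, -0.5))))
  # box bounds are closed ...
  expect_equal(region_membership(c(0.375, 0.25)), "U")
  expect_equal(region_membership(c(0.75, -0.5)), "F")
  # ... rhomboid bounds on <G'> are strict
  expect_true(is.na(region_membership(c(0.6, -0.2 * 0.6))))
  expect_equal(region_membership(c(0.6, -0.2 * 0.6 + 1e-9)), "IT")
  expect_true(is.na(region_membership(c(0.4, -1.07 * 0.4 - 0.26))))
  # TSE band
  expect_true(in_tse(0.5))
  expect_true(in_tse(0.53) && in_tse(0.47))
  expect_false(in_tse(0.54))
})

test_that("pathway classification reproduces scripted routes", {
  mk <- function(script, seed) make_scripted_series(script, seed = seed)
  fast <- list(list("U", 1200), list("IE-", 800), list("F", 1500))
  thr <- list(list("U", 1200), list("IT", 900), list("F", 1500))
  back <- list(list("U", 1200), list("IT", 900), list("U", 800),
               list("IE-", 700), list("F", 1500))
  trap <- list(list("U", 1200), list("IT", 1500))
  labels <- vapply(1:25, function(s) c(
    classify_pathway(mk(fast, s))$label,
    classify_pathway(mk(thr, s + 100))$label,
    classify_pathway(mk(back, s + 200))$label,
    classify_pathway(mk(trap, s + 300))$label
  ), character(4))
  expect_true(all(labels[1, ] == "fast_folding"))
  expect_true(all(labels[2, ] == "threading"))
  expect_true(all(labels[3, ] == "backtracking"))
  expect_true(all(labels[4, ] == "trapped"))
})

test_that("classification is invariant to prepending unfolded data", {
  thr <- make_scripted_series(list(list("U", 1200), list("IT", 900),
                                   list("F", 1500)), seed = 5)
  more_u <- make_scripted_series(list(list("U", 2000)), seed = 6)
  combined <- rbind(as.data.frame(more_u), as.data.frame(thr))
  combined$step <- seq_len(nrow(combined))
  expect_equal(classify_pathway(combined)$label, "threading")
})

test_that("trapped trajectories have no folding time", {
  trap <- make_scripted_series(list(list("U", 1200), list("IT", 1500)), seed = 2)
  rec <- classify_pathway(trap)
  expect_equal(rec$label, "trapped")
  expect_true(is.na(rec$folding_time))
})

test_that("folding time uses 250-step blocks and the per-protein criterion", {
  n <- 2000
  s <- data.frame(step = 1:n, Q = c(rep(0.1, 900), rep(0.9, n - 900)),
                  Gprime = c(rep(0, 900), rep(-0.8, n - 900)))
  ft <- folding_time(s, "entangled")
  # the 751..1000 block straddles the jump and misses the thresholds; the
  # first fully-folded block is 1001..1250, stamped at its center
  expect_equal(ft, mean(1001:1250))
  expect_equal(folding_time(s, "plain"), mean(1001:1250))

  # conjunction: Q crosses but the chain never entangles -> no folding time
  s2 <- s
  s2$Gprime <- 0
  expect_true(is.na(folding_time(s2, "entangled")))
  expect_false(is.na(folding_time(s2, "plain")))  # plain mode ignores <G'>
})

test_that("ensemble contact maps are formation fractions", {
  tn <- make_toy_native(12, "hairpin")
  m1 <- ensemble_contact_map(list(tn$native, tn$native), tn$topology)
  expect_true(all(m1$p == 1))
  stretched <- cbind(seq(0, by = 3.8, length.out = 12), 0, 0)
  m2 <- ensemble_contact_map(list(tn$native, stretched), tn$topology)
  expect_true(all(m2$p == 0.5))
  # permutation invariance
  confs <- list(tn$native, stretched, tn$native)
  expect_equal(ensemble_contact_map(confs, tn$topology)$p,
               ensemble_contact_map(rev(confs), tn$topology)$p)
})

test_that("Z-scores use the population standard deviation", {
  map <- structure(data.frame(i = 1:3, j = 5:7, p = c(0.9, 0.5, 0.1)),
                   class = c("contact_probability_map", "data.frame"))
  z <- contact_zscores(map)
  expect_equal(z, c(1.2247449, 0, -1.2247449), tolerance = 1e-6)
  expect_equal(mean(z), 0)
  map0 <- map
  map0$p <- rep(0.5, 3)
  expect_error(contact_zscores(map0), "variance")
})

test_that("special-contact selection combines the two intermediate maps", {
  mk_map <- function(p) structure(data.frame(i = 1:4, j = 6:9, p = p),
                                  class = c("contact_probability_map", "data.frame"))
  ie <- mk_map(c(0.95, 0.5, 0.2, 0.1))
  it <- mk_map(c(0.2, 0.9, 0.9, 0.85))
  ent <- data.frame(i = c(2, 3), j = c(7, 8))
  sel <- select_special_contacts(ie, it, ent)
  expect_equal(sel$trap_avoiding, data.frame(i = 1, j = 6))
  expect_equal(sel$first_entangling, data.frame(i = 2, j = 7))

  # identical maps cannot satisfy z > 1 and z < 1 simultaneously
  sel2 <- select_special_contacts(ie, ie, ent)
  expect_equal(nrow(sel2$trap_avoiding), 0)
  sel3 <- select_special_contacts(ie, it, ent[0, ])
  expect_equal(nrow(sel3$first_entangling), 0)
})
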