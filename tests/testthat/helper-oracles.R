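# Independent oracles used across the suite. Each reimplements a quantity by
# a different route than the package code it checks.

# exhaustive max-|G'| thread search (quadratic scan over all intervals)
brute_force_max_thread <- function(M, i1, i2, n, mj = 10) {
  best <- 0
  rec <- c(0, 0, 0)
  for (j1 in 1:n) {
    for (j2 in j1:n) {
      if (j2 - j1 < mj) next
      if (!(j2 <= i1 || j1 >= i2)) next
      g <- sum(M[i1:(i2 - 1), j1:(j2 - 1)])
      if (abs(g) > best + 1e-15) {
        best <- abs(g)
        rec <- c(j1, j2, g)
      }
    }
  }
  rec
}

# Horn's quaternion method for optimal-superposition RMSD
quaternion_rmsd <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  S <- crossprod(xc, yc)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(xc^2) + sum(yc^2) - 2 * lam) / nrow(x)
  sqrt(max(msd, 0))
}

# self-avoiding-ish random coil with fixed bond length
random_coil <- function(n, bond = 3.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(0, n, 3)
  for (i in 2:n) {
    repeat {
      d <- rnorm(3)
      cand <- x[i - 1, ] + bond * d / sqrt(sum(d^2))
      if (i < 4 || min(sqrt(rowSums(sweep(x[1:(i - 2), , drop = FALSE], 2,
                                          cand)^2))) > 2.5) break
    }
    x[i, ] <- cand
  }
  x
}

# dense smooth-geometry Gauss integral for the ideal lasso: a near-closed
# circle of radius rho (arc gap `gap`) against a straight segment on the z
# axis (pierce) or displaced by x0
smooth_lasso_gauss <- function(rho, halflength, x0 = 0, n_dense = 2000) {
  gap <- 0.6 / rho
  th <- gap + (seq_len(n_dense) - 1) * (2 * pi - 2 * gap) / (n_dense - 1)
  loop <- cbind(rho * cos(th), rho * sin(th), 0)
  z <- seq(-halflength, halflength, length.out = n_dense)
  thread <- cbind(x0, 0, z)
  gauss_linking(loop, thread, closed_a = FALSE, closed_b = FALSE)
}

# random-but-reproducible rigid motion
random_rigid_motion <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  list(rot = R, shift = rnorm(3, sd = 20))
}

apply_rigid <- function(x, rm) sweep(x %*% t(rm$rot), 2, rm$shift, `+`)

# central finite-difference force check; returns max relative component error
fd_force_error <- function(x, topo, params, h = 1e-6) {
  f <- forces(x, topo, params)
  pe <- function(z) potential_energy(z, topo, params)$total
  fd <- matrix(0, nrow(x), 3)
  for (i in seq_len(nrow(x))) {
    for (k in 1:3) {
      xp <- x; xp[i, k] <- xp[i, k] + h
      xm <- x; xm[i, k] <- xm[i, k] - h
      fd[i, k] <- -(pe(xp) - pe(xm)) / (2 * h)
    }
  }
  max(abs(f - fd) / pmax(abs(fd), 1))
}

# deterministic two-state samples: n draws from a Boltzmann two-level model
# with Omega-fold degenerate Q = 0 states at E = 0 and one Q = 1 state at -E0
two_state_series <- function(temperature, omega, e0, n, seed) {
  set.seed(seed)
  w <- c(omega, exp(e0 / temperature))
  q <- sample(c(0, 1), n, TRUE, w / sum(w))
  data.frame(Q = q, E = ifelse(q == 1, -e0, 0))
}
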