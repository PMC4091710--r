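test_that("a zero mutation prior pins every locus to the null genotype", {
  # with theta2 = 0, loci carrying variant reads are impossible under every
  # admissible genotype, so use an all-zero panel
  p <- tiny_panel(matrix(0L, 3, 3), matrix(20L, 3, 3))
  post <- e_step(p, random_P(2, 3), theta = c(0, 0))
  expect_equal(unname(post$q[, 1]), rep(1, 3))
  expect_equal(unname(post$marginals[, 2]), rep(0, 3))
})

test_that("a well-covered variant locus yields an essentially certain posterior", {
  p <- tiny_panel(matrix(c(0L, 300L), 1), matrix(c(1000L, 1000L), 1))
  P <- matrix(c(1, 0, 0.4, 0.6), 2)
  post <- e_step(p, P, theta = c(0, 0.5))
  expect_gt(post$marginals[1, 2], 0.999999)
})

test_that("E-step posteriors match linear-space Bayes enumeration", {
  for (seed in 1:5) {
    sim <- random_panel(M = 4, S = 3, C = 3, coverage = 25, seed = seed)
    set.seed(seed + 50)
    P <- random_P(3, 3)
    theta <- c(0, runif(2))
    post <- e_step(sim$panel, P, theta)
    expect_equal(post$q, brute_posterior(sim$panel, P, theta),
                 tolerance = 1e-10)
    expect_equal(unname(rowSums(post$q)), rep(1, 4), tolerance = 1e-10)
    # marginals are posterior mass over vectors carrying each mutation
    Z <- post$patterns
    expect_equal(unname(post$marginals), unname(post$q %*% Z),
                 tolerance = 1e-12)
    expect_equal(unname(post$marginals[, 1]), rep(0, 4))
  }
})

test_that("a structurally impossible locus is reported by name", {
  p <- tiny_panel(matrix(c(0L, 5L), 1), matrix(c(10L, 10L), 1),
                  loci = "badlocus")
  P <- matrix(c(1, 0, 1, 0), 2)      # tumor clone absent everywhere
  expect_error(e_step(p, P, theta = c(0, 0.5)), "badlocus")
})

test_that("the mutation-prior update is the posterior mean, verified by grid search", {
  sim <- random_panel(M = 6, S = 3, C = 3, coverage = 30, seed = 7)
  set.seed(57)
  post <- e_step(sim$panel, random_P(3, 3), c(0, runif(2)))
  theta <- m_step_theta(post)
  expect_equal(theta[1], 0)
  expect_equal(theta[-1], unname(colMeans(post$marginals))[-1],
               tolerance = 1e-12)
  # independent oracle: maximize the expected Bernoulli log-likelihood of
  # one clone on a fine grid
  marg <- post$marginals[, 2]
  grid <- seq(0.001, 0.999, by = 0.001)
  obj <- vapply(grid, function(t)
    sum(marg * log(t) + (1 - marg) * log(1 - t)), numeric(1))
  expect_equal(theta[2], grid[which.max(obj)], tolerance = 1e-3)
})

test_that("boundary posteriors give boundary priors", {
  post <- structure(list(q = diag(2), patterns = rbind(c(0, 0), c(0, 1)),
                         marginals = cbind(c(0, 0), c(1, 1)),
                         locus_loglik = NULL), class = "posterior_table")
  expect_equal(m_step_theta(post), c(0, 1))
  post$marginals <- cbind(c(0, 0), c(0.2, 0.8))
  expect_equal(m_step_theta(post), c(0, 0.5))
})

test_that("frequency update matches a one-dimensional grid search", {
  # C = 2, S = 2: after a sharp E step the only free parameter that the
  # likelihood sees is the tumor-clone fraction in the tumor subsection
  sim <- simulate_panel(M = 10, S = 2, C = 2, coverage = 500, seed = 21)
  post <- e_step(sim$panel, random_P(2, 2), c(0, 0.5))
  P1 <- m_step_P(sim$panel, post, random_P(2, 2))
  parts <- clonesect:::q1_parts(sim$panel, post)
  u_norm <- P1[2, 1]                 # the objective is separable by column
  obj1 <- function(u) clonesect:::q1_value(rbind(c(u_norm, u)), parts)
  coarse <- seq(0.001, 0.998, by = 0.001)
  u0 <- coarse[which.max(vapply(coarse, obj1, numeric(1)))]
  fine <- seq(max(u0 - 0.002, 0), min(u0 + 0.002, 0.999), by = 1e-6)
  u_star <- fine[which.max(vapply(fine, obj1, numeric(1)))]
  expect_lt(abs(P1[2, 2] - u_star), 1e-4)
  expect_equal(unname(colSums(P1)), c(1, 1), tolerance = 1e-8)
})

test_that("the analytic Q1 gradient matches central finite differences", {
  sim <- random_panel(M = 6, S = 3, C = 3, coverage = 80, seed = 31)
  set.seed(31)
  post <- e_step(sim$panel, random_P(3, 3), c(0, runif(2)))
  parts <- clonesect:::q1_parts(sim$panel, post)
  h <- 1e-6
  for (rep in 1:20) {
    u <- matrix(runif(6, 0.05, 0.45), 2, 3)   # interior feasible point
    g <- clonesect:::q1_gradient(u, parts)
    for (idx in seq_along(u)) {
      up <- u; up[idx] <- up[idx] + h
      dn <- u; dn[idx] <- dn[idx] - h
      fd <- (clonesect:::q1_value(up, parts) -
               clonesect:::q1_value(dn, parts)) / (2 * h)
      expect_equal(g[idx], fd, tolerance = 1e-4 * max(1, abs(fd)))
    }
  }
})

test_that("a flat objective still returns a feasible frequency matrix", {
  # all-zero variant counts put every locus's posterior on the null
  # genotype, so Q1 is constant in P
  p <- tiny_panel(matrix(0L, 4, 3), matrix(30L, 4, 3))
  post <- e_step(p, random_P(2, 3), c(0, 0.2))
  P1 <- m_step_P(p, post, random_P(2, 3))
  expect_equal(unname(colSums(P1)), rep(1, 3), tolerance = 1e-8)
  expect_true(all(P1[1, ] >= 1e-3 - 1e-10))
})

test_that("EM recovers the true structure on clean two-clone data", {
  hits <- 0L
  for (r in 1:20) {
    sim <- simulate_panel(M = 20, S = 4, C = 2, coverage = 1000,
                          seed = 600 + r)
    fit <- clonal_fit(sim$panel, 2, restarts = 10, seed = 600 + r)
    err <- match_and_score(sim$W, sim$P, fit$W, fit$P)
    if (err$genotype_error == 0) hits <- hits + 1L
    expect_true(all(diff(fit$loglik_trace) >=
                      -1e-6 * abs(fit$loglik_trace[-fit$n_iter])))
  }
  expect_gte(hits, 19L)
})

test_that("converged posterior mutation probabilities are numerically binary", {
  sim <- simulate_panel(M = 30, S = 6, C = 3, coverage = 1000, seed = 77)
  fit <- clonal_fit(sim$panel, 3, restarts = 5, seed = 77)
  expect_lt(max(abs(fit$marginals - round(fit$marginals))), 1e-6)
})

test_that("every iteration's frequencies satisfy the simplex and contamination floor", {
  sim <- simulate_panel(M = 15, S = 4, C = 3, coverage = 200, seed = 41)
  fit <- run_em(sim$panel, 3, seed = 41)
  expect_equal(unname(colSums(fit$P)), rep(1, 4), tolerance = 1e-8)
  expect_true(all(fit$P[1, ] >= 1e-3 - 1e-8))
  expect_true(all(fit$P >= -1e-12))
})

test_that("the normal subsection's fit concentrates on the normal clone", {
  sim <- simulate_panel(M = 40, S = 5, C = 3, coverage = 1000, seed = 51)
  fit <- clonal_fit(sim$panel, 3, restarts = 5, seed = 51)
  expect_gte(fit$P[1, 1], 1 - 10 * 1e-3)
})

test_that("permuting the initialization's tumor clones permutes the solution", {
  sim <- simulate_panel(M = 15, S = 4, C = 3, coverage = 300, seed = 61)
  set.seed(61)
  init <- list(P = random_P(3, 4), theta = c(0, 0.4, 0.7))
  f1 <- run_em(sim$panel, 3, seed = 1, init = init)
  perm <- c(1, 3, 2)
  f2 <- run_em(sim$panel, 3, seed = 1,
               init = list(P = init$P[perm, ], theta = init$theta[perm]))
  expect_equal(unname(f2$P), unname(f1$P[perm, ]), tolerance = 1e-6)
  expect_equal(unname(f2$theta), unname(f1$theta[perm]), tolerance = 1e-6)
  expect_equal(f2$Q_star, f1$Q_star, tolerance = 1e-8)
})

test_that("clone count above the sample count is rejected without an override", {
  sim <- simulate_panel(M = 10, S = 3, C = 2, coverage = 100, seed = 71)
  expect_error(run_em(sim$panel, 4, seed = 1), "may not exceed")
  expect_s3_class(run_em(sim$panel, 4, seed = 1, allow_extra_clones = TRUE),
                  "clone_fit")
})

test_that("one restart reduces to a single seeded run and more restarts never hurt", {
  sim <- simulate_panel(M = 12, S = 3, C = 2, coverage = 150, seed = 81)
  single <- clonal_fit(sim$panel, 2, restarts = 1, seed = 81)
  direct <- run_em(sim$panel, 2, seed = 82)
  expect_equal(single$Q_star, direct$Q_star)
  expect_equal(single$loglik_trace, direct$loglik_trace)
  best <- -Inf
  for (R in c(1, 3, 5)) {
    fit <- clonal_fit(sim$panel, 2, restarts = R, seed = 81)
    expect_gte(fit$Q_star, best)
    best <- fit$Q_star
  }
})

test_that("the EM fixed point matches a dense grid search of the marginal likelihood", {
  # C = 2, S = 2, tiny counts: the observed likelihood has three free
  # parameters (tumor fraction in each subsection, mutation prior)
  p <- tiny_panel(matrix(c(1L, 0L, 2L, 8L, 6L, 0L), 3),
                  matrix(c(20L, 20L, 20L, 20L, 20L, 20L), 3))
  fit <- clonal_fit(p, 2, restarts = 10, seed = 5)
  gr_u <- seq(0, 0.98, by = 0.01)    # tumor-clone fraction per subsection
  gr_t <- seq(0.01, 0.99, by = 0.01) # mutation prior
  l0 <- dbinom(p$X[, 1], p$N[, 1], 0) * dbinom(p$X[, 2], p$N[, 2], 0)
  lik1 <- vapply(gr_u, function(u) dbinom(p$X[, 1], p$N[, 1], u / 2),
                 numeric(3))
  lik2 <- vapply(gr_u, function(u) dbinom(p$X[, 2], p$N[, 2], u / 2),
                 numeric(3))
  best <- -Inf
  for (a in seq_along(gr_u)) {
    for (b in seq_along(gr_u)) {
      l1 <- lik1[, a] * lik2[, b]
      cand <- max(colSums(log(outer(l0, 1 - gr_t) + outer(l1, gr_t))))
      if (cand > best) best <- cand
    }
  }
  # the grid terms are dbinom products, so coefficients are on both sides
  expect_gte(fit$observed_loglik, best - 1e-6)
  expect_equal(fit$observed_loglik, best, tolerance = 0.05)
})
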