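# fabricate a minimal jsdm_fit object with prescribed draws, for testing the
# posterior summaries independently of the sampler
fake_fit <- function(beta, rho = NULL, lambda = NULL, h = NULL, sigma2 = NULL,
                     X = NULL, groups = NULL, family = "probit",
                     n_factors = if (is.null(lambda)) 0L else dim(lambda)[3]) {
  nd <- dim(beta)[1]; S <- dim(beta)[2]
  n <- if (!is.null(X)) nrow(X) else 4L
  spec <- jsdm_spec(family, n_factors = n_factors, n_iter = 2L, n_burn = 1L,
                    thin = 1L, n_chains = 1L)
  structure(list(beta = beta,
                 rho = rho %||% rep(0, nd),
                 lambda = lambda %||% array(0, c(nd, S, 0)),
                 h = h %||% array(0, c(nd, n, 0)),
                 sigma2 = sigma2 %||% matrix(1, nd, S),
                 chain = rep(1L, nd),
                 Y = matrix(0L, n, S, dimnames = list(NULL, dimnames(beta)[[2]])),
                 X = X, Xe = if (!is.null(X)) cbind(1, X),
                 groups = groups, C = diag(S), spec = spec,
                 rhat = c(rho = 1)),
            class = "jsdm_fit")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("tjur_r2 matches its definitional oracle", {
  expect_equal(tjur_r2(c(1, 0, 1, 0), c(0.8, 0.4, 0.6, 0.2)), 0.4)
  y <- c(1, 0, 1, 1, 0)
  expect_equal(tjur_r2(y, y), 1)
  expect_equal(tjur_r2(y, rep(0.37, 5)), 0)
  set.seed(9)
  for (i in 1:25) {
    y <- rbinom(30, 1, 0.5)
    if (sum(y) %in% c(0, 30)) next
    p <- runif(30)
    expect_equal(tjur_r2(y, p), tjur_brute(y, p), tolerance = 1e-12)
  }
  expect_error(tjur_r2(rep(1, 5), runif(5)), "single-class")
})

test_that("Gaussian sampler matches the conjugate closed form", {
  # rho = 0, no factors, fixed unit residual variance: the per-species
  # posterior of beta is N((X'X + I/tau2)^-1 X'y, (X'X + I/tau2)^-1)
  set.seed(5)
  n <- 40; S <- 5; P <- 3
  X <- matrix(rnorm(n * P), n, P, dimnames = list(NULL, paste0("x", 1:P)))
  B <- matrix(rnorm(S * P), S, P)
  Y <- X %*% t(B) + matrix(rnorm(n * S), n, S)
  colnames(Y) <- paste0("sp", 1:S)
  spec <- jsdm_spec("gaussian", n_factors = 0, rho_grid = 0, tau2 = 1,
                    tau_sample = FALSE, sigma2_fixed = 1,
                    n_iter = 4000, n_burn = 1000, thin = 1, n_chains = 2,
                    seed = 3)
  fit <- jsdm_fit(Y, X, C = NULL, spec)
  Xe <- cbind(1, X)
  Vpost <- solve(crossprod(Xe) + diag(ncol(Xe)))
  for (j in seq_len(S)) {
    mpost <- as.vector(Vpost %*% crossprod(Xe, Y[, j]))
    expect_equal(unname(colMeans(fit$beta[, j, ])), mpost, tolerance = 0.02)
    expect_equal(unname(diag(cov(fit$beta[, j, ]))), unname(diag(Vpost)),
                 tolerance = 0.12)
  }
  expect_lt(max(fit$rhat), 1.05)
})

test_that("flat-prior Gaussian posterior approaches per-species OLS", {
  set.seed(8)
  n <- 60; S <- 4; P <- 2
  X <- matrix(rnorm(n * P), n, P, dimnames = list(NULL, paste0("x", 1:P)))
  Y <- X %*% t(matrix(rnorm(S * P), S, P)) + matrix(rnorm(n * S, sd = 0.5), n, S)
  colnames(Y) <- paste0("sp", 1:S)
  spec <- jsdm_spec("gaussian", n_factors = 0, rho_grid = 0, tau2 = 100,
                    tau_sample = FALSE, n_iter = 2000, n_burn = 500, thin = 1,
                    n_chains = 1, seed = 2)
  fit <- jsdm_fit(Y, X, C = NULL, spec)
  Xe <- cbind(1, X)
  ols <- solve(crossprod(Xe)) %*% crossprod(Xe, Y)
  for (j in seq_len(S))
    expect_equal(unname(colMeans(fit$beta[, j, ])), unname(ols[, j]),
                 tolerance = 0.05)
})

test_that("intercept-only probit model reproduces empirical prevalences", {
  set.seed(2)
  n <- 150; S <- 20
  Y <- sapply(runif(S, 0.2, 0.8), function(p) rbinom(n, 1, p))
  colnames(Y) <- paste0("sp", 1:S)
  X <- matrix(numeric(0), n, 0)
  spec <- jsdm_spec("probit", n_factors = 0, rho_grid = 0,
                    n_iter = 1200, n_burn = 400, thin = 2, n_chains = 1,
                    seed = 1)
  fit <- jsdm_fit(Y, X, C = NULL, spec)
  phat <- pnorm(colMeans(fit$beta[, , 1]))
  expect_true(all(abs(phat - colMeans(Y)) < 0.05))
})

test_that("probit family rejects non-binary input and misaligned ids", {
  Y <- matrix(c(0, 1, 2, 1), 2, 2)
  expect_error(jsdm_fit(Y, matrix(rnorm(2), 2, 1), spec = jsdm_spec("probit")),
               "0/1")
  Y2 <- matrix(rbinom(20, 1, 0.5), 10, 2,
               dimnames = list(paste0("a", 1:10), c("s1", "s2")))
  X2 <- matrix(rnorm(10), 10, 1, dimnames = list(paste0("b", 1:10), "x"))
  expect_error(jsdm_fit(Y2, X2, spec = jsdm_spec("probit")), "misaligned")
})

test_that("support calls apply the inclusive 95% boundary", {
  nd <- 100; S <- 2
  beta <- array(0, c(nd, S, 2), dimnames = list(NULL, c("o1", "o2"),
                                                c("(Intercept)", "x")))
  beta[, 1, 2] <- abs(rnorm(nd)) + 0.1          # all positive
  beta[, 2, 2] <- c(rep(1, 95), rep(-1, 5))     # exactly 95% positive
  sc <- support_calls(fake_fit(beta))
  expect_equal(sc$call[sc$otu == "o1"], "positive-strong")
  expect_equal(sc$call[sc$otu == "o2"], "positive-strong")
  beta[, 2, 2] <- c(rep(1, 94), rep(-1, 6))     # 94%: no call
  expect_equal(support_calls(fake_fit(beta))$call[2], "none")
  beta[, 1, 2] <- -abs(rnorm(nd)) - 0.1
  expect_equal(support_calls(fake_fit(beta))$call[1], "negative-strong")

  # symmetric null posterior yields almost no calls
  set.seed(4)
  bnull <- array(rnorm(500 * 10 * 3), c(500, 10, 3),
                 dimnames = list(NULL, paste0("o", 1:10), c("(Intercept)", "a", "b")))
  scn <- support_calls(fake_fit(bnull))
  expect_lt(mean(scn$call != "none"), 0.2)
})

test_that("variance partitioning normalizes and respects generative control", {
  # single-group design, no factors: that group takes share 1
  set.seed(10)
  n <- 20; S <- 3; nd <- 50
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "pH"))
  beta <- array(rnorm(nd * S * 2), c(nd, S, 2),
                dimnames = list(NULL, paste0("o", 1:S), c("(Intercept)", "pH")))
  f <- fake_fit(beta, X = X, groups = 1L)
  vp <- variance_partition(f)
  expect_equal(unname(vp$species[, "G1"]), rep(1, S), tolerance = 1e-12)

  # shares sum to one and are invariant to compensated rescaling
  X2 <- cbind(X, z = rnorm(n))
  beta2 <- array(rnorm(nd * S * 3), c(nd, S, 3),
                 dimnames = list(NULL, paste0("o", 1:S),
                                 c("(Intercept)", "pH", "z")))
  f2 <- fake_fit(beta2, X = X2, groups = c(1L, 3L))
  vp2 <- variance_partition(f2)
  expect_equal(unname(rowSums(vp2$species)), rep(1, S), tolerance = 1e-8)
  X3 <- X2; X3[, 2] <- X3[, 2] * 10
  beta3 <- beta2; beta3[, , 3] <- beta3[, , 3] / 10
  vp3 <- variance_partition(fake_fit(beta3, X = X3, groups = c(1L, 3L)))
  expect_equal(vp3$species, vp2$species, tolerance = 1e-10)
})

test_that("pH-only generative control puts G1 on top of the partition", {
  cfg <- sim_config(n_blocks = 12, n_otus = 30, n_samples_dropped = 0,
                    read_depth_target = 1000, rho_true = 0.5,
                    beta_scale = c(G1 = 1.2, G2 = 0, G3 = 0, G4 = 0),
                    n_factors_true = 0, occupancy_sd = 0, seed = 33)
  sim <- simulate_dataset(cfg)
  Ypa <- (sim$counts > 0) * 1
  keep <- pa_filter(Ypa, 5, 5)
  X <- build_design(sim$soil)
  C <- phylo_correlation(sim$tree)[keep, keep]
  spec <- jsdm_spec("probit", n_factors = 2, n_iter = 600, n_burn = 200,
                    thin = 2, n_chains = 1, seed = 4)
  fit <- jsdm_fit(Ypa[, keep], X, C, spec)
  vp <- variance_partition(fit)
  shares <- vp$community
  grp <- shares[c("G1", "G2", "G3", "G4")]
  expect_equal(names(which.max(grp)), "G1")
  expect_equal(unname(sum(shares)), 1, tolerance = 1e-8)
})

test_that("phylo_signal_summary reduces the rho draws correctly", {
  f <- fake_fit(array(0, c(200, 2, 1),
                      dimnames = list(NULL, c("a", "b"), "(Intercept)")),
                rho = rep(0.5, 200))
  s <- phylo_signal_summary(f)
  expect_equal(s$mean, 0.5)
  expect_equal(s$ci, c(0.5, 0.5))
  grid <- seq(0, 1, length.out = 101)
  f2 <- fake_fit(array(0, c(101 * 40, 2, 1),
                       dimnames = list(NULL, c("a", "b"), "(Intercept)")),
                 rho = rep(grid, 40))
  s2 <- phylo_signal_summary(f2)
  expect_equal(s2$mean, 0.5, tolerance = 1e-9)
  expect_lt(max(abs(s2$ci - c(0.025, 0.975))), 0.02)
  expect_true(all(s2$ci >= 0 & s2$ci <= 1))
})

test_that("residual associations recover a planted positive block", {
  nd <- 200; S <- 8
  lam <- array(0, c(nd, S, 1))
  lam[, 1:4, 1] <- 1.5    # block sharing one strong factor
  beta <- array(0, c(nd, S, 1),
                dimnames = list(NULL, paste0("o", 1:S), "(Intercept)"))
  f <- fake_fit(beta, lambda = lam, h = array(0, c(nd, 4, 1)), n_factors = 1L)
  ra <- residual_associations(f)
  expect_equal(ra$correlation, t(ra$correlation))
  expect_equal(unname(diag(ra$correlation)), rep(1, S))
  expect_true(all(ra$support[1:4, 1:4] == 1))
  expect_true(all(ra$correlation[5:8, 5:8][upper.tri(diag(4))] == 0))

  # Lambda = 0 in all draws: no supported pairs off the diagonal
  f0 <- fake_fit(beta, lambda = array(0, c(nd, S, 1)),
                 h = array(0, c(nd, 4, 1)), n_factors = 1L)
  ra0 <- residual_associations(f0)
  expect_true(all(ra0$correlation[upper.tri(ra0$correlation)] == 0))
  expect_true(all(ra0$support[upper.tri(ra0$support)] <= 0))

  fno <- fake_fit(beta, n_factors = 0L)
  expect_true(residual_associations(fno)$no_random_effect)
})

test_that("latent factors absorb residual co-occurrence in the sampler", {
  set.seed(14)
  n <- 80; S <- 12
  h <- rnorm(n)
  lam <- c(rep(2, 6), rep(0, 6))
  Y <- (matrix(rnorm(n * S), n, S) + outer(h, lam) > 0) * 1
  colnames(Y) <- paste0("sp", 1:S)
  spec <- jsdm_spec("probit", n_factors = 1, rho_grid = 0,
                    n_iter = 1500, n_burn = 500, thin = 2, n_chains = 1,
                    seed = 6)
  fit <- jsdm_fit(Y, matrix(numeric(0), n, 0), C = NULL, spec)
  ra <- residual_associations(fit)
  block <- ra$correlation[1:6, 1:6][upper.tri(diag(6))]
  off <- ra$correlation[1:6, 7:12]
  expect_gt(mean(block), 0.3)
  expect_lt(mean(abs(off)), mean(block))
})
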