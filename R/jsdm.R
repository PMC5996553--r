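#' Specification of the joint species distribution model
#'
#' Defines the model family and sampler settings for [jsdm_fit()]. The model,
#' for sample i and species (OTU) j, is
#' \deqn{z_{ij} = x_i' \beta_j + h_i' \lambda_j + \epsilon_{ij}}
#' with an intercept prepended to the predictors internally. For the probit
#' family the residual variance is fixed at 1 and the observation is
#' `y = 1(z > 0)`; for the Gaussian family `z` is the (log-transformed,
#' centered) abundance and `sigma_j^2` has an inverse-gamma prior. Species
#' responses are tied across the phylogeny: each predictor's column of the
#' species-by-predictor matrix `B` has prior `N(0, tau2 * (rho*C + (1-rho)*I))`
#' where `C` is the phylogenetic tip correlation matrix and `rho` in `[0,1]`
#' measures the strength of the phylogenetic signal. `rho` is sampled from
#' its discrete full conditional on `rho_grid` (uniform grid prior). The
#' community-level random effect is a fixed-rank latent factor term with
#' standard-normal priors on scores and loadings.
#'
#' @param family `"probit"` (presence-absence, Bernoulli with probit link) or
#'   `"gaussian"` (log abundance).
#' @param n_factors latent factors (default 2; 0 disables the random effect).
#' @param rho_grid grid for the phylogenetic signal (default 101 equispaced
#'   points on `[0, 1]`).
#' @param tau2 prior variance of the species loadings on the standardized
#'   predictors (default 1). With `tau_sample = TRUE` (default) this is the
#'   initial value of per-predictor scales `tau2_k` that are sampled from
#'   conjugate inverse-gamma conditionals, letting the prior scale of each
#'   predictor's loadings adapt to the data; with `tau_sample = FALSE` the
#'   scale is held fixed at `tau2` (used for conjugate closed-form checks).
#' @param tau_sample sample the per-predictor prior scales (default TRUE).
#' @param tau_shape,tau_rate inverse-gamma prior for the sampled `tau2_k`
#'   (default 2, 1: mean 1).
#' @param sigma_shape,sigma_rate inverse-gamma prior for the Gaussian
#'   residual variances (default 0.1, 0.1).
#' @param sigma2_fixed optional fixed residual variance for the Gaussian
#'   family (disables the sigma update; used for conjugate checks).
#' @param n_iter,n_burn,thin,n_chains MCMC settings; retained draws number
#'   `(n_iter - n_burn) / thin * n_chains`.
#' @param seed integer seed; chains use derived seeds.
#' @return list of class `jsdm_spec`.
#' @export
jsdm_spec <- function(family = c("probit", "gaussian"), n_factors = 2L,
                      rho_grid = seq(0, 1, length.out = 101), tau2 = 1,
                      tau_sample = TRUE, tau_shape = 2, tau_rate = 1,
                      sigma_shape = 0.1, sigma_rate = 0.1, sigma2_fixed = NULL,
                      n_iter = 5000L, n_burn = 2500L, thin = 5L,
                      n_chains = 2L, seed = 1L) {
  family <- match.arg(family)
  if (any(rho_grid < 0 | rho_grid > 1)) stop("rho_grid must lie in [0, 1]")
  if (n_burn >= n_iter) stop("n_burn must be < n_iter")
  structure(list(family = family, n_factors = as.integer(n_factors),
                 rho_grid = rho_grid, tau2 = tau2, tau_sample = tau_sample,
                 tau_shape = tau_shape, tau_rate = tau_rate,
                 sigma_shape = sigma_shape, sigma_rate = sigma_rate,
                 sigma2_fixed = sigma2_fixed,
                 n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed)),
            class = "jsdm_spec")
}

# truncated standard-normal draw around mu with sign constrained by y
rtruncnorm_probit <- function(y, mu) {
  p0 <- stats::pnorm(-mu)                      # P(z <= 0)
  u <- ifelse(y > 0,
              p0 + stats::runif(length(mu)) * (1 - p0),
              stats::runif(length(mu)) * p0)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  mu + stats::qnorm(u)
}

#' Fit the joint species distribution model by blocked Gibbs sampling
#'
#' Sampler blocks: (a) probit latent liabilities from their truncated-normal
#' conditionals; (b) the whole species-by-predictor matrix `B` from its
#' matrix-normal full conditional, drawn exactly via simultaneous
#' diagonalization of the likelihood precision (`X'X`, eigendecomposed once)
#' and the species-side prior precision (whose eigenvectors are those of `C`
#' for the probit family, so no per-iteration decomposition is needed);
#' (c) `rho` from its discrete full conditional over `rho_grid`;
#' (d) factor loadings and scores from Gaussian conditionals; (e) Gaussian
#' residual variances from inverse-gamma conditionals.
#'
#' @param Y samples x species matrix; 0/1 for the probit family, numeric for
#'   the Gaussian family.
#' @param X samples x predictors design (no intercept column), e.g. a
#'   [build_design()] result. Rows must align with `Y`.
#' @param C species correlation matrix from [phylo_correlation()], indexed by
#'   `colnames(Y)`; `NULL` fixes `rho = 0` (no phylogenetic structure).
#' @param spec a [jsdm_spec()].
#' @return object of class `jsdm_fit` holding posterior draws (`beta`:
#'   draws x species x predictors, `rho`, `lambda`, `h`, `sigma2`), the data
#'   and design metadata, and split-chain potential-scale-reduction
#'   diagnostics for `rho` and the `beta` of the first species.
#' @export
jsdm_fit <- function(Y, X, C = NULL, spec = jsdm_spec()) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("Y and X row counts differ")
  if (!is.null(rownames(Y)) && !is.null(rownames(X)) &&
      !identical(rownames(Y), rownames(X)))
    stop("Y and X sample ids are misaligned")
  n <- nrow(Y); S <- ncol(Y)
  if (spec$family == "probit" && !all(Y %in% c(0, 1)))
    stop("probit family requires a 0/1 matrix")
  groups <- attr(X, "groups")
  Xe <- cbind(`(Intercept)` = 1, X)
  P <- ncol(Xe)

  if (!is.null(C)) {
    C <- as.matrix(C)
    if (!is.null(colnames(Y))) {
      if (!all(colnames(Y) %in% colnames(C)))
        stop("C does not cover all species in Y")
      C <- C[colnames(Y), colnames(Y)]
    }
    eC <- eigen(C, symmetric = TRUE)
    if (min(eC$values) < -1e-8) {
      eC <- eigen(C + diag(1e-8, S), symmetric = TRUE)
      if (min(eC$values) < -1e-8) stop("C is not positive semi-definite")
    }
    U <- eC$vectors; dC <- pmax(eC$values, 0)
    rho_grid <- spec$rho_grid
  } else {
    U <- diag(S); dC <- rep(1, S)
    rho_grid <- 0
  }
  G <- length(rho_grid)
  # eigenvalues of rho*C + (1-rho)*I for every grid value (shared basis U)
  lam_rho <- outer(dC, rho_grid, function(d, r) r * d + (1 - r))
  lam_rho <- pmax(lam_rho, 1e-10)
  logdet_rho <- colSums(log(lam_rho))

  XtX0 <- crossprod(Xe)

  FF <- spec$n_factors
  n_keep <- (spec$n_iter - spec$n_burn) %/% spec$thin
  nd <- n_keep * spec$n_chains
  beta_d <- array(NA_real_, c(nd, S, P),
                  dimnames = list(NULL, colnames(Y), colnames(Xe)))
  rho_d <- numeric(nd)
  lam_d <- array(NA_real_, c(nd, S, FF))
  h_d <- array(NA_real_, c(nd, n, FF))
  sig_d <- matrix(NA_real_, nd, S)
  chain_of <- rep(seq_len(spec$n_chains), each = n_keep)

  gauss <- spec$family == "gaussian"
  for (ch in seq_len(spec$n_chains)) {
    set.seed((spec$seed + 7919L * (ch - 1L)) %% .Machine$integer.max)
    z <- if (gauss) Y else ifelse(Y > 0, 0.7, -0.7)
    Bmat <- t(solve(XtX0 + diag(P), crossprod(Xe, z)))            # S x P init
    rho_i <- if (G > 1) (G + 1) %/% 2 else 1L
    Lam <- matrix(0, S, FF); Hf <- matrix(0, n, FF)
    sig2 <- if (gauss && !is.null(spec$sigma2_fixed))
      rep(spec$sigma2_fixed, S) else rep(1, S)
    tau2 <- rep(spec$tau2, P)

    for (it in seq_len(spec$n_iter)) {
      eta_fix <- Xe %*% t(Bmat)
      eta_lat <- if (FF > 0) Hf %*% t(Lam) else 0
      if (!gauss) z <- matrix(rtruncnorm_probit(Y, eta_fix + eta_lat), n, S)

      ## --- B: joint matrix-normal draw ---
      ## tau is absorbed into the design (B = A D_tau, A columns ~ N(0,
      ## Sigma_rho)); sigma is absorbed into the species side. The full
      ## conditional of A is then diagonalized by the eigenbases of
      ## Xt'Xt (P x P, cheap) and of the species-side precision.
      R <- z - eta_lat                                  # n x S target
      s <- sqrt(sig2); tau <- sqrt(tau2)
      Xt <- sweep(Xe, 2, tau, `*`)
      eX <- eigen(crossprod(Xt), symmetric = TRUE)
      Qx <- eX$vectors; lx <- pmax(eX$values, 0)
      lpsi_base <- 1 / lam_rho[, rho_i]                 # eig of Sigma_rho^-1
      if (gauss && stats::sd(s) > 1e-12) {
        # species-side precision of the scaled loadings: D_s Sigma_rho^-1 D_s
        Ps <- outer(s, s) * (U %*% (t(U) * lpsi_base))
        eP <- eigen((Ps + t(Ps)) / 2, symmetric = TRUE)
        V <- eP$vectors; lpsi <- pmax(eP$values, 1e-12)
      } else {
        V <- U; lpsi <- lpsi_base * s[1]^2
      }
      Bt_lik <- crossprod(R, Xt) / s                    # = D_s^{-1} R' Xt
      Btl <- crossprod(V, Bt_lik) %*% Qx                # transformed RHS
      denom <- outer(lpsi, lx, `+`)
      Gam_t <- Btl / denom +
        matrix(stats::rnorm(S * P), S, P) / sqrt(denom)
      A <- (V %*% Gam_t %*% t(Qx)) * s                  # A = D_s Gamma
      Bmat <- sweep(A, 2, tau, `*`)

      ## --- rho and tau: conditionals given B ---
      Btil <- crossprod(U, Bmat)                        # S x P in C's basis
      E2 <- Btil^2
      if (G > 1) {
        q <- as.vector(E2 %*% (1 / tau2))
        logp <- -(P / 2) * logdet_rho - colSums(q / lam_rho) / 2
        logp <- logp - max(logp)
        rho_i <- sample.int(G, 1L, prob = exp(logp))
      }
      if (isTRUE(spec$tau_sample)) {
        tk <- colSums(E2 / lam_rho[, rho_i])
        tau2 <- 1 / stats::rgamma(P, spec$tau_shape + S / 2,
                                  spec$tau_rate + tk / 2)
      }

      ## --- latent factors ---
      if (FF > 0) {
        E <- z - Xe %*% t(Bmat)
        # loadings
        eH <- eigen(crossprod(Hf), symmetric = TRUE)
        Qh <- eH$vectors; lh <- pmax(eH$values, 0)
        A <- crossprod(Qh, crossprod(Hf, E))            # F x S
        denL <- outer(lh, sig2, `/`) + 1
        At <- sweep(A, 2, sig2, `/`) / denL
        Lam <- t(Qh %*% (At + matrix(stats::rnorm(FF * S), FF, S) / sqrt(denL)))
        # scores
        Pf <- crossprod(Lam / sig2, Lam) + diag(FF)
        Rf <- chol(Pf)
        Mh <- t(backsolve(Rf, forwardsolve(t(Rf), t((E %*% (Lam / sig2))))))
        Hf <- Mh + t(backsolve(Rf, matrix(stats::rnorm(n * FF), FF, n)))
      }

      ## --- residual variances ---
      if (gauss && is.null(spec$sigma2_fixed)) {
        resid <- z - Xe %*% t(Bmat) - (if (FF > 0) Hf %*% t(Lam) else 0)
        sig2 <- 1 / stats::rgamma(S, spec$sigma_shape + n / 2,
                                  spec$sigma_rate + colSums(resid^2) / 2)
      }

      if (it > spec$n_burn && (it - spec$n_burn) %% spec$thin == 0) {
        ix <- (ch - 1L) * n_keep + (it - spec$n_burn) %/% spec$thin
        beta_d[ix, , ] <- Bmat
        rho_d[ix] <- rho_grid[rho_i]
        if (FF > 0) { lam_d[ix, , ] <- Lam; h_d[ix, , ] <- Hf }
        sig_d[ix, ] <- sig2
      }
    }
  }

  diag_rhat <- c(rho = split_rhat(matrix(rho_d, ncol = spec$n_chains)),
                 stats::setNames(
                   vapply(seq_len(P), function(k)
                     split_rhat(matrix(beta_d[, 1, k], ncol = spec$n_chains)),
                     numeric(1)),
                   paste0("beta1_", colnames(Xe))))

  structure(list(beta = beta_d, rho = rho_d, lambda = lam_d, h = h_d,
                 sigma2 = sig_d, chain = chain_of,
                 Y = Y, X = X, Xe = Xe, groups = groups, C = C,
                 spec = spec, rhat = diag_rhat),
            class = "jsdm_fit")
}

# split-chain potential scale reduction factor; draws as matrix draws x chains
split_rhat <- function(draws) {
  half <- floor(nrow(draws) / 2)
  segs <- cbind(draws[seq_len(half), , drop = FALSE],
                draws[half + seq_len(half), , drop = FALSE])
  m <- ncol(segs); nn <- nrow(segs)
  mu <- colMeans(segs)
  W <- mean(apply(segs, 2, stats::var))
  B <- nn * stats::var(mu)
  if (!is.finite(W) || W <= 1e-300) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' @export
print.jsdm_fit <- function(x, ...) {
  cat("JSDM fit (", x$spec$family, " family)\n", sep = "")
  cat(sprintf("  %d samples x %d species, %d predictors (+intercept), %d factors\n",
              nrow(x$Y), ncol(x$Y), ncol(x$X), x$spec$n_factors))
  cat(sprintf("  %d retained draws (%d chains)\n",
              length(x$rho), x$spec$n_chains))
  if (!is.null(x$C))
    cat(sprintf("  phylogenetic signal rho: %.3f (%.3f-%.3f)\n",
                mean(x$rho), stats::quantile(x$rho, 0.025),
                stats::quantile(x$rho, 0.975)))
  cat(sprintf("  max split-Rhat: %.3f\n", max(x$rhat, na.rm = TRUE)))
  invisible(x)
}
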