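#' Posterior sign-support calls per species and predictor
#'
#' For every species x predictor cell, the posterior probability that the
#' loading is positive (fraction of retained draws with `beta > 0`). A call
#' is `"positive-strong"` when that probability is at least 0.95,
#' `"negative-strong"` when it is at most 0.05 (boundary inclusive), and
#' `"none"` otherwise. The intercept is excluded.
#'
#' @param fit a [jsdm_fit()] result with at least 100 retained draws.
#' @return data.frame with `otu`, `predictor`, `beta_mean`, `p_positive`,
#'   `call`.
#' @export
support_calls <- function(fit) {
  stopifnot(inherits(fit, "jsdm_fit"))
  if (length(fit$rho) < 100) stop("need at least 100 retained draws")
  b <- fit$beta[, , -1, drop = FALSE]
  pm <- apply(b, c(2, 3), mean)
  pp <- apply(b, c(2, 3), function(d) mean(d > 0))
  out <- data.frame(
    otu = rep(rownames(pm), times = ncol(pm)),
    predictor = rep(colnames(pm), each = nrow(pm)),
    beta_mean = as.vector(pm), p_positive = as.vector(pp),
    stringsAsFactors = FALSE)
  out$call <- ifelse(out$p_positive >= 0.95, "positive-strong",
                     ifelse(out$p_positive <= 0.05, "negative-strong", "none"))
  out
}

#' Variance partitioning over predictor groups and the latent effect
#'
#' Per posterior draw and species, the variance (over samples) of each
#' predictor group's partial linear predictor `X_g beta_g` and of the latent
#' part `H lambda_j`; proportions are normalized per species and draw, then
#' averaged over draws, and over species for the community means. The
#' intercept contributes no variance and is excluded.
#'
#' @param fit a [jsdm_fit()] result whose design carried a `groups`
#'   attribute (as from [build_design()]).
#' @return list with `species` (species x components proportion matrix),
#'   `community` (named mean shares) and `flagged` (species with zero total
#'   variance in every draw, excluded from the community mean).
#' @export
variance_partition <- function(fit) {
  stopifnot(inherits(fit, "jsdm_fit"))
  groups <- fit$groups
  if (is.null(groups)) stop("design has no group labels")
  glev <- sort(unique(groups))
  nd <- length(fit$rho); S <- ncol(fit$Y)
  FF <- fit$spec$n_factors
  comp <- c(paste0("G", glev), if (FF > 0) "latent")
  acc <- array(0, c(nd, S, length(comp)))
  X <- fit$X
  popvar <- function(M) colMeans(M^2) - colMeans(M)^2
  for (t in seq_len(nd)) {
    v <- matrix(0, S, length(comp))
    for (gi in seq_along(glev)) {
      cols <- which(groups == glev[gi])
      Bg <- matrix(fit$beta[t, , cols + 1L], nrow = S)
      v[, gi] <- popvar(X[, cols, drop = FALSE] %*% t(Bg))
    }
    if (FF > 0) {
      Ht <- matrix(fit$h[t, , ], nrow = nrow(X))
      Lt <- matrix(fit$lambda[t, , ], nrow = S)
      v[, length(comp)] <- popvar(Ht %*% t(Lt))
    }
    tot <- rowSums(v)
    vn <- v / tot
    vn[tot <= 0, ] <- NA_real_
    acc[t, , ] <- vn
  }
  sp <- apply(acc, c(2, 3), mean, na.rm = TRUE)
  dimnames(sp) <- list(colnames(fit$Y), comp)
  flagged <- rownames(sp)[!is.finite(rowSums(sp))]
  list(species = sp,
       community = colMeans(sp[is.finite(rowSums(sp)), , drop = FALSE]),
       flagged = flagged)
}

#' Tjur's coefficient of discrimination
#'
#' Mean predicted probability among presences minus mean among absences.
#'
#' @param y binary observation vector with at least one 0 and one 1.
#' @param p predicted probabilities.
#' @return Tjur R2.
#' @export
tjur_r2 <- function(y, p) {
  if (length(y) != length(p)) stop("lengths differ")
  if (!all(y %in% c(0, 1))) stop("y must be binary")
  if (sum(y == 1) == 0 || sum(y == 0) == 0)
    stop("single-class y: Tjur R2 undefined")
  mean(p[y == 1]) - mean(p[y == 0])
}

#' Posterior predictions for new samples
#'
#' Gaussian family: posterior mean of the fixed linear predictor. Probit
#' family: by default the plug-in probability
#' `Phi(m / sqrt(1 + v + l))` with `m` and `v` the posterior mean and
#' variance of the fixed predictor and `l` the mean latent variance
#' `lambda_j' lambda_j` (held-out samples have unknown factor scores, which
#' are integrated out); `type = "draws"` averages `Phi` over draws instead.
#'
#' @param fit a [jsdm_fit()] result.
#' @param X_new new design rows on the same columns as the training design.
#' @param type `"plugin"` or `"draws"` (probit only).
#' @return matrix of predictions, samples x species.
#' @export
jsdm_predict <- function(fit, X_new, type = c("plugin", "draws")) {
  type <- match.arg(type)
  Xe <- cbind(1, as.matrix(X_new))
  nd <- length(fit$rho); S <- ncol(fit$Y); FF <- fit$spec$n_factors
  eta <- array(0, c(nd, nrow(Xe), S))
  for (t in seq_len(nd)) eta[t, , ] <- Xe %*% t(fit$beta[t, , ])
  if (fit$spec$family == "gaussian")
    return(apply(eta, c(2, 3), mean))
  latvar <- if (FF > 0)
    colMeans(apply(fit$lambda, c(1, 2), function(l) sum(l^2))) else rep(0, S)
  if (type == "plugin") {
    m <- apply(eta, c(2, 3), mean)
    v <- apply(eta, c(2, 3), stats::var)
    lat <- matrix(latvar, nrow(m), S, byrow = TRUE)
    stats::pnorm(m / sqrt(1 + v + lat))
  } else {
    lv <- if (FF > 0) apply(fit$lambda, c(1, 2), function(l) sum(l^2))
    else matrix(0, nd, S)
    pr <- array(0, c(nd, nrow(Xe), S))
    for (t in seq_len(nd))
      pr[t, , ] <- stats::pnorm(sweep(matrix(eta[t, , ], nrow = nrow(Xe)),
                                      2, sqrt(1 + lv[t, ]), `/`))
    apply(pr, c(2, 3), mean)
  }
}

#' Fivefold cross-validated predictive performance
#'
#' Randomly splits the samples into `k` balanced folds; each fold is
#' predicted by a model refitted to the remaining samples. Predictive skill
#' is assessed per species — Tjur R2 for the probit family, Pearson
#' correlation for the Gaussian family — on the assembled held-out
#' predictions, and averaged (unweighted) over species for the community
#' score. Species for which the score is undefined (single observed class,
#' or zero variance) are excluded from the mean with a message.
#'
#' @param Y,X,C,spec as in [jsdm_fit()].
#' @param k folds (default 5); fold sizes differ by at most 1.
#' @param seed seed for the fold assignment.
#' @return list with `folds`, `predictions` (samples x species),
#'   `species_scores`, `mean_score`, `family`, `n_scored`.
#' @export
cross_validate <- function(Y, X, C = NULL, spec = jsdm_spec(), k = 5,
                           seed = 1L) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  if (n < k) stop("need at least k samples")
  groups <- attr(X, "groups")
  set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = n))
  pred <- matrix(NA_real_, n, ncol(Y), dimnames = dimnames(Y))
  for (f in seq_len(k)) {
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]
    attr(Xtr, "groups") <- groups
    fit <- jsdm_fit(Y[tr, , drop = FALSE], Xtr, C, spec)
    pred[!tr, ] <- jsdm_predict(fit, X[!tr, , drop = FALSE])
  }
  scores <- vapply(seq_len(ncol(Y)), function(j) {
    y <- Y[, j]; p <- pred[, j]
    if (spec$family == "probit") {
      if (sum(y == 1) == 0 || sum(y == 0) == 0) return(NA_real_)
      tjur_r2(y, p)
    } else {
      if (stats::sd(y) == 0 || stats::sd(p) == 0) return(NA_real_)
      stats::cor(y, p)
    }
  }, numeric(1))
  names(scores) <- colnames(Y)
  if (anyNA(scores))
    message(sum(is.na(scores)), " species with undefined score excluded from the mean")
  list(folds = folds, predictions = pred, species_scores = scores,
       mean_score = mean(scores, na.rm = TRUE), family = spec$family,
       n_scored = sum(!is.na(scores)))
}

#' Cross-validated comparison of the full and reduced predictor designs
#'
#' Runs [cross_validate()] with shared fold assignments for the full
#' seven-variable model and the four reduced designs: (i) G1 only, (ii) G1
#' and G2, (iii) G1, G2 and G3, (iv) G1, G2 and G4.
#'
#' @param Y,X,C,spec,k,seed as in [cross_validate()]; `X` must carry group
#'   labels.
#' @return list with `summary` (data.frame of model, predictors, community
#'   mean score), `species_scores` (species x model matrix) and `folds`.
#' @export
reduced_models <- function(Y, X, C = NULL, spec = jsdm_spec(), k = 5,
                           seed = 1L) {
  groups <- attr(X, "groups")
  if (is.null(groups)) stop("design has no group labels")
  subsets <- list(`i: G1` = 1L, `ii: G1+G2` = c(1L, 2L),
                  `iii: G1+G2+G3` = c(1L, 2L, 3L),
                  `iv: G1+G2+G4` = c(1L, 2L, 4L),
                  full = sort(unique(groups)))
  res <- lapply(subsets, function(gs) {
    cols <- which(groups %in% gs)
    Xs <- X[, cols, drop = FALSE]
    attr(Xs, "groups") <- groups[cols]
    cross_validate(Y, Xs, C, spec, k = k, seed = seed)
  })
  list(summary = data.frame(
         model = names(subsets),
         predictors = vapply(subsets, function(gs)
           paste(colnames(X)[groups %in% gs], collapse = ","), character(1)),
         mean_score = vapply(res, `[[`, numeric(1), "mean_score"),
         row.names = NULL, stringsAsFactors = FALSE),
       species_scores = sapply(res, `[[`, "species_scores"),
       folds = res[[1]]$folds)
}

#' Residual species-to-species associations from the latent factors
#'
#' Per draw, the residual covariance `Lambda Lambda' + diag(sigma2)` (unit
#' residual variance for the probit family) converted to a correlation
#' matrix; reported as the posterior mean together with a mask of pairs
#' whose association is positive or negative with at least 95% posterior
#' probability, and two display orderings (average-linkage clustering on
#' `1 - |corr|`, and phylogeny tip order when a tree is supplied).
#'
#' @param fit a [jsdm_fit()] result with `n_factors >= 1`.
#' @param tree optional `phylo` used for the phylogeny ordering.
#' @return list with `correlation`, `support` (+1/-1/0 matrix),
#'   `order_cluster`, `order_phylo`.
#' @export
residual_associations <- function(fit, tree = NULL) {
  stopifnot(inherits(fit, "jsdm_fit"))
  if (fit$spec$n_factors == 0)
    return(list(no_random_effect = TRUE,
                correlation = NULL, support = NULL))
  nd <- length(fit$rho); S <- ncol(fit$Y)
  msum <- matrix(0, S, S); npos <- matrix(0, S, S)
  for (t in seq_len(nd)) {
    L <- matrix(fit$lambda[t, , ], S)
    Om <- tcrossprod(L) + diag(fit$sigma2[t, ], S)
    R <- stats::cov2cor(Om)
    msum <- msum + R
    npos <- npos + (R > 0)
  }
  corr <- msum / nd
  dimnames(corr) <- list(colnames(fit$Y), colnames(fit$Y))
  pp <- npos / nd
  support <- matrix(0L, S, S, dimnames = dimnames(corr))
  support[pp >= 0.95] <- 1L
  support[pp <= 0.05] <- -1L
  diag(support) <- 1L
  ord_c <- stats::hclust(stats::as.dist(1 - abs(corr)), method = "average")$order
  ord_p <- if (!is.null(tree)) match(intersect(tree$tip.label, colnames(corr)),
                                     colnames(corr)) else seq_len(S)
  list(correlation = corr, support = support,
       order_cluster = ord_c, order_phylo = ord_p)
}

#' Posterior summary of the phylogenetic signal
#'
#' @param fit a [jsdm_fit()] result.
#' @return list with `mean` and `ci` (equal-tailed 95% interval) of the
#'   `rho` draws.
#' @export
phylo_signal_summary <- function(fit) {
  stopifnot(inherits(fit, "jsdm_fit"))
  list(mean = mean(fit$rho),
       ci = unname(stats::quantile(fit$rho, c(0.025, 0.975))))
}
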