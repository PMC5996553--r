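#' Default covariate-to-group mapping of the conceptual model
#'
#' G1 (direct 1) is pH alone; G2 (direct 2) the liming co-variables Ca and
#' Mg; G3 (indirect 1) the element-availability variables Al, Fe, Mn, Cu, Zn,
#' P, B and CEC; G4 (indirect 2) the plant-growth / nutrient-cycling
#' variables soybean yield, litter, SOM, K and NO3.
#'
#' @param ph name of the pH column (default `"pH_CaCl2"`).
#' @return named list of character vectors `G1`..`G4`.
#' @export
default_group_map <- function(ph = "pH_CaCl2") {
  list(G1 = ph,
       G2 = c("Ca", "Mg"),
       G3 = c("Al", "Fe", "Mn", "Cu", "Zn", "P", "B", "CEC"),
       G4 = c("soy_yield", "litter", "SOM", "K", "NO3"))
}

#' Residualize covariates against pH
#'
#' Per variable, a simple OLS regression on (intercept, pH); the residual
#' vector replaces the variable so that the indirect covariates measure
#' influences beyond those explained by pH. Residuals are exactly orthogonal
#' to pH.
#'
#' @param vars data.frame/matrix of numeric covariates.
#' @param ph numeric pH vector, same length, non-constant.
#' @return list with `residuals` (matrix, same shape as `vars`) and
#'   `coefficients` (2 x p matrix of intercepts and pH slopes).
#' @export
residualize <- function(vars, ph) {
  vars <- as.matrix(vars)
  if (nrow(vars) < 3) stop("need at least 3 samples")
  if (stats::sd(ph) == 0) stop("pH is constant; residualization undefined")
  X <- cbind(`(Intercept)` = 1, pH = ph)
  coef <- solve(crossprod(X), crossprod(X, vars))
  res <- vars - X %*% coef
  rownames(res) <- rownames(vars)
  list(residuals = res, coefficients = coef)
}

#' Reduce one covariate group to its leading principal components
#'
#' Variables are z-scored and the correlation matrix eigendecomposed; the
#' top-`k` component scores are returned, variance-ordered and orthogonal,
#' with a deterministic sign convention (the largest-magnitude loading of
#' each component is positive).
#'
#' @param vars matrix of (residualized) covariates of one group.
#' @param k components to keep (default 2); requires at least `k` variables
#'   and `k + 1` samples.
#' @return list with `scores` (n x k), `loadings` (p x k) and `var_share`
#'   (proportion of total variance per retained component).
#' @export
reduce_pca <- function(vars, k = 2) {
  vars <- as.matrix(vars)
  if (ncol(vars) < k) stop("fewer variables than requested components")
  if (nrow(vars) < k + 1) stop("need at least k + 1 samples")
  pc <- stats::prcomp(vars, center = TRUE, scale. = TRUE)
  keep <- seq_len(k)
  load <- pc$rotation[, keep, drop = FALSE]
  flip <- apply(load, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, `*`)
  scores <- sweep(pc$x[, keep, drop = FALSE], 2, flip, `*`)
  share <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = load, var_share = share[keep])
}

#' Build the 7-variable predictor design
#'
#' Assembles `[pH, Ca_resid, Mg_resid, G3_1, G3_2, G4_1, G4_2]`: pH itself
#' (G1); Ca and Mg residualized against pH (G2); and the first two principal
#' components of the pH-residualized G3 and G4 variable sets. All columns are
#' centered and standardized to unit variance for model fitting; scaling and
#' PCA metadata are retained as attributes for back-transformation.
#'
#' @param samples sample table containing every mapped covariate.
#' @param group_map covariate grouping, see [default_group_map()].
#' @param k principal components per reduced group (default 2).
#' @return matrix (samples x 7) of class `predictor_design` with attributes
#'   `groups` (integer 1, 2, 2, 3, 3, 4, 4), `center`, `scale`,
#'   `resid_coefficients`, `pca_loadings` and `pca_var_share`.
#' @export
build_design <- function(samples, group_map = default_group_map(), k = 2) {
  needed <- unlist(group_map, use.names = FALSE)
  miss <- setdiff(needed, colnames(samples))
  if (length(miss) > 0)
    stop("missing covariate(s): ", paste(miss, collapse = ", "))
  ph <- samples[[group_map$G1[1]]]
  ids <- if (!is.null(samples$sample_id)) samples$sample_id else rownames(samples)

  g234 <- as.matrix(samples[, c(group_map$G2, group_map$G3, group_map$G4)])
  rz <- residualize(g234, ph)
  res <- rz$residuals
  p3 <- reduce_pca(res[, group_map$G3, drop = FALSE], k = k)
  p4 <- reduce_pca(res[, group_map$G4, drop = FALSE], k = k)

  raw <- cbind(pH = ph,
               Ca_resid = res[, group_map$G2[1]],
               Mg_resid = res[, group_map$G2[2]],
               p3$scores, p4$scores)
  colnames(raw) <- c("pH", "Ca_resid", "Mg_resid",
                     paste0("G3_", seq_len(k)), paste0("G4_", seq_len(k)))
  ctr <- colMeans(raw)
  scl <- apply(raw, 2, stats::sd)
  if (any(scl == 0)) stop("constant design column: ",
                          paste(colnames(raw)[scl == 0], collapse = ", "))
  X <- scale(raw, center = ctr, scale = scl)
  attributes(X)[c("scaled:center", "scaled:scale")] <- NULL
  rownames(X) <- ids
  structure(X,
            groups = c(1L, 2L, 2L, rep(3L, k), rep(4L, k)),
            center = ctr, scale = scl,
            resid_coefficients = rz$coefficients,
            pca_loadings = list(G3 = p3$loadings, G4 = p4$loadings),
            pca_var_share = list(G3 = p3$var_share, G4 = p4$var_share),
            class = c("predictor_design", "matrix", "array"))
}
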