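#' Configuration for permutation-based random-forest modelling
#'
#' @param n_trees trees per forest (default 500).
#' @param n_perm permutation refits per predictor for the null importance
#'   distribution (default 400); must be at least `1/alpha`.
#' @param alpha per-predictor selection level (default 0.05, no
#'   multiple-testing adjustment).
#' @param validation_min retention threshold on the validation score
#'   (default 0.1, boundary inclusive).
#' @param cv_folds folds for the cross-validated validation score (default 5).
#' @param validation `"r2"` (cross-validated R2, default) or `"cor"`
#'   (held-out Pearson correlation).
#' @param mtry predictors tried per split; default `max(1, floor(p/3))`, the
#'   regression-forest convention.
#' @param seed integer seed; every forest gets a deterministic derived seed.
#' @return list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 500L, n_perm = 400L, alpha = 0.05,
                      validation_min = 0.1, cv_folds = 5L,
                      validation = c("r2", "cor"), mtry = NULL, seed = 1L) {
  validation <- match.arg(validation)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_perm < 1 / alpha) stop("n_perm must be >= 1/alpha")
  structure(list(n_trees = as.integer(n_trees), n_perm = as.integer(n_perm),
                 alpha = alpha, validation_min = validation_min,
                 cv_folds = as.integer(cv_folds), validation = validation,
                 mtry = mtry, seed = as.integer(seed)),
            class = "rf_config")
}

rf_forest <- function(y, X, cfg, seed) {
  mtry <- if (is.null(cfg$mtry)) max(1L, floor(ncol(X) / 3)) else cfg$mtry
  ranger::ranger(y = y, x = X, num.trees = cfg$n_trees,
                 mtry = min(mtry, ncol(X)), importance = "permutation",
                 num.threads = 1, seed = seed %% .Machine$integer.max)
}

#' Select significant predictors for one response by permutation refits
#'
#' Permutation-refit predictor selection: (1) a forest on the full predictor
#' set gives each predictor's out-of-bag permutation importance; (2) for
#' each predictor j, `n_perm` forests are refitted on data in which only
#' column j has been row-permuted, and j's importance in each refit forms
#' its null distribution; (3) `p_j = (1 + #(null >= observed)) / (1 + n_perm)`
#' (never zero), and predictors with `p_j <= alpha` are selected; (4) a
#' final forest is refitted on the selected set. If no predictor is
#' significant, no model is produced.
#'
#' @param y numeric response (one OTU's abundance).
#' @param X data.frame/matrix of candidate predictors, rows aligned with `y`.
#' @param cfg an [rf_config()].
#' @return list of class `rf_model` with `selected`, `p_values`,
#'   `importance_obs`, `model` (final ranger forest or NULL), `r2`
#'   (out-of-bag variance explained), `validation_score`, `no_model`,
#'   `reason`.
#' @export
rf_select_and_fit <- function(y, X, cfg = rf_config()) {
  X <- as.data.frame(X)
  if (length(y) != nrow(X)) stop("y and X rows differ")
  if (stats::sd(y) == 0)
    return(structure(list(selected = character(0), p_values = NULL,
                          importance_obs = NULL, model = NULL,
                          r2 = NA_real_, validation_score = NA_real_,
                          no_model = TRUE, reason = "constant response"),
                     class = "rf_model"))
  p <- ncol(X)
  base_fit <- rf_forest(y, X, cfg, seed = cfg$seed)
  imp_obs <- base_fit$variable.importance

  set.seed(cfg$seed)
  perm_seeds <- matrix(sample.int(.Machine$integer.max - 1L, p * cfg$n_perm),
                       p, cfg$n_perm)
  p_values <- numeric(p)
  names(p_values) <- colnames(X)
  for (j in seq_len(p)) {
    exceed <- 0L
    for (b in seq_len(cfg$n_perm)) {
      set.seed(perm_seeds[j, b])
      Xp <- X
      Xp[[j]] <- X[[j]][sample.int(nrow(X))]
      nullfit <- rf_forest(y, Xp, cfg, seed = perm_seeds[j, b])
      if (nullfit$variable.importance[j] >= imp_obs[j]) exceed <- exceed + 1L
    }
    p_values[j] <- (1 + exceed) / (1 + cfg$n_perm)
  }
  selected <- names(p_values)[p_values <= cfg$alpha]
  if (length(selected) == 0)
    return(structure(list(selected = character(0), p_values = p_values,
                          importance_obs = imp_obs, model = NULL,
                          r2 = NA_real_, validation_score = NA_real_,
                          no_model = TRUE, reason = "no significant predictor"),
                     class = "rf_model"))
  final <- rf_forest(y, X[, selected, drop = FALSE], cfg, seed = cfg$seed + 1L)
  perf <- rf_performance(y, X[, selected, drop = FALSE], cfg)
  structure(list(selected = selected, p_values = p_values,
                 importance_obs = imp_obs, model = final,
                 r2 = perf$r2, validation_score = perf$validation_score,
                 no_model = FALSE, reason = NULL),
            class = "rf_model")
}

#' Forest performance: variance explained and validation score
#'
#' Variance explained is the out-of-bag R2, `1 - MSE_oob / Var(y)`. The
#' validation score is a k-fold cross-validated R2 (`1 - SSE_cv / SST`) with
#' the forest refitted on each training fold; with `validation = "cor"` the
#' held-out Pearson correlation is used instead.
#'
#' @param y response vector.
#' @param X_selected predictor columns of the final model.
#' @param cfg an [rf_config()].
#' @return list with `r2` and `validation_score`.
#' @export
rf_performance <- function(y, X_selected, cfg = rf_config()) {
  X_selected <- as.data.frame(X_selected)
  n <- length(y)
  if (n < cfg$cv_folds) stop("fewer samples than cv folds")
  fit <- rf_forest(y, X_selected, cfg, seed = cfg$seed + 1L)
  r2 <- 1 - fit$prediction.error / stats::var(y)
  set.seed(cfg$seed + 2L)
  folds <- sample(rep(seq_len(cfg$cv_folds), length.out = n))
  pred <- numeric(n)
  for (f in seq_len(cfg$cv_folds)) {
    tr <- folds != f
    m <- rf_forest(y[tr], X_selected[tr, , drop = FALSE], cfg,
                   seed = cfg$seed + 2L + f)
    pred[!tr] <- stats::predict(m,
                                data = X_selected[!tr, , drop = FALSE],
                                num.threads = 1)$predictions
  }
  score <- if (cfg$validation == "r2")
    1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  else stats::cor(y, pred)
  list(r2 = r2, validation_score = score)
}

#' Run the per-OTU random-forest pipeline over an abundance matrix
#'
#' @param abund samples x OTUs numeric matrix (relative abundance by
#'   default upstream).
#' @param predictors data.frame of candidate predictors (typically the raw
#'   covariates pH, Ca, Mg, Al, Fe, Mn, Cu, Zn, P, B, CEC, yield, litter,
#'   SOM, K, NO3).
#' @param cfg an [rf_config()]; each OTU gets a derived seed.
#' @return list of `rf_model` objects, one per OTU, plus a `summary`
#'   data.frame attribute via [rf_summary()].
#' @export
rf_run <- function(abund, predictors, cfg = rf_config()) {
  abund <- as.matrix(abund)
  res <- lapply(seq_len(ncol(abund)), function(j) {
    cfg_j <- cfg
    cfg_j$seed <- (cfg$seed + 131L * j) %% .Machine$integer.max
    rf_select_and_fit(abund[, j], predictors, cfg_j)
  })
  names(res) <- colnames(abund)
  res
}

#' Tabulate per-OTU random-forest model results
#'
#' @param results list of `rf_model` objects from [rf_run()].
#' @return data.frame with `otu`, `n_selected`, `selected`, `r2`,
#'   `validation_score`, `no_model`.
#' @export
rf_summary <- function(results) {
  data.frame(
    otu = names(results),
    n_selected = vapply(results, function(r) length(r$selected), integer(1)),
    selected = vapply(results, function(r)
      paste(r$selected, collapse = ","), character(1)),
    r2 = vapply(results, function(r) r$r2 %||% NA_real_, numeric(1)),
    validation_score = vapply(results, function(r)
      r$validation_score %||% NA_real_, numeric(1)),
    no_model = vapply(results, `[[`, logical(1), "no_model"),
    row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen fitted models by validation score
#'
#' Keeps models whose validation score is at least `validation_min`
#' (inclusive boundary: a score exactly at the threshold is retained, since
#' the exclusion rule drops scores *lower than* the threshold), and reports
#' counts and mean performance before and after.
#'
#' @param results list from [rf_run()].
#' @param validation_min threshold (default 0.1).
#' @return list with `retained` (named sub-list), `summary` data.frame of
#'   counts and mean r2/validation score for modeled and retained sets.
#' @export
rf_screen <- function(results, validation_min = 0.1) {
  tab <- rf_summary(results)
  modeled <- !tab$no_model
  keep <- modeled & !is.na(tab$validation_score) &
    tab$validation_score >= validation_min
  list(retained = results[keep],
       summary = data.frame(
         set = c("modeled", "retained"),
         n = c(sum(modeled), sum(keep)),
         mean_r2 = c(mean(tab$r2[modeled]), mean(tab$r2[keep])),
         mean_validation = c(mean(tab$validation_score[modeled]),
                             mean(tab$validation_score[keep])),
         stringsAsFactors = FALSE))
}

#' Aggregate predictor importance across retained models
#'
#' Within each model, the selected predictors' final-forest permutation
#' importances (negative values clamped to zero) are normalized to sum to
#' 100% over the model's candidate predictor set, unselected predictors
#' scoring 0; these percentages are then averaged across models. Group-level
#' distributions sum the percentages within each conceptual predictor group
#' per model, so each model's group total is 100%.
#'
#' @param retained list of retained `rf_model` objects (>= 1).
#' @param group_map named list mapping group labels to predictor names, as
#'   [default_group_map()].
#' @return list with `mean_importance` (named %, all candidates),
#'   `per_model` (models x predictors %), `group_distribution`
#'   (models x groups %).
#' @export
rf_aggregate_importance <- function(retained, group_map = default_group_map()) {
  if (length(retained) == 0) stop("no retained models")
  cand <- names(retained[[1]]$p_values)
  per_model <- t(vapply(retained, function(r) {
    imp <- stats::setNames(numeric(length(cand)), cand)
    vals <- pmax(r$model$variable.importance, 0)
    if (sum(vals) == 0) vals[] <- 1 / length(vals)   # degenerate: equal split
    imp[names(vals)] <- 100 * vals / sum(vals)
    imp
  }, numeric(length(cand))))
  groups <- stats::setNames(rep(names(group_map), lengths(group_map)),
                            unlist(group_map, use.names = FALSE))
  gl <- groups[cand]
  gl[is.na(gl)] <- "other"
  gd <- t(apply(per_model, 1, function(row) tapply(row, gl, sum)))
  list(mean_importance = colMeans(per_model),
       per_model = per_model,
       group_distribution = gd)
}
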