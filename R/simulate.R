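#' Configuration for the synthetic liming-gradient study
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate the
#' field design the pipeline was built around: four lime doses (0, 2250, 4500,
#' 6750 kg ha-1) with nine replicate plots each (36 plots), three lime brands
#' nested within dose, a soil pH (CaCl2) gradient spanning roughly 4.1-6.2,
#' strongly pH-anticorrelated Al, dose-driven Ca and Mg, and a zero-inflated,
#' phylogenetically structured OTU table resampled to a fixed read depth with
#' four deliberately under-sequenced samples (so rarefaction leaves 32).
#'
#' @param n_blocks replicate plots per dose.
#' @param doses lime application rates, kg ha-1.
#' @param n_brands lime brands, assigned cyclically within each dose.
#' @param n_otus number of OTUs (tips of the simulated phylogeny).
#' @param n_samples_dropped samples given sequencing depth below
#'   `read_depth_target`, so that [rarefy()] excludes them.
#' @param read_depth_target rarefaction depth, reads per sample.
#' @param rho_true phylogenetic signal in `[0,1]` blending the tip correlation
#'   matrix `C` with the identity in the covariance of species responses.
#' @param beta_scale named numeric, per-group effect-size standard deviations
#'   for predictor groups G1 (pH), G2 (Ca, Mg), G3 (element availability),
#'   G4 (plant growth / nutrient cycling).
#' @param n_factors_true latent community factors shared across species.
#' @param occupancy_base mean baseline occurrence probability; the species
#'   intercepts are centered so the marginal occurrence probability averages
#'   to this value.
#' @param occupancy_sd standard deviation (probit scale) of species baseline
#'   occupancy around `occupancy_base`, giving the wide occupancy spectrum
#'   seen in 16S surveys. 0 gives every species the same baseline and also
#'   disables the core fraction (fully homogeneous null).
#' @param core_fraction fraction of species that are "core" taxa with a high
#'   baseline (probit intercept 4 + |N(0,1)|), hence present in essentially
#'   every sample — the core/satellite structure of soil communities that
#'   feeds the abundance (present-in-all-samples) model. Only applies when
#'   `occupancy_sd > 0`.
#' @param dose_effect multiplier in `[0,1]` on every systematic dose->pH and
#'   pH->chemistry link; 0 turns the generator into a pure-noise null.
#' @param block_sd standard deviation of an optional plot-block pH offset
#'   (default 0; the magnitude of block effects is not constrained by the
#'   study design, so none is claimed).
#' @param seed integer seed; identical configurations give identical output.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_soil_gradient()], [simulate_community()]
#' @export
sim_config <- function(n_blocks = 9L,
                       doses = c(0, 2250, 4500, 6750),
                       n_brands = 3L,
                       n_otus = 150L,
                       n_samples_dropped = 4L,
                       read_depth_target = 31000L,
                       rho_true = 0.7,
                       beta_scale = c(G1 = 0.8, G2 = 0.25, G3 = 0.18, G4 = 0.12),
                       n_factors_true = 2L,
                       occupancy_base = 0.5,
                       occupancy_sd = 1.5,
                       core_fraction = 0.25,
                       dose_effect = 1,
                       block_sd = 0,
                       seed = 1L) {
  stopifnot(n_blocks >= 1, length(doses) >= 1, n_brands >= 1, n_otus >= 2,
            n_samples_dropped >= 0, read_depth_target >= 1)
  if (rho_true < 0 || rho_true > 1) stop("rho_true must be in [0, 1]")
  if (any(beta_scale < 0)) stop("beta_scale entries must be >= 0")
  if (is.null(names(beta_scale)) || !all(c("G1", "G2", "G3", "G4") %in% names(beta_scale)))
    stop("beta_scale must be named G1..G4")
  if (n_samples_dropped >= n_blocks * length(doses))
    stop("cannot drop all samples")
  structure(list(n_blocks = as.integer(n_blocks), doses = doses,
                 n_brands = as.integer(n_brands), n_otus = as.integer(n_otus),
                 n_samples_dropped = as.integer(n_samples_dropped),
                 read_depth_target = as.integer(read_depth_target),
                 rho_true = rho_true, beta_scale = beta_scale,
                 n_factors_true = as.integer(n_factors_true),
                 occupancy_base = occupancy_base, occupancy_sd = occupancy_sd,
                 core_fraction = core_fraction, dose_effect = dose_effect,
                 block_sd = block_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate the soil/plant/gas sample table for a liming gradient
#'
#' Generates one row per plot. pH (CaCl2) rises linearly with lime dose plus
#' plot noise and a small fixed brand offset nested in dose; aluminium follows
#' a steep decreasing logistic of pH (essentially zero above pH 5.5, where Al
#' precipitates); Fe, Mn, Cu and B decline weakly with pH; Ca and Mg rise with
#' dose; soybean yield rises weakly with pH; K, NO3, SOM and litter are
#' pH-independent noise; CEC is the sum H+Al+Ca+Mg+K by construction. Gas
#' fluxes are pH-independent noise centred on typical field values, and are
#' also the ground-truth fluxes for [simulate_chamber_series()].
#'
#' Setting `cfg$dose_effect = 0` removes every systematic link, so pH becomes
#' i.i.d. noise and all chemistry is independent of it.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with one row per sample (see field list in the README).
#' @export
simulate_soil_gradient <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  de <- cfg$dose_effect
  design <- expand.grid(block = seq_len(cfg$n_blocks), dose = cfg$doses,
                        KEEP.OUT.ATTRS = FALSE)
  n <- nrow(design)
  if (n <= 0) stop("non-positive sample count")
  brand <- ((design$block - 1L) %% cfg$n_brands) + 1L
  frac <- if (max(cfg$doses) > 0) design$dose / max(cfg$doses) else rep(0, n)

  brand_off <- (brand - (cfg$n_brands + 1) / 2) * 0.06 * de
  block_off <- stats::rnorm(cfg$n_blocks, 0, cfg$block_sd)[design$block]
  pH <- 4.3 + 1.6 * frac * de + brand_off + block_off + stats::rnorm(n, 0, 0.22)
  # chemistry responds to pH only through pH_eff, which is flat when de = 0
  pH_eff <- mean(pH) + de * (pH - mean(pH))
  frac_eff <- frac * de

  clamp <- function(x, lo = 0) pmax(x, lo)
  Al <- 1.2 * stats::plogis((4.9 - pH_eff) / 0.18) * exp(stats::rnorm(n, 0, 0.12))
  H  <- clamp(5.5 - 0.75 * pH_eff + stats::rnorm(n, 0, 0.25))
  Ca <- clamp(23 + 58 * frac_eff + stats::rnorm(n, 0, 10), 0.5)
  Mg <- clamp(9.6 + 12 * frac_eff + stats::rnorm(n, 0, 4), 0.5)
  K  <- clamp(1.6 + stats::rnorm(n, 0, 0.3), 0.05)
  Fe <- clamp(32 - 3.2 * pH_eff + stats::rnorm(n, 0, 3.4))
  Mn <- clamp(55 - 6 * pH_eff + stats::rnorm(n, 0, 6.5))
  Cu <- clamp(1.9 - 0.22 * pH_eff + stats::rnorm(n, 0, 0.24))
  Zn <- clamp(1.2 - 0.05 * pH_eff + stats::rnorm(n, 0, 0.35))
  B  <- clamp(0.45 - 0.055 * pH_eff + stats::rnorm(n, 0, 0.055))
  P  <- clamp(8 + 0.5 * pH_eff + stats::rnorm(n, 0, 2.2))
  NO3 <- clamp(6.4 + stats::rnorm(n, 0, 1.1))
  SOM <- clamp(31 + stats::rnorm(n, 0, 3.5))
  soy_yield <- clamp(1800 + 450 * pH_eff + stats::rnorm(n, 0, 520))
  litter <- clamp(78.8 + stats::rnorm(n, 0, 31.7))

  out <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    block = design$block, dose = design$dose, brand = brand,
    pH_CaCl2 = pH,
    pH_H2O = pH + 0.6 + stats::rnorm(n, 0, 0.05),
    H = H, Al = Al, Ca = Ca, Mg = Mg, K = K,
    Fe = Fe, Mn = Mn, Cu = Cu, Zn = Zn, B = B, P = P,
    NO3 = NO3, SOM = SOM,
    CEC = H + Al + Ca + Mg + K,
    soy_yield = soy_yield, litter = litter,
    CO2_flux = 107 + stats::rnorm(n, 0, 89),
    CH4_flux = -7 + stats::rnorm(n, 0, 19),
    N2O_flux = 13 + stats::rnorm(n, 0, 60),
    chamber_T = 298.15 + stats::rnorm(n, 0, 2),
    stringsAsFactors = FALSE
  )
  rownames(out) <- out$sample_id
  out
}

#' Simulate a rooted ultrametric phylogeny for the OTUs
#'
#' Pure-birth (Yule) tree with `n_otus` tips and unique labels `OTU0001`, ...
#'
#' @param n_otus number of tips (>= 2).
#' @param seed integer seed.
#' @return an [ape::rphylo] object of class `phylo`, rooted and ultrametric.
#' @export
simulate_tree <- function(n_otus, seed = 1L) {
  if (n_otus < 2) stop("n_otus must be >= 2")
  set.seed(seed)
  tree <- ape::rphylo(n_otus, birth = 1, death = 0)
  tree$tip.label <- sprintf("OTU%04d", seq_len(n_otus))
  tree
}

#' Simulate a phylogenetically structured, zero-inflated community
#'
#' Generative mirror of the two joint species distribution models the pipeline
#' fits. Species responses `beta` to 16 standardized soil covariates (grouped
#' G1 = pH; G2 = Ca, Mg; G3 = Al, Fe, Mn, Cu, Zn, P, B, CEC; G4 = yield,
#' litter, SOM, K, NO3) are drawn, per predictor, from a multivariate normal
#' across species with covariance `rho*C + (1-rho)*I` (C the tip correlation
#' matrix of `tree`) scaled by the group's `beta_scale`. Latent factor scores
#' (per sample) and loadings (per species) add residual co-occurrence.
#' Occurrence is a probit threshold of the linear predictor; log abundance is
#' a Gaussian linear predictor for occurring taxa; integer counts come from
#' multinomial read sampling at each sample's assigned depth, with
#' `n_samples_dropped` samples given depth below `read_depth_target`.
#'
#' @param soil output of [simulate_soil_gradient()].
#' @param tree output of [simulate_tree()]; tip count must equal `cfg$n_otus`.
#' @param cfg the same [sim_config()].
#' @return list with `counts` (samples x OTUs integer matrix), `depths`,
#'   `dropped` (sample ids under target depth), and `truth` (list holding
#'   `beta_true`, `rho_true`, `lambda_true`, `h_true`, `occ_prob`,
#'   `predictor_groups`, and `flux_true` taken from the soil table's gas
#'   columns).
#' @export
simulate_community <- function(soil, tree, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(soil) < 2) stop("need at least 2 samples")
  S <- cfg$n_otus
  if (length(tree$tip.label) != S) stop("tree tip count does not match n_otus")
  set.seed(cfg$seed + 1L)

  covars <- c("pH_CaCl2", "Ca", "Mg",
              "Al", "Fe", "Mn", "Cu", "Zn", "P", "B", "CEC",
              "soy_yield", "litter", "SOM", "K", "NO3")
  groups <- c(1L, 2L, 2L, rep(3L, 8L), rep(4L, 5L))
  X <- scale(as.matrix(soil[, covars]))
  X[, apply(X, 2, function(z) any(!is.finite(z)))] <- 0  # constant columns
  n <- nrow(X)

  C <- ape::vcv(tree, corr = TRUE)
  C <- C[tree$tip.label, tree$tip.label]
  Sig <- cfg$rho_true * C + (1 - cfg$rho_true) * diag(S)
  L <- t(chol(Sig + diag(1e-10, S)))

  sd_g <- cfg$beta_scale[paste0("G", groups)]
  beta <- sapply(seq_along(covars), function(k) as.vector(L %*% stats::rnorm(S)) * sd_g[k])
  dimnames(beta) <- list(tree$tip.label, covars)

  FF <- cfg$n_factors_true
  lambda <- if (FF > 0) matrix(stats::rnorm(S * FF, 0, 0.5), S, FF) else matrix(0, S, 0)
  Hf <- if (FF > 0) matrix(stats::rnorm(n * FF), n, FF) else matrix(0, n, 0)

  eta <- X %*% t(beta) + Hf %*% t(lambda)           # n x S shared predictor
  # species baseline occupancy: probit-scale jitter (centered so the
  # marginal occurrence probability averages occupancy_base) plus a core
  # fraction of near-ubiquitous taxa; occupancy_sd = 0 is fully homogeneous
  if (cfg$occupancy_sd > 0) {
    c0 <- stats::qnorm(cfg$occupancy_base) * sqrt(1 + cfg$occupancy_sd^2) +
      stats::rnorm(S, 0, cfg$occupancy_sd)
    core <- stats::runif(S) < cfg$core_fraction
    c0[core] <- 4 + abs(stats::rnorm(sum(core)))
  } else {
    c0 <- rep(stats::qnorm(cfg$occupancy_base), S)
  }
  occ_lin <- matrix(c0, n, S, byrow = TRUE) + eta
  occ <- (occ_lin + matrix(stats::rnorm(n * S), n, S)) > 0
  a0 <- stats::rnorm(S, 0, 1)                        # species abundance baseline
  log_ab <- matrix(a0, n, S, byrow = TRUE) + eta + matrix(stats::rnorm(n * S, 0, 0.5), n, S)

  w <- ifelse(occ, exp(log_ab), 0)
  empty <- rowSums(w) == 0
  if (any(empty)) w[empty, which.max(colMeans(occ))] <- 1

  depths <- as.integer(round(cfg$read_depth_target * (1 + stats::runif(n, 0.05, 0.5))))
  dropped_idx <- if (cfg$n_samples_dropped > 0)
    sample.int(n, cfg$n_samples_dropped) else integer(0)
  depths[dropped_idx] <- as.integer(round(cfg$read_depth_target *
                                            stats::runif(length(dropped_idx), 0.3, 0.95)))

  counts <- t(vapply(seq_len(n), function(i)
    as.integer(stats::rmultinom(1, depths[i], w[i, ])), integer(S)))
  dimnames(counts) <- list(soil$sample_id, tree$tip.label)

  list(counts = counts, depths = stats::setNames(depths, soil$sample_id),
       dropped = soil$sample_id[dropped_idx],
       truth = list(beta_true = beta, rho_true = cfg$rho_true,
                    lambda_true = lambda, h_true = Hf,
                    occ_prob = stats::pnorm(occ_lin),
                    predictor_groups = stats::setNames(groups, covars),
                    flux_true = as.matrix(soil[, c("CO2_flux", "CH4_flux", "N2O_flux")])))
}

#' Simulate a static-chamber gas concentration series
#'
#' Inverse of the flux equation `f = dC/dt * V/A * m/Vm`: produces a linear
#' concentration series (ppm by volume) whose noiseless slope corresponds
#' exactly to the requested flux, so [gas_flux()] recovers it.
#'
#' @param flux target flux, ug m-2 h-1 (use ug for CH4/N2O; for CO2 in
#'   mg m-2 h-1 multiply by 1000 first).
#' @param V chamber volume, L.
#' @param A covered soil area, m2.
#' @param T_K headspace air temperature, K.
#' @param times sampling times in minutes, strictly increasing, >= 2 points.
#' @param m molecular weight of the gas, g mol-1.
#' @param conc0 ambient concentration at time 0, ppm.
#' @param noise_sd Gaussian noise added to each concentration, ppm.
#' @param seed optional seed for the noise.
#' @return data.frame with `time_min` and `conc_ppm`.
#' @export
simulate_chamber_series <- function(flux, V, A, T_K, times = c(0, 5, 10, 20),
                                    m = 44.01, conc0 = 400, noise_sd = 0,
                                    seed = NULL) {
  if (length(times) < 2) stop("need at least 2 time points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (V <= 0 || A <= 0 || T_K <= 0) stop("V, A and T must be positive")
  if (!is.null(seed)) set.seed(seed)
  Vm <- 22.414 * T_K / 273.15
  slope_per_h <- flux * (A / V) * (Vm / m)   # ppm h-1
  conc <- conc0 + slope_per_h * times / 60 +
    if (noise_sd > 0) stats::rnorm(length(times), 0, noise_sd) else 0
  data.frame(time_min = times, conc_ppm = conc)
}

#' Simulate a full synthetic study
#'
#' Convenience wrapper: soil gradient, phylogeny and community in one call.
#'
#' @param cfg a [sim_config()].
#' @return list with `soil`, `tree`, `counts`, `depths`, `dropped`, `truth`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  soil <- simulate_soil_gradient(cfg)
  tree <- simulate_tree(cfg$n_otus, seed = cfg$seed)
  com <- simulate_community(soil, tree, cfg)
  c(list(soil = soil, tree = tree), com)
}

#' Write a simulated dataset to plain-text files
#'
#' Sample metadata and OTU counts as tab-separated text, the tree as Newick,
#' and the ground truth as a key-value text file.
#'
#' @param sim output of [simulate_dataset()].
#' @param outdir directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sim$soil, file.path(outdir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_otu_table(sim$counts, file.path(outdir, "otu_counts.tsv"))
  ape::write.tree(sim$tree, file.path(outdir, "tree.nwk"))
  tr <- sim$truth
  con <- file(file.path(outdir, "truth.txt"), "w")
  on.exit(close(con))
  writeLines(c(sprintf("rho_true\t%g", tr$rho_true),
               sprintf("n_factors_true\t%d", ncol(tr$lambda_true)),
               sprintf("dropped\t%s", paste(sim$dropped, collapse = ","))), con)
  utils::write.table(data.frame(otu = rownames(tr$beta_true), tr$beta_true,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
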