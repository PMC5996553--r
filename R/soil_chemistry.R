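#' Static-chamber gas flux from a concentration time series
#'
#' Computes the flux `f = dC/dt * V/A * m/Vm` from a closed-chamber
#' accumulation series. `dC/dt` is the ordinary least-squares slope of
#' concentration on time over all points (not an endpoint difference); the
#' molar volume is corrected for chamber air temperature at 1 atm,
#' `Vm = 22.414 * T/273.15` L mol-1.
#'
#' Unit chain: with concentrations in ppm by volume, times in minutes, `V` in
#' litres, `A` in m2 and `m` in g mol-1, the slope is converted to per-hour
#' and the flux is returned in ug m-2 h-1 (divide by 1000 for the mg m-2 h-1
#' scale conventionally used for CO2).
#'
#' @param times sampling times, minutes; >= 2 strictly increasing points.
#' @param conc concentrations, ppm by volume, same length as `times`.
#' @param V chamber volume, L.
#' @param A soil area covered by the chamber, m2.
#' @param T_K headspace air temperature, K.
#' @param m molecular weight of the gas, g mol-1.
#' @param gas optional gas label carried through to the result.
#' @return list with `gas`, `flux` (ug m-2 h-1), `slope` (ppm h-1) and `Vm`
#'   (L mol-1).
#' @export
gas_flux <- function(times, conc, V, A, T_K, m = 44.01, gas = NA_character_) {
  if (length(times) < 2) stop("need at least 2 time points")
  if (length(conc) != length(times)) stop("times and conc lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (T_K <= 0) stop("temperature must be positive (K)")
  if (V <= 0 || A <= 0) stop("V and A must be positive")
  th <- times / 60
  slope <- sum((th - mean(th)) * (conc - mean(conc))) / sum((th - mean(th))^2)
  Vm <- 22.414 * T_K / 273.15
  list(gas = gas, flux = slope * (V / A) * (m / Vm), slope = slope, Vm = Vm)
}

#' Cation exchange capacity as the sum of exchangeable cations
#'
#' `CEC = H + Al + Ca + Mg + K` (cmolc dm-3). A missing or negative component
#' yields `NA` for that sample (flagged, never silently zeroed).
#'
#' @param samples data.frame with columns `H`, `Al`, `Ca`, `Mg`, `K`.
#' @return numeric vector of CEC values, `NA` where a component is missing.
#' @export
compute_cec <- function(samples) {
  comp <- c("H", "Al", "Ca", "Mg", "K")
  miss <- setdiff(comp, colnames(samples))
  if (length(miss) > 0)
    stop("missing CEC component column(s): ", paste(miss, collapse = ", "))
  m <- as.matrix(samples[, comp])
  m[m < 0] <- NA
  out <- rowSums(m)          # NA propagates from any missing component
  flagged <- sum(is.na(out))
  if (flagged > 0)
    warning(flagged, " sample(s) with missing CEC components flagged as NA")
  out
}

#' Simpson diversity index of one sample
#'
#' `D = 1 - sum(p_i^2)` with `p_i` the relative abundances, as computed by
#' vegan's default "simpson" index. Invariant to rescaling the total count.
#'
#' @param counts non-negative per-OTU counts, total > 0.
#' @return Simpson index in `[0, 1]`.
#' @export
simpson_index <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) <= 0) stop("all-zero sample: Simpson index undefined")
  as.numeric(vegan::diversity(matrix(counts, nrow = 1), index = "simpson"))
}

#' Thresholded Pearson/Spearman correlation screen
#'
#' For every pair of an `X` and a `Y` variable, computes both Pearson r and
#' Spearman rho with two-sided p-values (pairwise-complete observations), and
#' reports the coefficient with the larger absolute value, tagged `"r"` or
#' `"rho"`. A pair passes the screen iff the reported |coefficient| exceeds
#' `threshold` and its p-value is below `alpha` (both strict), mirroring the
#' usual "only |coef| > 0.4 and P < 0.05 shown" table convention. Spearman
#' p-values use the t approximation for n >= 10 and the exact permutation
#' null of the rank statistic below that. Zero-variance variables are skipped
#' with a message. No multiple-testing correction is applied.
#'
#' @param X data.frame/matrix of numeric variables (screen rows).
#' @param Y data.frame/matrix of numeric variables (screen columns); defaults
#'   to `X`'s partner in an all-vs-all screen when omitted.
#' @param threshold absolute-coefficient threshold (default 0.4).
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per retained pair: `x`, `y`, `pearson_r`,
#'   `pearson_p`, `spearman_rho`, `spearman_p`, `coef` (the reported one),
#'   `coef_type`, `p` and `pass`.
#' @export
correlation_screen <- function(X, Y = X, threshold = 0.4, alpha = 0.05) {
  X <- as.data.frame(X); Y <- as.data.frame(Y)
  out <- list()
  for (xv in colnames(X)) for (yv in colnames(Y)) {
    x <- X[[xv]]; y <- Y[[yv]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 4) next
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      message("skipping zero-variance pair: ", xv, " vs ", yv)
      next
    }
    pe <- stats::cor.test(x, y, method = "pearson")
    sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = length(x) < 10))
    rep_pe <- abs(pe$estimate) >= abs(sp$estimate)
    coef <- if (rep_pe) unname(pe$estimate) else unname(sp$estimate)
    p <- if (rep_pe) pe$p.value else sp$p.value
    out[[length(out) + 1L]] <- data.frame(
      x = xv, y = yv,
      pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
      spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
      coef = coef, coef_type = if (rep_pe) "r" else "rho", p = p,
      pass = abs(coef) > threshold && p < alpha,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(x = character(), y = character(), pearson_r = numeric(),
                      pearson_p = numeric(), spearman_rho = numeric(),
                      spearman_p = numeric(), coef = numeric(),
                      coef_type = character(), p = numeric(),
                      pass = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
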