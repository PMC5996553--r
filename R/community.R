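#' Rarefy an OTU table to a fixed read depth
#'
#' Samples whose total is below `depth` are excluded and listed; the rest are
#' subsampled without replacement (hypergeometric draw, one realization per
#' sample) to exactly `depth` reads.
#'
#' @param counts samples x OTUs integer matrix.
#' @param depth target reads per sample.
#' @param seed integer seed recorded for the subsampling draw.
#' @return list with `counts` (rarefied table, row sums all equal `depth`)
#'   and `excluded` (character vector of dropped sample ids).
#' @export
rarefy <- function(counts, depth, seed = 1L) {
  counts <- as.matrix(counts)
  if (depth < 1) stop("depth must be >= 1")
  tot <- rowSums(counts)
  keep <- tot >= depth
  if (!any(keep)) stop("all samples fall below the rarefaction depth")
  excluded <- rownames(counts)[!keep]
  set.seed(seed)
  rare <- suppressWarnings(vegan::rrarefy(counts[keep, , drop = FALSE], depth))
  storage.mode(rare) <- "integer"
  list(counts = rare, excluded = excluded)
}

#' Presence/absence model filter
#'
#' Keeps OTUs that are both present (nonzero) in at least `min_present`
#' samples and absent in at least `min_absent` samples, i.e. those with
#' substantial variation in occurrence. Boundaries are inclusive.
#'
#' @param counts rarefied samples x OTUs matrix.
#' @param min_present,min_absent sample-count thresholds (default 10).
#' @return character vector of retained OTU ids (possibly empty, with a
#'   warning).
#' @export
pa_filter <- function(counts, min_present = 10, min_absent = 10) {
  counts <- as.matrix(counts)
  pres <- colSums(counts > 0)
  keep <- pres >= min_present & (nrow(counts) - pres) >= min_absent
  if (!any(keep)) warning("pa_filter retained no OTUs")
  colnames(counts)[keep]
}

#' Abundance-model filter and log transform
#'
#' Selects OTUs present in every sample (no absences), converts counts to
#' relative abundance, takes the natural log (no pseudocount is needed: the
#' selected set has no zeros by construction) and centers each OTU column to
#' mean zero.
#'
#' @param counts rarefied samples x OTUs matrix.
#' @return samples x retained-OTUs matrix of centered log relative abundance;
#'   zero columns if no OTU is omnipresent (warned).
#' @export
abundance_filter_transform <- function(counts) {
  counts <- as.matrix(counts)
  keep <- colSums(counts == 0) == 0
  if (!any(keep)) warning("no OTU present in all samples")
  sub <- counts[, keep, drop = FALSE]
  rel <- sub / rowSums(counts)
  out <- scale(log(rel), center = TRUE, scale = FALSE)
  attr(out, "scaled:center") <- NULL
  out
}

#' Phylogenetic tip correlation matrix
#'
#' `C[i, j]` is the shared root-to-tip path length of tips i and j divided by
#' the geometric mean of their depths (unit diagonal). Computed with
#' [ape::vcv()] on the rooted tree.
#'
#' @param tree rooted `phylo` with positive branch lengths.
#' @return symmetric positive semi-definite correlation matrix, rows/columns
#'   named and ordered by `tree$tip.label`.
#' @export
phylo_correlation <- function(tree) {
  # a pure star (single basal polytomy) is treated as rooted at that node
  if (!ape::is.rooted(tree) && tree$Nnode > 1) stop("tree must be rooted")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths")
  C <- ape::vcv(tree, corr = TRUE)
  C[tree$tip.label, tree$tip.label]
}

#' Unweighted UniFrac distances
#'
#' Fraction of the observed branch length unique to one of the two samples:
#' `d(i, j)` = (branch length leading exclusively to tips observed in exactly
#' one sample) / (branch length leading to tips observed in either). Backed
#' by [picante::unifrac()] after validation.
#'
#' @param counts samples x OTUs matrix (any positive value marks presence);
#'   every OTU must be a tip of `tree` and every sample must contain at least
#'   one OTU.
#' @param tree rooted `phylo` covering all OTUs.
#' @return symmetric distance matrix in `[0, 1]` with zero diagonal.
#' @export
unweighted_unifrac <- function(counts, tree) {
  counts <- as.matrix(counts)
  missing_tips <- setdiff(colnames(counts), tree$tip.label)
  if (length(missing_tips) > 0)
    stop("OTUs not in tree: ", paste(utils::head(missing_tips, 5), collapse = ", "))
  if (any(rowSums(counts > 0) == 0))
    stop("sample(s) with no observed OTUs: ",
         paste(rownames(counts)[rowSums(counts > 0) == 0], collapse = ", "))
  pa <- (counts > 0) * 1
  pruned <- ape::keep.tip(tree, colnames(pa))
  d <- picante::unifrac(pa, pruned)
  as.matrix(d)
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-D^2/2` followed by eigendecomposition
#' (via [stats::cmdscale()]). Axes with positive eigenvalues are retained up
#' to `n_axes`, ordered by decreasing eigenvalue; all signed eigenvalues
#' (including negative ones, uncorrected) are reported.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param n_axes axes to retain (default 2).
#' @return list with `coords` (samples x retained axes, centered),
#'   `eigenvalues` (all, signed, decreasing) and `prop_explained`
#'   (per retained axis, relative to the positive-eigenvalue sum).
#' @export
pcoa <- function(D, n_axes = 2) {
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  n <- nrow(D)
  fit <- suppressWarnings(stats::cmdscale(D, k = min(n_axes, n - 1), eig = TRUE))
  eig <- fit$eig
  pos <- sum(eig[eig > 1e-12])
  coords <- fit$points
  if (is.null(coords) || ncol(coords) == 0)
    coords <- matrix(0, n, n_axes, dimnames = list(rownames(D), NULL))
  if (ncol(coords) < n_axes)   # fewer positive axes than requested
    coords <- cbind(coords, matrix(0, n, n_axes - ncol(coords)))
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  ax_eig <- eig[seq_len(ncol(coords))]
  list(coords = coords, eigenvalues = eig,
       prop_explained = if (pos > 0) pmax(ax_eig, 0) / pos else rep(0, ncol(coords)))
}

#' Fit environmental vectors onto an ordination plane
#'
#' For each (standardized) variable, the direction cosines and squared
#' correlation r2 of its OLS regression on the first two ordination axes,
#' with a permutation p-value `(1 + #(permuted r2 >= observed)) / (1 + n_perm)`
#' obtained by row-permuting the variable. Backed by [vegan::envfit()].
#'
#' @param coords sample coordinates (first two axes used).
#' @param env data.frame of numeric environmental variables.
#' @param n_perm permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return data.frame with `variable`, `axis1`, `axis2` (unit-norm direction),
#'   `r2` and `p`.
#' @export
env_fit <- function(coords, env, n_perm = 999, seed = 1L) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  env <- as.data.frame(env)
  bad <- vapply(env, function(v) stats::sd(v, na.rm = TRUE) == 0, logical(1))
  if (any(bad)) stop("zero-variance variable(s): ",
                     paste(names(env)[bad], collapse = ", "))
  env <- as.data.frame(scale(env))
  set.seed(seed)
  ef <- vegan::envfit(coords, env, permutations = n_perm)
  data.frame(variable = rownames(ef$vectors$arrows),
             axis1 = ef$vectors$arrows[, 1], axis2 = ef$vectors$arrows[, 2],
             r2 = ef$vectors$r, p = ef$vectors$pvals,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write / read a samples-by-OTUs count table as tab-separated text
#'
#' @param counts samples x OTUs matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_otu_table
#' @param transposed set `TRUE` if the file stores OTUs in rows.
#' @return for `read_otu_table`: samples x OTUs integer matrix.
#' @export
read_otu_table <- function(path, transposed = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (transposed) m <- t(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a square distance matrix with header row and column
#'
#' @param D distance matrix.
#' @param path output file.
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(sample_id = rownames(as.matrix(D)), as.matrix(D),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
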