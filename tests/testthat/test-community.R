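test_that("rarefy excludes shallow samples and equalizes depth", {
  set.seed(2)
  m <- matrix(rpois(5 * 20, 30), 5, 20,
              dimnames = list(paste0("s", 1:5), paste0("o", 1:20)))
  depth <- min(rowSums(m))
  r <- rarefy(m, depth, seed = 1)
  expect_length(r$excluded, 0)
  expect_true(all(rowSums(r$counts) == depth))

  m2 <- m; m2[2, ] <- 0; m2[2, 1] <- depth - 1   # one read short
  r2 <- rarefy(m2, depth, seed = 1)
  expect_identical(r2$excluded, "s2")
  expect_false("s2" %in% rownames(r2$counts))

  # sample already exactly at depth passes through unchanged
  m3 <- m; m3[1, ] <- 0; m3[1, 1:3] <- c(depth - 10, 5, 5)
  r3 <- rarefy(m3, depth, seed = 9)
  expect_equal(unname(r3$counts["s1", 1:3]), c(depth - 10, 5, 5))

  expect_identical(rarefy(m, depth, seed = 3)$counts,
                   rarefy(m, depth, seed = 3)$counts)
  expect_error(rarefy(m, 10 * sum(m)), "below")
})

test_that("rarefaction is mean-preserving (hypergeometric oracle)", {
  counts <- matrix(c(100, 60, 30, 10), 1, 4,
                   dimnames = list("s1", paste0("o", 1:4)))
  depth <- 50
  reps <- 500
  acc <- matrix(0, reps, 4)
  for (i in seq_len(reps)) acc[i, ] <- rarefy(counts, depth, seed = i)$counts
  expected <- depth * counts[1, ] / sum(counts)   # hypergeometric mean
  p <- counts[1, ] / sum(counts)
  # finite-population variance of the hypergeometric draw
  vr <- depth * p * (1 - p) * (sum(counts) - depth) / (sum(counts) - 1)
  se <- sqrt(vr / reps)
  expect_true(all(abs(colMeans(acc) - expected) < 3 * se + 1e-9))
})

test_that("occurrence filters partition OTUs as enumerated by hand", {
  # 32-sample fixture with a known occupancy histogram
  n <- 32
  occup <- c(0, 5, 9, 10, 16, 22, 23, 31, 32)   # samples occupied per OTU
  m <- sapply(occup, function(k) c(rep(1L, k), rep(0L, n - k)))
  colnames(m) <- paste0("otu_occ", occup)
  rownames(m) <- paste0("s", 1:n)

  keep <- pa_filter(m, min_present = 10, min_absent = 10)
  # needs >= 10 present AND >= 10 absent: occupancies 10..22 qualify
  expect_setequal(keep, c("otu_occ10", "otu_occ16", "otu_occ22"))
  # boundary: present in exactly 10 of 20 samples
  m20 <- rbind(matrix(1L, 10, 1), matrix(0L, 10, 1))
  dimnames(m20) <- list(paste0("t", 1:20), "edge")
  expect_identical(pa_filter(m20), "edge")
  expect_warning(pa_filter(matrix(1L, 20, 1, dimnames = list(NULL, "x"))),
                 "no OTUs")

  abund <- suppressWarnings(abundance_filter_transform(m))
  expect_identical(colnames(abund), "otu_occ32")
  # the two model partitions never overlap
  expect_length(intersect(keep, colnames(abund)), 0)
})

test_that("abundance transform centers and is scale-invariant", {
  set.seed(4)
  m <- matrix(rpois(8 * 12, 20) + 1, 8, 12,
              dimnames = list(paste0("s", 1:8), paste0("o", 1:12)))
  m[3, 5] <- 0
  out <- abundance_filter_transform(m)
  expect_false("o5" %in% colnames(out))
  expect_equal(ncol(out), 11)
  expect_true(all(abs(colMeans(out)) < 1e-12))
  # doubling one sample's counts leaves its proportions, hence the output
  m2 <- m; m2[1, ] <- 2L * m[1, ]
  expect_equal(abundance_filter_transform(m2), out, tolerance = 1e-12)
})

test_that("phylogenetic correlation matches shared-path geometry", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  expect_equal(unname(phylo_correlation(star)), diag(4), tolerance = 1e-12)

  # cherry splitting at half depth: shared path 0.5 of total
  cherry <- ape::read.tree(text = "((a:0.5,b:0.5):0.5,c:1);")
  C <- phylo_correlation(cherry)
  expect_equal(C["a", "b"], 0.5)
  expect_equal(C["a", "c"], 0)
  expect_equal(diag(C), c(a = 1, b = 1, c = 1))

  for (s in 1:5) {
    tr <- simulate_tree(20, seed = s)
    ev <- eigen(phylo_correlation(tr), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("unweighted UniFrac agrees with per-branch brute force", {
  # hand-computable 4-tip case with printed branch lengths
  tr4 <- ape::read.tree(text = "((a:1,b:2):1,(c:1,d:3):2);")
  pa <- rbind(s1 = c(a = 1, b = 1, c = 0, d = 0),
              s2 = c(a = 1, b = 0, c = 1, d = 0))
  D <- unweighted_unifrac(pa, tr4)
  # shared: a(1), stem-ab(1); unique: b(2), c(1), stem-cd(2); total 7
  expect_equal(D["s1", "s2"], 5 / 7)

  # identical presence sets and fully disjoint clades
  pa2 <- rbind(x = c(a = 1, b = 1, c = 0, d = 0),
               y = c(a = 1, b = 1, c = 0, d = 0),
               z = c(a = 0, b = 0, c = 1, d = 1))
  D2 <- unweighted_unifrac(pa2, tr4)
  expect_equal(D2["x", "y"], 0)
  expect_equal(D2["x", "z"], 1)

  # random fixtures up to 16 tips against the brute-force oracle
  set.seed(8)
  for (ntip in c(5, 9, 16)) {
    tr <- simulate_tree(ntip, seed = ntip)
    pa <- matrix(rbinom(4 * ntip, 1, 0.55), 4, ntip,
                 dimnames = list(paste0("s", 1:4), tr$tip.label))
    pa[rowSums(pa) == 0, 1] <- 1
    got <- unweighted_unifrac(pa, tr)
    want <- unifrac_brute(pa, tr)
    expect_equal(got[rownames(want), colnames(want)], want, tolerance = 1e-10)
    expect_equal(got, t(got))
    expect_true(all(diag(got) == 0) && all(got >= 0 & got <= 1))
  }

  expect_error(unweighted_unifrac(rbind(s1 = c(a = 0, b = 0, c = 0, d = 0),
                                        s2 = c(a = 1, b = 0, c = 0, d = 0)),
                                  tr4), "no observed")
})

test_that("pcoa embeds Euclidean configurations exactly", {
  set.seed(12)
  pts <- cbind(rnorm(15), rnorm(15))
  D <- as.matrix(dist(pts))
  ord <- pcoa(D, n_axes = 2)
  # recovered inter-point distances equal the originals (Procrustes-free check)
  expect_equal(as.matrix(dist(ord$coords)), D, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(abs(colMeans(ord$coords)) < 1e-8))
  expect_true(all(diff(ord$eigenvalues) <= 1e-8))
  # eigenvalue sum equals the trace of the double-centered matrix
  G <- -0.5 * (diag(15) - 1 / 15) %*% D^2 %*% (diag(15) - 1 / 15)
  expect_equal(sum(ord$eigenvalues), sum(diag(G)), tolerance = 1e-8)

  expect_true(all(pcoa(matrix(0, 4, 4))$coords == 0))

  # collinear points: a single positive eigenvalue
  line <- as.matrix(dist(cbind(c(0, 1, 2), 0)))
  expect_equal(sum(pcoa(line)$eigenvalues > 1e-8), 1)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("env_fit recovers axis-aligned variables and is reproducible", {
  set.seed(3)
  coords <- cbind(a1 = rnorm(25), a2 = rnorm(25))
  env <- data.frame(v = coords[, 1], noise = rnorm(25))
  ef <- env_fit(coords, env, n_perm = 199, seed = 5)
  expect_equal(ef$r2[ef$variable == "v"], 1, tolerance = 1e-10)
  expect_equal(abs(ef$axis1[ef$variable == "v"]), 1, tolerance = 1e-6)
  expect_lte(ef$p[ef$variable == "v"], 1 / 200 + 1e-12)

  ef2 <- env_fit(coords, data.frame(v = env$v, v2 = env$v), n_perm = 199, seed = 5)
  expect_equal(ef2$r2[1], ef2$r2[2])
  expect_equal(ef2$p[1], ef2$p[2])
  expect_error(env_fit(coords, data.frame(k = rep(1, 25))), "zero-variance")
})

test_that("null env_fit r2 matches the two-regressor expectation", {
  set.seed(19)
  n <- 30; r2s <- numeric(200)
  coords <- cbind(rnorm(n), rnorm(n))
  for (i in 1:200)
    r2s[i] <- env_fit(coords, data.frame(v = rnorm(n)), n_perm = 49, seed = i)$r2
  # E[R2] = k/(n-1) for k regressors under the null
  expect_equal(mean(r2s), 2 / (n - 1), tolerance = 0.35)
})
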