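# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive quantities from first principles and
# never call the package functions they are used to check.

# Unweighted UniFrac by explicit per-branch enumeration: for every edge of
# the tree, find the tip set below it; the edge is "shared" if both samples
# contain at least one of those tips, "unique" if exactly one does.
unifrac_brute <- function(pa, tree) {
  n <- nrow(pa)
  tips <- tree$tip.label
  # descendant tips per node, accumulated child-before-parent
  desc <- vector("list", max(tree$edge))
  for (i in seq_along(tips)) desc[[i]] <- tips[i]
  for (e in ape::postorder(tree)) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  D <- matrix(0, n, n, dimnames = list(rownames(pa), rownames(pa)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    si <- colnames(pa)[pa[i, ] > 0]
    sj <- colnames(pa)[pa[j, ] > 0]
    uniq <- 0; tot <- 0
    for (e in seq_len(nrow(tree$edge))) {
      below <- desc[[tree$edge[e, 2]]]
      ini <- any(below %in% si); inj <- any(below %in% sj)
      if (ini || inj) tot <- tot + tree$edge.length[e]
      if (xor(ini, inj)) uniq <- uniq + tree$edge.length[e]
    }
    D[i, j] <- D[j, i] <- uniq / tot
  }
  D
}

# definitional Tjur R2
tjur_brute <- function(y, p) {
  s1 <- 0; n1 <- 0; s0 <- 0; n0 <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1) { s1 <- s1 + p[i]; n1 <- n1 + 1 }
    else { s0 <- s0 + p[i]; n0 <- n0 + 1 }
  }
  s1 / n1 - s0 / n0
}

# small default config for fast simulations
quick_config <- function(...) {
  args <- utils::modifyList(
    list(n_blocks = 9, n_otus = 40, n_samples_dropped = 2,
         read_depth_target = 1500, seed = 42),
    list(...))
  do.call(sim_config, args)
}

# standardized full-covariate matrix used for recovery experiments
raw_covariates <- function(soil) {
  covars <- c("pH_CaCl2", "Ca", "Mg", "Al", "Fe", "Mn", "Cu", "Zn", "P", "B",
              "CEC", "soy_yield", "litter", "SOM", "K", "NO3")
  scale(as.matrix(soil[, covars]))
}
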