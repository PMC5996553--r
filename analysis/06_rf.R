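#!/usr/bin/env Rscript
# Stage 6 — per-OTU random forests with permutation-based predictor
# selection (Hapfelmeier-Ulm style), validation-score screening and
# importance aggregation over the conceptual predictor groups.
#
# Response: relative abundance of each occurrence-variable or omnipresent
# OTU; candidates: the 16 raw soil/plant covariates. The permutation budget
# here is scaled to desk size (trees/permutations configurable via
# environment variables; the per-OTU procedure is identical at any budget).

suppressMessages(library(soilspill))

seed <- as.integer(Sys.getenv("SOILSPILL_SEED", "1"))
n_trees <- as.integer(Sys.getenv("SOILSPILL_RF_TREES", "100"))
n_perm <- as.integer(Sys.getenv("SOILSPILL_RF_PERMS", "60"))
n_otus <- as.integer(Sys.getenv("SOILSPILL_RF_OTUS", "25"))

cfg <- sim_config(seed = seed)
sim <- simulate_dataset(cfg)
rr <- rarefy(sim$counts, cfg$read_depth_target, seed = seed + 1L)
soil <- sim$soil[rownames(rr$counts), ]
soil$CEC <- compute_cec(soil)

rel <- rr$counts / rowSums(rr$counts)
modelled_set <- union(pa_filter(rr$counts, 10, 10),
                      colnames(abundance_filter_transform(rr$counts)))
otus <- names(sort(colMeans(rel[, modelled_set]), decreasing = TRUE))
otus <- otus[seq_len(min(n_otus, length(otus)))]
preds <- soil[, c("pH_CaCl2", "Ca", "Mg", "Al", "Fe", "Mn", "Cu", "Zn",
                  "P", "B", "CEC", "soy_yield", "litter", "SOM", "K", "NO3")]

cat(sprintf("modelling %d OTUs with %d trees, %d permutations\n",
            length(otus), n_trees, n_perm))
res <- rf_run(rel[, otus], preds,
              rf_config(n_trees = n_trees, n_perm = n_perm, seed = seed + 9L))
tab <- rf_summary(res)
utils::write.table(tab, "results/rf_models.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

scrn <- rf_screen(res, 0.1)
print(scrn$summary, row.names = FALSE)
if (length(scrn$retained) > 0) {
  agg <- rf_aggregate_importance(scrn$retained)
  imp <- sort(agg$mean_importance, decreasing = TRUE)
  cat("top predictors by mean importance (%):\n")
  print(round(utils::head(imp, 5), 1))
  utils::write.table(
    data.frame(predictor = names(agg$mean_importance),
               mean_importance_pct = unname(agg$mean_importance)),
    "results/rf_importance.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(otu = rownames(agg$group_distribution),
               agg$group_distribution),
    "results/rf_group_importance.tsv", sep = "\t", quote = FALSE,
    row.names = FALSE)
}
cat("wrote results/rf_{models,importance,group_importance}.tsv\n")
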