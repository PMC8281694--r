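#!/usr/bin/env Rscript
# Variable selection: for each yield trait, rank all 756 variables (and the
# 200 first-order candidates) with Boruta, permutation importance, a genetic
# algorithm, LASSO and recursive feature elimination; importances are
# averaged over repeated seeded runs and the top five variables per method
# are kept. Writes a long table shaped like a selection summary
# (rank x map x variable x date) per candidate mode.
#
# Note: the full grid (5 methods x 3 traits x 2 modes x 10 repeats) takes a
# while on one core; set repeats lower for a quick look.

library(phenoyield)

seed <- 1L
repeats <- 10
feat <- read.csv("results/features.csv", check.names = FALSE)
X <- as.matrix(feat[, -1])
yields <- read.csv("results/yields.csv")
yields <- yields[match(feat$plant_id, yields$plant_id), ]
Z <- normalize_features(X)
Zf <- Z[, grepl("_(AVE|SD|SKEW|RANGE|MAX)_", colnames(Z))]

truth <- jsonlite::read_json("results/truth.json", simplifyVector = TRUE)
causal <- truth$causal_features

rows <- list()
for (mode in c("all", "first_order")) {
  Zm <- if (mode == "all") Z else Zf
  for (trait in c("SM", "FW", "FN")) {
    y <- yields[[trait]]
    for (m in c("boruta", "permimp", "ga", "lasso", "rfe")) {
      res <- run_selection(Zm, y, method = m, repeats = repeats,
                           seed = stage_seed(seed, paste(m, trait, mode, sep = "-")))
      hits <- sum(causal %in% res$top_k)
      cat(sprintf("%-11s %-3s %-11s top5: %s  (causal hits %d)\n",
                  m, trait, mode, paste(res$top_k, collapse = ", "), hits))
      for (r in seq_along(res$top_k)) {
        parts <- strsplit(res$top_k[r], "_")[[1]]
        rows[[length(rows) + 1L]] <- data.frame(
          mode = mode, trait = trait, method = m, rank = r,
          map = parts[1], variable = parts[2],
          date = paste(parts[-(1:2)], collapse = "_"),
          importance = unname(res$importances[res$top_k[r]]))
      }
    }
  }
}
sel <- do.call(rbind, rows)
write.csv(sel, "results/selection_top5.csv", row.names = FALSE)
cat("wrote results/selection_top5.csv\n")
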