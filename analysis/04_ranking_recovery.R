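#!/usr/bin/env Rscript
# Ranking-recovery study: in single-station datasets with planted coupling
# strengths beta = 0, 0.3, 0.6, 0.9 to a hub target, does the composite
# score recover the beta ordering? 30 seeds.

library(stcrqa)
dir.create("results", showWarnings = FALSE)

cc <- study_config()
betas <- c(C00 = 0, C03 = 0.3, C06 = 0.6, C09 = 0.9)
n_seeds <- 30

scores <- matrix(NA_real_, n_seeds, 4, dimnames = list(NULL, names(betas)))
for (s in seq_len(n_seeds)) {
  ds <- ranking_study_dataset(seed = s)
  p <- suppressWarnings(coupling_panel(ds, "ST1:T", config = cc))
  scores[s, ] <- setNames(p$scores$score, p$scores$factor)[names(betas)]
}

means <- colMeans(scores)
ranks <- t(apply(scores, 1, function(x) rank(-x, ties.method = "max")))
out <- data.frame(candidate = names(betas), beta = as.numeric(betas),
                  mean_score = as.numeric(means),
                  first_rank_rate = colMeans(ranks == 1),
                  top2_rate = colMeans(ranks <= 2))
write.csv(out, "results/04_ranking_recovery.csv", row.names = FALSE)

cat("mean composite score by planted beta (", n_seeds, "seeds ):\n")
print(out, row.names = FALSE)
cat("\nbeta ordering recovered by the means:",
    all(diff(means) > 0), "\n")
cat("beta=0.9 ranked first in", mean(ranks[, "C09"] == 1) * 100, "% of seeds\n")
cat("beta=0 kept out of the top 2 in", mean(ranks[, "C00"] > 2) * 100,
    "% of seeds\n")
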