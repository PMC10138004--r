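#!/usr/bin/env Rscript
# Embedding-parameter selection: per-series AMI delay and FNN dimension on
# the synthetic campaign, and the best-match table for the published
# reference parameters of the emulated buoy campaign.

library(stcrqa)
dir.create("results", showWarnings = FALSE)

ds <- read_station_csv("scratch/campaign.csv")
cc <- study_config()

params <- do.call(rbind, lapply(names(ds$series), function(id) {
  x <- standardize_series(get_series(ds, id))
  p <- suppressWarnings(select_embedding(x, max_delay = cc$max_delay,
                                         max_dim = cc$max_dim,
                                         threshold = cc$fnn_threshold))
  data.frame(series = id, dimension = p$dimension, delay = p$delay,
             label = format(p))
}))
write.csv(params, "results/02_embedding_params.csv", row.names = FALSE)
cat("per-series embedding parameters (synthetic campaign):\n")
print(params, row.names = FALSE)

ref <- reference_embedding_params()
bm <- best_match_table(ref, "ST1", "pH")
write.csv(bm, "results/02_best_match_reference.csv", row.names = FALSE)
cat("\nbest-match table vs pH at ST1 (published reference parameters):\n")
print(bm, row.names = FALSE)
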