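#!/usr/bin/env Rscript
# Stage 3: ordered-state HMM event segmentation.
#
# Selects the number of neural events per network by nested cross-validation
# (each subject held out in turn; the rest split ~27:8-style into training
# and validation averages; K maximising validation log-likelihood wins),
# then fits the selected model and writes boundaries and log-likelihood
# curves. The DMN is fitted on voxel-level features (too few ROIs per
# network at this scale for ROI-mean patterns) and its segmentation is the
# event definition used by stage 4.

suppressPackageStartupMessages(library(dyadsync))

seed <- 20240103L
ds <- load_dataset("results/dataset/manifest.json")
truth <- jsonlite::read_json("results/dataset/ground_truth.json",
                             simplifyVector = TRUE)

dmn <- lapply(ds$subjects, function(s) {
  network_features(ds, s, network = "DMN", level = "voxel")
})
sel <- select_num_states(dmn, k_range = 1:10, seed = seed)
seg <- sel$model

cat(sprintf("DMN: selected K* = %d (true K = 5); boundaries %s (true: %s)\n",
            sel$k_star, paste(seg$boundaries, collapse = ", "),
            paste(truth$boundaries, collapse = ", ")))

dir.create("results/events", recursive = TRUE, showWarnings = FALSE)
jsonlite::write_json(
  list(network = "DMN", k_star = sel$k_star,
       boundaries = seg$boundaries,
       log_likelihood = seg$log_likelihood,
       mean_validation_loglik = as.list(setNames(sel$mean_loglik,
                                                 paste0("K", sel$k_range)))),
  "results/events/events_dmn.json", auto_unbox = TRUE, digits = NA)
write_results(list(
  assignments = data.frame(tr = seq_along(seg$assignment) - 1L,
                           state = seg$assignment)
), "results/events")
cat("event segmentation written to results/events\n")
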