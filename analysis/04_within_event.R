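#!/usr/bin/env Rscript
# Stage 4: within-event ISTS.
#
# Applies the DMN-defined event windows from stage 3 to every ROI: for each
# couple and ROI, trajectory matrices are rebuilt within each event window,
# correlated, and averaged across events. Also computes the within-clip
# variant from a 5-clip segmentation of the run for comparison.

suppressPackageStartupMessages(library(dyadsync))

ds <- load_dataset("results/dataset/manifest.json")
ev <- jsonlite::read_json("results/events/events_dmn.json", simplifyVector = TRUE)

b <- as.integer(ev$boundaries)
hmm_windows <- build_event_windows(
  data.frame(clip_id = seq_len(length(b) + 1L),
             start_tr = c(0L, b), end_tr = c(b, ds$n_tr)))
wit <- within_event_ists_table(ds, hmm_windows)
wwb <- whole_brain_average(wit)
wwb$dyad_class <- ds$dyads$dyad_class

# fixed-length pseudo-clips as the naive segmentation baseline
starts <- seq(0L, ds$n_tr - 1L, by = ds$n_tr %/% 5L)[1:5]
clip_windows <- build_event_windows(
  data.frame(clip_id = 1:5, start_tr = starts,
             end_tr = c(starts[-1L], ds$n_tr)))
wclip <- within_event_ists_table(ds, clip_windows)
cwb <- whole_brain_average(wclip)

cat(sprintf("within-event ISTS: high %.3f, low %.3f; within-clip: %.3f overall\n",
            mean(wwb$mean_ists[wwb$dyad_class == "couple_high"]),
            mean(wwb$mean_ists[wwb$dyad_class == "couple_low"]),
            mean(cwb$mean_ists)))

write_results(list(
  within_event_long = ists_long_format(wit, scope = "within_event"),
  within_clip_long = ists_long_format(wclip, scope = "within_clip"),
  within_event_whole_brain = wwb,
  n_event_windows = length(hmm_windows$windows),
  n_windows_skipped = hmm_windows$n_skipped
), "results/within_event")
cat("within-event tables written to results/within_event\n")
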