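#!/usr/bin/env Rscript
# Segment the day-1 detection stream written by 01_simulate.R into
# behavioral bouts: confidence filter at 0.45, per-second presence
# rasterization, then threshold/hysteresis bout identification (onset 5 s
# aggressive / 3 s ear and tail biting; termination gap 5 s). Compares the
# recovered bouts against the generator's ground truth.

suppressPackageStartupMessages(library(pigbouts))

det <- read_detection_csv("results/day01_control_detections.csv")
truth <- utils::read.csv("results/day01_control_true_bouts.csv")
date <- det$date[1]
crit <- bout_criteria()

ai <- do.call(rbind, lapply(behavior_classes(), function(cl) {
  p <- to_presence_series(filter_by_confidence(det, 0.45), date, cl)
  find_bouts(p, cl, crit, date = date)
}))
utils::write.csv(ai, "results/day01_control_ai_bouts.csv", row.names = FALSE)

for (cl in behavior_classes()) {
  cat(sprintf("%-12s true bouts %4d (total %6d s) | AI bouts %4d (total %6d s)\n",
              cl, sum(truth$class == cl),
              sum(truth$duration_s[truth$class == cl]),
              sum(ai$class == cl), sum(ai$duration_s[ai$class == cl])))
}
cat("AI bout table -> results/day01_control_ai_bouts.csv\n")
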