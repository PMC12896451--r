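# shared fixture builders; everything is generated in code under fixed seeds

# random valid detection table (boxless dialect)
random_detections <- function(n, date = as.Date("2024-07-01"),
                              channel = 11L) {
  detection_table(channel = rep(channel, n), date = rep(date, n),
                  timestamp_s = sample.int(86400L, n, replace = TRUE) - 1L,
                  class = sample(behavior_classes(), n, replace = TRUE),
                  confidence = round(runif(n), 3))
}

# random binary presence vector with tunable density
random_presence <- function(n, p = 0.5) {
  as.integer(runif(n) < p)
}

# the i-th (0-based) binary vector of length n
int_to_bits <- function(i, n) {
  as.integer(intToBits(i))[seq_len(n)]
}

# a noise-free config: detections and manual annotation reproduce the
# schedule exactly
noise_free_config <- function(seed = 1L) {
  sim_config(miss_prob = 0, false_positive_rate = 0,
             manual_boundary_jitter_sd_s = 0, manual_miss_prob = 0,
             box_jitter_sd_px = 0, box_drop_prob = 0,
             box_class_flip_prob = 0, box_spurious_rate = 0, seed = seed)
}

expect_same_bouts <- function(a, b) {
  expect_equal(a[c("class", "start_s", "end_s", "duration_s")],
               b[c("class", "start_s", "end_s", "duration_s")])
}
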