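#' Simulation configuration for the synthetic behavior generator
#'
#' Defines the stochastic model that stands in for the study's recordings:
#' per-class daily bout counts are Poisson with a log-linear day trend and a
#' multiplicative treatment (enrichment) effect, bout durations are rounded
#' lognormal seconds clipped to the class onset threshold, the detector is
#' emulated by per-second Bernoulli misses plus uniform false-positive
#' seconds with Beta-distributed confidences rescaled to [0.45, 1], and the
#' human observer by bout drops plus Gaussian boundary jitter.
#'
#' Default rates and durations are calibrated to the week-1 pen-level means
#' of the study population (control pen: 59.7 aggressive, 325.6 ear-biting
#' and 117.0 tail-biting bouts/day; mean durations 27.7 / 28.4 / 24.5 s per
#' bout), with treatment multipliers and day trends matching the reported
#' week-1-to-week-4 declines.
#'
#' @param base_bouts_per_day Named per-class expected bouts/day for the
#'   control group on day 1.
#' @param treatment_multiplier Named per-class multiplicative enrichment
#'   effect on the bout rate.
#' @param day_trend Named per-class log-linear slope per day of the bout
#'   rate (negative = decline).
#' @param duration_mu,duration_sigma Named per-class lognormal parameters of
#'   bout duration (log-seconds).
#' @param miss_prob Per-second probability that an in-bout second yields no
#'   detection.
#' @param false_positive_rate Expected spurious detection seconds per day
#'   per class.
#' @param confidence_beta_a,confidence_beta_b Beta shape parameters of the
#'   detection confidence before rescaling to [0.45, 1].
#' @param manual_boundary_jitter_sd_s SD (s) of the observer's Gaussian
#'   start/end jitter.
#' @param manual_miss_prob Probability the observer misses a bout entirely.
#' @param box_jitter_sd_px,box_drop_prob,box_class_flip_prob,box_spurious_rate
#'   Perturbation rates for the toy bounding-box fixture generator.
#' @param start_date Date mapped to day index 1.
#' @param seed Master seed; every generator output is a pure function of the
#'   seed and its arguments.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(base_bouts_per_day = c(aggressive = 59.7,
                                              ear_biting = 325.64,
                                              tail_biting = 116.95),
                       treatment_multiplier = c(aggressive = 0.52,
                                                ear_biting = 0.42,
                                                tail_biting = 0.27),
                       day_trend = c(aggressive = -0.041,
                                     ear_biting = -0.037,
                                     tail_biting = -0.029),
                       duration_mu = c(aggressive = 3.197,
                                       ear_biting = 3.221,
                                       tail_biting = 3.075),
                       duration_sigma = c(aggressive = 0.5,
                                          ear_biting = 0.5,
                                          tail_biting = 0.5),
                       miss_prob = 0.05,
                       false_positive_rate = 5,
                       confidence_beta_a = 5,
                       confidence_beta_b = 2,
                       manual_boundary_jitter_sd_s = 2,
                       manual_miss_prob = 0.05,
                       box_jitter_sd_px = 2,
                       box_drop_prob = 0.05,
                       box_class_flip_prob = 0.05,
                       box_spurious_rate = 0.3,
                       start_date = as.Date("2024-07-01"),
                       seed = 42L) {
  cfg <- list(base_bouts_per_day = base_bouts_per_day,
              treatment_multiplier = treatment_multiplier,
              day_trend = day_trend,
              duration_mu = duration_mu, duration_sigma = duration_sigma,
              miss_prob = miss_prob,
              false_positive_rate = false_positive_rate,
              confidence_beta_a = confidence_beta_a,
              confidence_beta_b = confidence_beta_b,
              manual_boundary_jitter_sd_s = manual_boundary_jitter_sd_s,
              manual_miss_prob = manual_miss_prob,
              box_jitter_sd_px = box_jitter_sd_px,
              box_drop_prob = box_drop_prob,
              box_class_flip_prob = box_class_flip_prob,
              box_spurious_rate = box_spurious_rate,
              start_date = as.Date(start_date), seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  per_class <- c("base_bouts_per_day", "treatment_multiplier", "day_trend",
                 "duration_mu", "duration_sigma")
  for (f in per_class)
    if (!all(behavior_classes() %in% names(cfg[[f]])))
      stop(f, " must be named with all behavior classes")
  stopifnot(all(cfg$base_bouts_per_day >= 0),
            all(cfg$treatment_multiplier > 0),
            all(cfg$duration_sigma > 0),
            cfg$miss_prob >= 0, cfg$miss_prob < 1,
            cfg$false_positive_rate >= 0,
            cfg$confidence_beta_a > 0, cfg$confidence_beta_b > 0,
            cfg$manual_boundary_jitter_sd_s >= 0,
            cfg$manual_miss_prob >= 0, cfg$manual_miss_prob < 1)
  invisible(cfg)
}

#' Read or write a simulation configuration as YAML
#' @param path YAML file path.
#' @return For the reader, a [sim_config()]; the writer returns the path
#'   invisibly.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$start_date <- as.Date(y$start_date)
  for (f in c("base_bouts_per_day", "treatment_multiplier", "day_trend",
              "duration_mu", "duration_sigma"))
    y[[f]] <- unlist(y[[f]])
  do.call(sim_config, y)
}

#' @rdname read_sim_config
#' @param cfg A [sim_config()].
#' @export
write_sim_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$start_date <- format(out$start_date)
  for (f in names(out)) if (!is.null(names(out[[f]])))
    out[[f]] <- as.list(out[[f]])
  yaml::write_yaml(out, path)
  invisible(path)
}

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# substream seed derived from the master seed and the call coordinates;
# kept below 2^31 - 1
derive_seed <- function(seed, group, day, class_label) {
  gi <- match(group, c("control", "treatment"))
  ci <- match(class_label, behavior_classes())
  as.integer((as.double(seed) + 1000003 * gi + 10007 * ci + 101 * day) %%
               2147483647)
}

group_channel <- function(group) {
  # house channel 10 = treatment, 11 = control
  c(control = 11L, treatment = 10L)[[group]]
}

#' Simulate a day's ground-truth bout schedule
#'
#' Draws the day's bout count from Poisson(base x exp(trend x (day - 1)) x
#' group multiplier), durations from a rounded lognormal clipped to the
#' class onset threshold, and places the bouts uniformly at random subject
#' to a minimum same-class separation equal to the termination gap (so the
#' schedule is exactly recoverable by bout segmentation when rendered
#' without noise). Deterministic given (cfg$seed, group, day, class).
#'
#' @param cfg A [sim_config()].
#' @param group \code{"control"} or \code{"treatment"}.
#' @param day Day index, 1-based.
#' @param class_label One of [behavior_classes()].
#' @param criteria [bout_criteria()] supplying onset and gap thresholds.
#' @return Bout \code{data.frame} (possibly empty), dated
#'   \code{cfg$start_date + day - 1}.
#' @export
simulate_bout_schedule <- function(cfg, group, day, class_label,
                                   criteria = bout_criteria()) {
  validate_sim_config(cfg)
  assert_class_label(class_label)
  group <- match.arg(group, c("control", "treatment"))
  mult <- if (group == "treatment") cfg$treatment_multiplier[[class_label]]
          else 1
  rate <- cfg$base_bouts_per_day[[class_label]] *
    exp(cfg$day_trend[[class_label]] * (day - 1)) * mult
  mean_dur <- exp(cfg$duration_mu[[class_label]] +
                    cfg$duration_sigma[[class_label]]^2 / 2)
  if (rate * (mean_dur + criteria$termination_gap_s) > DAY_SECONDS)
    stop("infeasible packing: expected bout time exceeds the day")
  date <- cfg$start_date + day - 1
  onset <- criteria$onset_min_s[[class_label]]
  gap <- criteria$termination_gap_s
  with_seed(derive_seed(cfg$seed, group, day, class_label), {
    n <- stats::rpois(1L, rate)
    d <- if (n > 0L)
      pmax(onset, round(stats::rlnorm(n, cfg$duration_mu[[class_label]],
                                      cfg$duration_sigma[[class_label]])))
    # shrink in the (rare) event a large draw cannot be packed
    while (n > 0L && sum(d[seq_len(n)]) + (n - 1L) * gap > DAY_SECONDS)
      n <- n - 1L
    if (n == 0L) bout_table()
    else {
      d <- as.integer(d[seq_len(n)])
      free <- DAY_SECONDS - sum(d) - (n - 1L) * gap
      # uniform placement on the feasible set: split the free time across
      # the n + 1 inter-bout slots by ordered uniform spacings
      offsets <- floor(sort(stats::runif(n)) * (free + 1))
      starts <- as.integer(offsets + c(0L, cumsum(d[-n] + gap)))
      bout_table(class = rep(class_label, n), date = rep(date, n),
                 start_s = starts, end_s = starts + d)
    }
  })
}

#' Render a bout schedule as a noisy detection stream
#'
#' Emulates the deployed 1-fps detector: every in-bout second yields a
#' detection with probability \code{1 - miss_prob}; spurious single-second
#' detections are added per behavior class at a Poisson rate of
#' \code{false_positive_rate} per day, uniformly over the day. Confidences
#' are Beta(a, b) rescaled to [0.45, 1] so every rendered detection
#' survives the default operating threshold.
#'
#' @param schedule Bout \code{data.frame} (any mix of classes, one date).
#' @param cfg A [sim_config()].
#' @param seed Seed for this rendering.
#' @param date Day of the stream; defaults to the schedule's date (required
#'   when the schedule is empty).
#' @param channel House channel (11 = control, 10 = treatment).
#' @return Detection \code{data.frame}, see [detection_table()].
#' @export
render_detections <- function(schedule, cfg, seed, date = NULL,
                              channel = 11L) {
  validate_sim_config(cfg)
  if (is.null(date)) {
    if (!nrow(schedule)) stop("date required for an empty schedule")
    date <- schedule$date[1L]
  }
  date <- as.Date(date)
  rconf <- function(k) 0.45 + 0.55 * stats::rbeta(k, cfg$confidence_beta_a,
                                                  cfg$confidence_beta_b)
  with_seed(seed, {
    ts <- integer(); cls <- character()
    for (cl in behavior_classes()) {
      b <- schedule[schedule$class == cl, , drop = FALSE]
      secs <- unlist(lapply(seq_len(nrow(b)), function(i)
        seq.int(b$start_s[i], b$end_s[i] - 1L)), use.names = FALSE)
      if (length(secs) && cfg$miss_prob > 0)
        secs <- secs[stats::runif(length(secs)) >= cfg$miss_prob]
      n_fp <- stats::rpois(1L, cfg$false_positive_rate)
      fp <- if (n_fp) sample.int(DAY_SECONDS, n_fp, replace = TRUE) - 1L
            else integer()
      all_s <- c(secs, fp)
      ts <- c(ts, all_s); cls <- c(cls, rep(cl, length(all_s)))
    }
    detection_table(channel = rep(channel, length(ts)),
                    date = rep(date, length(ts)), timestamp_s = ts,
                    class = cls, confidence = rconf(length(ts)))
  })
}

#' Render a bout schedule as observer-coded manual bouts
#'
#' Emulates trained-observer coding of the same recording: each true bout
#' is missed entirely with probability \code{manual_miss_prob}; surviving
#' bouts get independent Gaussian start and end jitter (SD
#' \code{manual_boundary_jitter_sd_s}, rounded to whole seconds), clipped
#' to the day with end kept strictly after start.
#'
#' @inheritParams render_detections
#' @return Bout \code{data.frame}.
#' @export
render_manual <- function(schedule, cfg, seed) {
  validate_sim_config(cfg)
  if (!nrow(schedule)) return(bout_table())
  with_seed(seed, {
    keep <- stats::runif(nrow(schedule)) >= cfg$manual_miss_prob
    b <- schedule[keep, , drop = FALSE]
    if (!nrow(b)) bout_table()
    else {
      sd <- cfg$manual_boundary_jitter_sd_s
      s <- b$start_s + round(stats::rnorm(nrow(b), 0, sd))
      e <- b$end_s + round(stats::rnorm(nrow(b), 0, sd))
      s <- pmax(0L, pmin(as.integer(s), DAY_SECONDS - 1L))
      e <- pmin(as.integer(e), DAY_SECONDS)
      e <- pmax(e, s + 1L)
      bout_table(class = b$class, date = b$date, start_s = s, end_s = e)
    }
  })
}

#' Toy bounding-box fixture for detector evaluation
#'
#' Generates random ground-truth boxes (1-3 per 800 x 800 image, random
#' class) and a matched prediction set obtained by perturbing them: corner
#' jitter, whole-box drops, class flips and spurious boxes at the rates in
#' \code{cfg}. With all perturbation rates zero the predictions reproduce
#' the ground truth exactly and every evaluation metric is 1.
#'
#' @param n_images Number of images.
#' @param cfg A [sim_config()].
#' @param seed Seed for this fixture.
#' @return List with \code{gt} and \code{pred} box \code{data.frame}s in
#'   the [read_box_csv()] dialect.
#' @export
make_box_fixture <- function(n_images, cfg, seed) {
  validate_sim_config(cfg)
  stopifnot(n_images >= 1)
  rand_box <- function(k) {
    x0 <- stats::runif(k, 0, 500); y0 <- stats::runif(k, 0, 500)
    w <- stats::runif(k, 80, 300); h <- stats::runif(k, 80, 300)
    data.frame(x_min = x0, y_min = y0, x_max = x0 + w, y_max = y0 + h)
  }
  rconf <- function(k) 0.45 + 0.55 * stats::rbeta(k, cfg$confidence_beta_a,
                                                  cfg$confidence_beta_b)
  with_seed(seed, {
    n_per <- sample.int(3L, n_images, replace = TRUE)
    img <- rep(seq_len(n_images), n_per)
    n_gt <- length(img)
    gt <- cbind(data.frame(image_id = img,
                           class = sample(behavior_classes(), n_gt,
                                          replace = TRUE),
                           stringsAsFactors = FALSE), rand_box(n_gt))
    keep <- stats::runif(n_gt) >= cfg$box_drop_prob
    pred <- gt[keep, , drop = FALSE]
    if (nrow(pred)) {
      jit <- matrix(stats::rnorm(nrow(pred) * 4, 0, cfg$box_jitter_sd_px),
                    ncol = 4)
      pred$x_min <- pmax(0, pred$x_min + jit[, 1])
      pred$y_min <- pmax(0, pred$y_min + jit[, 2])
      pred$x_max <- pmax(pred$x_min + 1, pred$x_max + jit[, 3])
      pred$y_max <- pmax(pred$y_min + 1, pred$y_max + jit[, 4])
      flip <- stats::runif(nrow(pred)) < cfg$box_class_flip_prob
      pred$class[flip] <- vapply(pred$class[flip], function(cl)
        sample(setdiff(behavior_classes(), cl), 1L), character(1))
      pred$confidence <- rconf(nrow(pred))
    } else pred$confidence <- numeric()
    n_sp <- stats::rpois(1L, cfg$box_spurious_rate * n_images)
    if (n_sp) {
      sp <- cbind(data.frame(image_id = sample.int(n_images, n_sp,
                                                   replace = TRUE),
                             class = sample(behavior_classes(), n_sp,
                                            replace = TRUE),
                             stringsAsFactors = FALSE), rand_box(n_sp))
      sp$confidence <- rconf(n_sp)
      pred <- rbind(pred, sp)
    }
    list(gt = reset_rownames(gt), pred = reset_rownames(pred))
  })
}

#' Simulate a full pen-day or experiment
#'
#' [simulate_pen_day()] draws, for one group and day, the per-class true
#' bout schedules, the rendered detection stream and the observer-coded
#' manual bouts. [simulate_experiment()] iterates over groups and days and
#' binds the results.
#'
#' @param cfg A [sim_config()].
#' @param group \code{"control"} or \code{"treatment"}.
#' @param day Day index, 1-based.
#' @param criteria [bout_criteria()].
#' @return [simulate_pen_day()]: list with \code{group}, \code{day},
#'   \code{date}, \code{true_bouts}, \code{detections},
#'   \code{manual_bouts}. [simulate_experiment()]: the same fields as
#'   \code{data.frame}s with \code{group} columns, in a list.
#' @export
simulate_pen_day <- function(cfg, group, day, criteria = bout_criteria()) {
  group <- match.arg(group, c("control", "treatment"))
  date <- cfg$start_date + day - 1
  schedules <- lapply(behavior_classes(), function(cl)
    simulate_bout_schedule(cfg, group, day, cl, criteria))
  true_bouts <- reset_rownames(do.call(rbind, schedules))
  seed_det <- derive_seed(cfg$seed + 7L, group, day, "aggressive")
  seed_man <- derive_seed(cfg$seed + 13L, group, day, "aggressive")
  detections <- render_detections(true_bouts, cfg, seed_det, date = date,
                                  channel = group_channel(group))
  manual_bouts <- render_manual(true_bouts, cfg, seed_man)
  list(group = group, day = day, date = date, true_bouts = true_bouts,
       detections = detections, manual_bouts = manual_bouts)
}

#' @rdname simulate_pen_day
#' @param days Number of days to simulate (study default 28).
#' @param groups Groups to simulate.
#' @export
simulate_experiment <- function(cfg, days = 28L,
                                groups = c("control", "treatment"),
                                criteria = bout_criteria()) {
  tb <- list(); det <- list(); man <- list()
  for (g in groups) for (day in seq_len(days)) {
    pd <- simulate_pen_day(cfg, g, day, criteria)
    add_group <- function(d) { d$group <- rep(g, nrow(d)); d }
    tb[[length(tb) + 1L]] <- add_group(pd$true_bouts)
    det[[length(det) + 1L]] <- add_group(pd$detections)
    man[[length(man) + 1L]] <- add_group(pd$manual_bouts)
  }
  bind <- function(l) reset_rownames(do.call(rbind, l))
  list(true_bouts = bind(tb), detections = bind(det),
       manual_bouts = bind(man))
}
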