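#' Construct a bout table
#'
#' A bout is a class-labeled half-open interval \code{[start_s, end_s)} of
#' seconds-of-day; \code{duration_s = end_s - start_s}, so a 5 s presence
#' run yields a bout of duration 5.
#'
#' @param class Behavior class label(s).
#' @param date Calendar date(s); may be \code{NA}.
#' @param start_s,end_s Integer second-of-day bounds, \code{end_s > start_s}.
#' @return \code{data.frame} with columns
#'   \code{class,date,start_s,end_s,duration_s}, sorted by
#'   (class, date, start_s).
#' @export
bout_table <- function(class = character(), date = as.Date(character()),
                       start_s = integer(), end_s = integer()) {
  b <- data.frame(class = as.character(class), date = as.Date(date),
                  start_s = as.integer(start_s), end_s = as.integer(end_s),
                  stringsAsFactors = FALSE)
  if (nrow(b)) {
    if (!all(b$class %in% behavior_classes()))
      stop("unknown class label in bout table")
    if (any(b$end_s <= b$start_s)) stop("bouts must have end_s > start_s")
    if (any(b$start_s < 0L) || any(b$end_s > DAY_SECONDS))
      stop("bout outside [0, 86400)")
  }
  b$duration_s <- b$end_s - b$start_s
  b <- b[order(b$class, b$date, b$start_s), , drop = FALSE]
  reset_rownames(b)
}

#' Identify behavioral bouts in a presence series
#'
#' Threshold-driven segmentation with temporal hysteresis: a bout of a class
#' opens once the class has been present for at least its onset threshold of
#' consecutive seconds (5 s aggressive, 3 s ear/tail biting by default) and
#' closes after an absence of at least the termination gap (5 s); shorter
#' absences are bridged and their seconds count toward the bout duration,
#' since duration is the difference of the start and end timestamps. Brief
#' isolated runs below the onset threshold produce no bout. A bout still
#' open at the end of the day is truncated there.
#'
#' @param presence Integer/logical vector of per-second presence (any
#'   length; a full day is 86400).
#' @param class_label One of [behavior_classes()]; selects the onset
#'   threshold.
#' @param criteria A [bout_criteria()] object.
#' @param date Calendar date attached to the output rows (may be \code{NA}).
#' @return Bout \code{data.frame}, see [bout_table()]; bouts are disjoint
#'   and sorted by start.
#' @examples
#' p <- integer(86400); p[11:16] <- 1L   # 6 s of aggression
#' find_bouts(p, "aggressive")
#' @export
find_bouts <- function(presence, class_label, criteria = bout_criteria(),
                       date = NA) {
  assert_class_label(class_label)
  stopifnot(inherits(criteria, "bout_criteria"))
  presence <- as.integer(presence != 0)
  m <- scan_bouts(presence, criteria$onset_min_s[[class_label]],
                  criteria$termination_gap_s)
  bout_table(class = rep(class_label, nrow(m)),
             date = rep(as.Date(date), nrow(m)),
             start_s = m[, "start_s"], end_s = m[, "end_s"])
}

#' Reference bout segmentation by run/block enumeration
#'
#' Independent re-implementation of [find_bouts()] used as a test oracle:
#' enumerate maximal presence runs with [rle()]; merge consecutive runs
#' whose separating gap is shorter than the termination gap into blocks;
#' within each block the bout starts at the first second of the earliest run
#' at least as long as the onset threshold and ends one past the block's
#' last present second; blocks with no qualifying run yield no bout.
#'
#' @inheritParams find_bouts
#' @return Bout \code{data.frame} identical to [find_bouts()] output.
#' @export
find_bouts_oracle <- function(presence, class_label,
                              criteria = bout_criteria(), date = NA) {
  assert_class_label(class_label)
  stopifnot(inherits(criteria, "bout_criteria"))
  m <- oracle_scan(as.integer(presence != 0),
                   criteria$onset_min_s[[class_label]],
                   criteria$termination_gap_s)
  bout_table(class = rep(class_label, nrow(m)),
             date = rep(as.Date(date), nrow(m)),
             start_s = m[, "start_s"], end_s = m[, "end_s"])
}

# run/block enumeration core shared with find_bouts_oracle; returns the
# same start/end matrix layout as scan_bouts
oracle_scan <- function(presence, onset, gap_min) {
  r <- rle(presence)
  run_end <- cumsum(r$lengths)                       # 1-based inclusive
  run_start <- run_end - r$lengths + 1L
  on <- which(r$values == 1L)
  empty <- matrix(integer(), 0, 2,
                  dimnames = list(NULL, c("start_s", "end_s")))
  if (!length(on)) return(empty)
  starts <- run_start[on]; ends <- run_end[on]; lens <- r$lengths[on]
  # gaps between consecutive presence runs; >= gap_min starts a new block
  gaps <- if (length(on) > 1L) starts[-1L] - ends[-length(on)] - 1L
          else integer()
  block <- cumsum(c(0L, as.integer(gaps >= gap_min)))
  out_start <- integer(); out_end <- integer()
  for (b in unique(block)) {
    i <- which(block == b)
    q <- i[lens[i] >= onset]
    if (!length(q)) next
    out_start <- c(out_start, starts[q[1L]])
    out_end <- c(out_end, ends[i[length(i)]])
  }
  if (!length(out_start)) return(empty)
  cbind(start_s = out_start - 1L, end_s = out_end)
}

#' Rasterize bouts back into a presence series
#'
#' Inverse-direction helper: marks every second covered by a bout interval.
#' Used for second-level agreement labeling and round-trip tests.
#'
#' @param bouts Bout \code{data.frame} (one class; one date).
#' @param n Series length in seconds, default one day.
#' @return Integer 0/1 vector of length \code{n}.
#' @export
bouts_to_presence <- function(bouts, n = DAY_SECONDS) {
  presence <- integer(n)
  for (i in seq_len(nrow(bouts))) {
    presence[(bouts$start_s[i] + 1L):min(bouts$end_s[i], n)] <- 1L
  }
  presence
}
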