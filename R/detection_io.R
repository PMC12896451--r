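#' Construct a detection table
#'
#' One row per detection of one behavior class in one 1-fps frame. This is
#' the canonical in-memory form of the detector's CSV log: house channel
#' (10 = treatment house, 11 = control house), calendar date, integer
#' second-of-day, class label, confidence, and optionally the bounding box.
#'
#' @param channel Integer house channel.
#' @param date Calendar date (\code{Date} or ISO-8601 string).
#' @param timestamp_s Integer second-of-day in [0, 86399].
#' @param class Behavior class label, see [behavior_classes()].
#' @param confidence Detector confidence in [0, 1].
#' @param x_min,y_min,x_max,y_max Optional pixel box corners (origin
#'   top-left); either all four or none.
#' @return A \code{data.frame} sorted by (date, timestamp_s), one row per
#'   detection.
#' @export
detection_table <- function(channel = integer(), date = as.Date(character()),
                            timestamp_s = integer(), class = character(),
                            confidence = numeric(),
                            x_min = NULL, y_min = NULL, x_max = NULL,
                            y_max = NULL) {
  d <- data.frame(channel = as.integer(channel),
                  date = as.Date(date),
                  timestamp_s = as.integer(timestamp_s),
                  class = as.character(class),
                  confidence = as.numeric(confidence),
                  stringsAsFactors = FALSE)
  has_box <- !is.null(x_min)
  if (has_box) {
    d$x_min <- as.numeric(x_min); d$y_min <- as.numeric(y_min)
    d$x_max <- as.numeric(x_max); d$y_max <- as.numeric(y_max)
  }
  validate_detections(d)
  d[order(d$date, d$timestamp_s), , drop = FALSE] |> reset_rownames()
}

reset_rownames <- function(d) { rownames(d) <- NULL; d }

validate_detections <- function(d, lines = NULL) {
  where <- function(i) {
    if (is.null(lines)) paste0("row ", i) else paste0("line ", lines[i])
  }
  bad <- which(!d$class %in% behavior_classes())
  if (length(bad))
    stop("unknown class label ", dQuote(d$class[bad[1]]), " at ",
         where(bad[1]))
  bad <- which(is.na(d$timestamp_s) | d$timestamp_s < 0L |
                 d$timestamp_s >= DAY_SECONDS)
  if (length(bad))
    stop("timestamp_s out of [0, 86399] at ", where(bad[1]))
  bad <- which(is.na(d$confidence) | d$confidence < 0 | d$confidence > 1)
  if (length(bad))
    stop("confidence outside [0, 1] at ", where(bad[1]))
  if (all(c("x_min", "x_max", "y_min", "y_max") %in% names(d)) &&
      nrow(d)) {
    ok <- is.na(d$x_min) | (d$x_min < d$x_max & d$y_min < d$y_max &
                              d$x_min >= 0 & d$y_min >= 0)
    if (!all(ok)) stop("degenerate bounding box at ", where(which(!ok)[1]))
  }
  invisible(d)
}

DETECTION_COLS <- c("channel", "date", "timestamp_s", "class", "confidence")
BOX_COLS <- c("x_min", "y_min", "x_max", "y_max")

#' Read a detection CSV log
#'
#' Reads the per-detection CSV dialect written by the inference pipeline:
#' header \code{channel,date,timestamp_s,class,confidence} with optional box
#' columns \code{x_min,y_min,x_max,y_max}. Malformed rows raise an error
#' naming the offending file line.
#'
#' @param path Path to a CSV file.
#' @return Detection \code{data.frame} ordered by (date, timestamp_s).
#' @seealso [write_detection_csv()]
#' @export
read_detection_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, colClasses = "character",
                       stringsAsFactors = FALSE)
  if (!all(DETECTION_COLS %in% names(d)))
    stop("bad header in ", path, "; expected columns: ",
         paste(DETECTION_COLS, collapse = ","))
  # file line numbers: +1 for the header
  lines <- seq_len(nrow(d)) + 1L
  out <- data.frame(channel = suppressWarnings(as.integer(d$channel)),
                    date = as.Date(d$date),
                    timestamp_s = suppressWarnings(as.integer(d$timestamp_s)),
                    class = d$class,
                    confidence = suppressWarnings(as.numeric(d$confidence)),
                    stringsAsFactors = FALSE)
  if (all(BOX_COLS %in% names(d)))
    for (cc in BOX_COLS) out[[cc]] <- suppressWarnings(as.numeric(d[[cc]]))
  validate_detections(out, lines = lines)
  out[order(out$date, out$timestamp_s), , drop = FALSE] |> reset_rownames()
}

#' Write a detection table as CSV
#'
#' Rows are written sorted by (date, timestamp_s) so that
#' \code{read_detection_csv(write_detection_csv(x))} reproduces \code{x}.
#'
#' @param records Detection \code{data.frame}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_detection_csv <- function(records, path) {
  validate_detections(records)
  records <- records[order(records$date, records$timestamp_s), , drop = FALSE]
  records$date <- format(as.Date(records$date), "%Y-%m-%d")
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter detections by confidence
#'
#' Keeps detections with confidence at or above \code{tau} (inclusive
#' boundary). The pipeline default, applied before bout identification,
#' is 0.45.
#'
#' @param records Detection \code{data.frame}.
#' @param tau Confidence threshold in [0, 1].
#' @return The subset of \code{records} with \code{confidence >= tau},
#'   original order preserved.
#' @export
filter_by_confidence <- function(records, tau = 0.45) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
      tau < 0 || tau > 1)
    stop("tau must be a single number in [0, 1]")
  records[records$confidence >= tau, , drop = FALSE] |> reset_rownames()
}

#' Rasterize detections into a per-second presence series
#'
#' Collapses detections of one class on one date into a binary vector of
#' length 86400 (1 Hz over a day): \code{presence[t + 1] == 1L} iff at least
#' one detection of \code{class_label} occurred at second-of-day \code{t}.
#' Multiple detections in the same second collapse to a single presence
#' second; detections of other dates or classes are ignored. Records are
#' expected to be confidence-filtered already.
#'
#' @param records Detection \code{data.frame}.
#' @param date Calendar date.
#' @param class_label One of [behavior_classes()].
#' @return Integer vector of length 86400 with values in \{0, 1\}.
#' @export
to_presence_series <- function(records, date, class_label) {
  assert_class_label(class_label)
  date <- as.Date(date)
  presence <- integer(DAY_SECONDS)
  keep <- records$class == class_label & records$date == date
  presence[unique(records$timestamp_s[keep]) + 1L] <- 1L
  presence
}
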