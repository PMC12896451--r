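#' Daily bout summary for one class
#'
#' The three daily outputs of the behavior pipeline: total bout frequency
#' per day, total bout duration (s) per day, and mean duration per bout (s).
#' With zero bouts the mean duration is reported missing (\code{NA}), never
#' zero.
#'
#' @param bouts Bout \code{data.frame}; all rows must share \code{date} and
#'   \code{class} (an empty table is allowed).
#' @param date,class_label The day and class being summarised.
#' @return One-row \code{data.frame}:
#'   \code{date,class,bout_count,total_duration_s,mean_duration_per_bout_s}.
#' @export
summarize_daily <- function(bouts, date, class_label) {
  assert_class_label(class_label)
  date <- as.Date(date)
  if (nrow(bouts)) {
    if (any(bouts$class != class_label))
      stop("bouts of a different class passed to summarize_daily")
    if (any(!is.na(bouts$date) & bouts$date != date))
      stop("bouts of a different date passed to summarize_daily")
  }
  n <- nrow(bouts)
  total <- if (n) sum(bouts$duration_s) else 0L
  data.frame(date = date, class = class_label, bout_count = n,
             total_duration_s = total,
             mean_duration_per_bout_s = if (n) total / n else NA_real_,
             stringsAsFactors = FALSE)
}

#' Daily summaries for all classes and dates in a bout table
#'
#' @param bouts Bout \code{data.frame} (possibly several dates/classes).
#' @param dates Dates to summarise (defaults to those present).
#' @return \code{data.frame}, one row per date x class.
#' @export
summarize_all_daily <- function(bouts, dates = sort(unique(bouts$date))) {
  rows <- list()
  for (d in as.list(as.Date(dates))) for (cl in behavior_classes()) {
    sub <- bouts[!is.na(bouts$date) & bouts$date == d & bouts$class == cl, ,
                 drop = FALSE]
    rows[[length(rows) + 1L]] <- summarize_daily(sub, d, cl)
  }
  reset_rownames(do.call(rbind, c(rows, list(stringsAsFactors = FALSE))))
}

#' Weekly means of the daily behavioral metrics
#'
#' Arithmetic mean over the available days for bout count/day and total
#' duration/day; duration per bout is averaged over the days with at least
#' one bout (a day without bouts carries no duration-per-bout observation).
#' Fewer than 7 days triggers a warning (e.g. a camera gap); missing days
#' are excluded, not imputed.
#'
#' @param dailies Daily-summary \code{data.frame} from [summarize_daily()]
#'   rows of a single class.
#' @param week Optional week index attached to the output.
#' @return One-row \code{data.frame} with the per-class weekly means.
#' @export
weekly_means <- function(dailies, week = NA_integer_) {
  if (!nrow(dailies)) stop("weekly_means needs at least one daily summary")
  if (length(unique(dailies$class)) != 1L)
    stop("weekly_means expects dailies of a single class")
  if (nrow(dailies) < 7L)
    warning("weekly mean over ", nrow(dailies), " day(s), not 7")
  with_bouts <- dailies$bout_count > 0
  data.frame(week = as.integer(week), class = dailies$class[1L],
             mean_count_per_day = mean(dailies$bout_count),
             mean_duration_per_day_s = mean(dailies$total_duration_s),
             mean_duration_per_bout_s = if (any(with_bouts))
               mean(dailies$mean_duration_per_bout_s[with_bouts])
             else NA_real_,
             n_days = nrow(dailies), stringsAsFactors = FALSE)
}

#' Average daily gain
#'
#' Body-weight gain divided by the number of days in the interval
#' (kg/day); weights are pen or pig means recorded weekly.
#'
#' @param bw_start_kg,bw_end_kg Body weight (kg) at interval start and end.
#' @param days Interval length in days (default one week).
#' @return ADG in kg/day.
#' @examples
#' compute_adg(16.70, 23.47)   # 0.967 kg/d
#' @export
compute_adg <- function(bw_start_kg, bw_end_kg, days = 7L) {
  if (any(days < 1)) stop("days must be >= 1")
  if (any(bw_start_kg <= 0) || any(bw_end_kg <= 0))
    stop("body weights must be positive")
  (bw_end_kg - bw_start_kg) / days
}

#' Feed conversion ratio
#'
#' ADFI / ADG on an as-fed basis. For enriched pens, hay consumed is added
#' to the feed intake with no dry-matter or nutrient-density correction.
#' A non-positive ADG makes the ratio undefined and returns \code{NA} with
#' a warning rather than a silent infinity.
#'
#' @param adfi_kg Average daily feed intake (kg/day, hay-inclusive where
#'   applicable).
#' @param adg_kg Average daily gain (kg/day).
#' @return FCR (dimensionless), \code{NA} where \code{adg_kg <= 0}.
#' @export
compute_fcr <- function(adfi_kg, adg_kg) {
  out <- adfi_kg / adg_kg
  bad <- adg_kg <= 0
  if (any(bad)) {
    warning("FCR undefined for non-positive ADG; returning NA")
    out[bad] <- NA_real_
  }
  out
}

#' Pen-level mean of per-pig welfare scores
#'
#' Lesion and fecal scores are ordinal; pigs are averaged within pen and
#' the pen mean is the experimental unit.
#'
#' @param per_pig_scores Numeric scores.
#' @param scale_max Upper bound of the scoring scale (3 for ear lesions and
#'   fecal score, 4 for tail lesions); scores must lie in [0, scale_max].
#' @return Arithmetic mean.
#' @export
pen_mean_score <- function(per_pig_scores, scale_max = 3) {
  if (!length(per_pig_scores)) stop("no scores supplied")
  if (any(is.na(per_pig_scores)) || any(per_pig_scores < 0) ||
      any(per_pig_scores > scale_max))
    stop("scores must lie in [0, ", scale_max, "]")
  mean(per_pig_scores)
}

#' Per-pig ear lesion score
#'
#' Mean of the left- and right-ear lesion scores (0-3 scale: 0 none to
#' 3 partial/total ear loss).
#'
#' @param left,right Per-ear scores in [0, 3].
#' @return Mean score in [0, 3].
#' @export
ear_pig_score <- function(left, right) {
  if (any(c(left, right) < 0) || any(c(left, right) > 3))
    stop("ear scores must lie in [0, 3]")
  (left + right) / 2
}
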