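#' Pearson correlation between paired measurements
#'
#' Thin, validating wrapper around the sample correlation used for
#' AI-versus-manual comparison of daily behavioral metrics. Constant input
#' is an error (the correlation is undefined), not a silent \code{NA}.
#'
#' @param x,y Equal-length numeric vectors, length >= 2.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must be paired with length >= 2")
  if (anyNA(x) || anyNA(y)) stop("missing values in paired measurements")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  stats::cor(x, y)
}

#' Absolute-agreement intraclass correlation, single measures
#'
#' ICC(A,1) in the McGraw-Wong convention: a two-way random-effects model
#' with absolute agreement, single rater, here with k = 2 raters (AI and
#' manual). Computed from the two-way ANOVA mean squares
#' \deqn{ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))}
#' where MSR, MSC, MSE are the row (subject), column (rater) and residual
#' mean squares. Unlike Pearson r it penalizes systematic offsets between
#' raters. The returned value is clipped to [-1, 1].
#'
#' @param x,y Paired measurements of the two raters, length n >= 2.
#' @return ICC(A,1) in [-1, 1].
#' @export
icc_2_1 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must be paired with length >= 2")
  if (anyNA(x) || anyNA(y)) stop("missing values in paired measurements")
  n <- length(x); k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  if (sum((m - grand)^2) == 0)
    stop("ICC undefined: zero total variance")
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  # residual: m_ij - rowmean_i - colmean_j + grand
  sse <- sum((sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  min(1, max(-1, icc))
}

#' Cohen's kappa for paired categorical labels
#'
#' Chance-corrected agreement \eqn{\kappa = (P_o - P_e)/(1 - P_e)} with
#' expected agreement from the product of the two marginal distributions.
#' Used here on per-second binary presence labels from [align_bouts()].
#' The degenerate case of perfect agreement on a single category
#' (\eqn{P_o = P_e = 1}) returns 1.
#'
#' @param labels_a,labels_b Equal-length vectors of categorical labels.
#' @return Kappa in [-1, 1].
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b) || !length(labels_a))
    stop("label sequences must be paired and non-empty")
  n <- length(labels_a)
  lev <- union(unique(labels_a), unique(labels_b))
  pa <- table(factor(labels_a, levels = lev)) / n
  pb <- table(factor(labels_b, levels = lev)) / n
  po <- mean(labels_a == labels_b)
  pe <- sum(pa * pb)
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Align AI and manual bouts of one class
#'
#' Produces the two ingredients of the agreement analysis: (a) per-second
#' binary presence labels for both sources over the analysis window and
#' (b) matched event pairs by temporal overlap — each AI bout is paired
#' with the manual bout it overlaps most (greedy on overlap, descending;
#' each bout matched at most once; zero overlap never matches).
#'
#' @param manual,ai Bout \code{data.frame}s of the same class (and date).
#' @param class_label Class to align.
#' @param n Window length in seconds (default one day).
#' @return List: \code{labels} (\code{data.frame} with per-second 0/1
#'   columns \code{manual} and \code{ai}) and \code{pairs}
#'   (\code{data.frame} \code{ai_row,manual_row,overlap_s}).
#' @export
align_bouts <- function(manual, ai, class_label, n = DAY_SECONDS) {
  assert_class_label(class_label)
  manual <- manual[manual$class == class_label, , drop = FALSE]
  ai <- ai[ai$class == class_label, , drop = FALSE]
  labels <- data.frame(manual = bouts_to_presence(manual, n),
                       ai = bouts_to_presence(ai, n))
  ov <- matrix(0, nrow(ai), nrow(manual))
  for (i in seq_len(nrow(ai))) for (j in seq_len(nrow(manual)))
    ov[i, j] <- max(0, min(ai$end_s[i], manual$end_s[j]) -
                      max(ai$start_s[i], manual$start_s[j]))
  pairs <- data.frame(ai_row = integer(), manual_row = integer(),
                      overlap_s = integer())
  while (length(ov) && any(ov > 0)) {
    idx <- arrayInd(which.max(ov), dim(ov))
    pairs <- rbind(pairs, data.frame(ai_row = idx[1], manual_row = idx[2],
                                     overlap_s = as.integer(ov[idx])))
    ov[idx[1], ] <- 0; ov[, idx[2]] <- 0
  }
  list(labels = labels, pairs = reset_rownames(pairs))
}

#' AI-versus-manual agreement report
#'
#' For each behavior class, pairs the daily metrics (event count, total
#' duration, duration per bout) of the two sources across days and reports
#' Pearson r and ICC(A,1) per metric, plus Cohen's kappa computed on the
#' pooled per-second presence labels of the class (the kappa column is a
#' class-level statistic repeated across the class's metric rows).
#' Metrics with fewer than two valid paired units are reported missing
#' with a warning, as are degenerate (constant) pairings.
#'
#' @param manual,ai Bout \code{data.frame}s spanning one or more dates.
#' @param dates Days forming the paired units (default: union of dates
#'   present in either source).
#' @return \code{data.frame}: \code{class,metric,r,icc,kappa,n_units}.
#' @export
agreement_report <- function(manual, ai,
                             dates = sort(unique(c(manual$date, ai$date)))) {
  dates <- as.Date(dates, origin = "1970-01-01")
  metrics <- c("event_count", "total_duration", "duration_per_bout")
  safe <- function(f, x, y) tryCatch(f(x, y), error = function(e) {
    warning(conditionMessage(e)); NA_real_
  })
  out <- list()
  for (cl in behavior_classes()) {
    sm <- do.call(rbind, lapply(as.list(dates), function(d)
      summarize_daily(manual[manual$class == cl & manual$date == d, ,
                             drop = FALSE], d, cl)))
    sa <- do.call(rbind, lapply(as.list(dates), function(d)
      summarize_daily(ai[ai$class == cl & ai$date == d, , drop = FALSE],
                      d, cl)))
    lab_m <- integer(); lab_a <- integer()
    for (d in as.list(dates)) {
      al <- align_bouts(manual[manual$date == d, , drop = FALSE],
                        ai[ai$date == d, , drop = FALSE], cl)
      lab_m <- c(lab_m, al$labels$manual); lab_a <- c(lab_a, al$labels$ai)
    }
    kap <- if (length(lab_m)) cohen_kappa(lab_m, lab_a) else NA_real_
    vals <- list(event_count = cbind(sm$bout_count, sa$bout_count),
                 total_duration = cbind(sm$total_duration_s,
                                        sa$total_duration_s),
                 duration_per_bout = cbind(sm$mean_duration_per_bout_s,
                                           sa$mean_duration_per_bout_s))
    for (met in metrics) {
      v <- vals[[met]]
      v <- v[stats::complete.cases(v), , drop = FALSE]
      n_units <- nrow(v)
      if (n_units < 2L) {
        warning("fewer than 2 paired units for ", cl, " / ", met)
        r <- icc <- NA_real_
      } else {
        r <- safe(pearson_r, v[, 1], v[, 2])
        icc <- safe(icc_2_1, v[, 1], v[, 2])
      }
      out[[length(out) + 1L]] <- data.frame(
        class = cl, metric = met, r = r, icc = icc, kappa = kap,
        n_units = n_units, stringsAsFactors = FALSE)
    }
  }
  reset_rownames(do.call(rbind, out))
}
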