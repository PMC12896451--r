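#' Image-dataset bookkeeping
#'
#' Totals and percentages for a train/validation/test split with
#' augmentation applied to the training subset only: the percentage of raw
#' data per subset, the images used per subset (raw + augmented), and the
#' grand totals.
#'
#' @param raw Named integer vector of raw image counts per subset, e.g.
#'   \code{c(training = 1668, validation = 446, test = 231)}.
#' @param augmented Named integer vector of augmented images per subset
#'   (zero where augmentation was not applied).
#' @return \code{data.frame} with one row per subset plus a \code{"total"}
#'   row: raw count, percent of raw (rounded to whole percent, as reported),
#'   images used, percent of images used.
#' @export
dataset_split_summary <- function(raw, augmented = stats::setNames(
                                    rep(0L, length(raw)), names(raw))) {
  stopifnot(length(raw) == length(augmented),
            all(names(raw) == names(augmented)))
  used <- raw + augmented
  d <- data.frame(subset = c(names(raw), "total"),
                  raw_images = c(raw, sum(raw)),
                  pct_raw = round(100 * c(raw, sum(raw)) / sum(raw)),
                  augmented_images = c(augmented, sum(augmented)),
                  images_used = c(used, sum(used)),
                  pct_used = round(100 * c(used, sum(used)) / sum(used)),
                  stringsAsFactors = FALSE)
  reset_rownames(d)
}

#' Pen geometry
#'
#' Floor area (m^2) of a rectangular pen and the initial stocking density
#' implied by the animals housed in it.
#'
#' @param length_m,width_m Pen sides in metres.
#' @return Area in m^2.
#' @examples
#' pen_area(2.35, 2.9)   # 6.815 m^2
#' @export
pen_area <- function(length_m, width_m) {
  if (any(length_m <= 0) || any(width_m <= 0)) stop("sides must be positive")
  length_m * width_m
}

#' @rdname pen_area
#' @param n_pigs Pigs per pen.
#' @param mean_bw_kg Mean body weight (kg).
#' @param area_m2 Pen area (m^2).
#' @return Stocking density in kg/m^2.
#' @export
stocking_density <- function(n_pigs, mean_bw_kg, area_m2) {
  n_pigs * mean_bw_kg / area_m2
}
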