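#' Behavior classes of the agonistic ethogram
#'
#' The pipeline recognises three classes of agonistic behavior in weaned
#' pigs: \code{"aggressive"} (head/body knocking, chasing, mounting),
#' \code{"ear_biting"} and \code{"tail_biting"}.
#'
#' @return Character vector of the three class labels.
#' @export
behavior_classes <- function() {
  c("aggressive", "ear_biting", "tail_biting")
}

#' Temporal bout criteria
#'
#' A bout of a behavior class opens once the class has been detected for at
#' least \code{onset_min_s} consecutive seconds and closes after the class
#' has been absent for at least \code{termination_gap_s} seconds. Defaults
#' follow the ethogram used for nursery pigs: 5 s onset for aggression, 3 s
#' for ear and tail biting, 5 s termination gap for all classes.
#'
#' @param onset_min_s Named integer vector of minimum consecutive presence
#'   seconds per class.
#' @param termination_gap_s Integer, minimum absence (seconds) that closes an
#'   open bout; gaps shorter than this are bridged.
#' @return A list of class \code{bout_criteria}.
#' @examples
#' bout_criteria()
#' bout_criteria(onset_min_s = c(aggressive = 1, ear_biting = 1, tail_biting = 1),
#'               termination_gap_s = 1)
#' @export
bout_criteria <- function(onset_min_s = c(aggressive = 5L,
                                          ear_biting = 3L,
                                          tail_biting = 3L),
                          termination_gap_s = 5L) {
  onset_min_s <- vapply(onset_min_s, as.integer, integer(1))
  termination_gap_s <- as.integer(termination_gap_s)
  if (!all(behavior_classes() %in% names(onset_min_s)))
    stop("onset_min_s must be named with all of: ",
         paste(behavior_classes(), collapse = ", "))
  if (any(onset_min_s < 1L)) stop("onset_min_s must be >= 1")
  if (termination_gap_s < 1L) stop("termination_gap_s must be >= 1")
  structure(list(onset_min_s = onset_min_s[behavior_classes()],
                 termination_gap_s = termination_gap_s),
            class = "bout_criteria")
}

#' Seconds in one recording day at 1 frame per second
#' @keywords internal
DAY_SECONDS <- 86400L

# internal: validate a class label argument
assert_class_label <- function(class_label) {
  if (length(class_label) != 1L || !class_label %in% behavior_classes())
    stop("class_label must be one of: ",
         paste(behavior_classes(), collapse = ", "))
  class_label
}
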