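#' Validate staining readings
#'
#' Intensity must be an integer grade 0--3 (0 no staining, 1+ weak, 2+
#' moderate, 3+ strong); percent positive must lie in 0-100.
#'
#' @param intensity integer vector of staining grades.
#' @param percent numeric vector of percent positive tumor cells.
#' @return invisibly `TRUE`; stops with the offending field named otherwise.
#' @keywords internal
validate_stain <- function(intensity, percent) {
  if (length(intensity) != length(percent)) {
    stop("intensity and percent must have equal length", call. = FALSE)
  }
  bad_i <- !is.na(intensity) &
    (intensity != round(intensity) | intensity < 0 | intensity > 3)
  if (any(bad_i)) {
    stop(sprintf("intensity out of range (must be an integer in 0..3): %s",
                 paste(utils::head(intensity[bad_i], 5), collapse = ", ")),
         call. = FALSE)
  }
  bad_p <- !is.na(percent) & (percent < 0 | percent > 100)
  if (any(bad_p)) {
    stop(sprintf("percent_positive out of range (must be in [0,100]): %s",
                 paste(utils::head(percent[bad_p], 5), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Quickscore (Q score) of an immunohistochemical reading
#'
#' The quickscore multiplies the percentage P of tumor cells showing
#' characteristic staining (0--100) by the staining intensity grade I
#' (0--3): Q = P x I, maximum 300.  A zero intensity or zero percent gives
#' Q = 0 regardless of the other reading.
#'
#' @param intensity integer vector, staining intensity grade in 0..3.
#' @param percent numeric vector, percent positive tumor cells in 0-100.
#' @return numeric vector of Q scores in 0-300.
#' @examples
#' quickscore(3, 100)  # 300, the maximum
#' quickscore(2, 40)   # 80
#' quickscore(0, 85)   # 0
#' @export
quickscore <- function(intensity, percent) {
  validate_stain(intensity, percent)
  as.numeric(percent) * as.numeric(intensity)
}

#' Single-marker positivity rule for mutation-specific antibodies
#'
#' The conventional read-out for the mutation-specific antibodies calls a
#' tumor positive when more than `min_percent` percent of tumor cells stain
#' at intensity `min_intensity` or above (default: more than 10% of cells
#' at 1+ or more).  The percent comparison is strict ("more than"); the
#' intensity comparison is inclusive.
#'
#' @inheritParams quickscore
#' @param min_intensity minimum intensity grade counted as staining
#'   (default 1).
#' @param min_percent percent positivity that must be exceeded (default 10).
#' @return logical vector of positivity calls.
#' @examples
#' intensity_positive(1, 15)   # TRUE
#' intensity_positive(3, 10)   # FALSE: exactly 10% does not exceed 10%
#' intensity_positive(0, 100)  # FALSE: below the intensity floor
#' @export
intensity_positive <- function(intensity, percent,
                               min_intensity = 1, min_percent = 10) {
  validate_stain(intensity, percent)
  intensity >= min_intensity & percent > min_percent
}

#' Pan-cytokeratin quality gate
#'
#' Pan-cytokeratin staining confirms the reactivity of a tissue section for
#' immunohistochemistry.  Samples whose pan-cytokeratin control shows no
#' staining at all (intensity 0) are considered uninterpretable and are
#' excluded from analysis.
#'
#' @param intensity integer vector of pan-cytokeratin intensity grades.
#' @return logical vector: `TRUE` where the sample passes the gate.
#' @export
panck_valid <- function(intensity) {
  validate_stain(intensity, rep(0, length(intensity)))
  !is.na(intensity) & intensity > 0
}
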