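COHORT_HEADER <- "# stainclass cohort v1"

stain_markers <- c("l858r", "del19", "total_egfr", "panck")

stain_columns <- function() {
  as.vector(t(outer(stain_markers, c("_intensity", "_percent"), paste0)))
}

#' Read and validate a cohort table
#'
#' Reads a tab-separated cohort file (one row per tumor; `#` lines are
#' comments), validates the staining columns, applies the tumor-content
#' enrollment gate and the pan-cytokeratin reactivity gate, and reports the
#' exclusions.  Sections whose tumor content falls below
#' `tumor_content_min` percent are excluded from analysis, as are samples
#' whose pan-cytokeratin control shows no staining.
#'
#' @param path path to a cohort TSV, see [write_cohort()] for the layout.
#' @param tumor_content_min minimum percent tumor cells for enrollment
#'   (default 60).
#' @return the enrolled cohort data.frame; `attr(, "exclusions")` is a list
#'   with `n_input`, `n_low_content`, `n_panck_invalid`, `n_retained`.
#' @export
read_cohort <- function(path, tumor_content_min = 60) {
  if (!file.size(path) > 0) {
    stop("empty cohort file: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0) stop("cohort file has a header but no rows: ", path,
                           call. = FALSE)
  validate_cohort(raw)
  low <- !is.na(raw$tumor_content) & raw$tumor_content < tumor_content_min
  panck_bad <- !panck_valid(raw$panck_intensity)
  keep <- !low & !panck_bad
  out <- raw[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- list(n_input = nrow(raw),
                                  n_low_content = sum(low),
                                  n_panck_invalid = sum(panck_bad & !low),
                                  n_retained = nrow(out))
  out
}

#' Validate a cohort data.frame
#'
#' Checks the required columns, uniqueness of patient ids, staining
#' invariants (integer intensities 0-3, percents in 0-100) and that every
#' genotype parses against the controlled vocabulary.  Failures name the
#' offending rows.
#'
#' @param cohort a cohort data.frame.
#' @return invisibly `TRUE`.
#' @export
validate_cohort <- function(cohort) {
  required <- c("patient_id", "genotype", "tumor_content", stain_columns())
  missing <- setdiff(required, names(cohort))
  if (length(missing) > 0) {
    stop("malformed cohort header; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cohort$patient_id)) {
    dup <- unique(cohort$patient_id[duplicated(cohort$patient_id)])
    stop("duplicate patient id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  for (m in stain_markers) {
    icol <- cohort[[paste0(m, "_intensity")]]
    pcol <- cohort[[paste0(m, "_percent")]]
    if (!is.numeric(icol) || !is.numeric(pcol)) {
      stop(sprintf("non-numeric stain values in %s columns", m), call. = FALSE)
    }
    bad <- which(is.na(icol) | icol != round(icol) | icol < 0 | icol > 3 |
                   is.na(pcol) | pcol < 0 | pcol > 100)
    if (length(bad) > 0) {
      stop(sprintf("invalid %s staining values in row(s): %s", m,
                   paste(utils::head(bad, 10), collapse = ", ")),
           call. = FALSE)
    }
  }
  parse_genotype(cohort$genotype)
  invisible(TRUE)
}

#' Write a cohort table
#'
#' Writes the cohort as UTF-8 tab-separated text with a versioned comment
#' header, normalized column order and empty strings for missing values, the
#' format read back by [read_cohort()].
#'
#' @param cohort a cohort data.frame.
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_cohort <- function(cohort, path) {
  lead <- c("patient_id", "genotype", "sex", "smoking", "tumor_content",
            stain_columns())
  rest <- setdiff(names(cohort), lead)
  cols <- c(intersect(lead, names(cohort)), sort(rest))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(COHORT_HEADER, con)
  utils::write.table(cohort[, cols, drop = FALSE], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
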