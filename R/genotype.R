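#' Controlled vocabulary of EGFR genotype components
#'
#' Each sequencing call is written as one or more component tokens joined by
#' `+` (complex mutations carry two or more concomitant components, e.g.
#' `"L858R+V834L"`).  Every token belongs to one class:
#' \describe{
#'   \item{`l858r`}{the exon-21 L858R point mutation}
#'   \item{`del19_e746a750`}{the E746-A750 in-frame deletion in exon 19}
#'   \item{`del19_other`}{any other in-frame exon-19 deletion}
#'   \item{`other`}{any other mutation (exon 18/20/21 points, insertions)}
#'   \item{`wild`}{wild type; cannot be combined with other tokens}
#' }
#'
#' @param extra a data.frame with columns `token` and `class` to extend the
#'   vocabulary, or `NULL`.
#' @return data.frame with columns `token` and `class`.
#' @export
genotype_vocabulary <- function(extra = NULL) {
  vocab <- data.frame(
    token = c("wild",
              "L858R",
              "delE746-A750",
              "delL747-T751", "delL747-P753", "delE746-T751insQ",
              "V834L", "E709V", "T790M", "K757N",
              "L861Q", "E709K", "G719A", "G719S",
              "N771-H773dupNPH", "K860I", "L861R", "R831C",
              "delE709-T710insD"),
    class = c("wild",
              "l858r",
              "del19_e746a750",
              "del19_other", "del19_other", "del19_other",
              "other", "other", "other", "other",
              "other", "other", "other", "other",
              "other", "other", "other", "other",
              "other"),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    stopifnot(is.data.frame(extra), all(c("token", "class") %in% names(extra)))
    vocab <- rbind(vocab, extra[, c("token", "class")])
  }
  vocab
}

#' Parse sequencing genotype strings into mutation labels
#'
#' Decomposes each genotype string into its `+`-joined components, checks
#' them against the controlled vocabulary, and derives the label set used
#' throughout the pipeline.  A complex mutation has two or more components;
#' it shows a *classical pattern* when at least one component is L858R or an
#' exon-19 deletion.  Label implications hold by construction:
#' `is_E746A750` implies `is_del19` implies `is_any_mutation`.
#'
#' @param genotype character vector of sequencing calls.
#' @param vocabulary token table, see [genotype_vocabulary()].
#' @return data.frame with one row per input and logical columns
#'   `is_L858R`, `is_E746A750`, `is_del19`, `is_any_mutation`,
#'   `is_complex`, `is_classical_pattern`.
#' @examples
#' parse_genotype(c("L858R+V834L", "wild", "delE746-A750"))
#' @export
parse_genotype <- function(genotype, vocabulary = genotype_vocabulary()) {
  stopifnot(is.character(genotype) | is.factor(genotype))
  genotype <- as.character(genotype)
  parts <- strsplit(genotype, "+", fixed = TRUE)
  all_tokens <- unique(unlist(parts))
  unknown <- setdiff(all_tokens, vocabulary$token)
  if (length(unknown) > 0) {
    stop(sprintf(
      "unknown genotype component(s): %s\nvalid tokens: %s",
      paste(unknown, collapse = ", "),
      paste(vocabulary$token, collapse = ", ")), call. = FALSE)
  }
  cls <- function(tok) vocabulary$class[match(tok, vocabulary$token)]
  one <- function(tok) {
    k <- cls(tok)
    if ("wild" %in% k && length(tok) > 1) {
      stop("'wild' cannot be combined with mutation components", call. = FALSE)
    }
    is_l858r <- any(k == "l858r")
    is_e746 <- any(k == "del19_e746a750")
    is_del19 <- is_e746 || any(k == "del19_other")
    is_mut <- any(k != "wild")
    is_complex <- is_mut && length(tok) >= 2
    c(is_L858R = is_l858r,
      is_E746A750 = is_e746,
      is_del19 = is_del19,
      is_any_mutation = is_mut,
      is_complex = is_complex,
      is_classical_pattern = is_complex && (is_l858r || is_del19))
  }
  out <- as.data.frame(t(vapply(parts, one, logical(6))))
  rownames(out) <- NULL
  out
}
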