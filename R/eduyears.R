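#' Recode qualifications to years of education
#'
#' Maps highest-qualification categories to a years-of-education phenotype.
#' Non-vocational categories take their value from a supplied mapping table
#' (the ISCED-style category-to-years table is survey-specific, so it is
#' injected rather than hard-coded). Holders of vocational-only qualifications
#' are coded as the age they reported leaving full-time education minus five;
#' vocational records reporting an age below 12 are dropped.
#'
#' @param qualification character vector of highest-qualification categories.
#' @param age_left_fte numeric vector, age at leaving full-time education
#'   (only used for vocational records; may be `NA` elsewhere).
#' @param mapping named numeric vector giving years of education for each
#'   non-vocational category.
#' @param vocational category label identifying vocational-only records.
#' @return Numeric vector of years of education; dropped records are `NA`.
#' @examples
#' recode_eduyears(c("degree", "vocational", "vocational"),
#'                 c(NA, 16, 11), mapping = c(degree = 20))
#' @export
recode_eduyears <- function(qualification, age_left_fte,
                            mapping, vocational = "vocational") {
  stopifnot(length(qualification) == length(age_left_fte),
            is.numeric(mapping), !is.null(names(mapping)))
  qualification <- as.character(qualification)
  known <- c(names(mapping), vocational)
  bad <- setdiff(unique(qualification), known)
  if (length(bad)) {
    stop("unknown qualification categories: ", paste(bad, collapse = ", "))
  }
  out <- unname(mapping[qualification])
  voc <- qualification == vocational
  out[voc] <- age_left_fte[voc] - 5
  out[voc & (is.na(age_left_fte) | age_left_fte < 12)] <- NA_real_
  out
}
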