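# Views of a simulated cohort as the input tables of the family and
# assortative-mating analyses.

pgi_by_id <- function(cohort, pgi = NULL) {
  if (is.null(pgi)) {
    stats::setNames(cohort$ped$gv_add, cohort$ped$id)
  } else {
    stopifnot(!is.null(names(pgi)))
    pgi
  }
}

#' Parent-offspring trios of a cohort
#'
#' One row per non-founder individual whose two parents are genotyped, with
#' the three PGIs standardized to the phenotyped sample.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param pgi named PGI vector by individual id; defaults to the true additive
#'   genetic value.
#' @param generation restrict to children of this generation (default: last).
#' @return Data frame `y`, `pgi_child`, `pgi_father`, `pgi_mother`,
#'   `family_id`.
#' @export
cohort_trios <- function(cohort, pgi = NULL, generation = NULL) {
  ped <- cohort$ped
  g <- generation %||% max(ped$generation)
  kids <- ped[ped$generation == g & !is.na(ped$father_id), , drop = FALSE]
  p <- pgi_by_id(cohort, pgi)
  sdp <- stats::sd(p); mup <- mean(p)
  data.frame(y = kids$y,
             pgi_child = (p[kids$id] - mup) / sdp,
             pgi_father = (p[kids$father_id] - mup) / sdp,
             pgi_mother = (p[kids$mother_id] - mup) / sdp,
             family_id = kids$sibship_id,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Genotyped sibling sets of a cohort
#'
#' @inheritParams cohort_trios
#' @return Data frame `y`, `pgi`, `sibship_id` for individuals in sibships of
#'   size >= 2 in the chosen generation.
#' @export
cohort_sibs <- function(cohort, pgi = NULL, generation = NULL) {
  ped <- cohort$ped
  g <- generation %||% max(ped$generation)
  kids <- ped[ped$generation == g & !is.na(ped$sibship_id), , drop = FALSE]
  size <- stats::ave(rep(1, nrow(kids)), kids$sibship_id, FUN = sum)
  kids <- kids[size >= 2, , drop = FALSE]
  p <- pgi_by_id(cohort, pgi)
  data.frame(y = kids$y, pgi = (p[kids$id] - mean(p)) / stats::sd(p),
             sibship_id = kids$sibship_id,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mate pairs of a cohort
#'
#' @inheritParams cohort_trios
#' @param generation restrict to couples whose partners belong to this
#'   generation (default: all couples).
#' @return Data frame `pgi_m`, `pgi_f`, `y_m`, `y_f` (one row per couple)
#'   plus any requested covariate columns copied per partner.
#' @param covariate_cols columns of `ped` to copy as `<col>_m` / `<col>_f`.
#' @export
cohort_mate_pairs <- function(cohort, pgi = NULL, generation = NULL,
                              covariate_cols = character(0)) {
  mp <- cohort$mate_pairs
  if (!is.null(generation)) mp <- mp[mp$generation == generation, ,
                                     drop = FALSE]
  ped <- cohort$ped
  im <- match(mp$id_m, ped$id); fi <- match(mp$id_f, ped$id)
  p <- pgi_by_id(cohort, pgi)
  ps <- (p - mean(p)) / stats::sd(p)
  out <- data.frame(pgi_m = ps[mp$id_m], pgi_f = ps[mp$id_f],
                    y_m = ped$y[im], y_f = ped$y[fi],
                    row.names = NULL, stringsAsFactors = FALSE)
  for (col in covariate_cols) {
    out[[paste0(col, "_m")]] <- ped[[col]][im]
    out[[paste0(col, "_f")]] <- ped[[col]][fi]
  }
  out
}
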