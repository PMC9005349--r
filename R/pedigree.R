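#' Pedigree inbreeding coefficients by recursive kinship
#'
#' Computes each individual's inbreeding coefficient `F` as the kinship
#' coefficient between its parents, using the standard recursive kinship
#' algebra (founders are unrelated and non-inbred; unknown parents are treated
#' as unrelated founders).
#'
#' @param ped data frame with columns `id`, `father_id`, `mother_id`
#'   (`NA` for unknown/founder parents).
#' @return Numeric vector of inbreeding coefficients, one per row of `ped`,
#'   named by `id`. Offspring of first cousins get 1/16, of full siblings 1/4.
#' @examples
#' ped <- data.frame(id = c("a", "b", "c", "d", "e"),
#'                   father_id = c(NA, NA, "a", "a", "c"),
#'                   mother_id = c(NA, NA, "b", "b", "d"))
#' pedigree_inbreeding(ped)["e"]  # offspring of full sibs: 0.25
#' @export
pedigree_inbreeding <- function(ped) {
  stopifnot(all(c("id", "father_id", "mother_id") %in% names(ped)))
  ids <- as.character(ped$id)
  if (anyDuplicated(ids)) stop("duplicate ids in pedigree")
  fa <- as.character(ped$father_id)
  mo <- as.character(ped$mother_id)
  idx <- stats::setNames(seq_along(ids), ids)
  fa_i <- ifelse(is.na(fa), NA_integer_, idx[fa])
  mo_i <- ifelse(is.na(mo), NA_integer_, idx[mo])
  if (any(!is.na(fa) & is.na(fa_i)) || any(!is.na(mo) & is.na(mo_i))) {
    stop("pedigree refers to parents absent from the id column")
  }

  # topological depth; cycle detection (an individual cannot be its own
  # ancestor)
  n <- length(ids)
  depth <- rep(NA_integer_, n)
  visiting <- rep(FALSE, n)
  get_depth <- function(i) {
    if (!is.na(depth[i])) return(depth[i])
    if (visiting[i]) stop("pedigree cycle: individual '", ids[i],
                          "' is its own ancestor")
    visiting[i] <<- TRUE
    d <- 0L
    if (!is.na(fa_i[i])) d <- max(d, get_depth(fa_i[i]) + 1L)
    if (!is.na(mo_i[i])) d <- max(d, get_depth(mo_i[i]) + 1L)
    visiting[i] <<- FALSE
    depth[i] <<- d
    d
  }
  for (i in seq_len(n)) get_depth(i)

  memo <- new.env(parent = emptyenv())
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- if (i <= j) paste0(i, ":", j) else paste0(j, ":", i)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      0.5 * (1 + phi(fa_i[i], mo_i[i]))
    } else {
      # recurse on the deeper individual so the recursion terminates at
      # founders
      if (depth[i] >= depth[j]) {
        if (depth[i] == 0L) 0 else 0.5 * (phi(fa_i[i], j) + phi(mo_i[i], j))
      } else {
        0.5 * (phi(fa_i[j], i) + phi(mo_i[j], i))
      }
    }
    memo[[key]] <- val
    val
  }

  out <- vapply(seq_len(n), function(i) phi(fa_i[i], mo_i[i]), numeric(1))
  stats::setNames(out, ids)
}
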