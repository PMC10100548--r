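#' Industry classification hierarchy
#'
#' A two-level industry hierarchy in the style of the NAICS coding system:
#' broad 2-digit-style "sectors", each containing one or more 3-digit-style
#' "subsectors". The hurdle model uses the subsector as the grouping level of
#' its random intercepts and the sector as the parent level of partial
#' pooling.
#'
#' @param sector_of Named character vector mapping each subsector code to its
#'   sector code. Names are subsector codes; values are sector codes.
#' @return An object of class `hierarchy_index` with elements
#'   `subsector_ids`, `sector_ids`, `sector_of` (named character vector),
#'   `n_subsectors` and `n_sectors`.
#' @export
hierarchy_index <- function(sector_of) {
  if (is.null(names(sector_of)) || anyNA(sector_of) || anyNA(names(sector_of))) {
    abort("`sector_of` must be a named character vector (subsector -> sector)")
  }
  sector_of <- vapply(sector_of, as.character, character(1))
  if (anyDuplicated(names(sector_of))) {
    abort("each subsector must map to exactly one sector")
  }
  out <- list(
    subsector_ids = names(sector_of),
    sector_ids = unique(unname(sector_of)),
    sector_of = sector_of,
    n_subsectors = length(sector_of),
    n_sectors = length(unique(unname(sector_of)))
  )
  if (out$n_sectors < 1L) abort("hierarchy must contain at least one sector")
  structure(out, class = "hierarchy_index")
}

#' @export
print.hierarchy_index <- function(x, ...) {
  cat("<hierarchy_index>", x$n_subsectors, "subsectors in", x$n_sectors,
      "sectors\n")
  invisible(x)
}

#' Generate a synthetic two-level industry hierarchy
#'
#' Builds NAICS-like codes: sectors are 2-digit codes starting at "11" and
#' subsectors append a 2-digit suffix (sector "11" owns "1101", "1102", ...).
#' Construction is deterministic; the seed argument is accepted for interface
#' uniformity with the other generators.
#'
#' @param n_sectors Number of sectors (>= 1).
#' @param subsectors_per_sector Either a single count applied to every sector
#'   or a vector of per-sector counts (each >= 1).
#' @param seed Integer seed (unused; the construction is deterministic).
#' @return A [hierarchy_index()].
#' @examples
#' h <- generate_hierarchy(2, 3)
#' h$n_subsectors # 6
#' @export
generate_hierarchy <- function(n_sectors, subsectors_per_sector, seed = NULL) {
  if (!is_count(n_sectors) || n_sectors < 1) {
    abort("`n_sectors` must be a positive integer")
  }
  m <- subsectors_per_sector
  if (length(m) == 1L) m <- rep(m, n_sectors)
  if (length(m) != n_sectors || !all(vapply(m, is_count, logical(1))) ||
      any(m < 1)) {
    abort("`subsectors_per_sector` must give each sector at least one subsector")
  }
  sectors <- sprintf("%02d", 10L + seq_len(n_sectors))
  sub <- unlist(lapply(seq_len(n_sectors), function(k) {
    codes <- sprintf("%s%02d", sectors[k], seq_len(m[k]))
    stats::setNames(rep(sectors[k], m[k]), codes)
  }))
  hierarchy_index(sub)
}

#' Build an identity concordance table for a hierarchy
#'
#' Maps legacy-style industry codes (prefix + subsector code) to their 2017
#' NAICS-style sector and subsector, one row per subsector. This is the
#' concordance under which synthetic raw records are mappable.
#'
#' @param hierarchy A [hierarchy_index()].
#' @param prefix Character prefix used to form the legacy code.
#' @return A data.frame with columns `old_code`, `sector`, `subsector`.
#' @export
build_concordance <- function(hierarchy, prefix = "L") {
  stopifnot(inherits(hierarchy, "hierarchy_index"))
  data.frame(
    old_code = paste0(prefix, hierarchy$subsector_ids),
    sector = unname(hierarchy$sector_of),
    subsector = hierarchy$subsector_ids,
    stringsAsFactors = FALSE
  )
}
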