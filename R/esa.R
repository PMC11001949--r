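# Desertification-sensitivity class-share accounting.
#
# The MEDALUS methodology classifies territory into environmentally
# sensitive areas (ESAs) to desertification: not affected, potential,
# fragile (1-3) and critical (1-3). This module works on the per-class
# share-of-territory table over survey years; it does not compute the ESAI
# index itself (which needs climate/soil/vegetation layers).

#' The eight MEDALUS ESA classes, least to most sensitive
#' @return character vector of class labels.
#' @export
esa_classes <- function() {
  c("not affected", "potential", "fragile 1", "fragile 2", "fragile 3",
    "critical 1", "critical 2", "critical 3")
}

#' Validate an ESA class-share table
#'
#' @param esa data.frame with columns `esa_class`, `year`, `share_percent`;
#'   classes among [esa_classes()], per-year shares summing to 100 (+- 0.5).
#' @param renormalize if `TRUE`, years whose shares drift from 100 within
#'   the tolerance are rescaled to sum exactly to 100.
#' @return the (possibly renormalised) table.
#' @export
validate_esa <- function(esa, renormalize = FALSE) {
  need <- c("esa_class", "year", "share_percent")
  stopifnot(is.data.frame(esa))
  if (!all(need %in% names(esa))) {
    stop("ESA table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(esa$esa_class), esa_classes())
  if (length(bad)) {
    stop("unknown ESA class(es): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sums <- tapply(esa$share_percent, esa$year, sum)
  off <- abs(sums - 100) > 0.5
  if (any(off)) {
    warning("ESA shares do not sum to 100 (+-0.5) in year(s): ",
            paste(names(sums)[off], collapse = ", "))
  }
  if (renormalize) {
    for (y in names(sums)) {
      i <- esa$year == as.numeric(y)
      esa$share_percent[i] <- 100 * esa$share_percent[i] / sums[[y]]
    }
  }
  esa
}

#' ESA share changes and affected-land aggregate
#'
#' Per-class share deltas between consecutive survey years, plus the
#' aggregate share of "affected" land per year, summed over a configurable
#' class subset (default: all fragile plus all critical classes).
#'
#' @param esa ESA share table (see [validate_esa()]).
#' @param affected_classes classes counted as affected land.
#' @return list with `deltas` (data.frame `esa_class, year_from, year_to,
#'   share_from, share_to, delta_pp`) and `affected` (data.frame `year,
#'   affected_pct`).
#' @export
esa_summary <- function(esa,
                        affected_classes = c("fragile 1", "fragile 2",
                                             "fragile 3", "critical 1",
                                             "critical 2", "critical 3")) {
  esa <- validate_esa(esa)
  years <- sort(unique(esa$year))
  if (length(years) < 2) stop("need at least 2 survey years", call. = FALSE)
  share_of <- function(cls, y) {
    v <- esa$share_percent[esa$esa_class == cls & esa$year == y]
    if (length(v)) v else 0
  }
  deltas <- do.call(rbind, lapply(seq_len(length(years) - 1), function(i) {
    y0 <- years[i]; y1 <- years[i + 1]
    cls <- unique(esa$esa_class)
    data.frame(
      esa_class = cls, year_from = y0, year_to = y1,
      share_from = vapply(cls, share_of, numeric(1), y = y0),
      share_to = vapply(cls, share_of, numeric(1), y = y1),
      stringsAsFactors = FALSE
    )
  }))
  deltas$delta_pp <- deltas$share_to - deltas$share_from
  rownames(deltas) <- NULL
  affected <- data.frame(
    year = years,
    affected_pct = vapply(years, function(y) {
      sum(esa$share_percent[esa$year == y &
                              esa$esa_class %in% affected_classes])
    }, numeric(1))
  )
  list(deltas = deltas, affected = affected)
}

#' Read an ESA class-share CSV
#'
#' Expects columns `esa_class, year, share_percent`.
#'
#' @param path CSV path.
#' @return validated ESA table.
#' @export
read_esa <- function(path) {
  validate_esa(utils::read.csv(path, stringsAsFactors = FALSE))
}
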