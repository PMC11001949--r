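# Multi-temporal land-cover composition and change accounting.
#
# A land-cover table is long-format: one row per (class_code, year) with the
# class area in hectares, or NA where the source map did not record the
# class ("n.a." in published tables). Class codes are CORINE Land Cover
# (CLC) level-III dotted codes such as "2.4.3"; tables in older national
# classifications (e.g. the 1958 CNR-TCI soil-use map) are re-keyed to CLC
# through a crosswalk before analysis. NA areas never enter a year's
# denominator: an unrecorded class is unknown, not zero.

#' Validate a land-cover class-area table
#'
#' @param table data.frame with columns `class_code`, `class_name`, `year`,
#'   `area_ha` (`NA` allowed); `(class_code, year)` must be unique, areas
#'   non-negative, and every year must have at least one recorded area.
#' @return `table`, invisibly.
#' @export
validate_landcover <- function(table) {
  need <- c("class_code", "class_name", "year", "area_ha")
  stopifnot(is.data.frame(table))
  if (!all(need %in% names(table))) {
    stop("land-cover table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(table$class_code, table$year)
  if (anyDuplicated(key)) {
    stop("duplicate (class_code, year): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  if (any(stats::na.omit(table$area_ha) < 0)) {
    stop("areas must be non-negative", call. = FALSE)
  }
  ok_years <- tapply(!is.na(table$area_ha), table$year, any)
  if (!all(ok_years)) {
    stop("year(s) with no recorded area: ",
         paste(names(ok_years)[!ok_years], collapse = ", "), call. = FALSE)
  }
  invisible(table)
}

#' Re-key a land-cover table through a classification crosswalk
#'
#' Maps source class labels (e.g. CNR-TCI soil-use classes) to CLC
#' level-III codes, summing areas where several source classes map to one
#' CLC code. The total mapped area is conserved.
#'
#' @param table land-cover table (see [validate_landcover()]).
#' @param map data.frame with columns `source_label`, `clc_code` and
#'   optionally `clc_name`.
#' @return re-keyed land-cover table.
#' @export
apply_crosswalk <- function(table, map) {
  validate_landcover(table)
  stopifnot(all(c("source_label", "clc_code") %in% names(map)))
  unmapped <- setdiff(unique(table$class_code), map$source_label)
  if (length(unmapped)) {
    stop("unmapped class(es): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(table$class_code, map$source_label)
  table$.code <- map$clc_code[idx]
  table$.name <- if ("clc_name" %in% names(map)) {
    map$clc_name[idx]
  } else {
    table$class_name
  }
  total_before <- sum(table$area_ha, na.rm = TRUE)
  agg <- stats::aggregate(
    area_ha ~ .code + year, data = table,
    FUN = function(v) sum(v), na.action = stats::na.pass
  )
  # keep NA only when every contributing source area was NA
  any_rec <- stats::aggregate(
    cbind(rec = !is.na(area_ha)) ~ .code + year, data = table, FUN = any
  )
  agg <- merge(agg, any_rec, by = c(".code", "year"))
  sums <- stats::aggregate(
    area_ha ~ .code + year, data = table[!is.na(table$area_ha), ], FUN = sum
  )
  names(sums)[3] <- "sum_rec"
  agg <- merge(agg, sums, by = c(".code", "year"), all.x = TRUE)
  out <- data.frame(
    class_code = agg$.code,
    class_name = table$.name[match(agg$.code, table$.code)],
    year = agg$year,
    area_ha = ifelse(agg$rec, agg$sum_rec, NA_real_),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$year, out$class_code), ]
  rownames(out) <- NULL
  total_after <- sum(out$area_ha, na.rm = TRUE)
  if (abs(total_after - total_before) > 0.01) {
    stop(sprintf("crosswalk failed to conserve area: %.3f vs %.3f ha",
                 total_before, total_after), call. = FALSE)
  }
  validate_landcover(out)
  out
}

#' Identity crosswalk for an already CLC-coded table
#'
#' @param table land-cover table.
#' @return crosswalk data.frame mapping every class code to itself.
#' @export
identity_crosswalk <- function(table) {
  u <- !duplicated(table$class_code)
  data.frame(source_label = table$class_code[u],
             clc_code = table$class_code[u],
             clc_name = table$class_name[u],
             stringsAsFactors = FALSE)
}

#' Per-class percentage composition for one year
#'
#' Share of each class in the year's total area. The denominator is the
#' sum of the recorded (non-`NA`) areas for that year; an explicit
#' `total_ha` can be supplied instead when the territory total is known to
#' exceed the mapped area.
#'
#' @param table land-cover table.
#' @param year year to compose.
#' @param total_ha optional denominator override in hectares.
#' @return data.frame `class_code, class_name, year, area_ha, share_pct`,
#'   `NA` share for unrecorded classes; recorded shares sum to 100 under
#'   the default denominator.
#' @export
composition <- function(table, year, total_ha = NULL) {
  validate_landcover(table)
  d <- table[table$year == year, ]
  if (!nrow(d)) stop("year ", year, " not present", call. = FALSE)
  denom <- if (is.null(total_ha)) sum(d$area_ha, na.rm = TRUE) else total_ha
  if (denom <= 0) stop("total area must be positive", call. = FALSE)
  d$share_pct <- 100 * d$area_ha / denom
  d <- d[order(d$class_code), c("class_code", "class_name", "year",
                                "area_ha", "share_pct")]
  rownames(d) <- NULL
  d
}

#' CLC level-1 rollup of a year's composition
#'
#' Aggregates level-III shares by the leading CLC digit (1 artificial
#' surfaces, 2 agricultural areas, 3 forest and semi-natural areas, 4
#' wetlands, 5 water bodies). By default each class share is first rounded
#' to `digits` decimals, matching the arithmetic of published composition
#' tables whose level-1 totals are sums of printed class percentages; set
#' `digits = NULL` to sum unrounded shares.
#'
#' @inheritParams composition
#' @param digits per-class rounding applied before summing (default 1,
#'   printed-table convention), or `NULL` for unrounded.
#' @return data.frame `level1, year, area_ha, share_pct`.
#' @export
rollup_level1 <- function(table, year, total_ha = NULL, digits = 1) {
  comp <- composition(table, year, total_ha)
  if (!all(grepl("^[1-5](\\.[0-9]+)*$", comp$class_code))) {
    stop("non-CLC class codes present; apply a crosswalk first",
         call. = FALSE)
  }
  lvl1 <- substr(comp$class_code, 1, 1)
  share <- if (is.null(digits)) comp$share_pct else round(comp$share_pct, digits)
  out <- data.frame(
    level1 = sort(unique(lvl1)),
    year = year,
    area_ha = as.numeric(tapply(comp$area_ha, lvl1, sum, na.rm = TRUE)),
    share_pct = as.numeric(tapply(share, lvl1, sum, na.rm = TRUE)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Between-year per-class change
#'
#' Area and composition-share changes per class between two years. A class
#' unrecorded (`NA`) in one year is treated as a 0 baseline for the delta
#' but flagged `missing_data`, since "n.a." in the source map is unknown
#' rather than zero.
#'
#' @param table land-cover table.
#' @param year_a,year_b distinct years present in the table.
#' @return data.frame `class_code, class_name, area_a, area_b, delta_ha,
#'   share_a, share_b, delta_pp, missing_data`.
#' @export
change_matrix <- function(table, year_a, year_b) {
  if (year_a == year_b) stop("years must differ", call. = FALSE)
  ca <- composition(table, year_a)
  cb <- composition(table, year_b)
  codes <- sort(unique(c(ca$class_code, cb$class_code)))
  ia <- match(codes, ca$class_code)
  ib <- match(codes, cb$class_code)
  area_a <- ca$area_ha[ia]; area_b <- cb$area_ha[ib]
  share_a <- ca$share_pct[ia]; share_b <- cb$share_pct[ib]
  missing_data <- is.na(area_a) | is.na(area_b)
  z <- function(v) ifelse(is.na(v), 0, v)
  nm <- ifelse(is.na(ia), cb$class_name[ib], ca$class_name[ia])
  out <- data.frame(
    class_code = codes, class_name = nm,
    area_a = area_a, area_b = area_b,
    delta_ha = z(area_b) - z(area_a),
    share_a = share_a, share_b = share_b,
    delta_pp = z(share_b) - z(share_a),
    missing_data = missing_data,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Read a land-cover class-area CSV
#'
#' Expects columns `class_code, class_name, year, area_ha` with "NA" for
#' unrecorded areas.
#'
#' @param path CSV path.
#' @return validated land-cover table.
#' @export
read_landcover <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(class_code = "character"))
  validate_landcover(d)
  d
}

#' Read a classification crosswalk CSV
#'
#' Expects columns `source_label, clc_code` (optional `clc_name`).
#'
#' @param path CSV path.
#' @return crosswalk data.frame.
#' @export
read_crosswalk <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  stopifnot(all(c("source_label", "clc_code") %in% names(d)))
  d
}
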