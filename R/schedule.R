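#' Construct a germination schedule
#'
#' A germination schedule records, for one Petri dish, the number of seeds
#' newly germinated at each daily check of a trial. Day 1 is the first 24-h
#' check after sowing and `daily_counts[i]` is the number of seeds whose
#' radicle first reached 1 mm on day `i` (new germinations, not cumulative
#' totals; see [as_daily_counts()] for converting cumulative series).
#'
#' @param daily_counts integer vector of new germinations per day, length
#'   `duration_days`.
#' @param total_seeds number of seeds sown in the dish (N).
#' @param duration_days trial length in days (k); defaults to
#'   `length(daily_counts)`.
#' @param dish_id,treatment_id optional identifiers carried through to
#'   index tables.
#' @return An object of class `germination_schedule`.
#' @examples
#' s <- germination_schedule(counts_from_events(c(26, 30, 30, 35), 60), 20)
#' final_germination_percentage(s)
#' @export
germination_schedule <- function(daily_counts, total_seeds,
                                 duration_days = length(daily_counts),
                                 dish_id = NA_character_,
                                 treatment_id = NA_character_) {
  s <- structure(
    list(
      dish_id = as.character(dish_id),
      treatment_id = as.character(treatment_id),
      total_seeds = as.integer(total_seeds),
      duration_days = as.integer(duration_days),
      daily_counts = as.integer(round(daily_counts))
    ),
    class = "germination_schedule"
  )
  validate_schedule(s)
  s
}

#' Validate a germination schedule
#'
#' Checks the structural invariants of a dish schedule: positive seed count
#' and duration, one non-negative integer count per day, and total
#' germinations not exceeding the seeds sown.
#'
#' @param s a `germination_schedule`.
#' @return `s`, invisibly; signals an error describing every violated rule.
#' @export
validate_schedule <- function(s) {
  stopifnot(inherits(s, "germination_schedule"))
  problems <- character()
  if (!isTRUE(s$total_seeds > 0)) {
    problems <- c(problems, "total_seeds must be > 0")
  }
  if (!isTRUE(s$duration_days > 0)) {
    problems <- c(problems, "duration_days must be > 0")
  }
  if (length(s$daily_counts) != s$duration_days) {
    problems <- c(problems, sprintf(
      "daily_counts has length %d but duration_days is %d",
      length(s$daily_counts), s$duration_days
    ))
  }
  if (anyNA(s$daily_counts) || any(s$daily_counts < 0)) {
    problems <- c(problems, "daily_counts must be non-negative integers")
  } else if (sum(s$daily_counts) > s$total_seeds) {
    problems <- c(problems, sprintf(
      "total germinations (%d) exceed total_seeds (%d)",
      sum(s$daily_counts), s$total_seeds
    ))
  }
  if (length(problems)) {
    stop("invalid germination schedule [", s$dish_id, "]: ",
         paste(problems, collapse = "; "), call. = FALSE)
  }
  invisible(s)
}

#' @export
print.germination_schedule <- function(x, ...) {
  g <- sum(x$daily_counts)
  cat(sprintf(
    "germination schedule: dish %s (treatment %s), %d/%d seeds germinated over %d days\n",
    x$dish_id, x$treatment_id, g, x$total_seeds, x$duration_days
  ))
  if (g > 0) {
    d <- which(x$daily_counts > 0)
    cat("  events:", paste(sprintf("day %d: %d", d, x$daily_counts[d]),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Build a daily-count vector from per-seed germination days
#'
#' @param event_days integer vector, one germination day per germinated seed.
#' @param duration_days trial length (k).
#' @return integer vector of length `duration_days`.
#' @export
counts_from_events <- function(event_days, duration_days) {
  event_days <- as.integer(event_days)
  if (length(event_days) &&
      (min(event_days) < 1L || max(event_days) > duration_days)) {
    stop("event days must lie in [1, duration_days]", call. = FALSE)
  }
  tabulate(event_days, nbins = as.integer(duration_days))
}

#' Convert a cumulative germination series to daily increments
#'
#' Some trial records report the running total of germinated seeds rather
#' than daily new germinations. A cumulative series is non-decreasing and
#' covers the full trial; this helper differences it back to daily counts.
#'
#' @param counts numeric vector of cumulative germinated-seed totals.
#' @return integer vector of daily increments of the same length.
#' @export
as_daily_counts <- function(counts) {
  if (is.unsorted(counts)) {
    stop("cumulative counts must be non-decreasing", call. = FALSE)
  }
  as.integer(diff(c(0, counts)))
}

#' Read dish schedules from CSV files
#'
#' Reads the long-format trial record used throughout the pipeline:
#' `schedules.csv` with columns `dish_id, treatment_id, day, n_germinated`
#' (days without germination may be omitted) and a companion `dishes.csv`
#' with columns `dish_id, treatment_id, total_seeds, duration_days`.
#'
#' @param schedules_path path to the long-format daily-count CSV.
#' @param dishes_path path to the per-dish metadata CSV.
#' @param cumulative if `TRUE`, `n_germinated` holds running totals and is
#'   differenced with [as_daily_counts()]; default is daily increments.
#' @return list of `germination_schedule` objects, one per dish.
#' @export
read_schedules <- function(schedules_path, dishes_path, cumulative = FALSE) {
  sch <- utils::read.csv(schedules_path, stringsAsFactors = FALSE)
  dsh <- utils::read.csv(dishes_path, stringsAsFactors = FALSE)
  need <- c("dish_id", "treatment_id", "day", "n_germinated")
  if (!all(need %in% names(sch))) {
    stop(schedules_path, " must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  need_d <- c("dish_id", "treatment_id", "total_seeds", "duration_days")
  if (!all(need_d %in% names(dsh))) {
    stop(dishes_path, " must have columns ", paste(need_d, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(sch$n_germinated < 0 | sch$day < 1)
  if (length(bad)) {
    stop(schedules_path, ": invalid row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (day must be >= 1 and n_germinated >= 0)", call. = FALSE)
  }
  lapply(seq_len(nrow(dsh)), function(i) {
    d <- dsh[i, ]
    rows <- sch[sch$dish_id == d$dish_id, ]
    counts <- rep(0L, d$duration_days)
    if (nrow(rows)) {
      if (any(rows$day > d$duration_days)) {
        stop("dish ", d$dish_id, ": day beyond duration_days", call. = FALSE)
      }
      counts[rows$day] <- counts[rows$day] + as.integer(rows$n_germinated)
      if (cumulative) counts <- as_daily_counts(cummax(counts))
    }
    germination_schedule(counts, d$total_seeds, d$duration_days,
                         dish_id = d$dish_id, treatment_id = d$treatment_id)
  })
}

#' Write dish schedules to the standard CSV pair
#'
#' Inverse of [read_schedules()]: writes the long-format daily-count table
#' (zero days omitted) and the per-dish metadata table.
#'
#' @param schedules list of `germination_schedule` objects.
#' @param schedules_path,dishes_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_schedules <- function(schedules, schedules_path, dishes_path) {
  long <- do.call(rbind, lapply(schedules, function(s) {
    d <- which(s$daily_counts > 0)
    if (!length(d)) return(NULL)
    data.frame(dish_id = s$dish_id, treatment_id = s$treatment_id,
               day = d, n_germinated = s$daily_counts[d])
  }))
  if (is.null(long)) {
    long <- data.frame(dish_id = character(), treatment_id = character(),
                       day = integer(), n_germinated = integer())
  }
  meta <- do.call(rbind, lapply(schedules, function(s) {
    data.frame(dish_id = s$dish_id, treatment_id = s$treatment_id,
               total_seeds = s$total_seeds, duration_days = s$duration_days)
  }))
  utils::write.csv(long, schedules_path, row.names = FALSE)
  utils::write.csv(meta, dishes_path, row.names = FALSE)
  invisible(c(schedules_path, dishes_path))
}
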