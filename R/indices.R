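# Germination time-course indices.
#
# All indices operate on a per-dish daily-count schedule with n_i new
# germinations on day t_i = i (i = 1..k) out of N seeds sown. Indices that
# are undefined for a dish (no germination, or a single germination for the
# time-dispersion statistics) return NA rather than 0: a silent zero would
# bias replicate means. Capacity-type indices (FGP, GRI, GI) are 0 for an
# empty schedule.

event_times <- function(s) {
  rep.int(seq_len(s$duration_days), s$daily_counts)
}

#' Final germination percentage (FGP)
#'
#' Percentage of sown seeds that germinated by trial end:
#' \eqn{100 \sum n_i / N}.
#'
#' @param s a [germination_schedule()].
#' @return percent in \[0, 100\]; 0 when nothing germinated.
#' @export
final_germination_percentage <- function(s) {
  validate_schedule(s)
  100 * sum(s$daily_counts) / s$total_seeds
}

#' Mean germination time (MGT)
#'
#' Germination-count-weighted mean day of germination,
#' \eqn{\sum n_i t_i / \sum n_i}, in days.
#'
#' @inheritParams final_germination_percentage
#' @return days; `NA` when no seed germinated.
#' @export
mean_germination_time <- function(s) {
  validate_schedule(s)
  g <- sum(s$daily_counts)
  if (g == 0) return(NA_real_)
  sum(s$daily_counts * seq_len(s$duration_days)) / g
}

#' Mean germination rate (MGR)
#'
#' The reciprocal of the mean germination time, in day^-1.
#'
#' @inheritParams final_germination_percentage
#' @return per-day rate; `NA` when MGT is undefined.
#' @export
mean_germination_rate <- function(s) {
  1 / mean_germination_time(s)
}

#' First and last day of germination (FDG, LDG)
#'
#' @inheritParams final_germination_percentage
#' @return named numeric vector `c(fdg = ..., ldg = ...)`; both `NA` when no
#'   seed germinated.
#' @export
germination_span <- function(s) {
  validate_schedule(s)
  d <- which(s$daily_counts > 0)
  if (!length(d)) return(c(fdg = NA_real_, ldg = NA_real_))
  c(fdg = as.numeric(min(d)), ldg = as.numeric(max(d)))
}

#' Median germination time (T50)
#'
#' Day by which half of the seeds that eventually germinated had germinated,
#' obtained by linear interpolation of the cumulative count. With N the
#' final number of germinated seeds and adjacent cumulative counts
#' \eqn{n_i} at \eqn{t_i} and \eqn{n_j} at \eqn{t_j} bracketing the
#' half-count target \eqn{(N+1)/2},
#' \deqn{T_{50} = t_i + \frac{((N+1)/2 - n_i)(t_j - t_i)}{n_j - n_i}.}
#'
#' Degenerate cases: if a cumulative count hits \eqn{(N+1)/2} exactly, that
#' day is returned; if the first germination day already reaches the target
#' (in particular when all germination falls on a single day) that day is
#' returned, as the continuity limit of the interpolation.
#'
#' @inheritParams final_germination_percentage
#' @return days; `NA` when no seed germinated.
#' @export
median_germination_time <- function(s) {
  validate_schedule(s)
  n_final <- sum(s$daily_counts)
  if (n_final == 0) return(NA_real_)
  days <- which(s$daily_counts > 0)
  cum <- cumsum(s$daily_counts)[days]
  half <- (n_final + 1) / 2
  hit <- which(cum == half)
  if (length(hit)) return(as.numeric(days[hit[1]]))
  if (cum[1] >= half) return(as.numeric(days[1]))
  i <- max(which(cum < half))
  ti <- days[i]; tj <- days[i + 1]
  ni <- cum[i]; nj <- cum[i + 1]
  ti + (half - ni) * (tj - ti) / (nj - ni)
}

#' Germination-time dispersion: variance and CVt
#'
#' Sample variance of the germination day over germinated seeds,
#' \eqn{s_t^2 = \sum n_i (t_i - MGT)^2 / (\sum n_i - 1)}, and the
#' coefficient of variation of the mean germination time,
#' \eqn{CV_t = 100\, s_t / MGT}.
#'
#' @inheritParams final_germination_percentage
#' @return named vector `c(s_t2 = days^2, cvt = percent)`; both `NA` with
#'   fewer than two germinations.
#' @export
germination_time_dispersion <- function(s) {
  validate_schedule(s)
  g <- sum(s$daily_counts)
  if (g < 2) return(c(s_t2 = NA_real_, cvt = NA_real_))
  mgt <- mean_germination_time(s)
  t_i <- seq_len(s$duration_days)
  s_t2 <- sum(s$daily_counts * (t_i - mgt)^2) / (g - 1)
  c(s_t2 = s_t2, cvt = 100 * sqrt(s_t2) / mgt)
}

#' Coefficient of velocity of germination (CVG)
#'
#' \eqn{100 \sum n_i / \sum n_i t_i}; identically equal to 100 times the
#' mean germination rate.
#'
#' @inheritParams final_germination_percentage
#' @return dimensionless (per-day x 100); `NA` when no seed germinated.
#' @export
coefficient_of_velocity <- function(s) {
  validate_schedule(s)
  g <- sum(s$daily_counts)
  if (g == 0) return(NA_real_)
  100 * g / sum(s$daily_counts * seq_len(s$duration_days))
}

#' Germination rate index (GRI)
#'
#' Sum over days of the germination percentage on that day divided by the
#' day number, \eqn{\sum_d G_d / d} in percent per day; early germination
#' weighs more. By default \eqn{G_d} is the daily increment percentage
#' (\eqn{100 n_d / N}, the Esechie-style GRI, finitely additive over days);
#' `cumulative = TRUE` instead uses the running cumulative percentage
#' through day d.
#'
#' @inheritParams final_germination_percentage
#' @param cumulative use the cumulative-percentage reading of \eqn{G_d}.
#' @return percent per day; 0 when nothing germinated.
#' @export
germination_rate_index <- function(s, cumulative = FALSE) {
  validate_schedule(s)
  d <- seq_len(s$duration_days)
  g_d <- 100 * s$daily_counts / s$total_seeds
  if (cumulative) g_d <- cumsum(g_d)
  sum(g_d / d)
}

#' Germination index (GI)
#'
#' Day-weighted germinated-seed count with weights decreasing linearly to 1
#' on the last trial day: \eqn{GI = \sum_d (k - d + 1)\, n_d}. For a 60-day
#' trial this is the classical \eqn{(60 \times n_1) + (59 \times n_2) +
#' \cdots + (1 \times n_{60})}; the weight generalises to trials of any
#' duration k.
#'
#' @inheritParams final_germination_percentage
#' @return weighted count; 0 when nothing germinated.
#' @export
germination_index <- function(s) {
  validate_schedule(s)
  d <- seq_len(s$duration_days)
  sum((s$duration_days - d + 1) * s$daily_counts)
}

#' All germination indices for one dish
#'
#' Computes the full set of time-course statistics — capacity (FGP), time
#' (MGT, FDG, LDG, T50), rate (MGR, CVG), speed (GRI, GI) and homogeneity
#' (CVt) — for a single dish schedule. Indices undefined for the dish carry
#' `NA` (see the per-index help pages for the rules).
#'
#' @inheritParams final_germination_percentage
#' @return one-row `data.frame` with columns `dish_id, treatment_id, fgp,
#'   mgt, mgr, fdg, ldg, t50, cvt, cvg, gri, gi`.
#' @export
germination_indices <- function(s) {
  validate_schedule(s)
  span <- germination_span(s)
  disp <- germination_time_dispersion(s)
  data.frame(
    dish_id = s$dish_id,
    treatment_id = s$treatment_id,
    fgp = final_germination_percentage(s),
    mgt = mean_germination_time(s),
    mgr = mean_germination_rate(s),
    fdg = unname(span["fdg"]),
    ldg = unname(span["ldg"]),
    t50 = median_germination_time(s),
    cvt = unname(disp["cvt"]),
    cvg = coefficient_of_velocity(s),
    gri = germination_rate_index(s),
    gi = germination_index(s),
    stringsAsFactors = FALSE
  )
}

#' Index table for a set of dishes
#'
#' @param schedules list of [germination_schedule()] objects.
#' @return `data.frame` with one row per dish (see [germination_indices()]).
#' @export
germination_index_table <- function(schedules) {
  do.call(rbind, lapply(schedules, germination_indices))
}

#' Treatment-level summary of germination indices
#'
#' Mean and standard deviation of each index across replicate dishes of a
#' treatment. Dishes where an index is undefined (`NA`) are excluded from
#' that index's mean and sd rather than counted as zero.
#'
#' @param indices index table from [germination_index_table()].
#' @param digits optional named rounding, e.g. `c(mgr = 3, .default = 1)`,
#'   matching the precision conventionally printed for these indices;
#'   `NULL` (default) leaves values unrounded.
#' @return `data.frame` with one row per treatment x index: columns
#'   `treatment_id, index, mean, sd, n_defined`.
#' @export
summarize_treatments <- function(indices, digits = NULL) {
  idx_cols <- setdiff(names(indices), c("dish_id", "treatment_id"))
  out <- do.call(rbind, lapply(split(indices, indices$treatment_id), function(d) {
    do.call(rbind, lapply(idx_cols, function(col) {
      v <- d[[col]]
      data.frame(
        treatment_id = d$treatment_id[1], index = col,
        mean = mean(v, na.rm = TRUE),
        sd = stats::sd(v, na.rm = TRUE),
        n_defined = sum(!is.na(v)),
        stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(out) <- NULL
  if (!is.null(digits)) {
    dflt <- if (".default" %in% names(digits)) digits[[".default"]] else 1
    dg <- ifelse(out$index %in% names(digits), digits[out$index], dflt)
    out$mean <- round(out$mean, dg)
    out$sd <- round(out$sd, dg)
  }
  out
}

#' Cut-test viability summary
#'
#' End-of-trial cut test: each ungerminated fruit is dissected and classified
#' as viable/fresh (white, firm embryo), empty (no embryo) or dead.
#'
#' @param n_viable,n_empty,n_dead non-negative counts; at least one seed
#'   must have been tested.
#' @return `data.frame` with one row per class: `class, n, percent`;
#'   percentages are over tested seeds and sum to 100.
#' @export
summarize_cut_test <- function(n_viable, n_empty, n_dead) {
  counts <- c(viable = n_viable, empty = n_empty, dead = n_dead)
  if (anyNA(counts) || any(counts < 0)) {
    stop("cut-test counts must be non-negative", call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0) stop("cut test requires at least one tested seed", call. = FALSE)
  data.frame(
    class = names(counts),
    n = as.integer(counts),
    percent = 100 * as.numeric(counts) / total,
    stringsAsFactors = FALSE
  )
}

#' Read cut-test counts from CSV
#'
#' Expects columns `dish_id, n_viable, n_empty, n_dead`.
#'
#' @param path CSV path.
#' @return `data.frame` of per-dish counts plus per-dish percentages.
#' @export
read_cut_test <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dish_id", "n_viable", "n_empty", "n_dead")
  if (!all(need %in% names(d))) {
    stop(path, " must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  tested <- d$n_viable + d$n_empty + d$n_dead
  if (any(tested == 0)) stop(path, ": dish with no tested seeds", call. = FALSE)
  d$pct_viable <- 100 * d$n_viable / tested
  d$pct_empty <- 100 * d$n_empty / tested
  d$pct_dead <- 100 * d$n_dead / tested
  d
}
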