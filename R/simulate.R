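# Seeded synthetic-data generators.
#
# Every generator is a pure function of (config, seed): the RNG state is
# set from `seed` locally and restored afterwards, so identical calls give
# identical output and callers' random streams are untouched.

local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# normal truncated to [lo, hi], inverse-CDF sampling
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

round_half_up <- function(x) floor(x + 0.5)

#' Default germination-trial simulation settings
#'
#' Encodes the trial design the pipeline targets: four treatments
#' (gibberellic acid on blotting paper or agar, at 10 or 15 degC), four
#' replicate dishes of 20 achenes, 60-day trials. Per-treatment
#' within-trial germination probabilities (0.17, 0.14, 0.32, 0.23), mean
#' germination days (30.3, 36, 32.5, 34.4) and day spreads are set to the
#' observed treatment-level statistics of low-germinating,
#' late-onset (about day 25-32) morpho-physiologically dormant seed; the
#' non-germinating fraction splits 80.1% empty / 15% dead / 4.9% viable as
#' in the reference cut test.
#'
#' @return list: `treatments` (data.frame `treatment_id, p_germ, mu_day,
#'   sigma_day`), `n_seeds`, `n_replicates`, `duration_days`,
#'   `empty_frac`, `dead_frac`, `day_law`.
#' @export
default_germination_config <- function() {
  list(
    treatments = data.frame(
      treatment_id = c("GA3_paper_10C", "GA3_paper_15C",
                       "GA3_agar_10C", "GA3_agar_15C"),
      p_germ = c(0.17, 0.14, 0.32, 0.23),
      mu_day = c(30.3, 36, 32.5, 34.4),
      sigma_day = c(4.5, 5.7, 5.1, 3.6),
      stringsAsFactors = FALSE
    ),
    n_seeds = 20L, n_replicates = 4L, duration_days = 60L,
    empty_frac = 0.801, dead_frac = 0.15, day_law = "truncnorm"
  )
}

#' Simulate a germination experiment
#'
#' Each seed germinates within the trial independently with probability
#' `p_germ`; germinating seeds receive a day drawn from a normal (or, with
#' `day_law = "lognormal"`, a lognormal with matching mean and sd)
#' truncated to `[1, duration_days]` with mean `mu_day` and sd
#' `sigma_day`, rounded half-up to an integer day. Non-germinating seeds
#' are partitioned into empty / dead / viable-ungerminated by the
#' configured fractions for the end-of-trial cut test.
#'
#' @param config settings list as from [default_germination_config()];
#'   fields may be overridden.
#' @param seed integer RNG seed; the call is reproducible given the seed
#'   and leaves the caller's RNG state untouched.
#' @return list with `schedules` (list of [germination_schedule()], one per
#'   dish) and `cut_test` (data.frame `dish_id, treatment_id, n_viable,
#'   n_empty, n_dead`).
#' @export
simulate_germination_experiment <- function(config = default_germination_config(),
                                            seed = 1L) {
  cfg <- utils::modifyList(default_germination_config(), config)
  stopifnot(all(cfg$treatments$p_germ >= 0 & cfg$treatments$p_germ <= 1),
            all(cfg$treatments$mu_day >= 1 &
                  cfg$treatments$mu_day <= cfg$duration_days),
            all(cfg$treatments$sigma_day >= 0))
  if (cfg$empty_frac < 0 || cfg$dead_frac < 0 ||
      cfg$empty_frac + cfg$dead_frac > 1) {
    stop("empty/dead fractions must be non-negative and sum to <= 1",
         call. = FALSE)
  }
  local_seed(seed, {
    schedules <- list()
    cut_rows <- list()
    for (t in seq_len(nrow(cfg$treatments))) {
      tr <- cfg$treatments[t, ]
      for (r in seq_len(cfg$n_replicates)) {
        dish <- sprintf("%s_r%d", tr$treatment_id, r)
        germ <- stats::rbinom(1, cfg$n_seeds, tr$p_germ)
        days <- if (germ > 0) {
          raw <- if (identical(cfg$day_law, "lognormal")) {
            sdlog <- sqrt(log(1 + (tr$sigma_day / tr$mu_day)^2))
            meanlog <- log(tr$mu_day) - sdlog^2 / 2
            v <- stats::rlnorm(germ * 4, meanlog, sdlog)
            v <- v[v >= 1 & v <= cfg$duration_days][seq_len(germ)]
            if (anyNA(v)) stop("lognormal day law: truncation too severe")
            v
          } else {
            rtrunc_norm(germ, tr$mu_day, tr$sigma_day, 1, cfg$duration_days)
          }
          pmin(pmax(round_half_up(raw), 1L), cfg$duration_days)
        } else {
          integer(0)
        }
        ungerm <- cfg$n_seeds - germ
        fate <- if (ungerm > 0) {
          sample(c("empty", "dead", "viable"), ungerm, replace = TRUE,
                 prob = c(cfg$empty_frac, cfg$dead_frac,
                          1 - cfg$empty_frac - cfg$dead_frac))
        } else {
          character(0)
        }
        schedules[[dish]] <- germination_schedule(
          counts_from_events(days, cfg$duration_days), cfg$n_seeds,
          cfg$duration_days, dish_id = dish, treatment_id = tr$treatment_id
        )
        cut_rows[[dish]] <- data.frame(
          dish_id = dish, treatment_id = tr$treatment_id,
          n_viable = sum(fate == "viable"),
          n_empty = sum(fate == "empty"),
          n_dead = sum(fate == "dead"),
          stringsAsFactors = FALSE
        )
      }
    }
    list(schedules = unname(schedules),
         cut_test = {
           ct <- do.call(rbind, cut_rows); rownames(ct) <- NULL; ct
         })
  })
}

#' Default climate simulation settings
#'
#' A 90-year annual series (1931-2020) with piecewise-linear means over the
#' three 30-year normals. Temperature runs 15.4 -> 15.2, 15.1 -> 16.2 and
#' 16.2 -> 15.2 degC across the segments (net warming about +0.5 degC over
#' the century with an overall mean near 15.6 degC); rainfall runs 1050 ->
#' 850, 950 -> 800 and 880 -> 1050 mm (long-run mean about 920 mm).
#' Interannual noise is Gaussian: sd 0.3 degC for temperature and 150 mm
#' for rainfall, typical station-scale variability.
#'
#' @return list with `temp_c` and `rain_mm` components, each holding
#'   `segments` (data.frame `start_year, end_year, start_value,
#'   end_value`) and `noise_sd`.
#' @export
default_climate_config <- function() {
  seg <- function(v0, v1) data.frame(
    start_year = c(1931, 1961, 1991), end_year = c(1960, 1990, 2020),
    start_value = v0, end_value = v1
  )
  list(
    temp_c = list(segments = seg(c(15.4, 15.1, 16.2), c(15.2, 16.2, 15.2)),
                  noise_sd = 0.3),
    rain_mm = list(segments = seg(c(1050, 950, 880), c(850, 800, 1050)),
                   noise_sd = 150)
  )
}

#' Simulate an annual climate series
#'
#' Piecewise-linear means plus Gaussian noise per variable; segments must
#' not overlap and together define the simulated years.
#'
#' @param config list as [default_climate_config()].
#' @inheritParams simulate_germination_experiment
#' @return data.frame `year, temp_c, rain_mm` (whichever variables the
#'   config defines), validated by [validate_climate_series()].
#' @export
simulate_climate <- function(config = default_climate_config(), seed = 1L) {
  cfg <- utils::modifyList(default_climate_config(), config)
  vars <- names(cfg)
  all_years <- sort(unique(unlist(lapply(vars, function(v) {
    s <- cfg[[v]]$segments
    unlist(mapply(seq, s$start_year, s$end_year, SIMPLIFY = FALSE))
  }))))
  out <- data.frame(year = all_years)
  local_seed(seed, {
    for (v in vars) {
      s <- cfg[[v]]$segments
      covered <- unlist(mapply(seq, s$start_year, s$end_year,
                               SIMPLIFY = FALSE))
      if (anyDuplicated(covered)) {
        stop("overlapping segments for ", v, call. = FALSE)
      }
      vals <- rep(NA_real_, length(all_years))
      for (i in seq_len(nrow(s))) {
        yrs <- s$start_year[i]:s$end_year[i]
        frac <- if (length(yrs) == 1) 0 else {
          (yrs - s$start_year[i]) / (s$end_year[i] - s$start_year[i])
        }
        mu <- s$start_value[i] + frac * (s$end_value[i] - s$start_value[i])
        vals[match(yrs, all_years)] <-
          mu + stats::rnorm(length(yrs), 0, cfg[[v]]$noise_sd)
      }
      if (v == "rain_mm") vals <- pmax(vals, 0)
      out[[v]] <- vals
    }
  })
  validate_climate_series(out)
  out
}

#' Default land-cover simulation settings
#'
#' A CLC-coded territory of 42,400 ha observed in 1958, 1990, 2000, 2006,
#' 2012 and 2018, starting agriculture-dominated (84% level-1 class 2, 16%
#' class 3, trace urban/water) and drifting per period from agricultural
#' classes towards forest and semi-natural ones, emulating land abandonment
#' and vegetation recovery.
#'
#' @return list: `classes` (data.frame `class_code, class_name`),
#'   `initial_shares` (%), `drift` (square matrix, pp moved from row class
#'   to column class per period), `years`, `total_area_ha`, `noise_sd`.
#' @export
default_landcover_config <- function() {
  classes <- data.frame(
    class_code = c("1.1.2", "2.1.1", "2.2.2", "2.4.3", "3.1.1", "3.2.1",
                   "3.3.3", "5.1.2"),
    class_name = c("Discontinuous urban fabric", "Non-irrigated arable land",
                   "Fruit trees and berry plantations",
                   "Agriculture with natural vegetation",
                   "Broad-leaved forest", "Natural grassland",
                   "Sparsely vegetated areas", "Water bodies"),
    stringsAsFactors = FALSE
  )
  k <- nrow(classes)
  drift <- matrix(0, k, k, dimnames = list(classes$class_code,
                                           classes$class_code))
  drift["2.1.1", "3.1.1"] <- 4   # arable abandoned to forest
  drift["2.1.1", "3.2.1"] <- 2
  drift["2.2.2", "2.4.3"] <- 3   # orchards to mixed agricultural mosaic
  drift["3.2.1", "3.1.1"] <- 1   # grassland closing to forest
  list(
    classes = classes,
    initial_shares = c(1.5, 31.5, 30, 20.2, 10, 4, 2, 0.8),
    drift = drift,
    years = c(1958, 1990, 2000, 2006, 2012, 2018),
    total_area_ha = 42400,
    noise_sd = 0.2
  )
}

#' Simulate a multi-temporal land-cover table
#'
#' Class shares evolve between consecutive survey years by the drift
#' matrix (percentage points moved from row class to column class per
#' period) plus Gaussian noise, are clipped at zero and renormalised to
#' 100 (with a warning if clipping occurred), then scaled to the fixed
#' territory area.
#'
#' @param config list as [default_landcover_config()].
#' @inheritParams simulate_germination_experiment
#' @return validated land-cover table (see [validate_landcover()]).
#' @export
simulate_landcover <- function(config = default_landcover_config(),
                               seed = 1L) {
  cfg <- utils::modifyList(default_landcover_config(), config)
  k <- nrow(cfg$classes)
  stopifnot(length(cfg$initial_shares) == k,
            all(dim(cfg$drift) == k),
            abs(sum(cfg$initial_shares) - 100) < 1e-6)
  local_seed(seed, {
    shares <- cfg$initial_shares
    rows <- list()
    clipped <- FALSE
    for (i in seq_along(cfg$years)) {
      if (i > 1) {
        shares <- shares - rowSums(cfg$drift) + colSums(cfg$drift) +
          stats::rnorm(k, 0, cfg$noise_sd)
        if (any(shares < 0)) {
          clipped <- TRUE
          shares <- pmax(shares, 0)
        }
        shares <- 100 * shares / sum(shares)
      }
      rows[[i]] <- data.frame(
        class_code = cfg$classes$class_code,
        class_name = cfg$classes$class_name,
        year = cfg$years[i],
        area_ha = cfg$total_area_ha * shares / 100,
        stringsAsFactors = FALSE
      )
    }
    if (clipped) warning("negative shares clipped and renormalised")
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    validate_landcover(out)
    out
  })
}

#' Default ESA-share simulation settings
#'
#' Eight MEDALUS sensitivity classes over the survey years 1960, 2000 and
#' 2020, tracing the observed arc: strong recovery to 2000 (not-affected
#' land rising from 14.3% to 70%) followed by sharp degradation to 2020
#' (not-affected collapsing to 35%).
#'
#' @return list with `shares`: matrix years x classes of percentages.
#' @export
default_esa_config <- function() {
  shares <- rbind(
    `1960` = c(14.3, 18.0, 12.0, 10.0, 12.0, 5.0, 3.7, 25.0),
    `2000` = c(70.0, 8.8, 6.0, 5.0, 4.0, 3.0, 3.2, 0.0),
    `2020` = c(35.0, 17.7, 12.0, 10.0, 9.0, 7.0, 6.0, 3.3)
  )
  colnames(shares) <- esa_classes()
  list(shares = shares)
}

#' Build an ESA share table from configured shares
#'
#' Deterministic table builder for the ESA accounting stage (the ESAI
#' layers behind real surveys are out of scope; this emulates their
#' class-share output).
#'
#' @param config list as [default_esa_config()].
#' @return validated ESA share table.
#' @export
simulate_esa <- function(config = default_esa_config()) {
  cfg <- utils::modifyList(default_esa_config(), config)
  m <- cfg$shares
  out <- data.frame(
    esa_class = rep(colnames(m), each = nrow(m)),
    year = rep(as.numeric(rownames(m)), times = ncol(m)),
    share_percent = as.vector(m),
    stringsAsFactors = FALSE
  )
  validate_esa(out)
}
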