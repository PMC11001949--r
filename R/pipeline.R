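# Pipeline orchestration: validation, staged execution, output manifest.
#
# A pipeline run reads whichever inputs the config names, executes the
# corresponding stages (germination indices -> treatment comparison ->
# climate windows -> land-cover / ESA change), writes one CSV per result
# table under the output directory and records a JSON manifest with the
# seed, the config echo and per-stage row counts. CSV dialect everywhere:
# comma-separated, UTF-8, header row, "NA" for missing, decimal point.

#' Assemble a pipeline configuration
#'
#' @param out_dir output directory (created if needed).
#' @param schedules,dishes,cut_test,climate,landcover,crosswalk,esa input
#'   CSV paths; `NULL` disables the stage needing them.
#' @param alpha familywise risk level for treatment comparisons.
#' @param windows data.frame of trend windows (default [default_windows()]).
#' @param indices which germination indices to compare across treatments.
#' @param seed integer seed recorded in the manifest and used by any
#'   stage needing randomness.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            schedules = NULL, dishes = NULL,
                            cut_test = NULL, climate = NULL,
                            landcover = NULL, crosswalk = NULL, esa = NULL,
                            alpha = 0.05, windows = default_windows(),
                            indices = c("fgp", "mgt"), seed = 1L) {
  structure(
    list(out_dir = out_dir, schedules = schedules, dishes = dishes,
         cut_test = cut_test, climate = climate, landcover = landcover,
         crosswalk = crosswalk, esa = esa, alpha = alpha,
         windows = windows, indices = indices, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Validate pipeline inputs
#'
#' Checks that every configured input file exists and satisfies its
#' module's structural invariants, without running any analysis.
#'
#' @param config a [pipeline_config()].
#' @return data.frame report with columns `input, path, ok, message`; one
#'   row per configured input.
#' @export
validate_inputs <- function(config) {
  check <- function(input, path, fn) {
    if (is.null(path)) return(NULL)
    msg <- NA_character_
    ok <- file.exists(path)
    if (!ok) {
      msg <- "file not found"
    } else {
      res <- tryCatch({ fn(path); TRUE },
                      error = function(e) conditionMessage(e),
                      warning = function(w) conditionMessage(w))
      if (!isTRUE(res)) { ok <- FALSE; msg <- res }
    }
    data.frame(input = input, path = path, ok = ok, message = msg,
               stringsAsFactors = FALSE)
  }
  rpt <- rbind(
    check("schedules", config$schedules, function(p) {
      read_schedules(p, config$dishes)
    }),
    check("cut_test", config$cut_test, read_cut_test),
    check("climate", config$climate, read_climate_series),
    check("landcover", config$landcover, read_landcover),
    check("crosswalk", config$crosswalk, read_crosswalk),
    check("esa", config$esa, read_esa)
  )
  if (is.null(rpt)) {
    rpt <- data.frame(input = character(), path = character(),
                      ok = logical(), message = character())
  }
  rpt
}

#' Run the configured pipeline stages
#'
#' Executes, in order and as configured: germination indices and treatment
#' summaries, nonparametric treatment comparison per index, cut-test
#' summaries, climate window trends, land-cover composition/rollup/change
#' and ESA share accounting. Each stage writes its tables as CSV under
#' `config$out_dir`; a `manifest.json` records the package version, seed,
#' config echo and per-stage outputs. Any validation failure aborts before
#' any stage runs.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  rpt <- validate_inputs(config)
  if (any(!rpt$ok)) {
    bad <- rpt[!rpt$ok, ]
    stop("input validation failed:\n",
         paste(sprintf("  %s (%s): %s", bad$input, bad$path, bad$message),
               collapse = "\n"), call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  emit <- function(stage, name, df) {
    path <- file.path(config$out_dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
    stages[[stage]] <<- c(stages[[stage]],
                          stats::setNames(list(nrow(df)), name))
  }

  if (!is.null(config$schedules)) {
    schedules <- read_schedules(config$schedules, config$dishes)
    idx <- germination_index_table(schedules)
    emit("indices", "indices", idx)
    emit("indices", "treatment_summary",
         summarize_treatments(idx, digits = c(mgr = 3, cvg = 2, gri = 2,
                                              t50 = 1, .default = 1)))
    for (index in config$indices) {
      keep <- !is.na(idx[[index]])
      if (length(unique(idx$treatment_id[keep])) >= 2) {
        cmp <- compare_groups(idx[[index]][keep], idx$treatment_id[keep],
                              design = "unrelated", alpha = config$alpha)
        ctr <- cmp$contrasts
        ctr$letters_group1 <- cmp$letters[ctr$group1]
        ctr$letters_group2 <- cmp$letters[ctr$group2]
        emit("compare", paste0("compare_", index), ctr)
      }
    }
  }
  if (!is.null(config$cut_test)) {
    ct <- read_cut_test(config$cut_test)
    emit("cut_test", "cut_test_summary", data.frame(
      class = c("viable", "empty", "dead"),
      mean_pct = c(mean(ct$pct_viable), mean(ct$pct_empty),
                   mean(ct$pct_dead)),
      sd_pct = c(stats::sd(ct$pct_viable), stats::sd(ct$pct_empty),
                 stats::sd(ct$pct_dead))
    ))
  }
  if (!is.null(config$climate)) {
    clim <- read_climate_series(config$climate)
    emit("climate", "climate_windows",
         summarize_windows(clim, config$windows))
  }
  if (!is.null(config$landcover)) {
    lc <- read_landcover(config$landcover)
    if (!is.null(config$crosswalk)) {
      lc <- apply_crosswalk(lc, read_crosswalk(config$crosswalk))
    }
    years <- sort(unique(lc$year))
    comp <- do.call(rbind, lapply(years, function(y) composition(lc, y)))
    emit("landcover", "composition", comp)
    emit("landcover", "rollup_level1",
         do.call(rbind, lapply(years, function(y) rollup_level1(lc, y))))
    if (length(years) >= 2) {
      emit("landcover", "change_first_last",
           change_matrix(lc, years[1], years[length(years)]))
    }
  }
  if (!is.null(config$esa)) {
    es <- esa_summary(read_esa(config$esa))
    emit("esa", "esa_deltas", es$deltas)
    emit("esa", "esa_affected", es$affected)
  }

  manifest <- list(
    package = "seedtrends",
    version = as.character(utils::packageVersion("seedtrends")),
    seed = config$seed,
    alpha = config$alpha,
    inputs = Filter(Negate(is.null),
                    config[c("schedules", "dishes", "cut_test", "climate",
                             "landcover", "crosswalk", "esa")]),
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
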