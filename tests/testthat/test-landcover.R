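lc_fixture <- function() read_landcover(seedtrends_example("landcover_areas.csv"))

test_that("published composition percentages are reproduced at 1 d.p.", {
  lc <- lc_fixture()
  printed_1990 <- c(
    "1.1.1" = 0.5, "1.1.2" = 1.0, "2.1.1" = 1.6, "2.1.2" = 0.0,
    "2.2.1" = 0.0, "2.2.2" = 20.4, "2.2.3" = 9.4, "2.3.1" = 0.0,
    "2.4.1" = 0.5, "2.4.2" = 0.3, "2.4.3" = 3.8, "3.1.1" = 21.5,
    "3.1.2" = 0.2, "3.1.3" = 1.9, "3.2.1" = 10.1, "3.2.2" = 7.4,
    "3.2.3" = 3.6, "3.2.4" = 15.6, "3.3.2" = 0.2, "3.3.3" = 1.7,
    "5.1.1" = 0.3
  )
  comp <- composition(lc, 1990)
  got <- round(comp$share_pct[match(names(printed_1990), comp$class_code)], 1)
  expect_equal(unname(got), unname(printed_1990))

  comp18 <- composition(lc, 2018)
  expect_equal(round(comp18$share_pct[comp18$class_code == "2.4.3"], 1), 30.2)
  expect_equal(round(comp18$share_pct[comp18$class_code == "3.1.1"], 1), 22.0)
  expect_equal(round(comp18$share_pct[comp18$class_code == "3.3.3"], 1), 13.6)
})

test_that("recorded shares sum to 100 for every year", {
  lc <- lc_fixture()
  for (y in unique(lc$year)) {
    expect_equal(sum(composition(lc, y)$share_pct, na.rm = TRUE), 100,
                 tolerance = 1e-3)
  }
  sim <- simulate_landcover(seed = 3)
  for (y in unique(sim$year)) {
    expect_equal(sum(composition(sim, y)$share_pct), 100, tolerance = 1e-9)
  }
  expect_error(composition(lc_fixture(), 1975), "not present")
})

test_that("an explicit territory total gives the alternative 1958 reading", {
  lc <- lc_fixture()
  default_read <- composition(lc, 1958)
  override <- composition(lc, 1958, total_ha = 42480)
  arable_def <- default_read$share_pct[default_read$class_code == "2.1.1"]
  arable_ovr <- override$share_pct[override$class_code == "2.1.1"]
  expect_equal(round(arable_def, 1), 32.3)  # printed-areas denominator
  expect_equal(round(arable_ovr, 1), 32.1)  # implied-territory denominator
})

test_that("level-1 rollup reproduces the published 2018 aggregates", {
  lc <- lc_fixture()
  r <- rollup_level1(lc, 2018)
  expect_equal(r$share_pct[r$level1 == "2"], 40.3, tolerance = 1e-9)
  expect_equal(r$share_pct[r$level1 == "3"], 58.1, tolerance = 1e-9)
  # unrounded reading differs only in the last decimal
  ru <- rollup_level1(lc, 2018, digits = NULL)
  expect_equal(ru$share_pct[ru$level1 == "2"], 40.25, tolerance = 0.01)
  # one class per level-1 group: rollup equals composition
  single <- data.frame(
    class_code = c("1.1.1", "2.1.1"), class_name = c("u", "a"),
    year = 2000, area_ha = c(25, 75)
  )
  expect_equal(rollup_level1(single, 2000, digits = NULL)$share_pct,
               composition(single, 2000)$share_pct)
  expect_error(rollup_level1(data.frame(
    class_code = "orchards", class_name = "o", year = 2000, area_ha = 10
  ), 2000), "crosswalk")
})

test_that("crosswalk conserves area and merges many-to-one classes", {
  tab <- data.frame(
    class_code = c("seminativo", "bosco ceduo", "bosco alto"),
    class_name = c("arable", "coppice", "high forest"),
    year = 1958, area_ha = c(120, 100, 50)
  )
  map <- data.frame(source_label = c("seminativo", "bosco ceduo", "bosco alto"),
                    clc_code = c("2.1.1", "3.1.1", "3.1.1"))
  out <- apply_crosswalk(tab, map)
  expect_equal(sort(out$class_code), c("2.1.1", "3.1.1"))
  expect_equal(out$area_ha[out$class_code == "3.1.1"], 150)
  expect_equal(sum(out$area_ha), sum(tab$area_ha))
  expect_error(apply_crosswalk(tab, map[1:2, ]), "unmapped")
  # identity map leaves a CLC-coded table unchanged
  lc <- lc_fixture()
  ident <- apply_crosswalk(lc, identity_crosswalk(lc))
  expect_equal(sum(ident$area_ha, na.rm = TRUE),
               sum(lc$area_ha, na.rm = TRUE))
  expect_setequal(ident$class_code, lc$class_code)
  c90 <- composition(ident, 1990)
  expect_equal(c90$share_pct, composition(lc, 1990)$share_pct)
})

test_that("change matrix reports deltas, antisymmetry and missing flags", {
  lc <- lc_fixture()
  ch <- change_matrix(lc, 2012, 2018)
  orchard <- ch[ch$class_code == "2.2.2", ]
  expect_equal(round(orchard$share_a, 1), 22.4)
  expect_equal(round(orchard$share_b, 1), 0.4)
  expect_equal(orchard$delta_pp, -22.0, tolerance = 0.05)
  moors <- ch[ch$class_code == "3.2.2", ]  # n.a. in 2012
  expect_true(moors$missing_data)
  expect_equal(moors$delta_pp, moors$share_b)
  back <- change_matrix(lc, 2018, 2012)
  expect_equal(back$delta_pp, -ch$delta_pp)
  expect_equal(back$delta_ha, -ch$delta_ha)
  expect_error(change_matrix(lc, 2018, 2018), "must differ")
})

test_that("land-cover validation catches structural errors", {
  bad <- data.frame(class_code = c("2.1.1", "2.1.1"), class_name = "x",
                    year = 2000, area_ha = c(1, 2))
  expect_error(validate_landcover(bad), "duplicate")
  bad2 <- data.frame(class_code = "2.1.1", class_name = "x", year = 2000,
                     area_ha = -3)
  expect_error(validate_landcover(bad2), "non-negative")
  bad3 <- data.frame(class_code = c("2.1.1", "3.1.1"), class_name = "x",
                     year = c(2000, 2006), area_ha = c(5, NA))
  expect_error(validate_landcover(bad3), "no recorded area")
})

test_that("ESA summary tracks class deltas and the affected aggregate", {
  esa <- read_esa(seedtrends_example("esa_shares_synthetic.csv"))
  out <- esa_summary(esa)
  na_rows <- out$deltas[out$deltas$esa_class == "not affected", ]
  d2000_2020 <- na_rows$delta_pp[na_rows$year_from == 2000]
  expect_equal(d2000_2020, -35)
  expect_equal(na_rows$share_from[na_rows$year_from == 2000], 70)
  # affected aggregate is the subset sum of fragile + critical by default
  for (y in unique(esa$year)) {
    expect_equal(out$affected$affected_pct[out$affected$year == y],
                 sum(esa$share_percent[esa$year == y &
                                         !esa$esa_class %in%
                                         c("not affected", "potential")]),
                 tolerance = 1e-9)
  }
  # configurable subset
  crit_only <- esa_summary(esa, affected_classes = c("critical 1",
                                                     "critical 2",
                                                     "critical 3"))
  expect_equal(crit_only$affected$affected_pct[crit_only$affected$year == 1960],
               5 + 3.7 + 25, tolerance = 1e-9)
  # one-class table: all deltas zero
  flat <- data.frame(esa_class = "not affected", year = c(2000, 2020),
                     share_percent = 100)
  expect_equal(suppressWarnings(esa_summary(flat))$deltas$delta_pp, 0)
  # shares off 100 warn
  off <- esa
  off$share_percent[1] <- off$share_percent[1] + 2
  expect_warning(validate_esa(off), "sum to 100")
  renorm <- suppressWarnings(validate_esa(off, renormalize = TRUE))
  expect_equal(sum(renorm$share_percent[renorm$year == 1960]), 100,
               tolerance = 1e-9)
})
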